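#' Imputation specification
#'
#' Parameters for the chained-equations imputer: number of completed
#' matrices `m`, the iteration cap and convergence tolerance of the
#' column-cycling, and the random seed (recorded in outputs so runs are
#' reproducible).
#'
#' @param method `"zero"` or `"mice"`.
#' @param m Number of imputations (completed matrices) for
#'   `method = "mice"`.
#' @param max_iter Maximum chained-equation cycles per imputation.
#' @param tol Stop cycling once the mean absolute change of imputed
#'   codes between cycles drops below this.
#' @param seed Integer seed for the imputation noise.
#' @return An object of class `ffq_impute_spec`.
#' @export
impute_spec <- function(method = c("mice", "zero"), m = 5L, max_iter = 10L,
                        tol = 1e-3, seed = 1L) {
  method <- match.arg(method)
  stopifnot(m >= 1L, max_iter >= 1L, tol > 0, is.numeric(seed))
  structure(list(method = method, m = as.integer(m),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "ffq_impute_spec")
}

#' Chained-equations imputation of unanswered questions
#'
#' Fills the missing (`NA`) cells of the columns outside `keep` by
#' iterated conditional modelling: each incomplete column is regressed
#' (ordinary least squares) on all other columns using the rows where it
#' is observed, missing entries are replaced by the prediction plus a
#' residual-scale noise draw, and the cycle repeats until the imputed
#' codes stabilise or `max_iter` is reached. Predictions are rounded to
#' the nearest valid frequency code and clipped to `[0, L-1]`, so the
#' completed matrices always feed the amount lookup legally. With
#' `spec$m > 1`, `m` completed matrices are returned; downstream amounts
#' are pooled by averaging (see [pool_imputations()]).
#'
#' Columns outside `keep` must be observed in at least some rows (e.g.
#' training-fold respondents stacked above the test fold); a column with
#' no observations at all cannot be conditioned on anything and raises
#' an error.
#'
#' @param answers Integer answer matrix with `NA` for missing cells;
#'   restricted to `keep` it must be complete.
#' @param keep Kept item tags (or an [feature_subset()]); must be
#'   non-empty.
#' @param spec An [impute_spec()].
#' @param n_levels Number of frequency codes `L` (codes `0 .. L-1`);
#'   default 8.
#' @return An object of class `ffq_imputations`: list with
#'   `imputations` (list of `m` completed matrices), `spec`, `keep`.
#' @export
mice_impute <- function(answers, keep, spec = impute_spec(), n_levels = 8L) {
  keep <- subset_items(keep)
  if (!length(keep))
    stop("keep set is empty: nothing to condition the imputation on",
         call. = FALSE)
  answers <- as.matrix(answers)
  storage.mode(answers) <- "double"
  if (anyNA(answers[, keep, drop = FALSE]))
    stop("kept columns contain missing answers", call. = FALSE)
  miss_cols <- colnames(answers)[colSums(is.na(answers)) > 0L]
  if (!length(miss_cols)) {
    out <- answers
    storage.mode(out) <- "integer"
    return(structure(list(imputations = replicate(spec$m, out,
                                                  simplify = FALSE),
                          spec = spec, keep = keep),
                     class = "ffq_imputations"))
  }
  fully_missing <- miss_cols[colSums(!is.na(answers[, miss_cols,
                                                    drop = FALSE])) == 0L]
  if (length(fully_missing))
    stop("column(s) with no observed values cannot be imputed: ",
         paste(fully_missing, collapse = ", "),
         "; stack reference (training) rows above the incomplete rows",
         call. = FALSE)
  # visit order: increasing missingness, questionnaire order breaking ties
  n_miss <- colSums(is.na(answers[, miss_cols, drop = FALSE]))
  miss_cols <- miss_cols[order(n_miss, match(miss_cols, colnames(answers)))]
  clip <- function(v) pmin(pmax(round(v), 0), n_levels - 1L)
  imputations <- withr::with_seed(spec$seed, lapply(seq_len(spec$m), function(im) {
    filled <- answers
    for (col in miss_cols) {
      obs <- !is.na(answers[, col])
      filled[!obs, col] <- clip(mean(answers[obs, col]))
    }
    for (iter in seq_len(spec$max_iter)) {
      prev <- filled[, miss_cols, drop = FALSE]
      for (col in miss_cols) {
        obs <- !is.na(answers[, col])
        predictors <- setdiff(colnames(filled), col)
        xo <- filled[obs, predictors, drop = FALSE]
        # drop constant predictors; OLS on the rest
        keep_p <- apply(xo, 2L, function(v) stats::var(v) > 0)
        if (!any(keep_p)) {
          mu <- mean(answers[obs, col])
          sigma <- stats::sd(answers[obs, col])
          pred <- rep(mu, sum(!obs))
        } else {
          fit <- stats::lm.fit(cbind(1, xo[, keep_p, drop = FALSE]),
                               answers[obs, col])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          sigma <- sqrt(mean(fit$residuals^2))
          pred <- drop(cbind(1, filled[!obs, predictors[keep_p],
                                       drop = FALSE]) %*% beta)
        }
        filled[!obs, col] <- clip(pred + stats::rnorm(sum(!obs), 0, sigma))
      }
      delta <- mean(abs(filled[, miss_cols, drop = FALSE] - prev))
      if (delta < spec$tol) break
    }
    storage.mode(filled) <- "integer"
    filled
  }))
  structure(list(imputations = imputations, spec = spec, keep = keep),
            class = "ffq_imputations")
}

#' Pool imputed matrices into amounts and scores
#'
#' For each target, the amount is computed on every completed matrix and
#' averaged over the `m` imputations; the pooled score is the cutoff
#' mapping of the pooled amount. (Rubin-style pooling of a deterministic
#' function of the completed data reduces to this average for point
#' prediction.)
#'
#' @param imp An `ffq_imputations` from [mice_impute()], or a single
#'   complete answer matrix.
#' @param qdef An [ffq_questionnaire()].
#' @return A data frame like [compute_ground_truth()]'s.
#' @export
pool_imputations <- function(imp, qdef) {
  if (!inherits(imp, "ffq_imputations"))
    return(compute_ground_truth(imp, qdef))
  mats <- imp$imputations
  rn <- rownames(mats[[1L]]) %||% as.character(seq_len(nrow(mats[[1L]])))
  records <- lapply(qdef$targets, function(t) {
    per_imp <- matrix(unlist(lapply(mats, amounts_for_target, target = t)),
                      nrow = nrow(mats[[1L]]))
    pooled <- rowMeans(per_imp)
    data.frame(respondent = rn, target = t$name,
               amount = pooled,
               score = amount_to_score(pooled, t$cutoffs),
               row.names = NULL)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
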