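#' Decision matrix for PROMETHEE ranking
#'
#' Alternatives (methods or question subsets) in rows, performance
#' measures in columns, with an orientation flag per measure saying
#' whether larger values are better (`"max"`: precision, recall, F1,
#' R2) or worse (`"min"`: MAE, MSE, RMSE).
#'
#' @param values Numeric matrix, alternatives x measures, with dimnames.
#' @param orientation Character vector (`"max"`/`"min"`), one per
#'   measure; default derived from measure names via
#'   [measure_orientation()].
#' @return Object of class `ffq_decision`.
#' @export
decision_matrix <- function(values, orientation = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("decision matrix must be finite", call. = FALSE)
  if (nrow(values) < 2L)
    stop("need at least 2 alternatives to rank", call. = FALSE)
  if (is.null(orientation))
    orientation <- measure_orientation(colnames(values))
  if (length(orientation) != ncol(values) ||
      !all(orientation %in% c("max", "min")))
    stop("orientation must be 'max'/'min', one per measure", call. = FALSE)
  structure(list(values = values, orientation = orientation),
            class = "ffq_decision")
}

#' PROMETHEE preference parameters
#'
#' @param Q Indifference threshold(s) of the V-shaped preference
#'   function, one per measure (recycled); `NULL` (default) sets each
#'   measure's Q to the largest observed pairwise difference on that
#'   measure, so the linear branch spans the observed range.
#' @param weights Per-measure non-negative weights; default all 1, which
#'   makes the preference index the plain mean of per-measure
#'   preferences.
#' @return Object of class `ffq_pref_params`.
#' @export
preference_params <- function(Q = NULL, weights = NULL) {
  if (!is.null(Q) && any(Q <= 0))
    stop("indifference thresholds Q must be positive", call. = FALSE)
  if (!is.null(weights) && (any(weights < 0) || all(weights == 0)))
    stop("weights must be non-negative and not all zero", call. = FALSE)
  structure(list(Q = Q, weights = weights), class = "ffq_pref_params")
}

#' V-shaped preference function
#'
#' `p(x) = 0` for `x <= 0`, `x / Q` on `(0, Q]`, and `1` beyond `Q`,
#' where `Q` is the indifference threshold — the greatest difference
#' still considered insignificant. Continuous and non-decreasing.
#'
#' @param d Numeric vector of performance differences.
#' @param Q Positive indifference threshold.
#' @return Preference degrees in `[0, 1]`.
#' @export
preference_value <- function(d, Q) {
  if (!is.numeric(Q) || length(Q) != 1L || Q <= 0)
    stop("Q must be a single positive number", call. = FALSE)
  pmin(pmax(d / Q, 0), 1)
}

#' Pairwise preference indices
#'
#' For each ordered pair of alternatives `(A, B)` and measure `j`, the
#' difference `d_j = q_j(A) - q_j(B)` (negated for minimizing measures)
#' goes through the V-shaped preference function, and the weighted
#' per-measure preferences are averaged into the index
#' `pi(A, B) = (1/N) * sum_j w_j P_j(A, B)`.
#'
#' @param D An [decision_matrix()].
#' @param params An [preference_params()].
#' @return Square matrix `pi` with zero diagonal, entries in `[0, 1]`
#'   for the default weights.
#' @export
pairwise_preferences <- function(D, params = preference_params()) {
  stopifnot(inherits(D, "ffq_decision"), inherits(params, "ffq_pref_params"))
  v <- D$values
  n_alt <- nrow(v)
  N <- ncol(v)
  w <- params$weights %||% rep(1, N)
  if (length(w) != N)
    stop("need one weight per measure (", N, "), got ", length(w),
         call. = FALSE)
  Q <- params$Q
  if (!is.null(Q)) {
    Q <- rep_len(Q, N)
  } else {
    Q <- vapply(seq_len(N), function(j) {
      span <- max(v[, j]) - min(v[, j])
      if (span > 0) span else 1
    }, numeric(1))
  }
  pi_mat <- matrix(0, n_alt, n_alt,
                   dimnames = list(rownames(v), rownames(v)))
  for (j in seq_len(N)) {
    d <- outer(v[, j], v[, j], "-")
    if (D$orientation[j] == "min") d <- -d
    pi_mat <- pi_mat + w[j] * preference_value(d, Q[j])
  }
  pi_mat <- pi_mat / N
  diag(pi_mat) <- 0
  pi_mat
}

#' Preference flows and fractional ranks
#'
#' The positive flow of alternative `i` is the mean preference of `i`
#' over the others, `phi+ = sum_x pi(i, x) / (n_alt - 1)`; the negative
#' flow is the mean preference of the others over `i`; the net flow is
#' their difference. Alternatives are ranked by decreasing net flow,
#' ties receiving the average of the ranks they span (fractional
#' ranking — two tied leaders both rank 1.5).
#'
#' @param pi_mat Square preference-index matrix with zero diagonal.
#' @return Object of class `ffq_flows`: data frame with columns
#'   `alternative`, `phi_plus`, `phi_minus`, `phi_net`, `rank`.
#' @export
flows <- function(pi_mat) {
  pi_mat <- as.matrix(pi_mat)
  if (nrow(pi_mat) != ncol(pi_mat))
    stop("preference matrix must be square", call. = FALSE)
  n_alt <- nrow(pi_mat)
  if (n_alt < 2L) stop("need at least 2 alternatives", call. = FALSE)
  phi_plus <- rowSums(pi_mat) / (n_alt - 1)
  phi_minus <- colSums(pi_mat) / (n_alt - 1)
  phi_net <- phi_plus - phi_minus
  out <- data.frame(
    alternative = rownames(pi_mat) %||% as.character(seq_len(n_alt)),
    phi_plus = phi_plus, phi_minus = phi_minus, phi_net = phi_net,
    rank = fractional_rank(phi_net), row.names = NULL)
  class(out) <- c("ffq_flows", class(out))
  out
}

# Fractional (average) ranks of x in DECREASING order: the best (largest)
# value ranks 1; tied values share the mean of the ranks they span.
fractional_rank <- function(x) {
  rank(-x, ties.method = "average")
}

#' Rank alternatives from a benchmark metric table
#'
#' Builds one decision matrix per context from the fold-mean `q_j`
#' values of a benchmark run and applies
#' [pairwise_preferences()] + [flows()]. With
#' `axis = "methods_per_subset"` the alternatives are the methods and
#' there is one context (decision matrix) per subset; with
#' `axis = "subsets_per_method"` the labels are swapped: the
#' alternatives are the subsets, one context per method.
#'
#' @param metrics An `ffq_metrics` table from [run_benchmark()].
#' @param axis `"methods_per_subset"` or `"subsets_per_method"`.
#' @param target Target name to rank for.
#' @param task `"classification"` or `"regression"` (their measure sets
#'   differ, so they are ranked separately).
#' @param params An [preference_params()].
#' @return Object of class `ffq_ranktable`: list with `ranks` (matrix
#'   methods x subsets of fractional ranks), `avg` (the "avg." fractional
#'   ranking of the mean ranks), `axis`, `target`, `task`, and `flows`
#'   (per-context flow tables, for audit).
#' @export
rank_alternatives <- function(metrics, axis = c("methods_per_subset",
                                                "subsets_per_method"),
                              target, task = c("classification",
                                               "regression"),
                              params = preference_params()) {
  axis <- match.arg(axis)
  task <- match.arg(task)
  m <- metrics[metrics$target == target & metrics$task == task, ]
  if (!nrow(m))
    stop("no metric records for target '", target, "', task '", task, "'",
         call. = FALSE)
  q <- stats::aggregate(value ~ model + subset + measure, m, mean)
  model_ids <- intersect(model_roster()$id, unique(q$model))
  subset_ids <- unique(metrics$subset)
  measures <- unique(q$measure)
  full <- expand.grid(model = model_ids, subset = subset_ids,
                      measure = measures, stringsAsFactors = FALSE)
  missing_cells <- !mapply(function(mo, su, me)
    any(q$model == mo & q$subset == su & q$measure == me),
    full$model, full$subset, full$measure)
  if (any(missing_cells))
    stop("metric table lacks cell(s): ",
         paste(utils::head(apply(full[missing_cells, ], 1L, paste,
                                 collapse = "/"), 5L), collapse = "; "),
         call. = FALSE)
  contexts <- if (axis == "methods_per_subset") subset_ids else model_ids
  flow_list <- list()
  ranks <- matrix(NA_real_, nrow = length(model_ids),
                  ncol = length(subset_ids),
                  dimnames = list(model_ids, subset_ids))
  for (ctx in contexts) {
    sel <- if (axis == "methods_per_subset") q$subset == ctx else q$model == ctx
    qc <- q[sel, ]
    alt_col <- if (axis == "methods_per_subset") "model" else "subset"
    alts <- if (axis == "methods_per_subset") model_ids else subset_ids
    vals <- matrix(NA_real_, length(alts), length(measures),
                   dimnames = list(alts, measures))
    for (i in seq_len(nrow(qc)))
      vals[qc[[alt_col]][i], qc$measure[i]] <- qc$value[i]
    fl <- flows(pairwise_preferences(decision_matrix(vals), params))
    flow_list[[ctx]] <- fl
    if (axis == "methods_per_subset")
      ranks[fl$alternative, ctx] <- fl$rank
    else
      ranks[ctx, fl$alternative] <- fl$rank
  }
  avg <- if (axis == "methods_per_subset")
    fractional_rank(-rowMeans(ranks))   # lower mean rank is better
  else
    fractional_rank(-colMeans(ranks))
  structure(list(ranks = ranks, avg = avg, axis = axis, target = target,
                 task = task, flows = flow_list),
            class = "ffq_ranktable")
}

#' @export
print.ffq_ranktable <- function(x, digits = 1L, ...) {
  cat("<ffq_ranktable> ", x$axis, " | target: ", x$target, " | task: ",
      x$task, "\n", sep = "")
  tab <- format_ranktable(x, digits)
  print(tab, quote = FALSE, right = TRUE)
  invisible(x)
}

# Aligned character table mirroring the published layout: subsets as
# columns, "avg." appended last (as a column for method rankings, as an
# "Average rank" row for subset rankings).
format_ranktable <- function(x, digits = 1L) {
  f <- function(v) formatC(v, format = "f", digits = digits)
  if (x$axis == "methods_per_subset") {
    cbind(f(x$ranks), avg. = f(x$avg))
  } else {
    rbind(f(x$ranks), `Average rank` = f(x$avg))
  }
}

#' Aggregate rank tables across targets
#'
#' Cell-wise mean of the per-target fractional ranks, followed by a
#' fractional re-ranking of the means along each ranking direction
#' (per subset column for method rankings, per method row for subset
#' rankings), including the "avg." ranking. Feeding a single table back
#' in reproduces it.
#'
#' @param tables List of conformable `ffq_ranktable` objects (same axis,
#'   task, alternatives and contexts; one per target).
#' @return An `ffq_ranktable` with `target = "overall"`.
#' @export
aggregate_ranks <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "ffq_ranktable")))
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(dimnames(t$ranks), dimnames(ref$ranks)) ||
        !identical(t$axis, ref$axis))
      stop("rank tables are not conformable", call. = FALSE)
  }
  mean_ranks <- Reduce(`+`, lapply(tables, `[[`, "ranks")) / length(tables)
  mean_avg <- Reduce(`+`, lapply(tables, `[[`, "avg")) / length(tables)
  if (ref$axis == "methods_per_subset") {
    ranks <- apply(mean_ranks, 2L, function(col) fractional_rank(-col))
    dimnames(ranks) <- dimnames(mean_ranks)
  } else {
    ranks <- t(apply(mean_ranks, 1L, function(row) fractional_rank(-row)))
    dimnames(ranks) <- dimnames(mean_ranks)
  }
  structure(list(ranks = ranks, avg = fractional_rank(-mean_avg),
                 axis = ref$axis, target = "overall", task = ref$task,
                 flows = NULL),
            class = "ffq_ranktable")
}
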