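#' Read an answer matrix from CSV
#'
#' The CSV dialect is a header row of item tags and one respondent per
#' row; an optional leading `respondent` column supplies row identifiers.
#' Cells may hold frequency-level labels (matched case-insensitively
#' against the scale), integer codes, or the missing token.
#'
#' @param path CSV path.
#' @param qdef The [ffq_questionnaire()] the answers belong to; column
#'   tags must be a subset of its items.
#' @param missing_token Cell content treated as missing (default: the
#'   empty cell). Missing cells become `NA` in the returned matrix.
#' @return An integer matrix (respondents x items) with `NA` marking
#'   missing answers; item tags as colnames, respondent ids as rownames.
#' @export
load_answers <- function(path, qdef, missing_token = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(inherits(qdef, "ffq_questionnaire"))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  ids <- NULL
  if (ncol(raw) && tolower(names(raw)[1L]) %in% c("respondent", "id")) {
    ids <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  unknown <- setdiff(names(raw), qdef$items)
  if (length(unknown))
    stop("answer file has unknown item tag(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(ids %||% as.character(seq_len(nrow(raw))),
                                names(raw)))
  for (j in seq_along(raw)) {
    cell <- raw[[j]]
    cell[cell == missing_token | is.na(cell)] <- NA
    codes <- tryCatch(resolve_codes(qdef$scale, cell), error = function(e) {
      bad <- which(!is.na(cell) &
                     vapply(cell, function(v)
                       inherits(tryCatch(resolve_codes(qdef$scale, v),
                                         error = identity), "error"),
                       logical(1)))
      stop("column '", names(raw)[j], "', row(s) ",
           paste(bad, collapse = ", "), ": ", conditionMessage(e),
           call. = FALSE)
    })
    out[, j] <- codes
  }
  validate_answers(out, qdef)
}

#' Validate an answer matrix against a questionnaire
#'
#' @param answers Matrix or data frame of integer codes (`NA` = missing),
#'   columns named by item tags.
#' @param qdef An [ffq_questionnaire()].
#' @return The validated integer matrix.
#' @export
validate_answers <- function(answers, qdef) {
  stopifnot(inherits(qdef, "ffq_questionnaire"))
  answers <- as.matrix(answers)
  storage.mode(answers) <- "integer"
  if (is.null(colnames(answers)))
    stop("answer matrix needs item-tag colnames", call. = FALSE)
  unknown <- setdiff(colnames(answers), qdef$items)
  if (length(unknown))
    stop("answer columns not in the questionnaire: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rng <- range(answers, na.rm = TRUE)
  L <- length(qdef$scale$levels)
  if (!all(is.na(answers)) && (rng[1L] < 0L || rng[2L] >= L))
    stop("answer codes must lie in 0..", L - 1L, call. = FALSE)
  if (is.null(rownames(answers)))
    rownames(answers) <- as.character(seq_len(nrow(answers)))
  answers
}

#' Write an answer matrix to CSV
#'
#' @param answers Integer answer matrix (`NA` = missing).
#' @param path Output path.
#' @param missing_token Token written for missing cells (default empty).
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers, path, missing_token = "") {
  df <- data.frame(respondent = rownames(answers) %||%
                     as.character(seq_len(nrow(answers))),
                   answers, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = missing_token)
  invisible(path)
}

#' Standardize answer codes to zero mean and unit variance
#'
#' Centres each column and scales to unit variance using the population
#' convention (variance divided by `n`), the usual scaler behaviour for
#' machine-learning preprocessing. Zero-variance columns are emitted as
#' all zeros with a warning, so downstream models never see non-finite
#' values. When `stats` from a previous fit are supplied they are applied
#' unchanged — the transform-only contract needed for cross-validation
#' test folds.
#'
#' @param x Numeric matrix (no missing values; impute first).
#' @param stats `NULL` to fit, or the `stats` element of a previous
#'   result to transform with frozen parameters.
#' @return List with `features` (the standardized matrix) and `stats`
#'   (list of per-column `mean` and `sd`).
#' @export
ffq_standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop("standardize requires complete data; impute missing answers first",
         call. = FALSE)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))
    if (any(sd_pop == 0))
      warning("zero-variance column(s) emitted as all zeros: ",
              paste(colnames(x)[sd_pop == 0], collapse = ", "),
              call. = FALSE)
    stats <- list(mean = mu, sd = sd_pop)
  } else {
    if (!setequal(names(stats$mean), colnames(x)))
      stop("supplied stats were fitted on a different item set",
           call. = FALSE)
    stats$mean <- stats$mean[colnames(x)]
    stats$sd <- stats$sd[colnames(x)]
  }
  sd_safe <- ifelse(stats$sd == 0, 1, stats$sd)
  features <- sweep(sweep(x, 2L, stats$mean), 2L, sd_safe, "/")
  features[, stats$sd == 0] <- 0
  list(features = features, stats = stats)
}
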