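#' Pearson correlation matrix between questionnaire items
#'
#' Standard Pearson coefficients per column pair. Zero-variance columns
#' (answers that never contributed data) get a correlation of 0 against
#' every other column — Pearson is undefined for them, and 0 keeps them
#' out of the redundancy removal. Since Pearson is invariant under
#' per-column affine maps, raw codes and standardized features give the
#' same matrix.
#'
#' @param features Numeric matrix with at least 2 rows, columns named by
#'   item tags.
#' @return A symmetric matrix with unit diagonal, class
#'   `ffq_correlation`.
#' @export
pearson_matrix <- function(features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 2L)
    stop("need at least 2 rows to estimate correlations", call. = FALSE)
  if (any(!is.finite(features)))
    stop("features must be finite", call. = FALSE)
  r <- suppressWarnings(stats::cor(features))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  structure(r, class = c("ffq_correlation", "matrix"))
}

#' A question subset produced by correlation thresholding
#'
#' @param tag Subset label, e.g. `"F1"`.
#' @param threshold The correlation threshold that produced it, or `NA`
#'   for the full set `F0`.
#' @param items Ordered item tags retained in the subset.
#' @param removed Data frame of audit triples (`kept`, `removed`, `r`)
#'   for the pass that produced this subset from the previous one.
#' @return An object of class `ffq_subset`.
#' @export
feature_subset <- function(tag, threshold, items,
                           removed = data.frame(kept = character(),
                                                removed = character(),
                                                r = numeric())) {
  structure(list(tag = tag, threshold = threshold,
                 items = as.character(items), removed = removed),
            class = "ffq_subset")
}

#' @export
print.ffq_subset <- function(x, ...) {
  cat("<ffq_subset> ", x$tag,
      if (!is.na(x$threshold)) paste0(" (TH=", x$threshold, ")"), ": ",
      length(x$items), " items\n", sep = "")
  invisible(x)
}

#' Build nested question subsets by correlation thresholding
#'
#' For each threshold `TH_i` of a strictly decreasing ladder, one member
#' of every remaining item pair whose correlation exceeds `TH_i` is
#' removed. Each subset `F_i` is built from the previous one
#' (`F_0` = all items), which makes the nesting
#' `F_0 ⊇ F_1 ⊇ ... ⊇ F_n` structurally guaranteed. Within
#' one pass, offending pairs are processed in decreasing `|r|`, skipping
#' pairs that already lost a member; the dropped member is chosen by
#' `rule`. Every removal is recorded as an audit triple.
#'
#' @param corr An [pearson_matrix()] result (or any symmetric correlation
#'   matrix with item dimnames).
#' @param thresholds Strictly decreasing numeric vector in (0, 1).
#' @param rule Which member of an offending pair to drop:
#'   `"later"` (default) drops the item later in questionnaire order;
#'   `"mean_abs_r"` drops the member with the higher mean absolute
#'   correlation to all other current items (ties broken by order).
#' @param use_abs Threshold on `|r|` (default `TRUE`); set `FALSE` to
#'   consider only positive correlations redundant.
#' @return List of `ffq_subset` objects `F0 .. Fn`, class `ffq_subsets`.
#' @export
build_subsets <- function(corr, thresholds, rule = c("later", "mean_abs_r"),
                          use_abs = TRUE) {
  rule <- match.arg(rule)
  r <- unclass(corr)
  items_all <- colnames(r)
  if (is.null(items_all))
    stop("correlation matrix needs item dimnames", call. = FALSE)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L || any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing", call. = FALSE)
  strength <- function(v) if (use_abs) abs(v) else v
  out <- list(feature_subset("F0", NA_real_, items_all))
  current <- items_all
  for (i in seq_along(thresholds)) {
    audit <- out[[1L]]$removed
    th <- thresholds[i]
    repeat_pairs <- which(upper.tri(r), arr.ind = TRUE)
    keep_rows <- items_all[repeat_pairs[, 1L]] %in% current &
      items_all[repeat_pairs[, 2L]] %in% current
    pairs <- repeat_pairs[keep_rows, , drop = FALSE]
    vals <- r[pairs]
    offend <- strength(vals) > th
    pairs <- pairs[offend, , drop = FALSE]
    vals <- vals[offend]
    ord <- order(-strength(vals), pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
    vals <- vals[ord]
    removed_now <- character()
    for (p in seq_len(nrow(pairs))) {
      a <- items_all[pairs[p, 1L]]
      b <- items_all[pairs[p, 2L]]
      if (a %in% removed_now || b %in% removed_now) next
      drop_item <- pick_removal(a, b, r, current, items_all, rule)
      keep_item <- if (drop_item == a) b else a
      removed_now <- c(removed_now, drop_item)
      audit <- rbind(audit, data.frame(kept = keep_item,
                                       removed = drop_item,
                                       r = vals[p]))
    }
    current <- setdiff(current, removed_now)
    out[[i + 1L]] <- feature_subset(paste0("F", i), th, current, audit)
  }
  structure(out, class = "ffq_subsets")
}

# Removal rule for one offending pair. "later": later questionnaire
# position goes; "mean_abs_r": the member more correlated on average
# with the other current items goes.
pick_removal <- function(a, b, r, current, items_all, rule) {
  if (rule == "later")
    return(if (match(a, items_all) > match(b, items_all)) a else b)
  others_a <- setdiff(current, a)
  others_b <- setdiff(current, b)
  ma <- mean(abs(r[a, others_a]))
  mb <- mean(abs(r[b, others_b]))
  if (ma > mb) a
  else if (mb > ma) b
  else if (match(a, items_all) > match(b, items_all)) a else b
}

#' @export
print.ffq_subsets <- function(x, ...) {
  for (s in x)
    cat(format(s$tag, width = 4),
        format(ifelse(is.na(s$threshold), "", s$threshold), width = 6),
        length(s$items), "items:",
        paste(s$items, collapse = ", "), "\n")
  invisible(x)
}

#' Write subsets (and their removal audit) as CSV
#'
#' @param subsets An `ffq_subsets` list.
#' @param path Two-column CSV (`subset`, `item`) output path.
#' @param audit_path Optional path for the removal audit
#'   (`subset`, `kept`, `removed`, `r`).
#' @return `path`, invisibly.
#' @export
write_subsets <- function(subsets, path, audit_path = NULL) {
  long <- do.call(rbind, lapply(subsets, function(s)
    if (length(s$items)) data.frame(subset = s$tag, item = s$items)
    else NULL))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(audit_path)) {
    audits <- do.call(rbind, lapply(subsets[-1L], function(s) {
      new_rows <- s$removed
      if (nrow(new_rows)) cbind(subset = s$tag, new_rows) else NULL
    }))
    utils::write.csv(audits, audit_path, row.names = FALSE)
  }
  invisible(path)
}

#' The published subset ladder of the ESFFFQ
#'
#' The five nested subsets obtained on the study cohort with thresholds
#' 0.40, 0.30, 0.25, 0.20 and 0.10 (19, 16, 10, 6 and 2 questions),
#' shipped as a regression fixture, preceded by the full 27-item `F0`.
#'
#' @return An `ffq_subsets` list `F0 .. F5`.
#' @export
esfffq_subsets <- function() {
  path <- system.file("extdata", "esfffq_subsets.csv",
                      package = "ffqreduce", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  qdef <- esfffq()
  ths <- c(F1 = 0.40, F2 = 0.30, F3 = 0.25, F4 = 0.20, F5 = 0.10)
  subsets <- c(list(feature_subset("F0", NA_real_, qdef$items)),
               lapply(names(ths), function(tag)
                 feature_subset(tag, ths[[tag]],
                                tab$item[tab$subset == tag])))
  structure(subsets, class = "ffq_subsets")
}
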