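#' Nutrient intake amount for one respondent and one target
#'
#' Sums the per-item gram contributions of the answered frequency codes
#' over the items the target's amount table covers. Example: with the
#' published vegetable table, salad at "1-2 times a day" (120 g) plus
#' vegetables at "4-6 times a week" (56.8 g) gives 176.8 g/day.
#'
#' @param row Named integer vector (or 1-row matrix) of frequency codes;
#'   names are item tags. Every item the target covers must be present
#'   and non-missing — impute first if it is not.
#' @param target An [ffq_target()].
#' @return Amount in grams/day.
#' @export
compute_amount <- function(row, target) {
  stopifnot(inherits(target, "ffq_target"))
  if (is.matrix(row)) {
    stopifnot(nrow(row) == 1L)
    row <- stats::setNames(as.integer(row[1L, ]), colnames(row))
  }
  covered <- rownames(target$amounts)
  absent <- setdiff(covered, names(row))
  if (length(absent))
    stop("target '", target$name, "': no answer for item(s) ",
         paste(absent, collapse = ", "), call. = FALSE)
  codes <- row[covered]
  if (anyNA(codes))
    stop("target '", target$name, "': missing answer for item(s) ",
         paste(covered[is.na(codes)], collapse = ", "),
         "; impute before scoring", call. = FALSE)
  if (any(codes < 0L | codes >= ncol(target$amounts)))
    stop("target '", target$name, "': answer code out of scale range",
         call. = FALSE)
  sum(target$amounts[cbind(match(covered, rownames(target$amounts)),
                           codes + 1L)])
}

#' Map a nutrient amount to a discrete diet-quality score
#'
#' Piecewise-constant mapping through the two cutoff boundaries; both
#' boundaries belong to the middle class (an amount of exactly 80 g or
#' 240 g under the vegetable cutoffs is "medium"). For a
#' `"higher_better"` target the classes are 1 (bad) / 2 (medium) /
#' 3 (good) in increasing amount; for `"lower_better"` the order is
#' reversed.
#'
#' @param amount Numeric vector of amounts in grams/day, all `>= 0`.
#' @param cutoffs An [ffq_cutoffs()].
#' @return Integer scores in `{1, 2, 3}`.
#' @export
amount_to_score <- function(amount, cutoffs) {
  stopifnot(inherits(cutoffs, "ffq_cutoffs"))
  amount <- as.numeric(amount)
  if (any(!is.finite(amount)) || any(amount < 0))
    stop("amounts must be finite and non-negative", call. = FALSE)
  b <- cutoffs$boundaries
  band <- ifelse(amount < b[1L], 1L, ifelse(amount <= b[2L], 2L, 3L))
  if (cutoffs$direction == "higher_better") band else 4L - band
}

#' Ground-truth amounts and scores from complete answers
#'
#' The deterministic scoring pipeline applied to the full questionnaire:
#' one record per respondent per target. These are the "true values"
#' that subset-based predictions are benchmarked against.
#'
#' @param answers Complete integer answer matrix (no `NA`).
#' @param qdef An [ffq_questionnaire()] with at least one target.
#' @return A data frame with columns `respondent`, `target`, `amount`,
#'   `score`.
#' @export
compute_ground_truth <- function(answers, qdef) {
  stopifnot(inherits(qdef, "ffq_questionnaire"))
  answers <- validate_answers(answers, qdef)
  if (anyNA(answers))
    stop("ground truth needs complete answers; found missing cells",
         call. = FALSE)
  if (!length(qdef$targets))
    stop("questionnaire defines no targets", call. = FALSE)
  records <- lapply(qdef$targets, function(t) {
    amounts <- amounts_for_target(answers, t)
    data.frame(respondent = rownames(answers), target = t$name,
               amount = amounts,
               score = amount_to_score(amounts, t$cutoffs),
               row.names = NULL)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

# Vectorised amount computation for a whole matrix (same sum as
# compute_amount per row, computed by column lookup).
amounts_for_target <- function(answers, target) {
  covered <- rownames(target$amounts)
  absent <- setdiff(covered, colnames(answers))
  if (length(absent))
    stop("target '", target$name, "': no answer column for ",
         paste(absent, collapse = ", "), call. = FALSE)
  acc <- numeric(nrow(answers))
  for (item in covered)
    acc <- acc + target$amounts[item, answers[, item] + 1L]
  unname(acc)
}

#' Zero imputation: unanswered questions as "rarely or never"
#'
#' Columns in `keep` are returned unchanged; every other column of the
#' questionnaire is set to code 0 for every respondent. Because amount
#' contributions are non-negative and zero at code 0, the resulting
#' amounts can only underestimate the true intake.
#'
#' @param answers Integer answer matrix; the kept columns must be
#'   complete.
#' @param keep Character vector of item tags to keep (or an
#'   [feature_subset()] object).
#' @return A complete answer matrix over the same columns.
#' @export
zero_impute <- function(answers, keep) {
  keep <- subset_items(keep)
  answers <- as.matrix(answers)
  bad <- setdiff(keep, colnames(answers))
  if (length(bad))
    stop("keep set contains unknown column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(answers[, keep, drop = FALSE]))
    stop("kept columns contain missing answers", call. = FALSE)
  out <- answers
  out[, setdiff(colnames(out), keep)] <- 0L
  storage.mode(out) <- "integer"
  out
}

# Accept either a character vector or an ffq_subset.
subset_items <- function(keep) {
  if (inherits(keep, "ffq_subset")) keep$items else as.character(keep)
}
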