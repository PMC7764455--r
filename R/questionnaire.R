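#' Frequency scale for a non-quantitative FFQ
#'
#' An ordered set of consumption-frequency levels. Level labels are stored
#' normalised (lower case, ASCII hyphens); codes run `0 .. L-1` in increasing
#' consumption, and code 0 must be the "rarely or never" level so that
#' zero imputation maps unanswered items to zero intake.
#'
#' @param levels Character vector of ordered level labels, lowest
#'   consumption first. At least 2 levels.
#' @return An object of class `ffq_scale` with elements `levels` and
#'   `codes` (integers `0 .. L-1`).
#' @seealso [esfffq_scale()] for the 8-level scale used by the ESFFFQ.
#' @export
ffq_scale <- function(levels) {
  levels <- normalize_label(levels)
  if (length(levels) < 2L)
    stop("a frequency scale needs at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("frequency scale labels must be unique", call. = FALSE)
  if (levels[1L] != "rarely or never")
    stop("level 0 of the scale must be 'rarely or never', got '",
         levels[1L], "'", call. = FALSE)
  structure(list(levels = levels, codes = seq_along(levels) - 1L),
            class = "ffq_scale")
}

#' @export
print.ffq_scale <- function(x, ...) {
  cat("<ffq_scale> ", length(x$levels), " levels: ",
      paste0(x$codes, "='", x$levels, "'", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The 8-level ESFFFQ consumption-frequency scale
#'
#' Levels from "rarely or never" (code 0) up to "5+ a day" (code 7).
#' @return An `ffq_scale` with 8 levels.
#' @export
esfffq_scale <- function() {
  ffq_scale(c("rarely or never", "less than once a week", "once a week",
              "2-3 times a week", "4-6 times a week", "1-2 times a day",
              "3-4 times a day", "5+ a day"))
}

# Lower-case, trim, collapse whitespace, unify unicode dashes to '-'.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[‐‑‒–—]", "-", x)
  gsub("[[:space:]]+", " ", x)
}

#' Resolve frequency labels or codes against a scale
#'
#' @param scale An [ffq_scale()].
#' @param x Character vector of level labels (matched case-insensitively,
#'   dashes unified) or integers/strings of valid codes.
#' @return Integer codes; `NA` input stays `NA`.
#' @export
resolve_codes <- function(scale, x) {
  stopifnot(inherits(scale, "ffq_scale"))
  out <- rep(NA_integer_, length(x))
  miss <- is.na(x)
  lab <- normalize_label(x[!miss])
  idx <- match(lab, scale$levels)
  # fall back to numeric codes for labels that are plain integers
  numeric_like <- is.na(idx) & grepl("^-?[0-9]+$", lab)
  idx[numeric_like] <- as.integer(lab[numeric_like]) + 1L
  bad <- is.na(idx) | idx < 1L | idx > length(scale$levels)
  if (any(bad))
    stop("unresolvable frequency value(s): ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  out[!miss] <- scale$codes[idx]
  out
}

#' Score cutoffs mapping a nutrient amount to a diet-quality class
#'
#' Two strictly increasing boundaries split the amount axis into three
#' classes. Both boundaries belong to the middle class (the printed
#' recommendation phrasing "80 g to 240 g" is inclusive). `direction`
#' says whether a larger amount is the better diet (vegetable, fiber,
#' protein) or the worse one (fat, sugar, salt).
#'
#' @param boundaries Numeric length-2, strictly increasing, in grams/day.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return An object of class `ffq_cutoffs`.
#' @export
ffq_cutoffs <- function(boundaries, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 2L || any(!is.finite(boundaries)) ||
      diff(boundaries) <= 0)
    stop("cutoff boundaries must be 2 strictly increasing finite numbers",
         call. = FALSE)
  structure(list(boundaries = boundaries, direction = direction),
            class = "ffq_cutoffs")
}

#' A scored target of the questionnaire
#'
#' Bundles the per-item, per-frequency amount contributions with the
#' score cutoffs for one nutrient or food-group target.
#'
#' @param name Target label, e.g. `"vegetable"`.
#' @param amounts Numeric matrix, rows = item tags (rownames), columns =
#'   frequency codes `0 .. L-1`. Each row must start at 0 and be
#'   non-decreasing and non-negative (consumption frequency can only add
#'   intake).
#' @param cutoffs An [ffq_cutoffs()].
#' @return An object of class `ffq_target`.
#' @export
ffq_target <- function(name, amounts, cutoffs) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(cutoffs, "ffq_cutoffs"))
  amounts <- as.matrix(amounts)
  if (is.null(rownames(amounts)))
    stop("target '", name, "': amount table needs item-tag rownames",
         call. = FALSE)
  if (anyDuplicated(rownames(amounts)))
    stop("target '", name, "': duplicate item tags in amount table",
         call. = FALSE)
  storage.mode(amounts) <- "double"
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("target '", name, "': amount contributions must be finite and ",
         "non-negative", call. = FALSE)
  if (any(amounts[, 1L] != 0))
    stop("target '", name, "': contribution at code 0 ('rarely or never') ",
         "must be 0", call. = FALSE)
  if (ncol(amounts) >= 2L && any(amounts[, -1L, drop = FALSE] <
                                 amounts[, -ncol(amounts), drop = FALSE]))
    stop("target '", name, "': contributions must be non-decreasing in ",
         "frequency code", call. = FALSE)
  structure(list(name = name, amounts = amounts, cutoffs = cutoffs),
            class = "ffq_target")
}

#' Questionnaire definition
#'
#' The full instrument: ordered item tags, the frequency scale and one or
#' more scored targets whose amount tables cover subsets of the items.
#'
#' @param items Character vector of unique item tags, in questionnaire
#'   order (the order is used as the deterministic tie-break when the
#'   subset builder drops one member of a correlated pair).
#' @param scale An [ffq_scale()].
#' @param targets List of [ffq_target()] objects with unique names.
#' @param name Optional instrument name.
#' @return An object of class `ffq_questionnaire`.
#' @export
ffq_questionnaire <- function(items, scale, targets = list(), name = "FFQ") {
  items <- as.character(items)
  if (anyDuplicated(items))
    stop("duplicate item tags: ",
         paste(unique(items[duplicated(items)]), collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(scale, "ffq_scale"))
  L <- length(scale$levels)
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, function(t) t$name, character(1))
  for (t in targets) {
    if (!inherits(t, "ffq_target"))
      stop("targets must be ffq_target objects", call. = FALSE)
    if (ncol(t$amounts) != L)
      stop("target '", t$name, "': amount table has ", ncol(t$amounts),
           " columns but the scale has ", L, " levels", call. = FALSE)
    unknown <- setdiff(rownames(t$amounts), items)
    if (length(unknown))
      stop("target '", t$name, "': amount table covers unknown item(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(targets)))
    stop("duplicate target names", call. = FALSE)
  structure(list(name = name, items = items, scale = scale, targets = targets),
            class = "ffq_questionnaire")
}

#' @export
print.ffq_questionnaire <- function(x, ...) {
  cat("<ffq_questionnaire> '", x$name, "': ", length(x$items), " items, ",
      length(x$scale$levels), "-level scale, targets: ",
      if (length(x$targets)) paste(names(x$targets), collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Read a questionnaire definition from a YAML file
#'
#' The schema is a mapping with keys `name`, `scale` (`levels:` list),
#' `items` (list of tags) and `targets` (list of mappings with `name`,
#' `direction`, `cutoffs` (two boundaries) and `amounts`, a mapping of
#' item tag to the per-frequency gram contributions). All structural
#' invariants are validated; violations name the offending field.
#'
#' @param path Path to a YAML questionnaire file.
#' @return An [ffq_questionnaire()].
#' @export
load_questionnaire <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (key in c("scale", "items"))
    if (is.null(doc[[key]]))
      stop("questionnaire file lacks required field '", key, "'",
           call. = FALSE)
  if (is.null(doc$scale$levels))
    stop("questionnaire file lacks field 'scale: levels'", call. = FALSE)
  scale <- ffq_scale(unlist(doc$scale$levels))
  targets <- lapply(doc$targets, function(t) {
    for (key in c("name", "cutoffs", "amounts"))
      if (is.null(t[[key]]))
        stop("target entry lacks required field '", key, "'", call. = FALSE)
    amounts <- do.call(rbind, lapply(t$amounts, as.numeric))
    rownames(amounts) <- names(t$amounts)
    ffq_target(t$name, amounts,
               ffq_cutoffs(unlist(t$cutoffs),
                           direction = t$direction %||% "higher_better"))
  })
  ffq_questionnaire(unlist(doc$items), scale, targets,
                    name = doc$name %||% "FFQ")
}

#' Write a questionnaire definition to a YAML file
#'
#' Inverse of [load_questionnaire()]; a written file parses back to an
#' identical structure.
#'
#' @param qdef An [ffq_questionnaire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(qdef, path) {
  stopifnot(inherits(qdef, "ffq_questionnaire"))
  doc <- list(
    name = qdef$name,
    scale = list(levels = as.list(qdef$scale$levels)),
    items = as.list(qdef$items),
    targets = unname(lapply(qdef$targets, function(t) {
      amounts <- lapply(seq_len(nrow(t$amounts)),
                        function(i) as.list(unname(t$amounts[i, ])))
      names(amounts) <- rownames(t$amounts)
      list(name = t$name,
           direction = t$cutoffs$direction,
           cutoffs = as.list(t$cutoffs$boundaries),
           amounts = amounts)
    })))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' The bundled ESFFFQ definition
#'
#' Loads the packaged 27-item Extended Short Form FFQ definition: the
#' 8-level frequency scale, the item list, and the published vegetable
#' target (per-frequency gram contributions for the `salad` and
#' `vegetables` items and the 80 g / 240 g score cutoffs). Amount tables
#' for the other targets are not published for this instrument; supply
#' them in your own definition file or generate synthetic ones with
#' [generate_amount_tables()]. Eight of the 27 item tags were
#' reconstructed from the parent instrument and are marked as such in the
#' fixture file.
#'
#' @return An [ffq_questionnaire()] with 27 items.
#' @export
esfffq <- function() {
  load_questionnaire(system.file("extdata", "esfffq.yaml",
                                 package = "ffqreduce", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
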