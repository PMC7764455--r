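#' Configuration for a synthetic FFQ cohort
#'
#' Describes the cohort the generator draws: ordinal answers arise from
#' a Gaussian copula — a latent multivariate normal row per respondent,
#' thresholded per item at cut-points that induce the marginal level
#' frequencies — which gives exact control over planted inter-item
#' correlation while keeping the answers valid frequency codes.
#'
#' @param n_respondents Cohort size. Default 289, the pooled size of the
#'   two study cohorts the generator emulates (92 + 197 adults).
#' @param items Item tags; default the 27 ESFFFQ items.
#' @param pairs Planted correlations: data frame (or list of triples)
#'   with columns `a`, `b`, `r` — latent correlation `r` in (-1, 1)
#'   between items `a` and `b`.
#' @param background_r Latent correlation between all remaining pairs
#'   (default 0).
#' @param marginal Probabilities of the `L` frequency levels (one vector
#'   recycled to every item, or a named list per item). Default: a
#'   mildly right-skewed 8-level marginal (most answers in the lower
#'   frequencies, as in real consumption data); this default is
#'   arbitrary since the real answer marginals are unpublished.
#' @param targets Per-target recipe used by [generate_amount_tables()]:
#'   named list, each entry a list with `items` (contributing tags),
#'   optional `weights` (per-item grams at the top frequency; default
#'   480 as in the published vegetable row), optional `direction`, and
#'   optional `preset = "vegetable"` to request the exact published
#'   vegetable table instead of a generated one.
#' @param noise Non-negative latent noise level; independent Gaussian
#'   noise of this standard deviation is mixed into the latent rows
#'   (then rescaled to unit variance), attenuating all planted
#'   correlations by `1 / (1 + noise^2)`.
#' @param seed Integer seed.
#' @return Object of class `ffq_synth_config`.
#' @export
synthetic_config <- function(n_respondents = 289L,
                             items = esfffq()$items,
                             pairs = NULL,
                             background_r = 0,
                             marginal = NULL,
                             targets = NULL,
                             noise = 0,
                             seed = 1L) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, function(p)
      data.frame(a = p[[1L]], b = p[[2L]], r = as.numeric(p[[3L]]))))
  if (is.null(pairs))
    pairs <- data.frame(a = character(), b = character(), r = numeric())
  stopifnot(n_respondents >= 2L, noise >= 0,
            abs(background_r) < 1, all(abs(pairs$r) < 1),
            all(pairs$a %in% items), all(pairs$b %in% items))
  if (is.null(marginal))
    marginal <- c(0.30, 0.20, 0.14, 0.11, 0.09, 0.07, 0.05, 0.04)
  if (!is.list(marginal)) marginal <- list(marginal)
  for (p in marginal)
    if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      stop("marginal level probabilities must be positive and sum to 1",
           call. = FALSE)
  if (is.null(targets)) {
    targets <- list(intake = list(items = items))
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 items = as.character(items), pairs = pairs,
                 background_r = background_r, marginal = marginal,
                 targets = targets, noise = noise,
                 seed = as.integer(seed)),
            class = "ffq_synth_config")
}

# Latent correlation matrix implied by the config; repaired to the
# nearest positive semi-definite correlation by eigenvalue clipping if
# the planted spec is not PSD (with a warning).
latent_correlation <- function(config) {
  p <- length(config$items)
  r <- matrix(config$background_r, p, p,
              dimnames = list(config$items, config$items))
  diag(r) <- 1
  for (i in seq_len(nrow(config$pairs))) {
    a <- config$pairs$a[i]; b <- config$pairs$b[i]
    r[a, b] <- r[b, a] <- config$pairs$r[i]
  }
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warning("planted correlation spec is not positive semi-definite; ",
            "repaired by eigenvalue clipping", call. = FALSE)
    vals <- pmax(ev$values, 1e-8)
    r <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    r <- stats::cov2cor(r)
    dimnames(r) <- list(config$items, config$items)
  }
  r
}

# The published per-frequency gram profile (salad/vegetables row of the
# vegetable table), normalised to its top level.
amount_profile <- function() {
  c(0, 4, 11.2, 28.8, 56.8, 120, 280, 480) / 480
}

#' The published vegetable target
#'
#' The exact vegetable amount table (salad and vegetables rows, 8
#' frequency levels) and score cutoffs (<80 g bad, 80-240 g medium,
#' >240 g good).
#'
#' @return An [ffq_target()].
#' @export
vegetable_target <- function() {
  grams <- c(0, 4, 11.2, 28.8, 56.8, 120, 280, 480)
  ffq_target("vegetable",
             rbind(salad = grams, vegetables = grams),
             ffq_cutoffs(c(80, 240), "higher_better"))
}

#' Generate per-target amount tables and cutoffs
#'
#' For each target recipe in the config, builds an amount table whose
#' per-item contribution follows the shape of the published vegetable
#' row (zero at "rarely or never", convex growth to the per-item weight
#' at the top frequency), and places the two score cutoffs at the 1/3
#' and 2/3 quantiles of the amount distribution induced by a
#' calibration cohort drawn under the config — so all three score
#' classes are populated. A `preset = "vegetable"` recipe returns the
#' published table verbatim.
#'
#' @param config An [synthetic_config()].
#' @param quantiles The two cutoff quantiles (default `c(1/3, 2/3)`).
#' @return Named list of [ffq_target()] objects.
#' @export
generate_amount_tables <- function(config, quantiles = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(config, "ffq_synth_config"))
  L <- length(config$marginal[[1L]])
  profile <- amount_profile()[seq_len(L)]
  calib <- draw_codes(config, n = 2000L, seed = config$seed + 777L)
  out <- list()
  for (name in names(config$targets)) {
    recipe <- config$targets[[name]]
    if (identical(recipe$preset, "vegetable")) {
      out[[name]] <- vegetable_target()
      next
    }
    its <- recipe$items
    if (!length(its))
      stop("target '", name, "' has no contributing items", call. = FALSE)
    w <- recipe$weights %||% rep(480, length(its))
    w <- rep_len(w, length(its))
    amounts <- outer(w, profile)
    rownames(amounts) <- its
    amt <- numeric(nrow(calib))
    for (k in seq_along(its))
      amt <- amt + amounts[k, calib[, its[k]] + 1L]
    b <- unname(stats::quantile(amt, quantiles))
    if (diff(b) <= 0) b <- b[1L] + c(0, 1e-6)
    out[[name]] <- ffq_target(name, amounts,
                              ffq_cutoffs(b, recipe$direction %||%
                                            "higher_better"))
  }
  out
}

# Draw an n x p matrix of ordinal codes from the latent copula.
draw_codes <- function(config, n = config$n_respondents,
                       seed = config$seed) {
  r <- latent_correlation(config)
  p <- length(config$items)
  z <- withr::with_seed(seed, {
    z0 <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = r)
    if (config$noise > 0) {
      eps <- matrix(stats::rnorm(n * p, 0, config$noise), n, p)
      (z0 + eps) / sqrt(1 + config$noise^2)
    } else z0
  })
  codes <- matrix(0L, n, p,
                  dimnames = list(as.character(seq_len(n)), config$items))
  for (j in seq_len(p)) {
    probs <- if (length(config$marginal) == 1L) config$marginal[[1L]]
             else config$marginal[[config$items[j]]]
    cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
    codes[, j] <- findInterval(z[, j], cuts)
  }
  codes
}

#' Generate a synthetic FFQ cohort with known structure
#'
#' Draws latent multivariate-normal rows under the planted correlation
#' structure, thresholds each item at the cut-points implied by its
#' marginal, assembles a questionnaire definition from
#' [generate_amount_tables()], and computes the deterministic
#' ground-truth amounts and scores through the scoring pipeline.
#' Identical config and seed give an identical cohort.
#'
#' @param config An [synthetic_config()].
#' @return Object of class `ffq_synthetic`: list with `answers`
#'   (complete code matrix), `qdef`, `truth` (ground-truth score
#'   records), `latent_corr`, `planted_pairs` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ffq_synth_config"))
  qdef <- ffq_questionnaire(
    config$items,
    ffq_scale(esfffq_scale()$levels[seq_len(length(config$marginal[[1L]]))]),
    generate_amount_tables(config),
    name = "synthetic FFQ")
  answers <- draw_codes(config)
  truth <- compute_ground_truth(answers, qdef)
  structure(list(answers = answers, qdef = qdef, truth = truth,
                 latent_corr = latent_correlation(config),
                 planted_pairs = config$pairs, config = config),
            class = "ffq_synthetic")
}

#' Mask the answers outside a kept question subset
#'
#' Kept columns are unchanged; every other column becomes missing —
#' the situation of a respondent who answers only a subset of the
#' questionnaire. Composing with [zero_impute()] on the same keep set
#' reproduces the zero-imputed matrix directly.
#'
#' @param answers Integer answer matrix.
#' @param keep Kept item tags (or an [feature_subset()]).
#' @return The matrix with `NA` outside `keep`.
#' @export
make_missing <- function(answers, keep) {
  keep <- subset_items(keep)
  answers <- as.matrix(answers)
  bad <- setdiff(keep, colnames(answers))
  if (length(bad))
    stop("keep set contains unknown column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- answers
  out[, setdiff(colnames(out), keep)] <- NA_integer_
  out
}

#' Write a synthetic cohort and its truth sidecar
#'
#' The answers go to the same CSV dialect [load_answers()] reads; the
#' sidecar (JSON) records the seed, planted pairs and latent
#' correlations so the cohort is auditable.
#'
#' @param cohort An `ffq_synthetic` from [generate_cohort()].
#' @param answers_path CSV output path.
#' @param sidecar_path Optional JSON sidecar path.
#' @return `answers_path`, invisibly.
#' @export
write_cohort <- function(cohort, answers_path, sidecar_path = NULL) {
  stopifnot(inherits(cohort, "ffq_synthetic"))
  write_answers(cohort$answers, answers_path)
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(
      list(seed = cohort$config$seed,
           n_respondents = cohort$config$n_respondents,
           planted_pairs = cohort$planted_pairs,
           background_r = cohort$config$background_r,
           latent_corr = cohort$latent_corr),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(answers_path)
}
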