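#' Experiment configuration
#'
#' One object that drives the full pipeline: where the questionnaire and
#' answers come from (a CSV or a synthetic cohort), the correlation
#' threshold ladder, the fold plan, the model roster and the PROMETHEE
#' parameters. A single `seed` fans out deterministically to the fold
#' plan (`seed`), the learners (`seed * 1000 + fold * 20 + learner`),
#' the imputation baseline (`seed * 100 + fold`) and the synthetic
#' generator (`seed`), so one integer reproduces the whole bundle.
#'
#' @param questionnaire An [ffq_questionnaire()] or a path to a YAML
#'   definition.
#' @param answers A complete answer matrix, a CSV path, or `NULL` to use
#'   `synthetic`.
#' @param synthetic An [synthetic_config()] used when `answers` is
#'   `NULL`; its questionnaire replaces `questionnaire`.
#' @param thresholds Strictly decreasing correlation thresholds in
#'   (0, 1).
#' @param targets Targets to benchmark (default all defined).
#' @param models Model ids from [model_roster()].
#' @param tasks Tasks to run.
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @param promethee An [preference_params()].
#' @param mice_m,mice_max_iter Chained-equations baseline parameters.
#' @param out_dir Output directory for the report bundle, or `NULL` to
#'   keep results in memory only.
#' @return Object of class `ffq_run_config`.
#' @export
run_config <- function(questionnaire = NULL, answers = NULL,
                       synthetic = NULL,
                       thresholds = c(0.40, 0.30, 0.25, 0.20, 0.10),
                       targets = NULL,
                       models = model_roster()$id,
                       tasks = c("classification", "regression"),
                       k = 5L, seed = 1L,
                       promethee = preference_params(),
                       mice_m = 5L, mice_max_iter = 10L,
                       out_dir = NULL) {
  if (is.null(answers) && is.null(synthetic))
    stop("provide either answers or a synthetic config", call. = FALSE)
  structure(list(questionnaire = questionnaire, answers = answers,
                 synthetic = synthetic, thresholds = thresholds,
                 targets = targets, models = models, tasks = tasks,
                 k = as.integer(k), seed = as.integer(seed),
                 promethee = promethee, mice_m = as.integer(mice_m),
                 mice_max_iter = as.integer(mice_max_iter),
                 out_dir = out_dir),
            class = "ffq_run_config")
}

#' Run the full questionnaire-shortening experiment
#'
#' Orchestrates load/generate -> score -> correlation subsets ->
#' cross-validated benchmark -> PROMETHEE ranking -> cross-target
#' aggregation. Per target and task it produces a methods-ranking table
#' (methods per subset) and a subsets-ranking table (subsets per
#' method); across targets it produces the overall best-method,
#' best-subset and per-subset tables. All intermediates (subsets with
#' removal audit, the tidy metric table, flows) are kept in the bundle
#' and, when `out_dir` is set, persisted as CSV plus rendered text
#' tables. Identical config and seed give an identical bundle.
#'
#' @param config An [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return Object of class `ffq_bundle`: list with `qdef`, `answers`,
#'   `truth`, `subsets`, `folds`, `metrics`, `rankings` (nested per
#'   target/axis/task), `overall` (per axis/task), `config`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ffq_run_config"))
  say <- function(...) if (!quiet) message("[ffqreduce] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # -- inputs ---------------------------------------------------------
  if (is.null(config$answers)) {
    say("generating synthetic cohort (n = ",
        config$synthetic$n_respondents, ")")
    cohort <- stage("simulate", generate_cohort(config$synthetic))
    qdef <- cohort$qdef
    answers <- cohort$answers
  } else {
    qdef <- config$questionnaire
    if (is.character(qdef)) qdef <- stage("load", load_questionnaire(qdef))
    answers <- config$answers
    if (is.character(answers))
      answers <- stage("load", load_answers(answers, qdef))
    answers <- stage("validate", validate_answers(answers, qdef))
  }
  targets <- config$targets %||% names(qdef$targets)
  say("scoring ground truth for ", length(targets), " target(s)")
  truth <- stage("score", compute_ground_truth(answers, qdef))
  # -- subsets --------------------------------------------------------
  say("building subsets at thresholds ",
      paste(config$thresholds, collapse = ", "))
  corr <- stage("correlate", pearson_matrix(answers))
  subsets <- stage("reduce", build_subsets(corr, config$thresholds))
  # -- benchmark ------------------------------------------------------
  plan <- make_folds(nrow(answers), config$k, config$seed)
  say("benchmarking ", length(intersect(config$models, model_roster()$id)),
      " models x ", length(subsets), " subsets x ", plan$k, " folds")
  metrics <- stage("benchmark", run_benchmark(
    answers, qdef, subsets, plan, targets = targets,
    tasks = config$tasks, models = config$models,
    mice = impute_spec(m = config$mice_m,
                       max_iter = config$mice_max_iter,
                       seed = config$seed)))
  # -- ranking --------------------------------------------------------
  say("PROMETHEE ranking")
  axes <- c("methods_per_subset", "subsets_per_method")
  rankings <- list()
  for (tg in targets)
    for (axis in axes)
      for (task in config$tasks)
        rankings[[tg]][[axis]][[task]] <- stage("rank", rank_alternatives(
          metrics, axis, tg, task, config$promethee))
  overall <- list()
  for (axis in axes)
    for (task in config$tasks)
      overall[[axis]][[task]] <- stage("aggregate", aggregate_ranks(
        lapply(rankings, function(r) r[[axis]][[task]])))
  bundle <- structure(list(qdef = qdef, answers = answers, truth = truth,
                           subsets = subsets, folds = plan,
                           metrics = metrics, rankings = rankings,
                           overall = overall, config = config),
                      class = "ffq_bundle")
  if (!is.null(config$out_dir)) {
    say("writing bundle to ", config$out_dir)
    stage("write", write_bundle(bundle, config$out_dir))
  }
  bundle
}

#' Persist a report bundle as CSV and rendered text tables
#'
#' @param bundle An `ffq_bundle` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_subsets(bundle$subsets, p("subsets.csv"), p("removals.csv"))
  utils::write.csv(bundle$metrics, p("metrics.csv"), row.names = FALSE)
  utils::write.csv(bundle$truth, p("ground_truth.csv"), row.names = FALSE)
  for (tg in names(bundle$rankings))
    for (axis in names(bundle$rankings[[tg]]))
      for (task in names(bundle$rankings[[tg]][[axis]])) {
        rt <- bundle$rankings[[tg]][[axis]][[task]]
        base <- paste(tg, axis, task, sep = "_")
        utils::write.csv(as.data.frame(format_ranktable(rt)),
                         p(paste0("ranks_", base, ".csv")))
        writeLines(utils::capture.output(print(rt)),
                   p(paste0("ranks_", base, ".txt")))
        fl <- do.call(rbind, lapply(names(rt$flows), function(ctx)
          cbind(context = ctx, rt$flows[[ctx]])))
        utils::write.csv(fl, p(paste0("flows_", base, ".csv")),
                         row.names = FALSE)
      }
  for (axis in names(bundle$overall))
    for (task in names(bundle$overall[[axis]])) {
      rt <- bundle$overall[[axis]][[task]]
      base <- paste("overall", axis, task, sep = "_")
      utils::write.csv(as.data.frame(format_ranktable(rt)),
                       p(paste0("ranks_", base, ".csv")))
      writeLines(utils::capture.output(print(rt)),
                 p(paste0("ranks_", base, ".txt")))
    }
  writeLines(c(paste0("seed: ", bundle$config$seed),
               paste0("folds: ", bundle$folds$k),
               paste0("thresholds: ",
                      paste(bundle$config$thresholds, collapse = ", ")),
               paste0("models: ",
                      paste(bundle$config$models, collapse = ", ")),
               paste0("R: ", R.version.string)),
             p("run_log.txt"))
  invisible(dir)
}

#' Recommend which questions to ask under a budget
#'
#' Questions are ordered by subset nesting — the innermost subset `F_n`
#' first, then the questions `F_{n-1}` adds, and so on — and truncated
#' at the budget, so an interrupted respondent always leaves the most
#' informative (least redundant) answers behind. The suggested model is
#' the best-ranked method for the largest subset fully covered by the
#' budget (when the budget falls strictly between two subsets, the
#' covered one is used).
#'
#' @param subsets An `ffq_subsets` list (e.g. from a bundle or
#'   [esfffq_subsets()]).
#' @param budget Maximum number of questions; must be at least the size
#'   of the innermost subset.
#' @param ranking Optional `ffq_ranktable` with
#'   `axis = "methods_per_subset"` (e.g.
#'   `bundle$overall$methods_per_subset$classification`) used to pick
#'   the model.
#' @return List with `questions` (ordered tags, length `<= budget`),
#'   `covered_subset` (tag of the largest fully covered subset) and
#'   `model` (best-ranked method id for it, or `NA` without a ranking).
#' @export
recommend_questions <- function(subsets, budget, ranking = NULL) {
  stopifnot(inherits(subsets, "ffq_subsets"))
  sizes <- vapply(subsets, function(s) length(s$items), integer(1))
  inner <- subsets[[which.min(sizes)]]
  if (budget < length(inner$items))
    stop("budget ", budget, " is below the innermost subset size; ",
         "minimum feasible budget is ", length(inner$items),
         call. = FALSE)
  ord <- order(sizes)   # innermost first
  questions <- character()
  for (i in ord)
    questions <- c(questions, setdiff(subsets[[i]]$items, questions))
  questions <- questions[seq_len(min(budget, length(questions)))]
  covered <- subsets[ord][sizes[ord] <= length(questions)]
  covered_subset <- covered[[length(covered)]]$tag
  model <- NA_character_
  if (!is.null(ranking)) {
    stopifnot(inherits(ranking, "ffq_ranktable"),
              ranking$axis == "methods_per_subset")
    col <- ranking$ranks[, covered_subset]
    model <- names(col)[which.min(col)]
  }
  list(questions = questions, covered_subset = covered_subset,
       model = model)
}
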