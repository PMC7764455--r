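#' Cross-validation fold plan
#'
#' A balanced k-fold partition of the respondents, drawn once and reused
#' for every model, subset and target so the comparison is fair.
#'
#' @param n Number of respondents.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the same `(n, k, seed)` always gives the
#'   same assignment.
#' @return Object of class `ffq_folds`: list with `k`, `seed` and
#'   `assignments` (integer fold id per respondent). Fold sizes differ
#'   by at most 1.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n < k) stop("cannot split ", n, " respondents into ", k, " folds",
                  call. = FALSE)
  assignments <- withr::with_seed(seed,
                                  sample(rep(seq_len(k), length.out = n)))
  structure(list(k = k, seed = as.integer(seed), assignments = assignments),
            class = "ffq_folds")
}

#' The benchmark model roster
#'
#' Eight learner families (run at library default settings — no
#' hyperparameter tuning, so the comparison between them stays fair)
#' plus the two statistical baselines. Each family has a classification
#' and a regression variant; the voting ensemble combines the other
#' seven by majority vote (classification) or prediction averaging
#' (regression).
#'
#' @return Data frame with columns `id`, `label`, `kind`
#'   (`"learner"`/`"baseline"`).
#' @export
model_roster <- function() {
  data.frame(
    id = c("linear_model", "knn", "tree", "svm", "bagging", "grad_boost",
           "random_forest", "voting", "zero_imputation",
           "multiple_imputation"),
    label = c("Logistic/Linear Regression", "K-Nearest Neighbors",
              "Decision Tree", "SVM", "Bagging", "Gradient Boosting",
              "Random Forest", "Voting Ensemble", "Zero imputation",
              "Multiple imputation"),
    kind = c(rep("learner", 8L), "baseline", "baseline"))
}

base_learners <- function() {
  setdiff(model_roster()$id[model_roster()$kind == "learner"], "voting")
}

# Fit one learner family and predict the test fold. Classification y is
# a factor (full class set as levels); regression y numeric. A training
# fold degenerate to a single class/value falls back to a constant
# predictor with a warning so the benchmark never aborts.
fit_predict <- function(family, xtr, ytr, xte, task, seed) {
  if (length(unique(as.character(ytr))) == 1L) {
    warning("degenerate training fold for ", family,
            ": single outcome value; predicting the constant",
            call. = FALSE)
    v <- if (task == "classification") as.character(ytr[1L]) else ytr[1L]
    return(rep(v, nrow(xte)))
  }
  dtr <- data.frame(.y = ytr, xtr, check.names = TRUE)
  dte <- data.frame(xte, check.names = TRUE)
  withr::with_seed(seed, {
    if (task == "classification") {
      pred <- switch(
        family,
        linear_model = {
          fit <- nnet::multinom(.y ~ ., dtr, trace = FALSE, maxit = 200L)
          as.character(stats::predict(fit, dte))
        },
        knn = {
          fit <- caret::knn3(x = xtr, y = ytr)
          as.character(stats::predict(fit, xte, type = "class"))
        },
        tree = {
          fit <- rpart::rpart(.y ~ ., dtr, method = "class")
          as.character(stats::predict(fit, dte, type = "class"))
        },
        svm = {
          fit <- e1071::svm(x = xtr, y = ytr)
          as.character(stats::predict(fit, xte))
        },
        bagging = {
          fit <- ipred::bagging(.y ~ ., dtr)
          as.character(stats::predict(fit, dte, type = "class"))
        },
        grad_boost = {
          fit <- xgboost::xgboost(as.matrix(xtr), droplevels(ytr),
                                  nrounds = 100L, nthreads = 1L)
          as.character(stats::predict(fit, as.matrix(xte),
                                      type = "class"))
        },
        random_forest = {
          fit <- randomForest::randomForest(x = xtr, y = ytr)
          as.character(stats::predict(fit, xte))
        },
        stop("unknown learner family: ", family, call. = FALSE))
      pred
    } else {
      switch(
        family,
        linear_model = {
          fit <- stats::lm(.y ~ ., dtr)
          unname(stats::predict(fit, dte))
        },
        knn = {
          fit <- caret::knnreg(x = xtr, y = ytr)
          unname(stats::predict(fit, xte))
        },
        tree = {
          fit <- rpart::rpart(.y ~ ., dtr, method = "anova")
          unname(stats::predict(fit, dte))
        },
        svm = {
          fit <- e1071::svm(x = xtr, y = ytr)
          unname(stats::predict(fit, xte))
        },
        bagging = {
          fit <- ipred::bagging(.y ~ ., dtr)
          unname(stats::predict(fit, dte))
        },
        grad_boost = {
          fit <- xgboost::xgboost(as.matrix(xtr), ytr,
                                  nrounds = 100L, nthreads = 1L)
          unname(stats::predict(fit, as.matrix(xte)))
        },
        random_forest = {
          fit <- randomForest::randomForest(x = xtr, y = ytr)
          unname(stats::predict(fit, xte))
        },
        stop("unknown learner family: ", family, call. = FALSE))
    }
  })
}

# Majority vote over classifier predictions (ties -> lowest label) /
# mean over regressor predictions.
combine_votes <- function(pred_list, task) {
  if (task == "regression")
    return(rowMeans(do.call(cbind, pred_list)))
  m <- do.call(cbind, pred_list)
  apply(m, 1L, function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1L]]
    sort(winners)[1L]
  })
}

#' Benchmark learners and baselines over subsets under shared folds
#'
#' For every (subset, target, fold) cell: the eight learners are fit on
#' the standardized kept columns of the training folds (scaler fitted on
#' the training rows only) against ground-truth scores (classification)
#' or amounts (regression) computed from the full questionnaire, and
#' evaluated on the test fold. The two baselines instead impute the
#' dropped columns of the test fold — zero imputation, or chained
#' equations conditioned on the training respondents' complete answers —
#' and run the deterministic scoring pipeline; they enter the metric
#' table like any other method. Per-fold metric values are recorded; the
#' fold mean is the `q_j` a decision matrix is later built from.
#'
#' @param answers Complete integer answer matrix over all questionnaire
#'   items.
#' @param qdef An [ffq_questionnaire()]; every target needs an amount
#'   table.
#' @param subsets An `ffq_subsets` list (see [build_subsets()]).
#' @param plan An [make_folds()] plan for `nrow(answers)` respondents.
#' @param targets Target names to benchmark (default: all in `qdef`).
#' @param tasks `"classification"`, `"regression"` or both (default).
#' @param models Model ids to run (default: the full [model_roster()]).
#' @param mice An [impute_spec()] for the multiple-imputation baseline.
#' @param average Class-averaging mode for classification metrics.
#' @return Data frame of class `ffq_metrics`: one row per
#'   (model, subset, target, task, fold, measure) with the metric
#'   `value`.
#' @export
run_benchmark <- function(answers, qdef, subsets, plan,
                          targets = names(qdef$targets),
                          tasks = c("classification", "regression"),
                          models = model_roster()$id,
                          mice = impute_spec(seed = plan$seed),
                          average = "weighted") {
  answers <- validate_answers(answers, qdef)
  if (anyNA(answers))
    stop("benchmark needs complete answers", call. = FALSE)
  stopifnot(inherits(plan, "ffq_folds"),
            length(plan$assignments) == nrow(answers))
  tasks <- match.arg(tasks, several.ok = TRUE)
  bad <- setdiff(models, model_roster()$id)
  if (length(bad))
    stop("unknown model id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  truth <- compute_ground_truth(answers, qdef)
  learners <- intersect(models, base_learners())
  rows <- list()
  for (s in subsets) {
    x_all <- answers[, s$items, drop = FALSE]
    for (fold in seq_len(plan$k)) {
      te <- plan$assignments == fold
      tr <- !te
      std <- ffq_standardize(x_all[tr, , drop = FALSE])
      xtr <- std$features
      xte <- ffq_standardize(x_all[te, , drop = FALSE], std$stats)$features
      base_records <- baseline_scores(answers, qdef, s, tr, te, mice,
                                      fold, models)
      for (tg in targets) {
        tr_truth <- truth[truth$target == tg, ]
        tr_truth <- tr_truth[match(rownames(answers), tr_truth$respondent), ]
        for (task in tasks) {
          y <- if (task == "classification")
            factor(tr_truth$score, levels = sort(unique(tr_truth$score)))
          else tr_truth$amount
          preds <- list()
          for (fam in learners)
            preds[[fam]] <- fit_predict(
              fam, xtr, y[tr], xte, task,
              seed = plan$seed * 1000L + fold * 20L + match(fam, base_learners()))
          if ("voting" %in% models)
            preds$voting <- combine_votes(preds[learners], task)
          for (b in intersect(models, c("zero_imputation",
                                        "multiple_imputation"))) {
            rec <- base_records[[b]]
            rec <- rec[rec$target == tg, ]
            rec <- rec[match(rownames(answers)[te], rec$respondent), ]
            preds[[b]] <- if (task == "classification")
              as.character(rec$score) else rec$amount
          }
          y_te <- y[te]
          for (mod in names(preds)) {
            vals <- if (task == "classification")
              classification_metrics(preds[[mod]], as.character(y_te),
                                     average = average)
            else regression_metrics(preds[[mod]], y_te)
            rows[[length(rows) + 1L]] <- data.frame(
              model = mod, subset = s$tag, target = tg, task = task,
              fold = fold, measure = names(vals), value = unname(vals))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_seed") <- plan$seed
  class(out) <- c("ffq_metrics", class(out))
  out
}

# Deterministic score records of the two baselines on the test fold.
baseline_scores <- function(answers, qdef, s, tr, te, mice_spec, fold,
                            models) {
  out <- list()
  if ("zero_imputation" %in% models) {
    z <- zero_impute(answers[te, , drop = FALSE], s$items)
    out$zero_imputation <- compute_ground_truth(z, qdef)
  }
  if ("multiple_imputation" %in% models) {
    dropped <- setdiff(colnames(answers), s$items)
    if (!length(dropped)) {
      out$multiple_imputation <- compute_ground_truth(
        answers[te, , drop = FALSE], qdef)
    } else {
      masked <- answers
      storage.mode(masked) <- "double"
      masked[te, dropped] <- NA_real_
      spec <- mice_spec
      spec$seed <- mice_spec$seed * 100L + fold
      imp <- mice_impute(masked, s$items, spec,
                         n_levels = length(qdef$scale$levels))
      imp$imputations <- lapply(imp$imputations,
                                function(m) m[te, , drop = FALSE])
      out$multiple_imputation <- pool_imputations(imp, qdef)
    }
  }
  out
}
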