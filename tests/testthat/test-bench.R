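# Small complete cohort + subset ladder reused across benchmark tests.
bench_fixture <- function(n = 40, seed = 17) {
  q <- toy_questionnaire()
  ans <- toy_answers(n = n, seed = seed)
  subsets <- list(feature_subset("F0", NA_real_, q$items),
                  feature_subset("F1", 0.4, c("a", "c")))
  class(subsets) <- "ffq_subsets"
  list(q = q, ans = ans, subsets = subsets)
}

test_that("fold plans are balanced, deterministic and exhaustive", {
  plan <- make_folds(10, 5, seed = 1)
  expect_identical(sort(unique(plan$assignments)), 1:5)
  expect_true(all(table(plan$assignments) == 2L))
  expect_identical(plan$assignments, make_folds(10, 5, seed = 1)$assignments)
  expect_false(identical(plan$assignments,
                         make_folds(10, 5, seed = 2)$assignments))
  sizes <- sort(as.integer(table(make_folds(289, 5, 3)$assignments)))
  expect_identical(sizes, c(57L, 58L, 58L, 58L, 58L))
  expect_error(make_folds(4, 5), "folds")
})

test_that("a tree memorizes a deterministic mapping on the training rows", {
  withr::local_seed(5)
  x <- matrix(rnorm(300), ncol = 3, dimnames = list(NULL, c("u", "v", "w")))
  y_cls <- factor(ifelse(x[, "u"] > 0, 1L, ifelse(x[, "v"] > 0, 2L, 3L)))
  pred <- ffqreduce:::fit_predict("tree", x, y_cls, x, "classification", 1)
  expect_equal(classification_metrics(pred, as.character(y_cls))[["F1"]], 1)
  pred_r <- ffqreduce:::fit_predict("knn", x, as.numeric(y_cls), x,
                                    "regression", 1)
  expect_lte(regression_metrics(pred_r, as.numeric(y_cls))[["MSE"]], 0.5)
})

test_that("degenerate single-class training folds fall back to a constant with a warning", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("u", "v")))
  y <- factor(rep(2L, 10), levels = 1:3)
  expect_warning(
    pred <- ffqreduce:::fit_predict("svm", x, y, x, "classification", 1),
    "degenerate")
  expect_identical(pred, rep("2", 10L))
})

test_that("the metric table has full cardinality and internally consistent values", {
  fx <- bench_fixture()
  plan <- make_folds(nrow(fx$ans), 4, seed = 2)
  models <- c("linear_model", "tree", "zero_imputation")
  metrics <- suppressWarnings(run_benchmark(
    fx$ans, fx$q, fx$subsets, plan, models = models))
  # |records| per model x measure = |subsets| x |targets| x folds
  counts <- table(metrics$model, metrics$measure)
  expect_true(all(counts == 2L * 2L * 4L))
  expect_setequal(unique(metrics$measure),
                  c("precision", "recall", "F1", "MAE", "MSE", "RMSE", "R2"))
  expect_true(all(is.finite(metrics$value)))
  # RMSE^2 == MSE record-wise
  wide <- merge(metrics[metrics$measure == "RMSE", ],
                metrics[metrics$measure == "MSE", ],
                by = c("model", "subset", "target", "task", "fold"))
  expect_equal(wide$value.x^2, wide$value.y)
  # deterministic under identical plan and models
  again <- suppressWarnings(run_benchmark(fx$ans, fx$q, fx$subsets, plan,
                                          models = models))
  expect_identical(metrics, again)
})

test_that("both baselines reproduce the ground truth exactly on the full question set", {
  fx <- bench_fixture(n = 30, seed = 23)
  plan <- make_folds(30, 3, seed = 4)
  f0_only <- structure(fx$subsets[1L], class = "ffq_subsets")
  metrics <- run_benchmark(fx$ans, fx$q, f0_only, plan,
                           models = c("zero_imputation",
                                      "multiple_imputation"))
  cls <- metrics[metrics$task == "classification", ]
  expect_true(all(cls$value == 1))
  reg_err <- metrics[metrics$measure %in% c("MAE", "MSE", "RMSE"), ]
  expect_true(all(reg_err$value == 0))
  expect_true(all(metrics$value[metrics$measure == "R2"] == 1))
})

test_that("the voting ensemble is the majority/mean of the other learners", {
  votes <- list(a = c("1", "2", "3"), b = c("1", "2", "1"),
                c = c("2", "3", "1"))
  expect_identical(ffqreduce:::combine_votes(votes, "classification"),
                   c("1", "2", "1"))
  # two-way tie resolves to the lowest label
  tie <- list(a = c("3"), b = c("1"))
  expect_identical(ffqreduce:::combine_votes(tie, "classification"), "1")
  nums <- list(a = c(1, 4), b = c(3, 0))
  expect_equal(ffqreduce:::combine_votes(nums, "regression"), c(2, 2))
})
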