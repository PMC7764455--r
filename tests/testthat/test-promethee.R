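test_that("the V-shaped preference function follows its piecewise definition", {
  expect_equal(preference_value(-0.3, 1), 0)
  expect_equal(preference_value(0, 1), 0)
  expect_equal(preference_value(0.5, 1), 0.5)
  expect_equal(preference_value(1, 1), 1)
  expect_equal(preference_value(2, 1), 1)
  # continuity and monotonicity across the branch points
  d <- seq(-1, 3, by = 0.01)
  v <- preference_value(d, 1.5)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(preference_value(1, 0), "positive")
})

test_that("pairwise preference indices saturate and vanish as expected", {
  vals <- rbind(A = c(F1 = 0.9, R2 = 0.8), B = c(F1 = 0.9, R2 = 0.8))
  D <- decision_matrix(vals, orientation = c("max", "max"))
  p <- pairwise_preferences(D, preference_params(Q = 0.1))
  expect_true(all(p == 0))
  vals["A", ] <- c(0.95, 0.9); vals["B", ] <- c(0.5, 0.4)
  p2 <- pairwise_preferences(decision_matrix(vals, c("max", "max")),
                             preference_params(Q = 0.1))
  expect_equal(p2["A", "B"], 1)
  expect_equal(p2["B", "A"], 0)
})

test_that("two-alternative flows match the hand evaluation", {
  p <- matrix(c(0, 0.1, 0.6, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  fl <- flows(p)
  expect_equal(fl$phi_net[fl$alternative == "A"], 0.5)
  expect_equal(fl$phi_net[fl$alternative == "B"], -0.5)
  expect_equal(fl$rank, c(1, 2))
  # all-zero preferences: everything tied at the middle rank
  z <- flows(matrix(0, 3, 3))
  expect_true(all(z$phi_net == 0))
  expect_true(all(z$rank == 2))
})

test_that("identical alternatives share a fractional rank such as 1.5", {
  vals <- rbind(zero = c(F1 = 1, precision = 1),
                mi = c(F1 = 1, precision = 1),
                learner = c(F1 = 0.7, precision = 0.72))
  fl <- flows(pairwise_preferences(decision_matrix(vals)))
  expect_equal(fl$rank[fl$alternative %in% c("zero", "mi")], c(1.5, 1.5))
  expect_equal(fl$rank[fl$alternative == "learner"], 3)
})

test_that("preference indices, flows and ranks match the brute-force oracle", {
  cases <- 0L
  for (seed in 1:100) {
    for (shape in list(c(3L, 2L), c(4L, 3L))) {
      withr::local_seed(seed * 10L + shape[1L])
      v <- matrix(rnorm(prod(shape)), shape[1L], shape[2L],
                  dimnames = list(paste0("M", seq_len(shape[1L])),
                                  paste0("q", seq_len(shape[2L]))))
      orient <- sample(c("max", "min"), shape[2L], replace = TRUE)
      Q <- runif(shape[2L], 0.2, 3)
      w <- if (seed %% 2L) NULL else runif(shape[2L], 0.1, 2)
      params <- preference_params(Q = Q, weights = w)
      p <- pairwise_preferences(decision_matrix(v, orient), params)
      expect_equal(p, oracle_pi(v, orient, Q, w))
      fl <- flows(p)
      want <- oracle_flows(p)
      expect_equal(fl$phi_net, want$net)
      expect_equal(fl$rank, want$rank)
      # flow conservation
      expect_lt(abs(sum(fl$phi_net)), 1e-9)
      # one-sided preference per measure: d and -d never both preferred
      for (j in seq_len(shape[2L])) {
        d <- outer(v[, j], v[, j], "-")
        expect_true(all(pmin(preference_value(d, Q[j]),
                             preference_value(-d, Q[j])) == 0))
      }
      cases <- cases + 1L
    }
  }
  expect_gte(cases, 200L)
})

test_that("scaling a measure and its Q together leaves preferences unchanged", {
  withr::local_seed(77)
  v <- matrix(runif(12), 4, 3, dimnames = list(paste0("M", 1:4),
                                               paste0("q", 1:3)))
  Q <- c(0.5, 1, 2)
  p1 <- pairwise_preferences(decision_matrix(v, rep("max", 3)),
                             preference_params(Q = Q))
  v2 <- v; v2[, 2L] <- v2[, 2L] * 37
  Q2 <- Q; Q2[2L] <- Q2[2L] * 37
  p2 <- pairwise_preferences(decision_matrix(v2, rep("max", 3)),
                             preference_params(Q = Q2))
  expect_equal(p1, p2)
})

test_that("weak dominance on every measure implies a no-worse net flow", {
  for (seed in 1:30) {
    withr::local_seed(seed)
    n <- sample(3:5, 1); N <- sample(2:4, 1)
    v <- matrix(rnorm(n * N), n, N,
                dimnames = list(paste0("M", 1:n), paste0("q", 1:N)))
    orient <- sample(c("max", "min"), N, replace = TRUE)
    # make M1 weakly dominate M2, strictly on measure 1
    v[1L, ] <- v[2L, ] + ifelse(orient == "max", 1, -1) *
      c(0.5, rep(0, N - 1L))
    fl <- flows(pairwise_preferences(decision_matrix(v, orient)))
    expect_gte(fl$phi_net[1L], fl$phi_net[2L])
  }
})

test_that("a single measure ranks identically to the orientation-aware sort", {
  for (orient in c("max", "min")) {
    withr::local_seed(42)
    v <- matrix(runif(6), 6, 1, dimnames = list(paste0("M", 1:6), "q1"))
    fl <- flows(pairwise_preferences(decision_matrix(v, orient)))
    want <- if (orient == "max") rank(-v[, 1L]) else rank(v[, 1L])
    expect_equal(fl$rank, unname(want))
  }
})

test_that("rank aggregation averages then re-ranks, and is idempotent and order-invariant", {
  mk <- function(ranks, avg) structure(
    list(ranks = ranks, avg = avg, axis = "methods_per_subset",
         target = "t", task = "classification", flows = NULL),
    class = "ffq_ranktable")
  r1 <- mk(cbind(F0 = c(M1 = 1, M2 = 2, M3 = 3)), c(M1 = 1, M2 = 2, M3 = 3))
  r2 <- mk(cbind(F0 = c(M1 = 2, M2 = 1, M3 = 3)), c(M1 = 2, M2 = 1, M3 = 3))
  agg <- aggregate_ranks(list(r1, r2))
  expect_equal(unname(agg$ranks[, "F0"]), c(1.5, 1.5, 3))
  expect_equal(unname(agg$avg), c(1.5, 1.5, 3))
  # single table: re-ranking its own ranks reproduces it
  expect_equal(aggregate_ranks(list(r1))$ranks, r1$ranks)
  # permuting target order changes nothing
  expect_equal(aggregate_ranks(list(r2, r1))$ranks, agg$ranks)
})

test_that("a dominating model tops every context and the average column", {
  fx_q <- toy_questionnaire()
  metrics <- expand.grid(model = c("linear_model", "tree", "svm"),
                         subset = c("F0", "F1"), target = "alpha",
                         task = "classification", fold = 1:2,
                         measure = c("precision", "recall", "F1"),
                         stringsAsFactors = FALSE)
  base <- c(linear_model = 0.9, tree = 0.6, svm = 0.75)
  metrics$value <- base[metrics$model] +
    ifelse(metrics$fold == 1, -0.01, 0.01)
  rt <- rank_alternatives(metrics, "methods_per_subset", "alpha",
                          "classification")
  expect_true(all(rt$ranks["linear_model", ] == 1))
  expect_equal(unname(rt$avg["linear_model"]), 1)
  expect_true(all(rt$ranks["tree", ] == 3))
  # swapped-label orientation: subsets ranked within each method
  metrics$value <- metrics$value + ifelse(metrics$subset == "F0", 0.05, 0)
  rs <- rank_alternatives(metrics, "subsets_per_method", "alpha",
                          "classification")
  expect_true(all(rs$ranks[, "F0"] == 1))
  expect_true(all(rs$ranks[, "F1"] == 2))
  expect_equal(rs$avg, c(F0 = 1, F1 = 2))
  # missing cells are named
  expect_error(rank_alternatives(metrics[metrics$model != "svm" |
                                           metrics$subset != "F1", ],
                                 "methods_per_subset", "alpha",
                                 "classification"),
               "lacks cell")
})
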