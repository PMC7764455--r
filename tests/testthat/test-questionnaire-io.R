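test_that("bundled ESFFFQ definition loads with 27 items and the published vegetable table", {
  q <- esfffq()
  expect_s3_class(q, "ffq_questionnaire")
  expect_length(q$items, 27L)
  expect_length(q$scale$levels, 8L)
  expect_identical(q$scale$levels[1L], "rarely or never")
  expect_identical(q$scale$levels[8L], "5+ a day")
  veg <- q$targets$vegetable
  expect_equal(unname(veg$amounts["salad", resolve_codes(q$scale, "once a week") + 1L]),
               11.2)
  # the two published rows are identical
  expect_equal(veg$amounts["salad", ], veg$amounts["vegetables", ])
  expect_equal(veg$cutoffs$boundaries, c(80, 240))
})

test_that("questionnaire definitions round-trip through YAML bit-exactly", {
  for (q in list(esfffq(), toy_questionnaire())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_questionnaire(q, path)
    expect_equal(load_questionnaire(path), q)
  }
})

test_that("invalid questionnaire structures are rejected with field context", {
  scale <- ffq_scale(c("rarely or never", "daily"))
  expect_error(ffq_target("t", rbind(a = c(0, -1)), ffq_cutoffs(c(1, 2))),
               "non-negative")
  expect_error(ffq_target("t", rbind(a = c(1, 2)), ffq_cutoffs(c(1, 2))),
               "code 0")
  expect_error(ffq_target("t", rbind(a = c(0, 5, 3)), ffq_cutoffs(c(1, 2))),
               "non-decreasing")
  expect_error(ffq_questionnaire(c("a", "a"), scale), "duplicate")
  expect_error(
    ffq_questionnaire("a", scale,
                      list(ffq_target("t", rbind(b = c(0, 1)),
                                      ffq_cutoffs(c(1, 2))))),
    "unknown item")
  expect_error(ffq_scale(c("often", "rarely or never")), "rarely or never")
  # a written file with a negative amount fails on load
  path <- withr::local_tempfile(fileext = ".yaml")
  write_questionnaire(toy_questionnaire(), path)
  txt <- readLines(path)
  i <- grep("^\\s*- 10(\\.0)?$", txt)[1L]
  txt[i] <- sub("10", "-10", txt[i])
  writeLines(txt, path)
  expect_error(load_questionnaire(path), "non-negative")
})

test_that("answer CSVs resolve labels, codes and missing tokens", {
  q <- esfffq()
  path <- system.file("extdata", "example_answers.csv", package = "ffqreduce")
  ans <- load_answers(path, q)
  expect_identical(dim(ans), c(3L, 4L))
  expect_identical(unname(ans["r1", ]), c(5L, 4L, 2L, 0L))
  expect_true(is.na(ans["r2", "juice"]))        # blank cell -> missing
  expect_identical(unname(ans["r3", ]), c(0L, 7L, 5L, 3L))  # raw codes
  # unknown label and unknown item tag are rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("salad", "weekly"), bad)
  expect_error(load_answers(bad, q), "weekly")
  writeLines(c("notanitem", "0"), bad)
  expect_error(load_answers(bad, q), "notanitem")
})

test_that("standardization follows the population-variance convention", {
  x <- cbind(v = c(0, 2, 4))
  out <- ffq_standardize(x)
  expect_equal(unname(out$features[, 1L]), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  expect_equal(unname(out$stats$sd), sqrt(8 / 3))
  # fitted output has mean 0 and unit population variance per column
  m <- toy_answers(n = 30)
  f <- ffq_standardize(m)$features
  expect_equal(unname(colMeans(f)), rep(0, 4L))
  expect_equal(unname(colMeans(f^2)), rep(1, 4L))
})

test_that("zero-variance columns standardize to all zeros with a warning", {
  x <- cbind(u = c(1, 1, 1), v = c(0, 1, 2))
  expect_warning(out <- ffq_standardize(x), "zero-variance")
  expect_equal(unname(out$features[, "u"]), c(0, 0, 0))
})

test_that("transform-only standardization applies frozen stats and is idempotent", {
  fitted <- ffq_standardize(toy_answers(n = 25, seed = 1))
  other <- toy_answers(n = 10, seed = 2)
  out <- ffq_standardize(other, fitted$stats)
  manual <- sweep(sweep(other, 2, fitted$stats$mean), 2, fitted$stats$sd, "/")
  expect_equal(out$features, manual)
  # re-applying a fit's own stats to the same matrix reproduces it
  again <- ffq_standardize(toy_answers(n = 25, seed = 1), fitted$stats)
  expect_equal(again$features, fitted$features)
  expect_error(ffq_standardize(other[, 1:2], fitted$stats), "different item set")
})
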