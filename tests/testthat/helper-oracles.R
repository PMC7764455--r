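# Independent brute-force oracles used to cross-check the package
# implementations. They are deliberately written differently from the
# package code (explicit loops, no shared helpers).

# PROMETHEE preference index by exhaustive pairwise looping.
oracle_pi <- function(values, orientation, Q, weights = NULL) {
  n <- nrow(values); N <- ncol(values)
  if (is.null(weights)) weights <- rep(1, N)
  p <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n)) for (ii in seq_len(n)) {
    if (i == ii) next
    acc <- 0
    for (j in seq_len(N)) {
      d <- values[i, j] - values[ii, j]
      if (orientation[j] == "min") d <- -d
      pj <- if (d <= 0) 0 else if (d <= Q[j]) d / Q[j] else 1
      acc <- acc + weights[j] * pj
    }
    p[i, ii] <- acc / N
  }
  p
}

# Flows and fractional ranks by explicit sums and pair counting.
oracle_flows <- function(p) {
  n <- nrow(p)
  plus <- minus <- numeric(n)
  for (i in seq_len(n)) {
    for (x in seq_len(n)) {
      if (x == i) next
      plus[i] <- plus[i] + p[i, x]
      minus[i] <- minus[i] + p[x, i]
    }
  }
  net <- (plus - minus) / (n - 1)
  rk <- numeric(n)
  for (i in seq_len(n))
    rk[i] <- 1 + sum(net > net[i]) + sum(net == net[i] & seq_len(n) != i) / 2
  list(net = net, rank = rk)
}

# Subset thresholding by repeatedly locating the strongest surviving
# offending pair (no sorted pair list, no skip bookkeeping).
oracle_subsets <- function(r, thresholds, use_abs = TRUE) {
  items <- colnames(r)
  strength <- function(v) if (use_abs) abs(v) else v
  current <- items
  out <- list(current)
  for (th in thresholds) {
    repeat {
      best <- NULL; best_v <- th
      for (a in current) for (b in current) {
        if (match(a, items) >= match(b, items)) next
        if (strength(r[a, b]) > best_v) {
          best <- c(a, b); best_v <- strength(r[a, b])
        }
      }
      if (is.null(best)) break
      drop <- if (match(best[1], items) > match(best[2], items))
        best[1] else best[2]
      current <- setdiff(current, drop)
    }
    out[[length(out) + 1]] <- current
  }
  out
}

# Confusion-matrix classification metrics, support-weighted.
oracle_classification <- function(pred, truth) {
  classes <- sort(unique(truth))
  p <- r <- f <- w <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(pred == cl & truth == cl)
    p[k] <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    r[k] <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f[k] <- if (p[k] + r[k] > 0) 2 * p[k] * r[k] / (p[k] + r[k]) else 0
    w[k] <- sum(truth == cl) / length(truth)
  }
  c(precision = sum(p * w), recall = sum(r * w), F1 = sum(f * w))
}

# A tiny complete questionnaire for unit tests: 4 items, 4-level scale,
# two targets with hand-set amount tables.
toy_questionnaire <- function() {
  scale <- ffq_scale(c("rarely or never", "sometimes", "often", "daily"))
  amounts_a <- rbind(a = c(0, 10, 20, 40), b = c(0, 5, 15, 30))
  amounts_b <- rbind(c = c(0, 1, 2, 4), d = c(0, 2, 4, 8))
  ffq_questionnaire(
    c("a", "b", "c", "d"), scale,
    list(ffq_target("alpha", amounts_a, ffq_cutoffs(c(20, 50))),
         ffq_target("beta", amounts_b, ffq_cutoffs(c(3, 8), "lower_better"))),
    name = "toy")
}

toy_answers <- function(n = 20, seed = 42, items = c("a", "b", "c", "d"),
                        n_levels = 4) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:(n_levels - 1), n * length(items), replace = TRUE),
                nrow = n, dimnames = list(NULL, items))
    storage.mode(m) <- "integer"
    m
  })
}
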