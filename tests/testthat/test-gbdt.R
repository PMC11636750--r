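test_that("min-max normalization maps endpoints and preserves order", {
  expect_equal(normalize01(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize01(c(0, 0.3, 1)), c(0, 0.3, 1))
  set.seed(1)
  y <- rnorm(20)
  expect_equal(order(normalize01(y)), order(y))
  expect_error(normalize01(rep(2, 5)), "constant")
})

test_that("GOSS keeps the exact top-gradient set and amplifies the rest", {
  set.seed(2)
  g <- rnorm(1000)
  full <- goss_sample(g, b = 1, c = 0.1)
  expect_equal(full$indices, 1:1000)
  expect_true(all(full$weights == 1))

  s <- goss_sample(g, b = 0.2, c = 0.1, seed = 1)
  expect_equal(sum(s$weights == 1), 200)
  expect_equal(sum(s$weights != 1), 100)
  expect_equal(unique(s$weights[s$weights != 1]), (1 - 0.2) / 0.1)
  top <- order(abs(g), decreasing = TRUE)[1:200]
  expect_setequal(s$indices[s$weights == 1], top)
  expect_error(goss_sample(g, b = 0.6, c = 0.6), "b \\+ c")
})

test_that("amplified sampled gradient sums are unbiased for the full sum", {
  set.seed(3)
  g <- rnorm(800)
  sums <- vapply(1:2000, function(s) {
    gs <- goss_sample(g, 0.2, 0.1, seed = s)
    sum(gs$weights * g[gs$indices])
  }, numeric(1))
  se <- sd(sums) / sqrt(2000)
  expect_lt(abs(mean(sums) - sum(g)), 3 * se)
})

test_that("variance gain with b = 1 equals the exact two-sum oracle", {
  set.seed(4)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 8), 50, 8)
    h <- rnorm(50)
    for (k in 1:8) {
      for (e in sort(X[, k])[-50]) {
        got <- variance_gain(X[, k], h, rep(1, 50), e, o = 50)
        l <- X[, k] <= e
        oracle <- (sum(h[l])^2 / sum(l) + sum(h[!l])^2 / sum(!l)) / 50
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("variance gain prefers the separating threshold and scales as s^2", {
  x <- c(1:10)
  h <- c(rep(1, 5), rep(-1, 5))
  g_best <- variance_gain(x, h, rep(1, 10), 5, o = 10)
  for (e in c(1:4, 6:9)) {
    expect_gt(g_best, variance_gain(x, h, rep(1, 10), e, o = 10))
  }
  expect_equal(variance_gain(x, 3 * h, rep(1, 10), 5, o = 10), 9 * g_best)
  expect_equal(variance_gain(x, h, rep(1, 10), 11, o = 10), -Inf)
})

test_that("GBDT fits separable data within its structural constraints", {
  set.seed(9)
  n <- 500
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  p <- gbdt_params(nti = 50, mdl = 20, nl = 31, md = 6, seed = 3)
  m <- fit_gbdt(X, y, p)
  acc <- mean((predict_proba(m, X) >= 0.5) == y)
  expect_gte(acc, 0.99)
  expect_true(all(diff(m$train_loss) <= 1e-9))  # loss never increases

  for (tr in m$trees) {
    leaves <- Filter(function(nd) nd$is_leaf, tr)
    expect_lte(length(leaves), p$nl)
    for (nd in leaves) {
      expect_gte(nd$n_rows, p$mdl)
      expect_lte(nd$depth, p$md)
    }
  }

  # JSON round trip preserves predictions
  path <- tempfile(fileext = ".json")
  write_gbdt(m, path)
  m2 <- read_gbdt(path)
  expect_equal(predict_proba(m2, X), predict_proba(m, X), tolerance = 1e-12)

  expect_error(fit_gbdt(X, rep(1, n), p), "degenerate")
  expect_error(fit_gbdt(X[1:30, ], y[1:30], p), "MDL")
})
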