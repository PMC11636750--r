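test_that("rotation matrix has the block form and is orthogonal", {
  expect_equal(rotation_matrix(2), matrix(c(0, 1, -1, 0), 2))
  for (n in 2:10) {
    R <- rotation_matrix(n)
    expect_equal(R %*% t(R), diag(n), tolerance = 1e-12)
    # block structure: first row (0 ... 0 -1), identity below-left
    expect_equal(R[1, ], c(rep(0, n - 1), -1))
    expect_equal(R[2:n, 1:(n - 1), drop = FALSE], diag(n - 1))
  }
  R2 <- rotation_matrix(2)
  expect_equal(R2 %*% R2 %*% R2 %*% R2, diag(2))
  expect_error(rotation_matrix(1), ">= 2")
})

test_that("step rate follows the periodic-descent and convergence schedules", {
  pd <- spiral_config(dim = 5, k_max = 100, delta = 1e-3,
                      mode = "periodic_descent")
  expect_equal(step_rate(5, pd), 0.001^0.01, tolerance = 1e-10)
  expect_equal(round(step_rate(5, pd), 5), 0.93325)

  cv <- spiral_config(dim = 7, k_max = 100, delta = 0.5, mode = "convergence")
  expect_equal(step_rate(10, cv, k_star = 10), 1)
  expect_equal(step_rate(10 + 2 * 7 - 1, cv, k_star = 10), 1)
  expect_equal(step_rate(10 + 2 * 7, cv, k_star = 10), 0.5^(1 / 14))
  expect_error(spiral_config(delta = 0), "delta")
})

test_that("spiral steps rotate and contract points about the center", {
  R <- rotation_matrix(3)
  center <- c(0.5, 0.5, 0.5)
  pts <- rbind(center, c(0.9, 0.1, 0.4), c(0.2, 0.8, 0.6))
  moved <- spiral_step(pts, center, 1, R)
  expect_equal(moved[1, ], center)                     # center fixed
  d0 <- sqrt(rowSums(sweep(pts, 2, center)^2))
  d1 <- sqrt(rowSums(sweep(moved, 2, center)^2))
  expect_equal(d1, d0, tolerance = 1e-12)              # r = 1 preserves radii
  half <- spiral_step(pts, center, 0.5, R)
  dh <- sqrt(rowSums(sweep(half, 2, center)^2))
  expect_equal(dh, d0 / 2, tolerance = 1e-12)          # r = 0.5 halves radii
})

test_that("dependency degree matches the partition-enumeration oracle", {
  # 4-object toy table: attribute 1 separates the decision classes
  X <- cbind(a1 = c(1, 1, 2, 2), a2 = c(1, 2, 1, 2))
  d <- c(0, 0, 1, 1)
  expect_equal(gamma_dependency(X, d, c(TRUE, FALSE)), 1)
  expect_equal(gamma_dependency(X, d), 1)
  expect_equal(gamma_dependency(X, d, c(FALSE, FALSE)), 0)
  expect_equal(gamma_dependency(X, d, c(FALSE, TRUE)), 0)  # a2 mixes classes

  # brute-force oracle over random tables and random subsets
  set.seed(7)
  for (rep in 1:20) {
    Xr <- matrix(sample(1:3, 40 * 4, replace = TRUE), 40, 4)
    dr <- sample(0:1, 40, replace = TRUE)
    sub <- runif(4) < 0.6
    keys <- apply(Xr[, sub, drop = FALSE], 1, paste, collapse = "|")
    if (!any(sub)) keys <- rep("all", 40)
    pos <- sum(unlist(lapply(split(seq_len(40), keys), function(ix) {
      if (length(unique(dr[ix])) == 1) length(ix) else 0
    })))
    expect_equal(gamma_dependency(Xr, dr, sub), pos / 40)
  }
})

test_that("dependency is monotone under attribute refinement and bounded", {
  set.seed(8)
  for (rep in 1:200) {
    X <- matrix(sample(1:3, 30 * 5, replace = TRUE), 30, 5)
    d <- sample(0:1, 30, replace = TRUE)
    sub <- runif(5) < 0.5
    g0 <- gamma_dependency(X, d, sub)
    expect_gte(g0, 0); expect_lte(g0, 1)
    add <- which(!sub)
    if (length(add)) {
      a <- add[1]
      expect_gte(gamma_dependency(X, d, replace(sub, a, TRUE)), g0 - 1e-12)
    }
  }
})

test_that("exhaustive reduct finds minimal subsets and drops duplicates", {
  X <- cbind(a = c(1, 1, 2, 2, 3, 3), b = c(1, 2, 1, 2, 1, 2))
  d <- c(0, 0, 1, 1, 0, 0)
  r <- exhaustive_reduct(X, d)
  expect_equal(which(r), 1L)  # single informative attribute

  Xd <- cbind(X[, 1], X[, 1], X[, 2])  # duplicated informative column
  r2 <- exhaustive_reduct(Xd, d)
  expect_equal(sum(r2), 1L)
  expect_equal(gamma_dependency(Xd, d, r2), gamma_dependency(Xd, d))
  expect_error(exhaustive_reduct(matrix(0, 2, 15), c(0, 1)), "refused")
})

test_that("the spiral selector recovers a planted minimal reduct", {
  tab <- planted_reduct_table()
  oracle <- exhaustive_reduct(tab$X, tab$d)
  expect_equal(which(oracle), c(1L, 2L))
  hits <- 0
  for (s in 1:5) {
    b <- select_features(tab$X, tab$d, spiral_config(m = 30, k_max = 60, seed = s))
    if (identical(as.logical(b), as.logical(oracle))) hits <- hits + 1
    expect_equal(attr(b, "gamma"), gamma_dependency(tab$X, tab$d))
    expect_true(all(diff(attr(b, "fitness")) >= 0))  # incumbent retained
  }
  expect_gte(hits, 4)

  b1 <- select_features(tab$X, tab$d, spiral_config(m = 20, k_max = 30, seed = 3))
  b2 <- select_features(tab$X, tab$d, spiral_config(m = 20, k_max = 30, seed = 3))
  expect_identical(b1, b2)

  expect_error(select_features(matrix(1, 10, 3), rep(0:1, 5)), "constant")
})

test_that("equal-frequency discretization yields balanced integer bins", {
  set.seed(9)
  x <- cbind(u = runif(100), v = rnorm(100), const = rep(2, 100))
  d <- discretize_features(x, bins = 4)
  expect_true(all(d[, 1] %in% 1:4))
  expect_true(all(table(d[, 1]) == 25))
  expect_true(all(d[, 3] == 1L))
})
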