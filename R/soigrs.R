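# Hybrid spiral-optimization / generalized-rough-set feature selection.
#
# The spiral search moves m candidate points in [0,1]^n about the incumbent
# best (x <- c + r * R %*% (x - c)) with the block rotation matrix R and a
# step rate r(k) from either the periodic-descent or the convergence
# schedule.  Points are binarized at 0.5 into feature subsets and scored by
# the rough-set dependency degree gamma (positive-region fraction) traded
# against subset size.

#' Block rotation matrix used by the spiral search
#'
#' The n x n composition `[[0_{n-1}^T, -1], [I_{n-1}, 0_{n-1}]]`: the first
#' row is `(0, ..., 0, -1)` and the remaining rows are the identity followed
#' by a zero column.  Orthogonal for every n.
#'
#' @param n Dimension (>= 2).
#' @return An n x n orthogonal matrix.
#' @export
rotation_matrix <- function(n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  R <- matrix(0, n, n)
  R[1, n] <- -1
  R[2:n, 1:(n - 1)] <- diag(n - 1)
  R
}

#' Spiral search configuration
#'
#' @param m Number of search points (>= 2).
#' @param dim Search dimension (number of features).
#' @param k_max Iteration budget.
#' @param delta Contraction parameter in (0, 1\]; the periodic-descent
#'   schedule uses `r = delta^(1/k_max)` throughout, the convergence schedule
#'   holds `r = 1` for `2n` iterations after each incumbent update at `k*`
#'   and contracts by `h = delta^(1/(2n))` otherwise (delta = 0.5 by
#'   default there).
#' @param mode `"convergence"` (default) or `"periodic_descent"`.
#' @param seed Integer seed.
#' @return Object of class `spiral_config`.
#' @export
spiral_config <- function(m = 30L, dim = 2L, k_max = 100L, delta = 0.5,
                          mode = c("convergence", "periodic_descent"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (m < 2) stop("`m` must be >= 2", call. = FALSE)
  if (delta <= 0 || delta > 1) stop("`delta` must lie in (0, 1]", call. = FALSE)
  structure(list(m = as.integer(m), dim = as.integer(dim),
                 k_max = as.integer(k_max), delta = delta, mode = mode,
                 seed = as.integer(seed)),
            class = "spiral_config")
}

#' Step rate r(k) of the spiral search
#'
#' Periodic descent: the constant `delta^(1/k_max)`.  Convergence: 1 while
#' `k* <= k <= k* + 2n - 1` (the window after the incumbent update at
#' iteration `k*`), and `h = delta^(1/(2n))` once `k >= k* + 2n`.
#'
#' @param k Current iteration (>= 0).
#' @param cfg A [spiral_config()].
#' @param k_star Iteration of the latest incumbent update (convergence mode).
#' @return Step rate in (0, 1\].
#' @export
step_rate <- function(k, cfg, k_star = 0L) {
  stopifnot(inherits(cfg, "spiral_config"), k >= 0)
  if (cfg$mode == "periodic_descent") {
    cfg$delta^(1 / cfg$k_max)
  } else {
    n <- cfg$dim
    if (k >= k_star && k <= k_star + 2 * n - 1) 1 else cfg$delta^(1 / (2 * n))
  }
}

#' One spiral update of all points about the incumbent center
#'
#' `x <- center + r * R %*% (x - center)` for every non-center point.
#'
#' @param points Matrix with one point per row.
#' @param center Incumbent best point (length = ncol(points)).
#' @param r Step rate.
#' @param R Rotation matrix from [rotation_matrix()].
#' @return Updated points matrix.
#' @export
spiral_step <- function(points, center, r, R) {
  d <- sweep(points, 2, center, `-`)
  sweep(r * d %*% t(R), 2, center, `+`)
}

#' Rough-set dependency degree of the decision on a feature subset
#'
#' Objects are partitioned into indiscernibility classes by the selected
#' (discretized) attributes; the positive region is the union of classes
#' whose members share one decision value, and
#' `gamma = |POS_B(d)| / |U|`.  The empty subset puts every object in one
#' class, so gamma is 1 only for a constant decision.
#'
#' @param table Data frame or matrix of integer-coded condition attributes.
#' @param decision Vector of decision values (one per object).
#' @param subset Logical or 0/1 vector selecting attributes (may be empty).
#' @return Dependency degree in \[0, 1\].
#' @export
gamma_dependency <- function(table, decision, subset = rep(TRUE, ncol(table))) {
  X <- as.matrix(table)
  subset <- as.logical(subset)
  stopifnot(length(subset) == ncol(X), length(decision) == nrow(X))
  n <- nrow(X)
  if (!any(subset)) {
    return(if (length(unique(decision)) <= 1) 1 else 0)
  }
  # deterministic collision-free row key: integer codes weighted by sqrt of
  # distinct primes (rationally independent, so distinct rows get distinct
  # keys up to floating precision far beyond the code magnitudes here)
  w <- sqrt(c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173, 179, 181,
              191, 193, 197, 199, 211, 223, 227, 229))
  k <- sum(subset)
  if (k > length(w)) stop("too many attributes for keyed grouping", call. = FALSE)
  key <- as.numeric(X[, subset, drop = FALSE] %*% w[seq_len(k)])
  g <- match(key, unique(key))
  d <- as.numeric(match(decision, unique(decision)))
  counts <- tabulate(g)
  s1 <- rowsum(d, g, reorder = TRUE)[, 1]
  s2 <- rowsum(d^2, g, reorder = TRUE)[, 1]
  pure <- counts * s2 == s1^2  # zero within-class decision variance
  sum(counts[pure]) / n
}

# Fitness of a binary mask: alpha * gamma + beta * (1 - |B|/n); empty masks
# are repaired before scoring.
subset_fitness <- function(bits, table, decision, alpha = 0.9, beta = 0.1) {
  alpha * gamma_dependency(table, decision, bits) + beta * (1 - mean(bits))
}

#' Discretize continuous features into equal-frequency bins
#'
#' @param x Data frame or matrix of numeric features.
#' @param bins Number of bins (constant columns stay single-binned).
#' @return Integer matrix of bin codes (1-based).
#' @export
discretize_features <- function(x, bins = 4L) {
  X <- as.matrix(x)
  out <- matrix(1L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE))
    if (length(qs) > 2) {
      out[, j] <- as.integer(cut(v, breaks = qs, include.lowest = TRUE))
    }
  }
  colnames(out) <- colnames(x)
  out
}

#' Select features by spiral search over rough-set dependency
#'
#' Search points live in \[0, 1\]^n and are binarized at 0.5; fitness is
#' `0.9 * gamma(B) + 0.1 * (1 - |B|/n)`, so dependency dominates and size
#' breaks ties.  One initial point is placed at the full subset so the
#' incumbent never scores below the full feature set; the remaining points
#' are uniform, resampled until the pairwise difference directions span the
#' space (full-rank initialization check).  The spiral contracts about the
#' incumbent with the configured step-rate schedule; the incumbent is only
#' replaced on strict improvement, so the best fitness is non-decreasing.
#' Deterministic for a fixed seed.
#'
#' @param table Integer-coded decision-table attributes (use
#'   [discretize_features()] for continuous features).
#' @param decision Decision attribute (binary labels).
#' @param cfg A [spiral_config()]; `cfg$dim` is overridden by `ncol(table)`.
#' @return Logical vector of length n (the selected subset, never empty),
#'   with attributes `fitness` (incumbent trace) and `gamma`.
#' @export
select_features <- function(table, decision, cfg = spiral_config()) {
  X <- as.matrix(table)
  n <- ncol(X)
  if (n < 2) stop("need at least two attributes", call. = FALSE)
  if (all(apply(X, 2, function(v) length(unique(v)) == 1))) {
    stop("all attributes constant: nothing to select", call. = FALSE)
  }
  cfg$dim <- n
  R <- rotation_matrix(n)
  with_seed(cfg$seed, {
    pts <- matrix(stats::runif(cfg$m * n), nrow = cfg$m)
    pts[1, ] <- 0.75  # full subset: anchors gamma at the full-set value
    for (attempt in 1:20) {  # Eq-15-style rank condition by rejection
      d0 <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ], `-`)
      if (qr(d0)$rank == min(dim(d0)) || nrow(d0) < 2) break
      pts[-1, ] <- matrix(stats::runif((cfg$m - 1) * n), nrow = cfg$m - 1)
    }
    to_bits <- function(p) {
      b <- p >= 0.5
      if (!any(b)) b[which.min(abs(p - 0.5))] <- TRUE  # repair empty mask
      b
    }
    # rough-set refinement of an incumbent: steepest-ascent single-attribute
    # flips (drop or add) while the dependency-weighted fitness improves;
    # this is the exploitation half of the hybrid, the spiral supplies the
    # global moves
    refine <- function(bits) {
      f0 <- subset_fitness(bits, X, decision)
      repeat {
        best_j <- 0L; best_gain <- 1e-12
        for (j in seq_len(n)) {
          cand <- bits; cand[j] <- !cand[j]
          if (!any(cand)) next
          fj <- subset_fitness(cand, X, decision)
          if (fj - f0 > best_gain) {
            best_gain <- fj - f0; best_j <- j
          }
        }
        if (best_j == 0L) break
        bits[best_j] <- !bits[best_j]
        f0 <- f0 + best_gain
      }
      list(bits = bits, fitness = f0)
    }
    # refine every starting point: the incumbent begins at the best local
    # optimum reachable from the initial population
    best_f <- -Inf; best_bits <- NULL; best_i <- 1L
    for (i in seq_len(cfg$m)) {
      ref <- refine(to_bits(pts[i, ]))
      if (ref$fitness > best_f) {
        best_f <- ref$fitness; best_bits <- ref$bits; best_i <- i
      }
    }
    best_x <- ifelse(best_bits, pmax(pts[best_i, ], 0.75), pmin(pts[best_i, ], 0.25))
    k_star <- 0L
    trace <- numeric(cfg$k_max)
    for (k in seq_len(cfg$k_max)) {
      r <- step_rate(k, cfg, k_star)
      pts <- spiral_step(pts, best_x, r, R)
      pts <- pmin(pmax(pts, 0), 1)
      fits <- apply(pts, 1, function(p) subset_fitness(to_bits(p), X, decision))
      {
        ref <- refine(to_bits(pts[which.max(fits), ]))
        if (ref$fitness > best_f + 1e-12) {
          best_f <- ref$fitness
          best_bits <- ref$bits
          cand_x <- pts[which.max(fits), ]
          best_x <- ifelse(best_bits, pmax(cand_x, 0.75), pmin(cand_x, 0.25))
          k_star <- k
        }
      }
      trace[k] <- best_f
    }
    structure(best_bits,
              fitness = trace,
              gamma = gamma_dependency(X, decision, best_bits))
  })
}

#' Exhaustive minimal reduct (test oracle)
#'
#' Enumerates all 2^n - 1 non-empty subsets (n <= 14) and returns the
#' smallest one whose dependency degree equals the full set's; ties are
#' broken lexicographically (earlier attributes preferred).
#'
#' @inheritParams gamma_dependency
#' @return Logical subset vector.
#' @export
exhaustive_reduct <- function(table, decision) {
  X <- as.matrix(table)
  n <- ncol(X)
  if (n > 14) stop("exhaustive search refused for n > 14", call. = FALSE)
  g_full <- gamma_dependency(X, decision)
  best <- rep(TRUE, n)
  # order subsets by (size, lexicographic on attribute indices)
  masks <- lapply(1:(2^n - 1), function(code) as.logical(bitwAnd(code, 2^(0:(n - 1))) > 0))
  sizes <- vapply(masks, sum, numeric(1))
  lex <- vapply(masks, function(b) paste(as.integer(!b), collapse = ""), character(1))
  ord <- order(sizes, lex, method = "radix")
  for (i in ord) {
    if (gamma_dependency(X, decision, masks[[i]]) >= g_full - 1e-12) {
      return(masks[[i]])
    }
  }
  best
}
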