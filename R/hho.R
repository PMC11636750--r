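# Harris-hawks optimization with an elite-mutation exploitation boost, and
# grid-projected hyperparameter tuning of the GBDT classifier.

# Levy flight step (Mantegna's algorithm, beta = 1.5); used by the rapid
# dives of the exploitation phase.
levy_flight <- function(dim) {
  beta <- 1.5
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dim) * sigma
  v <- stats::rnorm(dim)
  0.01 * u / abs(v)^(1 / beta)
}

#' Harris-hawks optimization
#'
#' Canonical HHO: the escape energy `E = 2 * E0 * (1 - t/T)` switches the
#' population between exploration (|E| >= 1: random-hawk or mean-position
#' moves) and exploitation (|E| < 1: soft/hard besiege, with Levy-flight
#' rapid dives when the prey's escape chance is high).  On top of the base
#' phases, the top 10% of hawks receive a Gaussian elite mutation with scale
#' decaying as `t^(-1/2)`, accepted only on improvement; the incumbent best
#' (the rabbit) is never worsened.
#'
#' @param objective Function mapping a position vector to a scalar to
#'   minimize.
#' @param lower,upper Numeric bounds (recycled to the dimension).
#' @param n_hawks Population size.
#' @param T Number of iterations (>= 1).
#' @param seed Integer seed; the trajectory is deterministic given it.
#' @return List with `position`, `value`, and the per-iteration incumbent
#'   `trace` (monotone non-increasing).
#' @export
hho_optimize <- function(objective, lower, upper, n_hawks = 30L, T = 200L,
                         seed = 1L) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    stop("bounds must be finite with upper > lower", call. = FALSE)
  }
  dim <- max(length(lower), length(upper))
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  clip <- function(x) pmin(pmax(x, lower), upper)
  with_seed(seed, {
    X <- matrix(stats::runif(n_hawks * dim, lower, upper),
                nrow = n_hawks, byrow = TRUE)
    fit <- apply(X, 1, objective)
    best_i <- which.min(fit)
    rabbit <- X[best_i, ]; rabbit_f <- fit[best_i]
    trace <- numeric(T)
    for (t in seq_len(T)) {
      mean_pos <- colMeans(X)
      for (i in seq_len(n_hawks)) {
        E0 <- stats::runif(1, -1, 1)
        E <- 2 * E0 * (1 - t / T)
        J <- 2 * (1 - stats::runif(1))
        if (abs(E) >= 1) {                    # exploration
          if (stats::runif(1) >= 0.5) {
            k <- sample.int(n_hawks, 1)
            Xn <- X[k, ] - stats::runif(1) * abs(X[k, ] - 2 * stats::runif(1) * X[i, ])
          } else {
            Xn <- (rabbit - mean_pos) - stats::runif(1) *
              (lower + stats::runif(dim) * (upper - lower))
          }
        } else {                              # exploitation
          r <- stats::runif(1)
          if (r >= 0.5 && abs(E) >= 0.5) {    # soft besiege
            Xn <- (rabbit - X[i, ]) - E * abs(J * rabbit - X[i, ])
          } else if (r >= 0.5) {              # hard besiege
            Xn <- rabbit - E * abs(rabbit - X[i, ])
          } else if (abs(E) >= 0.5) {         # soft besiege, rapid dives
            Y <- rabbit - E * abs(J * rabbit - X[i, ])
            Y <- clip(Y)
            if (objective(Y) < fit[i]) {
              Xn <- Y
            } else {
              Z <- clip(Y + stats::rnorm(dim) * levy_flight(dim))
              Xn <- if (objective(Z) < fit[i]) Z else X[i, ]
            }
          } else {                            # hard besiege, rapid dives
            Y <- rabbit - E * abs(J * rabbit - mean_pos)
            Y <- clip(Y)
            if (objective(Y) < fit[i]) {
              Xn <- Y
            } else {
              Z <- clip(Y + stats::rnorm(dim) * levy_flight(dim))
              Xn <- if (objective(Z) < fit[i]) Z else X[i, ]
            }
          }
        }
        Xn <- clip(Xn)
        fn <- objective(Xn)
        if (fn <= fit[i]) {  # greedy per-hawk acceptance keeps search stable
          X[i, ] <- Xn; fit[i] <- fn
        } else if (abs(E) >= 1) {  # exploration may accept worse moves
          X[i, ] <- Xn; fit[i] <- fn
        }
      }
      # elite Gaussian mutation, scale ~ t^(-1/2), greedy acceptance
      n_elite <- max(1L, floor(0.1 * n_hawks))
      elite <- order(fit)[seq_len(n_elite)]
      scale <- (upper - lower) * 0.1 / sqrt(t)
      for (i in elite) {
        Xm <- clip(X[i, ] + stats::rnorm(dim) * scale)
        fm <- objective(Xm)
        if (fm < fit[i]) {
          X[i, ] <- Xm; fit[i] <- fm
        }
      }
      ib <- which.min(fit)
      if (fit[ib] < rabbit_f) {
        rabbit <- X[ib, ]; rabbit_f <- fit[ib]
      }
      trace[t] <- rabbit_f
    }
    list(position = rabbit, value = rabbit_f, trace = trace)
  })
}

#' Hyperparameter grids for GBDT tuning
#'
#' @return Named list of grids: `mdl = seq(20, 250, 20)`,
#'   `nti = seq(10, 450, 10)`, `nl = 20:256`, `md = 1:12`.
#' @export
default_grids <- function() {
  list(mdl = seq(20L, 250L, by = 20L),
       nti = seq(10L, 450L, by = 10L),
       nl = 20:256,
       md = 1:12)
}

# Map a continuous position in [0,1]^4 to the nearest grid points.
position_to_params <- function(pos, grids, base = gbdt_params()) {
  pick <- function(u, grid) grid[pmax(1L, pmin(length(grid), round(u * (length(grid) - 1)) + 1L))]
  p <- base
  p$mdl <- as.integer(pick(pos[1], grids$mdl))
  p$nti <- as.integer(pick(pos[2], grids$nti))
  p$nl <- as.integer(pick(pos[3], grids$nl))
  p$md <- as.integer(pick(pos[4], grids$md))
  p
}

# Stratified k-fold assignment, deterministic per seed.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Tune GBDT hyperparameters with the Harris-hawks optimizer
#'
#' Hawks search the continuous cube \[0, 1\]^4; positions are projected to
#' the nearest points of the MDL/NTI/NL/MD grids and scored by
#' `1 - mean cross-validated accuracy` over stratified folds.  The returned
#' parameters always lie exactly on the grids.
#'
#' @param X Feature table (a `label` column is dropped).
#' @param y Binary 0/1 labels.
#' @param grids Grids as from [default_grids()].
#' @param cv_folds Number of stratified folds (default 3).
#' @param n_hawks,T HHO budget.
#' @param base Baseline [gbdt_params()] supplying the non-tuned fields.
#' @param seed Integer seed.
#' @return A grid-feasible `gbdt_params` with attribute `cv_error`.
#' @export
tune_gbdt <- function(X, y, grids = default_grids(), cv_folds = 3L,
                      n_hawks = 6L, T = 8L, base = gbdt_params(), seed = 1L) {
  stopifnot(all(lengths(grids) >= 1))
  y <- as.numeric(y)
  if (cv_folds > min(table(y))) stop("`cv_folds` exceeds a class count", call. = FALSE)
  Xd <- as.data.frame(X)
  Xd <- Xd[, setdiff(colnames(Xd), "label"), drop = FALSE]
  fold <- stratified_folds(y, cv_folds, derive_seed(seed, 11L))
  cache <- new.env(parent = emptyenv())
  objective <- function(pos) {
    p <- position_to_params(pos, grids, base)
    key <- paste(p$mdl, p$nti, p$nl, p$md, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (nrow(Xd) < 2L * p$mdl) {
      cache[[key]] <- 1
      return(1)
    }
    accs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(tr) < 2L * p$mdl) {
        accs[f] <- 0
        next
      }
      pf <- p; pf$seed <- derive_seed(seed, 100L + f)
      fit <- fit_gbdt(Xd[tr, , drop = FALSE], y[tr], pf)
      pr <- predict_proba(fit, Xd[!tr, , drop = FALSE])
      accs[f] <- mean((pr >= 0.5) == (y[!tr] == 1))
    }
    err <- 1 - mean(accs)
    cache[[key]] <- err
    err
  }
  if (all(lengths(grids) == 1)) {
    p <- position_to_params(rep(0, 4), grids, base)
    attr(p, "cv_error") <- objective(rep(0, 4))
    return(p)
  }
  res <- hho_optimize(objective, lower = rep(0, 4), upper = rep(1, 4),
                      n_hawks = n_hawks, T = T, seed = derive_seed(seed, 12L))
  if (res$value >= 1 - 1e-12) {
    # no grid point was feasible at this sample size; keep the baseline
    attr(base, "cv_error") <- NA_real_
    return(base)
  }
  p <- position_to_params(res$position, grids, base)
  attr(p, "cv_error") <- res$value
  p
}
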