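# Gradient-boosted decision trees with gradient-based one-side sampling
# (GOSS).  Trees are grown leaf-wise: at every step the leaf/split pair with
# the largest GOSS variance gain is expanded, subject to the minimum-data-in-
# leaf (MDL), maximum-leaves (NL) and maximum-depth (MD) constraints.

#' Min-max normalization to \[0, 1\]
#'
#' `y~ = (y - min y) / (max y - min y)`; a monotone map sending the minimum
#' to 0 and the maximum to 1.
#'
#' @param y Numeric vector with `max(y) > min(y)`.
#' @return Normalized vector.
#' @export
normalize01 <- function(y) {
  rng <- range(y)
  if (rng[1] == rng[2]) stop("constant vector cannot be min-max normalized", call. = FALSE)
  (y - rng[1]) / (rng[2] - rng[1])
}

#' GBDT parameter set
#'
#' Grids follow the tuning design: MDL in `seq(20, 250, 20)`, NTI in
#' `seq(10, 450, 10)`, NL in 20..256, MD in 1..12.
#'
#' @param mdl Minimum data in leaf.
#' @param nti Number of boosting iterations (trees).
#' @param nl Maximum number of leaves per tree.
#' @param md Maximum tree depth.
#' @param learning_rate Shrinkage applied to each tree's contribution.
#' @param goss_b Top-gradient fraction b kept with weight 1.
#' @param goss_c Random fraction c of the remainder, amplified by (1-b)/c.
#' @param n_bins Histogram bins per feature for split candidates.
#' @param seed Integer seed for the GOSS sampling.
#' @return Object of class `gbdt_params`.
#' @export
gbdt_params <- function(mdl = 20L, nti = 100L, nl = 31L, md = 6L,
                        learning_rate = 0.1, goss_b = 0.2, goss_c = 0.1,
                        n_bins = 32L, seed = 1L) {
  if (goss_b <= 0 || goss_b > 1 || goss_c <= 0 || goss_c > 1 || goss_b + goss_c > 1 + 1e-12) {
    if (goss_b != 1) stop("require b, c in (0, 1] with b + c <= 1", call. = FALSE)
  }
  structure(list(mdl = as.integer(mdl), nti = as.integer(nti),
                 nl = as.integer(nl), md = as.integer(md),
                 learning_rate = learning_rate, goss_b = goss_b,
                 goss_c = goss_c, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "gbdt_params")
}

#' Gradient-based one-side sampling
#'
#' Keeps the `ceil(b * o)` instances with the largest absolute gradients at
#' weight 1 and samples `ceil(c * o)` uniformly from the remainder at weight
#' `(1 - b) / c`, so weighted gradient sums are unbiased for the full-data
#' sums.  `b = 1` keeps everything at weight 1.
#'
#' @param gradients Numeric vector of per-instance gradients.
#' @param b,c GOSS fractions, `b, c` in (0, 1\], `b + c <= 1`.
#' @param seed Integer seed.
#' @return List with `indices` and matching `weights`.
#' @export
goss_sample <- function(gradients, b, c, seed = 1L) {
  o <- length(gradients)
  if (b <= 0 || b > 1) stop("`b` must lie in (0, 1]", call. = FALSE)
  if (b >= 1) {
    return(list(indices = seq_len(o), weights = rep(1, o)))
  }
  if (c <= 0 || c > 1 || b + c > 1 + 1e-12) stop("require c in (0, 1] with b + c <= 1", call. = FALSE)
  n_top <- ceiling(b * o)
  n_rand <- ceiling(c * o)
  if (n_top + n_rand > o) stop("sample fractions too large for n", call. = FALSE)
  ord <- order(abs(gradients), decreasing = TRUE)
  top <- ord[seq_len(n_top)]
  rest <- ord[(n_top + 1L):o]
  rnd <- with_seed(seed, sort(sample(rest, n_rand)))
  list(indices = c(top, rnd),
       weights = c(rep(1, n_top), rep((1 - b) / c, n_rand)))
}

#' GOSS variance gain of a split candidate
#'
#' For feature values `x` of the sampled instances with gradients `h` and
#' GOSS weights `w`, the gain of threshold `e` is
#' `(1/o) * [ (sum of weighted h on the left)^2 / n_left
#'          + (sum of weighted h on the right)^2 / n_right ]`,
#' where the left/right sums combine the top-gradient instances at weight 1
#' with the amplified sampled instances, and `n_left`/`n_right` count the
#' sampled instances on each side.  With `b = 1` this is the exact
#' (unsampled) variance gain.
#'
#' @param x Feature values of the sampled instances.
#' @param h Gradients of the sampled instances.
#' @param w GOSS weights of the sampled instances.
#' @param e Split threshold (left: `x <= e`).
#' @param o Total instance count of the node before sampling.
#' @return Scalar gain; `-Inf` if either side is empty.
#' @export
variance_gain <- function(x, h, w, e, o = length(x)) {
  left <- x <= e
  nl <- sum(left); nr <- sum(!left)
  if (nl == 0 || nr == 0) return(-Inf)
  sl <- sum(w[left] * h[left]); sr <- sum(w[!left] * h[!left])
  (sl^2 / nl + sr^2 / nr) / o
}

# Histogram split-candidate thresholds: up to n_bins - 1 evenly spaced
# midpoints between adjacent distinct values.  Midpoints keep every training
# row strictly away from the threshold, so serialized models reproduce the
# same partitions.
split_candidates <- function(x, n_bins) {
  u <- sort(unique(x))
  if (length(u) < 2) return(numeric(0))
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) > n_bins - 1) {
    mids <- mids[unique(round(seq(1, length(mids), length.out = n_bins - 1)))]
  }
  mids
}

# Grow one regression tree leaf-wise on (X, grad) with GOSS row sampling.
# Returns a list of nodes; leaf values are Newton steps computed on the full
# data reaching the leaf.
grow_tree <- function(X, grad, hess, p, seed) {
  n <- nrow(X)
  smp <- goss_sample(grad, p$goss_b, p$goss_c, seed = seed)
  in_sample <- smp$indices
  w_sample <- smp$weights
  nodes <- list(list(id = 1L, is_leaf = TRUE, depth = 0L,
                     rows = seq_len(n), value = 0))
  find_best <- function(rows) {
    srows <- intersect(in_sample, rows)
    if (length(srows) < 2) return(NULL)
    sw <- w_sample[match(srows, in_sample)]
    best <- NULL; best_gain <- 0
    for (k in seq_len(ncol(X))) {
      xk <- X[rows, k]
      xs <- X[srows, k]
      for (e in split_candidates(xs, p$n_bins)) {
        if (sum(xk <= e) < p$mdl || sum(xk > e) < p$mdl) next
        g <- variance_gain(xs, grad[srows], sw, e, o = length(rows))
        if (is.finite(g) && g > best_gain) {
          best_gain <- g
          best <- list(feature = k, threshold = e, gain = g)
        }
      }
    }
    best
  }
  # best split per leaf is computed once when the leaf is created
  cands <- list()
  leaf_cand <- function(nd) {
    if (nd$depth >= p$md || length(nd$rows) < 2L * p$mdl) return(NULL)
    find_best(nd$rows)
  }
  cands[1] <- list(leaf_cand(nodes[[1]]))
  n_leaves <- 1L
  repeat {
    if (n_leaves >= p$nl) break
    gains <- vapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$is_leaf && i <= length(cands) && !is.null(cands[[i]])) {
        cands[[i]]$gain
      } else -Inf
    }, numeric(1))
    if (all(!is.finite(gains))) break
    best_i <- which.max(gains)
    cand <- cands[[best_i]]
    cand_node <- nodes[[best_i]]
    left_rows <- cand_node$rows[X[cand_node$rows, cand$feature] <= cand$threshold]
    right_rows <- setdiff(cand_node$rows, left_rows)
    id_l <- length(nodes) + 1L; id_r <- length(nodes) + 2L
    nodes[[cand_node$id]]$is_leaf <- FALSE
    nodes[[cand_node$id]]$feature <- cand$feature
    nodes[[cand_node$id]]$threshold <- cand$threshold
    nodes[[cand_node$id]]$left <- id_l
    nodes[[cand_node$id]]$right <- id_r
    nodes[[id_l]] <- list(id = id_l, is_leaf = TRUE, depth = cand_node$depth + 1L,
                          rows = left_rows, value = 0)
    nodes[[id_r]] <- list(id = id_r, is_leaf = TRUE, depth = cand_node$depth + 1L,
                          rows = right_rows, value = 0)
    cands[best_i] <- list(NULL)
    cands[id_l] <- list(leaf_cand(nodes[[id_l]]))
    cands[id_r] <- list(leaf_cand(nodes[[id_r]]))
    n_leaves <- n_leaves + 1L
  }
  for (i in seq_along(nodes)) {
    if (nodes[[i]]$is_leaf) {
      rows <- nodes[[i]]$rows
      nodes[[i]]$value <- sum(grad[rows]) / (sum(hess[rows]) + 1e-6)
    }
  }
  nodes
}

tree_predict <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- nodes[[id]]
    if (nd$is_leaf) {
      out[rows] <<- nd$value
      return(invisible(NULL))
    }
    left <- rows[X[rows, nd$feature] <= nd$threshold]
    right <- setdiff(rows, left)
    if (length(left)) walk(nd$left, left)
    if (length(right)) walk(nd$right, right)
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Fit a GOSS gradient-boosted tree classifier
#'
#' Binary logistic-loss boosting: `G_n(y) = G_{n-1}(y) + lambda_n i_n(y)`
#' with shrinkage `learning_rate`, each base tree grown leaf-wise on the
#' GOSS-sampled negative gradients.  Leaf values are Newton steps on the
#' full data reaching the leaf.
#'
#' @param X Numeric feature matrix or data frame (a `label` column, if
#'   present, is dropped).
#' @param y Binary 0/1 labels (1 = cancer).
#' @param p A [gbdt_params()].
#' @return Object of class `gbdt_model` with `trees`, `base_score`, and the
#'   parameters used.
#' @export
fit_gbdt <- function(X, y, p = gbdt_params()) {
  X <- as.matrix(as.data.frame(X)[, setdiff(colnames(as.data.frame(X)), "label"), drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("degenerate labels", call. = FALSE)
  if (nrow(X) < 2L * p$mdl) stop("need at least 2 * MDL rows", call. = FALSE)
  base <- log(mean(y) / (1 - mean(y)))
  F <- rep(base, nrow(X))
  trees <- vector("list", p$nti)
  loss <- numeric(p$nti)
  for (m in seq_len(p$nti)) {
    prob <- sigmoid(F)
    grad <- y - prob            # negative gradient of the logistic loss
    hess <- prob * (1 - prob)
    nodes <- grow_tree(X, grad, hess, p, seed = derive_seed(p$seed, m))
    upd <- tree_predict(nodes, X)
    F <- F + p$learning_rate * upd
    trees[[m]] <- lapply(nodes, function(nd) {
      nd$n_rows <- length(nd$rows)  # retained for constraint audits
      nd[setdiff(names(nd), "rows")]
    })
    prob <- sigmoid(F)
    loss[m] <- -mean(y * log(pmax(prob, 1e-12)) + (1 - y) * log(pmax(1 - prob, 1e-12)))
  }
  structure(list(trees = trees, base_score = base, params = p,
                 train_loss = loss, features = colnames(X)),
            class = "gbdt_model")
}

#' Predict class probabilities from a fitted GBDT model
#'
#' @param model A `gbdt_model`.
#' @param X Feature matrix/data frame with the training columns.
#' @return Numeric vector of P(label = 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "gbdt_model"))
  Xd <- as.data.frame(X)
  if (!is.null(model$features) && all(model$features %in% colnames(Xd))) {
    Xd <- Xd[, model$features, drop = FALSE]
  } else {
    Xd <- Xd[, setdiff(colnames(Xd), "label"), drop = FALSE]
  }
  Xm <- as.matrix(Xd)
  F <- rep(model$base_score, nrow(Xm))
  for (tr in model$trees) {
    F <- F + model$params$learning_rate * tree_predict(tr, Xm)
  }
  sigmoid(F)
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("<gbdt_model> %d trees, lr %.3f, GOSS b=%.2f c=%.2f\n",
              length(x$trees), x$params$learning_rate,
              x$params$goss_b, x$params$goss_c))
  invisible(x)
}
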