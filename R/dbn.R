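# Patch-wise tumor segmentation with a two-layer deep belief network:
# a Gaussian-Bernoulli RBM on standardized raw patches, a Bernoulli-Bernoulli
# RBM on its hidden activations, and a logistic head on the top activations.
# The patch label is the ground-truth mask value at the patch center.

# Extract all patch_size x patch_size patches at the given stride as rows of
# a matrix (column-major over patch pixels); also return patch-center
# coordinates.  Patch grid starts at (1,1); the last start is clamped so the
# full image width/height is covered.
patch_grid <- function(h, w, patch_size, stride) {
  starts <- function(extent) {
    s <- seq(1L, extent - patch_size + 1L, by = stride)
    if (s[length(s)] != extent - patch_size + 1L) s <- c(s, extent - patch_size + 1L)
    s
  }
  list(rows = starts(h), cols = starts(w))
}

extract_patches <- function(img, patch_size, stride) {
  h <- nrow(img); w <- ncol(img)
  if (h < patch_size || w < patch_size) stop("image smaller than patch", call. = FALSE)
  g <- patch_grid(h, w, patch_size, stride)
  nr <- length(g$rows); nc <- length(g$cols)
  out <- matrix(0, nrow = nr * nc, ncol = patch_size^2)
  centers <- matrix(0L, nrow = nr * nc, ncol = 2)
  half <- patch_size %/% 2L
  k <- 1L
  for (cj in g$cols) {
    for (ri in g$rows) {
      out[k, ] <- as.vector(img[ri:(ri + patch_size - 1L), cj:(cj + patch_size - 1L)])
      centers[k, ] <- c(ri + half, cj + half)
      k <- k + 1L
    }
  }
  list(patches = out, centers = centers, grid = g)
}

#' Train the deep-belief-network patch segmenter
#'
#' Greedy layer-wise pretraining: the GB-RBM is trained by contrastive
#' divergence on standardized raw patches and the BB-RBM on the GB hidden
#' activation probabilities, both on a class-balanced patch subsample.  A
#' logistic head is then fitted on the top activations against the patch
#' labels (ground-truth mask value at the patch center), and the whole
#' stack is fine-tuned by backpropagation on the natural patch distribution
#' with the same optimizer settings.
#'
#' @param images List of preprocessed image matrices.
#' @param masks List of aligned 0/1 ground-truth masks.
#' @param cfg A [train_config()] (Adam, learning rate 0.001, 10 epochs by
#'   default).
#' @param patch_size,stride Patch geometry in pixels.
#' @param hidden_sizes Length-2 integer vector: GB and BB hidden unit counts.
#' @param threshold Probability threshold for mask binarization.
#' @param max_patches Cap on the number of training patches after balancing.
#' @return Object of class `dbn_model` with the RBM stack, logistic head,
#'   patch geometry, threshold, and patch-standardization constants.
#' @export
train_segmenter <- function(images, masks, cfg = train_config(),
                            patch_size = 16L, stride = 4L,
                            hidden_sizes = c(48L, 24L), threshold = 0.5,
                            max_patches = 8000L) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  pieces <- vector("list", length(images))
  labs <- vector("list", length(images))
  for (i in seq_along(images)) {
    ep <- extract_patches(images[[i]], patch_size, stride)
    pieces[[i]] <- ep$patches
    labs[[i]] <- masks[[i]][ep$centers]
  }
  X <- do.call(rbind, pieces)
  y <- unlist(labs)
  if (length(unique(y)) < 2) {
    stop("training masks contain a single class of patches", call. = FALSE)
  }
  # class-balanced subsample for the unsupervised RBM pretraining; the head
  # is fitted on the natural patch distribution so its intercept carries the
  # true foreground prior.
  sel <- with_seed(derive_seed(cfg$seed, 101L), {
    pos <- which(y == 1); neg <- which(y == 0)
    per <- min(length(pos), length(neg), max_patches %/% 2L)
    c(sample(pos, per), sample(neg, per))
  })
  mu <- mean(X[sel, ]); sdv <- stats::sd(as.vector(X[sel, ]))
  Xs <- (X - mu) / sdv
  gb <- rbm_params(patch_size^2, hidden_sizes[1], kind = "GB",
                   seed = derive_seed(cfg$seed, 1L))
  cfg_gb <- cfg; cfg_gb$seed <- derive_seed(cfg$seed, 2L)
  gb <- cd_train(gb, Xs[sel, , drop = FALSE], cfg_gb)
  H1 <- cond_hidden(Xs, gb)
  bb <- rbm_params(hidden_sizes[1], hidden_sizes[2], kind = "BB",
                   seed = derive_seed(cfg$seed, 3L))
  cfg_bb <- cfg; cfg_bb$seed <- derive_seed(cfg$seed, 4L)
  bb <- cd_train(bb, H1[sel, , drop = FALSE], cfg_bb)
  H2 <- cond_hidden(H1, bb)
  head_fit <- suppressWarnings(stats::glm.fit(
    cbind(1, H2), y, family = stats::binomial(),
    control = stats::glm.control(maxit = 50)
  ))
  model <- structure(list(
    stack = list(gb, bb), head = as.numeric(stats::coef(head_fit)),
    patch_size = as.integer(patch_size), stride = as.integer(stride),
    threshold = threshold, standardize = c(mu = mu, sd = sdv),
    epochs = cfg$epochs
  ), class = "dbn_model")
  finetune_dbn(model, Xs, y, cfg)
}

# Supervised fine-tuning of the pretrained stack: backpropagation through
# both sigmoid layers and the logistic head with Adam, on the natural patch
# distribution.  Foreground patches are up-weighted by
# sqrt(n_background / n_foreground) — a partial rebalance that trades a
# little precision for the boundary recall the Dice overlap needs.
finetune_dbn <- function(model, Xs, y, cfg) {
  W1 <- model$stack[[1]]$WT; b1 <- model$stack[[1]]$b_hid
  W2 <- model$stack[[2]]$WT; b2 <- model$stack[[2]]$b_hid
  wo <- model$head[-1]; c0 <- model$head[1]
  n <- nrow(Xs)
  n_pos <- sum(y == 1); n_neg <- n - n_pos
  wts <- ifelse(y == 1, sqrt(n_neg / max(n_pos, 1)), 1)
  params <- list(W1, b1, W2, b2, wo, c0)
  ms <- lapply(params, function(z) z * 0); vs <- ms
  beta1 <- cfg$momentum; beta2 <- cfg$gradient_decay; eps <- 1e-8; t <- 0L
  with_seed(derive_seed(cfg$seed, 5L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1L, n)]
        x <- Xs[idx, , drop = FALSE]; yy <- y[idx]; ww <- wts[idx]
        z1 <- sigmoid(sweep(x %*% params[[1]], 2, params[[2]], `+`))
        z2 <- sigmoid(sweep(z1 %*% params[[3]], 2, params[[4]], `+`))
        p <- as.numeric(sigmoid(z2 %*% params[[5]] + params[[6]]))
        d3 <- ww * (p - yy) / sum(ww)
        d2 <- (d3 %o% params[[5]]) * z2 * (1 - z2)
        d1 <- (d2 %*% t(params[[3]])) * z1 * (1 - z1)
        grads <- list(t(x) %*% d1, colSums(d1), t(z1) %*% d2, colSums(d2),
                      as.numeric(t(z2) %*% d3), sum(d3))
        t <- t + 1L
        for (k in 1:6) {
          ms[[k]] <- beta1 * ms[[k]] + (1 - beta1) * grads[[k]]
          vs[[k]] <- beta2 * vs[[k]] + (1 - beta2) * grads[[k]]^2
          params[[k]] <- params[[k]] - cfg$learning_rate *
            (ms[[k]] / (1 - beta1^t)) / (sqrt(vs[[k]] / (1 - beta2^t)) + eps)
        }
      }
    }
  })
  model$stack[[1]]$WT <- params[[1]]; model$stack[[1]]$b_hid <- params[[2]]
  model$stack[[2]]$WT <- params[[3]]; model$stack[[2]]$b_hid <- params[[4]]
  model$head <- c(params[[6]], params[[5]])
  model
}

# Patch probabilities under a dbn_model for a patch matrix (rows = patches).
dbn_patch_proba <- function(model, patches) {
  Xs <- (patches - model$standardize["mu"]) / model$standardize["sd"]
  H1 <- cond_hidden(Xs, model$stack[[1]])
  H2 <- cond_hidden(H1, model$stack[[2]])
  as.numeric(sigmoid(cbind(1, H2) %*% model$head))
}

#' Segment an image with a trained DBN model
#'
#' Patch probabilities are computed on the sliding-window grid at the model's
#' stride and assembled back to pixel resolution: each pixel takes the
#' probability of the patch whose center is nearest (equivalently,
#' nearest-neighbor upsampling of the stride-resolution probability map),
#' then the map is thresholded at `model$threshold`.
#'
#' @param img Image matrix at least `patch_size` in both dimensions.
#' @param model A `dbn_model` from [train_segmenter()].
#' @return Binary mask matrix (0/1) of the same shape as `img`.
#' @export
segment <- function(img, model) {
  stopifnot(inherits(model, "dbn_model"))
  assert_image(img)
  ep <- extract_patches(img, model$patch_size, model$stride)
  proba <- dbn_patch_proba(model, ep$patches)
  pm <- probability_map(img, ep, proba)
  matrix(as.integer(pm >= model$threshold), nrow = nrow(img))
}

# Assemble per-patch probabilities into a full-resolution probability map by
# nearest patch-center assignment.
probability_map <- function(img, ep, proba) {
  h <- nrow(img); w <- ncol(img)
  g <- ep$grid
  nr <- length(g$rows); nc <- length(g$cols)
  P <- matrix(proba, nrow = nr, ncol = nc)
  centers_r <- g$rows + (ep$centers[1, 1] - g$rows[1])
  centers_c <- g$cols + (ep$centers[1, 2] - g$cols[1])
  ri <- findInterval(seq_len(h), c(-Inf, (centers_r[-nr] + centers_r[-1]) / 2)) |>
    pmin(nr) |> pmax(1)
  ci <- findInterval(seq_len(w), c(-Inf, (centers_c[-nc] + centers_c[-1]) / 2)) |>
    pmin(nc) |> pmax(1)
  P[ri, ci, drop = FALSE]
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> GB %d->%d, BB %d->%d, patch %d stride %d, threshold %.2f\n",
              nrow(x$stack[[1]]$WT), ncol(x$stack[[1]]$WT),
              nrow(x$stack[[2]]$WT), ncol(x$stack[[2]]$WT),
              x$patch_size, x$stride, x$threshold))
  invisible(x)
}

#' Mean Dice overlap between predicted and reference masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; images where both masks are empty contribute 1,
#' and an empty/non-empty pair contributes 0.
#'
#' @param pred,truth Binary mask matrices or lists of them.
#' @return Scalar mean Dice coefficient.
#' @export
dice_coefficient <- function(pred, truth) {
  if (is.list(pred)) {
    return(mean(mapply(dice_coefficient, pred, truth)))
  }
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred * truth) / (a + b)
}
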