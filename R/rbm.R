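# Restricted Boltzmann machines: Bernoulli-Bernoulli (BB) and
# Gaussian-Bernoulli (GB) variants, exact enumeration oracles at tiny sizes,
# and contrastive-divergence training with Adam updates.

#' Create RBM parameters
#'
#' @param n_visible,n_hidden Unit counts.
#' @param kind `"BB"` (binary visibles) or `"GB"` (Gaussian visibles,
#'   unit variance).
#' @param init_sd Standard deviation of the random weight initialization.
#' @param seed Integer seed for the initialization.
#' @return Object of class `rbm_params` with `WT` (n_visible x n_hidden
#'   weight matrix), `b_vis`, `b_hid`, and `kind`.
#' @export
rbm_params <- function(n_visible, n_hidden, kind = c("BB", "GB"),
                       init_sd = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    structure(list(
      WT = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                  nrow = n_visible, ncol = n_hidden),
      b_vis = rep(0, n_visible),
      b_hid = rep(0, n_hidden),
      kind = kind
    ), class = "rbm_params")
  })
}

#' RBM energy of a joint configuration
#'
#' BB: `E(v,h) = -sum_ij WT_ij v_i h_j - sum_i b_vis_i v_i - sum_j b_hid_j h_j`.
#' GB (unit variance): `E(v,h) = sum_i (v_i - b_vis_i)^2 / 2
#'   - sum_j b_hid_j h_j - sum_ij WT_ij v_i h_j`.
#'
#' @param v Visible vector (binary for BB).
#' @param h Binary hidden vector.
#' @param p An [rbm_params()].
#' @return Scalar energy.
#' @export
rbm_energy <- function(v, h, p) {
  stopifnot(inherits(p, "rbm_params"))
  if (length(v) != nrow(p$WT) || length(h) != ncol(p$WT)) {
    stop("shape mismatch between configuration and parameters", call. = FALSE)
  }
  if (p$kind == "BB" && !all(v %in% c(0, 1))) {
    stop("BB visibles must be binary", call. = FALSE)
  }
  inter <- as.numeric(t(v) %*% p$WT %*% h)
  if (p$kind == "BB") {
    -inter - sum(p$b_vis * v) - sum(p$b_hid * h)
  } else {
    sum((v - p$b_vis)^2) / 2 - sum(p$b_hid * h) - inter
  }
}

#' Hidden-unit activation probabilities given visibles
#'
#' `P(h_j = 1 | v) = sigmoid(sum_i v_i WT_ij + b_hid_j)` for both RBM kinds.
#'
#' @param v Visible vector, or matrix with one configuration per row.
#' @param p An [rbm_params()].
#' @return Probability vector (or matrix, one row per input row).
#' @export
cond_hidden <- function(v, p) {
  stopifnot(inherits(p, "rbm_params"))
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(vm) != nrow(p$WT)) stop("shape mismatch", call. = FALSE)
  out <- sigmoid(sweep(vm %*% p$WT, 2, p$b_hid, `+`))
  if (is.matrix(v)) out else as.numeric(out)
}

#' Visible-unit conditionals given hiddens
#'
#' BB: `P(v_i = 1 | h) = sigmoid(sum_j WT_ij h_j + b_vis_i)`.
#' GB: the conditional Gaussian mean `b_vis_i + sum_j WT_ij h_j`.
#'
#' @param h Binary hidden vector, or matrix with one configuration per row.
#' @param p An [rbm_params()].
#' @return Probability (BB) or mean (GB) vector/matrix.
#' @export
cond_visible <- function(h, p) {
  stopifnot(inherits(p, "rbm_params"))
  hm <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (ncol(hm) != ncol(p$WT)) stop("shape mismatch", call. = FALSE)
  act <- sweep(hm %*% t(p$WT), 2, p$b_vis, `+`)
  out <- if (p$kind == "BB") sigmoid(act) else act
  if (is.matrix(h)) out else as.numeric(out)
}

# Energies of every (v, h) pair for enumerable state sets: returns a matrix
# with rows indexing visible states and columns hidden states.
energy_grid <- function(V, H, p) {
  inter <- V %*% p$WT %*% t(H)
  if (p$kind == "BB") {
    -(inter + as.numeric(V %*% p$b_vis) +
        matrix(as.numeric(H %*% p$b_hid), nrow = nrow(V), ncol = nrow(H), byrow = TRUE))
  } else {
    quad <- rowSums(sweep(V, 2, p$b_vis, `-`)^2) / 2
    quad - inter -
      matrix(as.numeric(H %*% p$b_hid), nrow = nrow(V), ncol = nrow(H), byrow = TRUE)
  }
}

#' Brute-force partition function
#'
#' Enumerates every visible/hidden configuration and sums `exp(-E)`.  For BB
#' machines the visible states are all binary vectors; for GB machines a
#' discrete grid of visible configurations must be supplied.  Refuses more
#' than 20 total units (combinatorial guard).
#'
#' @param p An [rbm_params()].
#' @param v_states Optional matrix of visible configurations (rows); required
#'   for GB machines.
#' @return Scalar partition function.
#' @export
partition_bruteforce <- function(p, v_states = NULL) {
  stopifnot(inherits(p, "rbm_params"))
  nv <- nrow(p$WT); nh <- ncol(p$WT)
  if (is.null(v_states)) {
    if (p$kind == "GB") stop("GB machines need an explicit `v_states` grid", call. = FALSE)
    if (nv + nh > 20) stop("too many units for brute-force enumeration", call. = FALSE)
    v_states <- binary_states(nv)
  } else if (nh > 20) {
    stop("too many hidden units for brute-force enumeration", call. = FALSE)
  }
  H <- binary_states(nh)
  sum(exp(-energy_grid(v_states, H, p)))
}

#' Joint probability of a configuration under the Boltzmann distribution
#'
#' `P(v, h) = exp(-E(v, h)) / Omega`, with the partition function obtained by
#' brute-force enumeration ([partition_bruteforce()]).
#'
#' @inheritParams rbm_energy
#' @param v_states Optional visible grid for GB machines.
#' @return Probability in \[0, 1\] (density for GB on the supplied grid).
#' @export
joint_prob <- function(v, h, p, v_states = NULL) {
  exp(-rbm_energy(v, h, p)) / partition_bruteforce(p, v_states)
}

# Exact negative log-likelihood of binary data under a BB RBM, via the free
# energy and brute-force partition function.  Test/monitoring oracle only.
exact_nll_bb <- function(data, p) {
  H <- binary_states(ncol(p$WT))
  E <- energy_grid(data, H, p)
  lz <- log(partition_bruteforce(p))
  # log sum_h exp(-E(v, h)) per data row, stabilized
  m <- apply(-E, 1, max)
  ll <- m + log(rowSums(exp(-E - m))) - lz
  -mean(ll)
}

#' Training configuration for RBM / DBN stages
#'
#' Defaults follow the network's training recipe: Adam with learning rate
#' 0.001, mini-batch 64, 10 epochs, first-moment decay (momentum) 0.9 and
#' second-moment (gradient) decay 0.9.
#'
#' @param learning_rate Adam step size.
#' @param batch Mini-batch size.
#' @param epochs Number of full passes over the data.
#' @param momentum Adam beta1.
#' @param gradient_decay Adam beta2.
#' @param cd_k Gibbs steps per contrastive-divergence update (>= 1).
#' @param seed Integer seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch = 64L, epochs = 10L,
                         momentum = 0.9, gradient_decay = 0.9, cd_k = 1L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch >= 1, epochs >= 1, cd_k >= 1)
  structure(list(learning_rate = learning_rate, batch = as.integer(batch),
                 epochs = as.integer(epochs), momentum = momentum,
                 gradient_decay = gradient_decay, cd_k = as.integer(cd_k),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train an RBM by contrastive divergence
#'
#' CD-k: hidden states are sampled from `cond_hidden`; the visible
#' reconstruction uses the conditional mean (BB probability / GB Gaussian
#' mean) rather than a sample, the usual low-variance choice.  Gradient
#' estimates are applied with Adam.  Deterministic for a fixed seed.
#'
#' @param p An [rbm_params()].
#' @param data Matrix with one visible configuration per row (binary for BB,
#'   standardized for GB).
#' @param cfg A [train_config()].
#' @param monitor_nll Record the exact NLL after each epoch (BB machines
#'   small enough to enumerate only).
#' @return Trained `rbm_params`; if monitored, with an `nll` attribute
#'   (length `epochs + 1`: initial then after each epoch).
#' @export
cd_train <- function(p, data, cfg = train_config(), monitor_nll = FALSE) {
  stopifnot(inherits(p, "rbm_params"), inherits(cfg, "train_config"))
  if (!is.matrix(data) || nrow(data) == 0) stop("`data` must be a non-empty matrix", call. = FALSE)
  if (ncol(data) != nrow(p$WT)) stop("data columns must match visible size", call. = FALSE)
  n <- nrow(data)
  nll <- if (monitor_nll) exact_nll_bb(data, p) else NULL
  # Adam state for (WT, b_vis, b_hid)
  mW <- vW <- matrix(0, nrow(p$WT), ncol(p$WT))
  mv <- vv <- rep(0, nrow(p$WT)); mh <- vh <- rep(0, ncol(p$WT))
  b1 <- cfg$momentum; b2 <- cfg$gradient_decay; eps <- 1e-8; t <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1L, n)]
        v0 <- data[idx, , drop = FALSE]
        ph0 <- cond_hidden(v0, p)
        vk <- v0
        phk <- ph0
        for (step in seq_len(cfg$cd_k)) {
          hs <- matrix(as.numeric(stats::runif(length(phk)) < phk), nrow = nrow(phk))
          vk <- cond_visible(hs, p)
          if (p$kind == "BB") {
            vk <- matrix(as.numeric(stats::runif(length(vk)) < vk), nrow = nrow(vk))
          }
          phk <- cond_hidden(vk, p)
        }
        m <- length(idx)
        gW <- (t(v0) %*% ph0 - t(vk) %*% phk) / m
        gv <- colMeans(v0) - colMeans(vk)
        gh <- colMeans(ph0) - colMeans(phk)
        t <- t + 1L
        upd <- function(m1, v1, g) {
          m1 <- b1 * m1 + (1 - b1) * g
          v1 <- b2 * v1 + (1 - b2) * g^2
          list(m1, v1, cfg$learning_rate * (m1 / (1 - b1^t)) /
                 (sqrt(v1 / (1 - b2^t)) + eps))
        }
        s <- upd(mW, vW, gW); mW <- s[[1]]; vW <- s[[2]]; p$WT <- p$WT + s[[3]]
        s <- upd(mv, vv, gv); mv <- s[[1]]; vv <- s[[2]]; p$b_vis <- p$b_vis + s[[3]]
        s <- upd(mh, vh, gh); mh <- s[[1]]; vh <- s[[2]]; p$b_hid <- p$b_hid + s[[3]]
      }
      if (monitor_nll) nll <- c(nll, exact_nll_bb(data, p))
    }
  })
  if (monitor_nll) attr(p, "nll") <- nll
  p
}
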