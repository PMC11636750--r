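# Shared fixtures, all generated in code.

# Small, fast phantom configuration used across tests.
small_phantom_cfg <- function(...) {
  args <- list(...)
  if (is.null(args$tumor_radius_range)) args$tumor_radius_range <- c(7, 13)
  do.call(phantom_config, c(list(height = 96, width = 96), args))
}

# Brute-force conditional P(h_j = 1 | v) by enumerating hidden states of the
# Boltzmann joint; independent of cond_hidden().
enum_cond_hidden <- function(v, p) {
  H <- lungct:::binary_states(ncol(p$WT))
  pe <- vapply(seq_len(nrow(H)), function(i) exp(-rbm_energy(v, H[i, ], p)),
               numeric(1))
  pe <- pe / sum(pe)
  vapply(seq_len(ncol(H)), function(j) sum(pe[H[, j] == 1]), numeric(1))
}

# Brute-force conditional P(v_i = 1 | h) by enumerating visible states (BB).
enum_cond_visible <- function(h, p) {
  V <- lungct:::binary_states(nrow(p$WT))
  pe <- vapply(seq_len(nrow(V)), function(i) exp(-rbm_energy(V[i, ], h, p)),
               numeric(1))
  pe <- pe / sum(pe)
  vapply(seq_len(ncol(V)), function(i) sum(pe[V[, i] == 1]), numeric(1))
}

# Decision table with a planted two-attribute reduct: the decision is an
# exclusive-or of thresholded f1 and f2, the other attributes are noise.
# Enough objects that random noise subsets cannot shatter the table into
# singleton (spuriously pure) indiscernibility classes.
planted_reduct_table <- function(n_obj = 200, n_attr = 12, seed = 42) {
  set.seed(seed)
  X <- matrix(sample(0:3, n_obj * n_attr, replace = TRUE), n_obj, n_attr)
  d <- as.integer(xor(X[, 1] >= 2, X[, 2] >= 2))
  list(X = X, d = d)
}

# Sample binary vectors from a BB RBM by exact enumeration of the marginal.
sample_rbm_visibles <- function(p, n, seed) {
  V <- lungct:::binary_states(nrow(p$WT))
  H <- lungct:::binary_states(ncol(p$WT))
  E <- lungct:::energy_grid(V, H, p)
  pv <- rowSums(exp(-E))
  pv <- pv / sum(pv)
  set.seed(seed)
  V[sample(seq_len(nrow(V)), n, replace = TRUE, prob = pv), , drop = FALSE]
}
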