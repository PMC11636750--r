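#' @keywords internal
"_PACKAGE"

# Logistic function; used by RBM conditionals and the boosted classifier.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps every stream below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + offset) %% 2147483647L)
}

# Round half away from zero downward: 127.5 -> 127.  The equalization map
# uses this fixed rule so the gray-level remap is identical on every platform.
round_half_down <- function(x) ceiling(x - 0.5)

stopifnot_odd <- function(k, name = "k") {
  if (length(k) != 1 || !is.finite(k) || k < 3 || k %% 2 != 1) {
    stop(sprintf("`%s` must be an odd integer >= 3", name), call. = FALSE)
  }
}

# All distinct binary vectors of length n as a (2^n x n) matrix; rows ordered
# by integer value so enumeration oracles are reproducible.
binary_states <- function(n) {
  if (n == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n))[, n:1, drop = FALSE])
  dimnames(states) <- NULL
  states
}

is_image <- function(img) is.matrix(img) && is.numeric(img) && all(is.finite(img))

assert_image <- function(img, name = "img") {
  if (!is_image(img)) stop(sprintf("`%s` must be a finite numeric matrix", name), call. = FALSE)
  invisible(img)
}
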