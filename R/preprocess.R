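# Noise-removal filters and histogram equalization.
#
# All filters use zero padding at the borders: the window is conceptually
# laid over an image extended with zeros, matching the 3x3 "add zeros to two
# sides" masking construction that the median filter follows.

# Gather the k x k zero-padded neighborhood of every pixel as an
# (H*W) x k^2 matrix (column-major pixel order).  Shared by all filters.
neighborhoods <- function(img, k) {
  h <- nrow(img); w <- ncol(img); r <- (k - 1L) %/% 2L
  pad <- matrix(0, nrow = h + 2L * r, ncol = w + 2L * r)
  pad[r + seq_len(h), r + seq_len(w)] <- img
  out <- matrix(0, nrow = h * w, ncol = k * k)
  col <- 1L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      out[, col] <- as.vector(pad[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L])
      col <- col + 1L
    }
  }
  out
}

# Row-wise medians of a numeric matrix without per-row apply() overhead:
# sort each row by ordering the flattened matrix within rows.
row_medians <- function(m) {
  n <- nrow(m); p <- ncol(m)
  idx <- matrix(order(row(m), m), nrow = n, byrow = TRUE)  # row-sorted positions
  sorted <- matrix(m[idx], nrow = n)
  if (p %% 2 == 1) sorted[, (p + 1L) %/% 2L]
  else (sorted[, p %/% 2L] + sorted[, p %/% 2L + 1L]) / 2
}

#' Average (mean) filter with zero padding
#'
#' Each output pixel is the mean of its k x k neighborhood on the
#' zero-padded image.
#'
#' @param img Numeric image matrix.
#' @param k Odd window size >= 3.
#' @return Filtered image matrix of the same shape.
#' @export
average_filter <- function(img, k = 3L) {
  assert_image(img)
  stopifnot_odd(k, "k")
  nb <- neighborhoods(img, as.integer(k))
  matrix(rowMeans(nb), nrow = nrow(img))
}

#' Plain 3 x 3 median filter with zero padding
#'
#' Every pixel is replaced by the center of the ascending sort of its
#' zero-padded 3 x 3 neighborhood (the 5th of 9 values).
#'
#' @param img Numeric image matrix, at least 3 x 3.
#' @return Filtered image matrix.
#' @export
median_filter3 <- function(img) {
  assert_image(img)
  if (nrow(img) < 3 || ncol(img) < 3) stop("image must be at least 3x3", call. = FALSE)
  nb <- neighborhoods(img, 3L)
  matrix(row_medians(nb), nrow = nrow(img))
}

#' Two-stage adaptive median filter
#'
#' The classical impulse-targeted filter: at each pixel the window grows from
#' 3 x 3 by steps of 2 until the window median is not an impulse (strictly
#' between the window minimum and maximum) or `s_max` is reached.  If the
#' median is not an impulse, the pixel itself is returned unchanged when it
#' is also strictly between the window extremes, and replaced by the median
#' otherwise.  If no window up to `s_max` yields a non-impulse median, the
#' `s_max` median is returned.  Windows are zero-padded at the borders.
#'
#' @param img Numeric image matrix.
#' @param s_max Maximum odd window size (default 7).
#' @return Filtered image matrix.
#' @export
adaptive_median_filter <- function(img, s_max = 7L) {
  assert_image(img)
  stopifnot_odd(s_max, "s_max")
  if (s_max > min(dim(img)) + 2L) stop("`s_max` exceeds the image extent", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  out <- img
  unresolved <- rep(TRUE, h * w)
  px <- as.vector(img)
  med_last <- px
  for (s in seq(3L, as.integer(s_max), by = 2L)) {
    idx <- which(unresolved)
    if (length(idx) == 0) break
    nb <- neighborhoods(img, s)[idx, , drop = FALSE]
    mn <- do.call(pmin, as.data.frame(nb))
    mx <- do.call(pmax, as.data.frame(nb))
    md <- row_medians(nb)
    med_last[idx] <- md
    ok <- (md > mn & md < mx) | (mn == mx)  # constant window: median is exact
    if (any(ok)) {
      sel <- idx[ok]
      keep <- px[sel] > mn[ok] & px[sel] < mx[ok]
      out[sel] <- ifelse(keep, px[sel], md[ok])
      unresolved[sel] <- FALSE
    }
  }
  still <- which(unresolved)
  if (length(still)) out[still] <- med_last[still]
  out
}

#' Histogram equalization over N gray levels
#'
#' For a discrete image with gray levels 0..N-1, the level frequencies are
#' normalized to probabilities P(k) = n_k / n, accumulated into the empirical
#' CDF, and each level remapped to `round_half_down(CDF(k) * (N - 1))`,
#' stretching the occupied range toward the full scale and flattening the
#' histogram.  Float images in \[0, 1\] are quantized to N levels first and
#' mapped back to \[0, 1\] afterwards.
#'
#' @param img Numeric image matrix: integers in 0..N-1, or floats in \[0,1\].
#' @param n_levels Number of gray levels N (default 256).
#' @return Equalized image on the same scale as the input.
#' @export
histogram_equalize <- function(img, n_levels = 256L) {
  assert_image(img)
  if (length(img) == 0) stop("empty image", call. = FALSE)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  n_levels <- as.integer(n_levels)
  is_float <- any(img != floor(img)) || (max(img) <= 1 && min(img) >= 0)
  if (is_float) {
    if (min(img) < 0 || max(img) > 1) stop("float images must lie in [0, 1]", call. = FALSE)
    lev <- pmin(floor(img * n_levels), n_levels - 1L)
  } else {
    if (min(img) < 0 || max(img) > n_levels - 1L) {
      stop("integer image values must lie in 0..N-1", call. = FALSE)
    }
    lev <- img
  }
  counts <- tabulate(as.vector(lev) + 1L, nbins = n_levels)
  p <- counts / length(lev)            # P_m(k), sums to 1
  cdf <- cumsum(p)
  map <- round_half_down(cdf * (n_levels - 1L))
  eq <- matrix(map[as.vector(lev) + 1L], nrow = nrow(img))
  if (is_float) eq / (n_levels - 1L) else eq
}

#' Gray-level probabilities of an image (histogram normalization)
#'
#' @param img Integer image with levels 0..N-1 or float image in \[0,1\].
#' @param n_levels Number of gray levels N.
#' @return Numeric vector of length N summing to 1.
#' @export
gray_level_probs <- function(img, n_levels = 256L) {
  assert_image(img)
  n_levels <- as.integer(n_levels)
  if (any(img != floor(img)) || (max(img) <= 1 && min(img) >= 0)) {
    lev <- pmin(floor(img * n_levels), n_levels - 1L)
  } else {
    lev <- img
  }
  tabulate(as.vector(lev) + 1L, nbins = n_levels) / length(img)
}

#' Default preprocessing chain
#'
#' Adaptive median filter (impulse removal), then the average filter
#' (residual Gaussian noise), then histogram equalization of the filtered
#' image — filtering precedes enhancement.
#'
#' @param img Image matrix in \[0, 1\].
#' @param s_max Adaptive-median maximum window (default 7).
#' @param k Average-filter window (default 3).
#' @param equalize Apply histogram equalization (default TRUE).
#' @param n_levels Gray levels for equalization.
#' @return Preprocessed image in \[0, 1\].
#' @export
preprocess_image <- function(img, s_max = 7L, k = 3L, equalize = TRUE,
                             n_levels = 256L) {
  out <- adaptive_median_filter(img, s_max = s_max)
  out <- average_filter(out, k = k)
  out <- pmin(pmax(out, 0), 1)
  if (equalize) out <- histogram_equalize(out, n_levels = n_levels)
  out
}
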