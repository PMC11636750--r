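# Fixed 50-feature descriptor of a segmented region.
#
# Catalogue (frozen; names and order are stable across runs):
#   5  region intensity moments  (region_mean, region_var, region_sd,
#                                 region_skew, region_kurt)
#   5  whole-image moments       (image_mean, ..., image_kurt)
#   16 region histogram bins     (hist_01 .. hist_16), equal-width on [0,1]
#   8  shape descriptors         (area_fraction, perimeter, eccentricity,
#                                 solidity, extent, major_axis, minor_axis,
#                                 compactness)
#   8  gray-level co-occurrence  (glcm_contrast, glcm_correlation,
#                                 glcm_energy, glcm_homogeneity, glcm_entropy,
#                                 glcm_dissimilarity, glcm_maxprob, glcm_var)
#   8  gradient/edge statistics  (grad_mean, grad_sd, grad_median, grad_max,
#                                 grad_p90, edge_fraction, lap_mean_abs,
#                                 lap_sd)

feature_catalogue <- function() {
  c("region_mean", "region_var", "region_sd", "region_skew", "region_kurt",
    "image_mean", "image_var", "image_sd", "image_skew", "image_kurt",
    sprintf("hist_%02d", 1:16),
    "area_fraction", "perimeter", "eccentricity", "solidity", "extent",
    "major_axis", "minor_axis", "compactness",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity",
    "glcm_entropy", "glcm_dissimilarity", "glcm_maxprob", "glcm_var",
    "grad_mean", "grad_sd", "grad_median", "grad_max", "grad_p90",
    "edge_fraction", "lap_mean_abs", "lap_sd")
}

#' First-order population moments of a pixel sample
#'
#' Population (not sample-corrected) moments: variance `m2`, skewness
#' `m3 / m2^(3/2)`, and excess kurtosis `m4 / m2^2 - 3`.  A degenerate
#' (zero-variance) sample reports skewness and kurtosis 0.
#'
#' @param x Numeric vector with at least one value.
#' @return Named numeric vector `(mean, variance, sd, skewness, kurtosis)`.
#' @export
first_order_stats <- function(x) {
  if (length(x) == 0) stop("empty pixel sample", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    return(c(mean = mu, variance = 0, sd = 0, skewness = 0, kurtosis = 0))
  }
  m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  c(mean = mu, variance = m2, sd = sqrt(m2),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Shape descriptors of a binary mask via coordinate moments (regionprops
# conventions: axes = 4*sqrt(eigenvalues of the coordinate covariance)).
shape_features <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  area <- nrow(idx)
  # 4-connected boundary pixel count as the perimeter estimate
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  nb4 <- pad[1:h, 2:(w + 1L)] + pad[3:(h + 2L), 2:(w + 1L)] +
    pad[2:(h + 1L), 1:w] + pad[2:(h + 1L), 3:(w + 2L)]
  perimeter <- sum(inner == 1L & nb4 < 4L)
  cov_m <- stats::cov(idx) * (area - 1) / max(area, 1)  # population covariance
  if (area < 2 || any(!is.finite(cov_m))) {
    ev <- c(0, 0)
  } else {
    ev <- sort(pmax(eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  extent <- area / bbox
  solidity <- area / convex_hull_area(idx)
  compact <- if (perimeter > 0) 4 * pi * area / perimeter^2 else 0
  c(area_fraction = area / (h * w), perimeter = perimeter,
    eccentricity = ecc, solidity = min(solidity, 1), extent = extent,
    major_axis = major, minor_axis = minor, compactness = compact)
}

# Area of the convex hull of pixel centers (shoelace on chull vertices),
# counting each hull pixel as a unit square via the +perimeter/2+1 Pick-style
# correction so a single pixel has hull area 1.
convex_hull_area <- function(idx) {
  if (nrow(idx) == 1) return(1)
  pts <- unique(idx)
  if (nrow(pts) == 1) return(1)
  ch <- grDevices::chull(pts[, 2], pts[, 1])
  v <- pts[ch, , drop = FALSE]
  n <- nrow(v)
  if (n < 3) {
    # collinear: length of the segment, one pixel wide
    return(max(abs(diff(range(pts[, 1]))), abs(diff(range(pts[, 2])))) + 1)
  }
  x <- v[, 2]; y <- v[, 1]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  edge <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area + edge / 2 + 1
}

# Gray-level co-occurrence statistics: 16 levels, symmetric, offsets right
# and down averaged, restricted to pixel pairs inside the mask.
glcm_features <- function(img, mask, levels = 16L) {
  q <- pmin(floor(img * levels), levels - 1L) + 1L
  h <- nrow(img); w <- ncol(img)
  pairs_i <- cbind(as.vector(q[, -w]), as.vector(q[, -1]))
  keep_i <- as.vector(mask[, -w] & mask[, -1])
  pairs_j <- cbind(as.vector(q[-h, ]), as.vector(q[-1, ]))
  keep_j <- as.vector(mask[-h, ] & mask[-1, ])
  P <- matrix(0, levels, levels)
  tab <- function(pp) {
    m <- matrix(0, levels, levels)
    if (nrow(pp) == 0) return(m)
    t1 <- table(factor(pp[, 1], levels = 1:levels), factor(pp[, 2], levels = 1:levels))
    m + unclass(t1)
  }
  P <- tab(pairs_i[keep_i, , drop = FALSE]) + tab(pairs_j[keep_j, , drop = FALSE])
  P <- P + t(P)  # symmetric
  if (sum(P) == 0) P[1, 1] <- 1
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 0
  nz <- P[P > 0]
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_entropy = -sum(nz * log(nz)),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_maxprob = max(P),
    glcm_var = sum((i - mu_i)^2 * P))
}

# Gradient/edge statistics over the region: central-difference gradient
# magnitude and 4-neighbor Laplacian, sampled at mask pixels.
gradient_features <- function(img, mask) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gm <- sqrt(gx^2 + gy^2)
  lap <- matrix(0, h, w)
  lap[2:(h - 1), 2:(w - 1)] <- img[1:(h - 2), 2:(w - 1)] + img[3:h, 2:(w - 1)] +
    img[2:(h - 1), 1:(w - 2)] + img[2:(h - 1), 3:w] - 4 * img[2:(h - 1), 2:(w - 1)]
  g <- gm[mask > 0]; l <- lap[mask > 0]
  c(grad_mean = mean(g), grad_sd = sqrt(mean((g - mean(g))^2)),
    grad_median = stats::median(g), grad_max = max(g),
    grad_p90 = as.numeric(stats::quantile(g, 0.9, names = FALSE)),
    edge_fraction = mean(g > 0.1),
    lap_mean_abs = mean(abs(l)), lap_sd = sqrt(mean((l - mean(l))^2)))
}

#' Extract the fixed 50-feature vector from a segmented region
#'
#' Combines region and whole-image intensity moments, a 16-bin region
#' histogram, shape descriptors of the mask, gray-level co-occurrence
#' statistics, and gradient/edge statistics (see the catalogue at the top of
#' the features source file).  A pure function of `(img, mask)`.
#'
#' @param img Image matrix in \[0, 1\].
#' @param mask Aligned binary mask with at least one foreground pixel.
#' @return Named numeric vector of length 50 (finite values).
#' @export
extract_feature_vector <- function(img, mask) {
  assert_image(img)
  if (!all(dim(img) == dim(mask))) stop("mask not aligned to image", call. = FALSE)
  if (sum(mask) == 0) stop("empty mask: no segmented region to describe", call. = FALSE)
  region <- img[mask > 0]
  f_region <- first_order_stats(region)
  f_image <- first_order_stats(as.vector(img))
  bins <- pmin(floor(region * 16) + 1L, 16L)
  f_hist <- tabulate(bins, nbins = 16L) / length(region)
  out <- c(f_region, f_image, f_hist, shape_features(mask),
           glcm_features(img, mask > 0), gradient_features(img, mask))
  names(out) <- feature_catalogue()
  stopifnot(length(out) == 50, all(is.finite(out)))
  out
}

#' Build a feature table from a dataset of images and masks
#'
#' @param images List of image matrices.
#' @param masks List of aligned binary masks; empty masks fall back to the
#'   whole-image region when `fallback_whole_image` is TRUE (the pipeline's
#'   behavior for images segmented as tumor-free), and error otherwise.
#' @param labels Character or 0/1 labels; cancer = 1.
#' @param fallback_whole_image Use an all-ones mask for empty masks.
#' @return A tibble with 50 feature columns plus a `label` column (0/1).
#' @export
feature_table <- function(images, masks, labels, fallback_whole_image = FALSE) {
  stopifnot(length(images) == length(masks), length(images) == length(labels))
  rows <- lapply(seq_along(images), function(i) {
    m <- masks[[i]]
    if (sum(m) == 0) {
      if (!fallback_whole_image) stop("empty mask at sample ", i, call. = FALSE)
      m <- matrix(1L, nrow(images[[i]]), ncol(images[[i]]))
    }
    extract_feature_vector(images[[i]], m)
  })
  tbl <- tibble::as_tibble(do.call(rbind, rows))
  lab <- if (is.character(labels)) as.integer(labels == "cancer") else as.integer(labels)
  tbl$label <- lab
  tbl
}
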