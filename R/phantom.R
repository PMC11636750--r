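#' Configuration for synthetic lung-CT phantoms
#'
#' A phantom is a 2-D grayscale image in \[0, 1\] emulating an axial chest CT
#' slice: a soft-tissue background, two darker elliptical lung fields, and
#' zero or more bright tumor blobs inside the lungs.  Each phantom carries a
#' pixel-exact ground-truth tumor mask and a binary image-level label
#' (cancer iff at least one tumor was placed).
#'
#' @param height,width Image dimensions in pixels (>= 32). Default 240x240,
#'   the slice size of typical local CT collections.
#' @param lung_ellipses A list of two ellipse specs, each
#'   `list(cx=, cy=, rx=, ry=)` in relative \[0,1\] coordinates.
#' @param tumor_count Number of tumors to place (>= 0).
#' @param tumor_radius_range Length-2 numeric, tumor radius bounds in pixels.
#' @param tumor_intensity Additive tumor contrast over the lung-field
#'   intensity, in \[0, 1\].
#' @param gaussian_sigma Standard deviation of additive Gaussian noise.
#' @param sp_density Salt-and-pepper impulse fraction in \[0, 1\].
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 240, width = 240,
                           lung_ellipses = list(
                             list(cx = 0.32, cy = 0.50, rx = 0.17, ry = 0.34),
                             list(cx = 0.68, cy = 0.50, rx = 0.17, ry = 0.34)
                           ),
                           tumor_count = 1,
                           tumor_radius_range = c(10, 22),
                           tumor_axis_ratio = c(0.7, 1),
                           tumor_intensity = 0.40,
                           gaussian_sigma = 0.03,
                           sp_density = 0.02,
                           seed = 1L) {
  if (height < 32 || width < 32) stop("phantom dimensions must be >= 32 pixels", call. = FALSE)
  if (sp_density < 0 || sp_density > 1) stop("`sp_density` must lie in [0, 1]", call. = FALSE)
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0", call. = FALSE)
  if (tumor_count < 0) stop("`tumor_count` must be >= 0", call. = FALSE)
  if (length(tumor_radius_range) != 2 || any(tumor_radius_range <= 0) ||
      tumor_radius_range[1] > tumor_radius_range[2]) {
    stop("`tumor_radius_range` must be increasing and positive", call. = FALSE)
  }
  if (tumor_intensity < 0 || tumor_intensity > 1) stop("`tumor_intensity` must lie in [0, 1]", call. = FALSE)
  max_ry <- max(vapply(lung_ellipses, function(e) e$ry, numeric(1)))
  if (tumor_radius_range[2] >= max_ry * height) {
    stop("tumor radius does not fit inside the lung field", call. = FALSE)
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    lung_ellipses = lung_ellipses, tumor_count = as.integer(tumor_count),
    tumor_radius_range = tumor_radius_range,
    tumor_axis_ratio = tumor_axis_ratio, tumor_intensity = tumor_intensity,
    gaussian_sigma = gaussian_sigma, sp_density = sp_density,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Boolean mask of an ellipse (center/radii in pixel units) on an H x W grid.
ellipse_mask <- function(h, w, cx, cy, rx, ry) {
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Generate one synthetic CT-like phantom
#'
#' Draws the soft-tissue/lung-field background, places `tumor_count` bright
#' elliptical tumors fully inside randomly chosen lung fields, then applies
#' Gaussian noise followed by salt-and-pepper impulses (so the impulse
#' extremes reach the filters intact).  Deterministic for fixed config and
#' seed.
#'
#' @param cfg A [phantom_config()].
#' @param seed Optional integer overriding `cfg$seed`.
#' @return An object of class `phantom_sample`: a list with `image` (H x W
#'   matrix in \[0,1\]), `mask` (0/1 matrix), and `label` (`"cancer"` or
#'   `"non-cancer"`).  The mask is non-zero iff the label is `"cancer"`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  h <- cfg$height; w <- cfg$width
  with_seed(seed, {
    # intensities: mid-gray soft tissue, dark air-filled lungs, and tumors
    # brighter than both so the tumor is the brightest structure in frame
    img <- matrix(0.40, nrow = h, ncol = w)
    lung <- matrix(FALSE, nrow = h, ncol = w)
    for (e in cfg$lung_ellipses) {
      lung <- lung | ellipse_mask(h, w, e$cx * w, e$cy * h, e$rx * w, e$ry * h)
    }
    img[lung] <- 0.15
    mask <- matrix(0L, nrow = h, ncol = w)
    tumors <- list()
    if (cfg$tumor_count > 0) {
      for (t in seq_len(cfg$tumor_count)) {
        r <- stats::runif(1, cfg$tumor_radius_range[1], cfg$tumor_radius_range[2])
        axis_ratio <- stats::runif(1, cfg$tumor_axis_ratio[1], cfg$tumor_axis_ratio[2])
        e <- cfg$lung_ellipses[[sample.int(length(cfg$lung_ellipses), 1)]]
        ok <- FALSE
        for (try in 1:200) {
          # sample a center such that the tumor bounding circle stays inside
          # the (shrunken) lung ellipse
          u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
          if (u^2 + v^2 > 1) next
          cx <- e$cx * w + u * (e$rx * w - r)
          cy <- e$cy * h + v * (e$ry * h - r)
          if (e$rx * w - r <= 0 || e$ry * h - r <= 0) break
          ok <- TRUE
          break
        }
        if (!ok) stop("tumor does not fit in lung field", call. = FALSE)
        tm <- ellipse_mask(h, w, cx, cy, r, r * axis_ratio)
        mask[tm] <- 1L
        img[tm] <- 0.15 + cfg$tumor_intensity
        tumors[[t]] <- list(cx = cx, cy = cy, rx = r, ry = r * axis_ratio)
      }
    }
    noise_seed <- derive_seed(seed, 7L)
    img <- add_noise(img, cfg$gaussian_sigma, cfg$sp_density, seed = noise_seed)
    structure(list(
      image = img, mask = mask,
      label = if (cfg$tumor_count > 0) "cancer" else "non-cancer",
      tumors = tumors
    ), class = "phantom_sample")
  })
}

#' Add Gaussian and salt-and-pepper noise to an image
#'
#' Gaussian noise is added first and the result clipped to \[0, 1\]; impulse
#' noise then sets a fraction `sp_density` of pixels to 0 or 1 (half each in
#' expectation), so the impulse extremes are exact and the median filters can
#' be assessed against them.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param sp_density Fraction of pixels hit by impulses, in \[0, 1\].
#' @param seed Integer seed.
#' @return Noisy image matrix in \[0, 1\].
#' @export
add_noise <- function(img, sigma, sp_density, seed = 1L) {
  assert_image(img)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sp_density < 0 || sp_density > 1) stop("`sp_density` must lie in [0, 1]", call. = FALSE)
  if (sigma == 0 && sp_density == 0) return(img)
  with_seed(seed, {
    out <- img
    if (sigma > 0) {
      out <- out + matrix(stats::rnorm(length(img), 0, sigma), nrow = nrow(img))
      out <- pmin(pmax(out, 0), 1)
    }
    if (sp_density > 0) {
      hit <- stats::runif(length(img)) < sp_density
      salt <- stats::runif(length(img)) < 0.5
      out[hit & salt] <- 1
      out[hit & !salt] <- 0
    }
    out
  })
}

#' Generate a labelled, split phantom dataset
#'
#' Class counts follow `prevalence` within rounding; train/validation/test
#' splits are stratified by label so each split keeps the dataset prevalence.
#'
#' @param n Number of phantoms (>= 10).
#' @param prevalence Fraction of cancer-labelled samples, in (0, 1).
#' @param split_fracs Length-3 fractions (train, validation, test) summing to 1.
#' @param cfg Base [phantom_config()]; `tumor_count` is overridden per sample
#'   (0 for non-cancer, its configured value with a minimum of 1 for cancer).
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @return An object of class `ct_dataset`: list with `samples`, `labels`
#'   (character vector), and `split` (list of index vectors `train`,
#'   `validation`, `test`; disjoint, union = all indices).
#' @export
generate_dataset <- function(n, prevalence = 0.5,
                             split_fracs = c(0.4, 0.3, 0.3),
                             cfg = phantom_config(), seed = 1L) {
  if (n < 10) stop("`n` must be >= 10", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  if (length(split_fracs) != 3 || abs(sum(split_fracs) - 1) > 1e-8) {
    stop("`split_fracs` must be three fractions summing to 1", call. = FALSE)
  }
  n_cancer <- round(n * prevalence)
  labels <- rep(c("cancer", "non-cancer"), c(n_cancer, n - n_cancer))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$tumor_count <- if (labels[i] == "cancer") max(1L, cfg$tumor_count) else 0L
    samples[[i]] <- generate_phantom(ci, seed = derive_seed(seed, i))
  }
  split <- make_split(labels, split_fracs, seed = derive_seed(seed, 0L))
  structure(list(samples = samples, labels = labels, split = split),
            class = "ct_dataset")
}

#' Stratified train/validation/test split
#'
#' Splits are stratified by label.  `split_fracs` may be a single length-3
#' vector applied to every class, or a matrix with one row per class (row
#' names = class labels), so per-class split distributions — such as a
#' dataset whose two classes are spread differently over train, validation,
#' and test — can be reproduced.
#'
#' @param labels Character vector of class labels.
#' @param split_fracs Length-3 fractions summing to 1, or a per-class matrix
#'   of such rows.
#' @param seed Integer seed.
#' @return List of sorted index vectors `train`, `validation`, `test`;
#'   disjoint with union equal to all indices.
#' @export
make_split <- function(labels, split_fracs = c(0.4, 0.3, 0.3), seed = 1L) {
  fr_for <- function(lab) {
    if (is.matrix(split_fracs)) split_fracs[lab, ] else split_fracs
  }
  for (lab in unique(labels)) {
    fr <- fr_for(lab)
    if (length(fr) != 3 || abs(sum(fr) - 1) > 1e-8) {
      stop("split fractions must be three values summing to 1", call. = FALSE)
    }
  }
  with_seed(seed, {
    out <- list(train = integer(0), validation = integer(0), test = integer(0))
    for (lab in unique(labels)) {
      fr <- fr_for(lab)
      idx <- sample(which(labels == lab))
      m <- length(idx)
      n_tr <- min(round(m * fr[1]), m)
      n_va <- min(round(m * fr[2]), m - n_tr)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$validation <- c(out$validation, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[setdiff(seq_len(m), seq_len(n_tr + n_va))])
    }
    lapply(out, sort)
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, label=%s, tumor pixels=%d\n",
              nrow(x$image), ncol(x$image), x$label, sum(x$mask)))
  invisible(x)
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat(sprintf("<ct_dataset> n=%d (cancer=%d), splits train/val/test = %d/%d/%d\n",
              length(x$samples), sum(x$labels == "cancer"),
              length(x$split$train), length(x$split$validation), length(x$split$test)))
  invisible(x)
}
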