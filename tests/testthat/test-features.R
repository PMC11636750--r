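test_that("first-order moments match closed forms and the sum oracle", {
  const <- first_order_stats(rep(3.2, 10))
  expect_equal(unname(const), c(3.2, 0, 0, 0, 0))

  two <- first_order_stats(c(0, 1))
  expect_equal(unname(two[c("skewness", "kurtosis")]), c(0, -2))

  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(50)
    got <- first_order_stats(x)
    mu <- sum(x) / 50
    m2 <- sum((x - mu)^2) / 50
    m3 <- sum((x - mu)^3) / 50
    m4 <- sum((x - mu)^4) / 50
    expect_equal(unname(got),
                 c(mu, m2, sqrt(m2), m3 / m2^1.5, m4 / m2^2 - 3),
                 tolerance = 1e-12)
  }
  expect_error(first_order_stats(numeric(0)), "empty")
})

test_that("the feature vector is complete, named, finite, and pure", {
  s <- generate_phantom(small_phantom_cfg(), seed = 3)
  fv <- extract_feature_vector(s$image, s$mask)
  expect_length(fv, 50)
  expect_equal(anyDuplicated(names(fv)), 0)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_feature_vector(s$image, s$mask))

  expect_error(extract_feature_vector(s$image, matrix(0L, 96, 96)), "empty mask")
})

test_that("intensity, histogram, and shape features are translation invariant", {
  img <- matrix(0.2, 64, 64)
  x <- matrix(rep(1:64, each = 64), 64); y <- matrix(rep(1:64, 64), 64)
  disk1 <- ((x - 25)^2 + (y - 25)^2 <= 64) * 1L
  img1 <- img; img1[disk1 == 1] <- 0.8
  disk2 <- ((x - 40)^2 + (y - 37)^2 <= 64) * 1L
  img2 <- img; img2[disk2 == 1] <- 0.8
  f1 <- extract_feature_vector(img1, disk1)
  f2 <- extract_feature_vector(img2, disk2)
  keep <- c(sprintf("hist_%02d", 1:16),
            "region_mean", "region_var", "region_sd", "region_skew", "region_kurt",
            "area_fraction", "perimeter", "eccentricity", "solidity", "extent",
            "major_axis", "minor_axis", "compactness")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-12)
})

test_that("area fraction equals the rasterized disk count", {
  img <- matrix(0.5, 80, 80)
  x <- matrix(rep(1:80, each = 80), 80); y <- matrix(rep(1:80, 80), 80)
  disk <- ((x - 40)^2 + (y - 40)^2 <= 12^2) * 1L
  fv <- extract_feature_vector(img, disk)
  expect_equal(unname(fv["area_fraction"]), sum(disk) / (80 * 80))
})

test_that("feature tables are rectangular with 0/1 cancer labels", {
  ss <- lapply(1:4, function(i) generate_phantom(small_phantom_cfg(
    tumor_count = i %% 2), seed = i))
  tbl <- feature_table(lapply(ss, `[[`, "image"),
                       lapply(ss, `[[`, "mask"),
                       vapply(ss, `[[`, character(1), "label"),
                       fallback_whole_image = TRUE)
  expect_s3_class(tbl, "tbl_df")
  expect_equal(dim(tbl), c(4, 51))
  expect_setequal(unique(tbl$label), c(0L, 1L))
  expect_error(feature_table(lapply(ss, `[[`, "image"),
                             lapply(ss, `[[`, "mask"),
                             vapply(ss, `[[`, character(1), "label")),
               "empty mask")
})
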