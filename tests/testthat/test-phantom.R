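test_that("phantom generation honors the no-tumor case and determinism", {
  cfg <- small_phantom_cfg(tumor_count = 0, gaussian_sigma = 0, sp_density = 0)
  s <- generate_phantom(cfg, seed = 1)
  expect_equal(sum(s$mask), 0)
  expect_equal(s$label, "non-cancer")
  expect_true(all(s$image >= 0 & s$image <= 1))

  cfg2 <- small_phantom_cfg(seed = 3)
  expect_identical(generate_phantom(cfg2), generate_phantom(cfg2))
})

test_that("a circular tumor mask matches brute-force disk rasterization", {
  cfg <- small_phantom_cfg(tumor_radius_range = c(10, 10),
                           tumor_axis_ratio = c(1, 1),
                           gaussian_sigma = 0, sp_density = 0)
  s <- generate_phantom(cfg, seed = 5)
  tum <- s$tumors[[1]]
  x <- matrix(rep(1:96, each = 96), 96)
  y <- matrix(rep(1:96, times = 96), 96)
  oracle <- sum((x - tum$cx)^2 + (y - tum$cy)^2 <= 10^2)
  expect_equal(sum(s$mask), oracle)
})

test_that("mask is non-zero exactly for cancer labels across seeds", {
  for (seed in 1:5) {
    s1 <- generate_phantom(small_phantom_cfg(tumor_count = 1), seed = seed)
    s0 <- generate_phantom(small_phantom_cfg(tumor_count = 0), seed = seed)
    expect_true(sum(s1$mask) > 0 && s1$label == "cancer")
    expect_true(sum(s0$mask) == 0 && s0$label == "non-cancer")
  }
})

test_that("oversized tumors are rejected as configuration errors", {
  expect_error(phantom_config(height = 96, width = 96,
                              tumor_radius_range = c(40, 40)),
               "fit inside")
})

test_that("noise injection matches its nominal statistics", {
  img <- matrix(0.5, 240, 240)
  expect_identical(add_noise(img, 0, 0, seed = 1), img)

  noisy <- add_noise(img, 0, 0.1, seed = 2)
  frac <- mean(noisy %in% c(0, 1))
  sd3 <- 3 * sqrt(0.1 * 0.9 / length(img))
  expect_lt(abs(frac - 0.1), sd3)

  gn <- add_noise(img, 0.05, 0, seed = 3)
  expect_lt(abs(sd(as.vector(gn - img)) - 0.05), 0.005)
})

test_that("datasets have the requested class balance and a partition split", {
  cfg <- small_phantom_cfg(gaussian_sigma = 0, sp_density = 0)
  ds <- generate_dataset(100, prevalence = 0.5, cfg = cfg, seed = 4)
  expect_equal(sum(ds$labels == "cancer"), 50)
  idx <- unname(unlist(ds$split))
  expect_equal(sort(idx), 1:100)
  expect_equal(length(idx), length(unique(idx)))
  # stratified: each split keeps the prevalence within rounding
  for (s in ds$split) {
    expect_lt(abs(mean(ds$labels[s] == "cancer") - 0.5), 0.05)
  }
  # determinism at the dataset level
  ds2 <- generate_dataset(100, prevalence = 0.5, cfg = cfg, seed = 4)
  expect_identical(ds, ds2)
})

test_that("per-class split fractions reproduce a two-class three-way table", {
  # class-by-split cell structure with distinct per-class distributions
  counts <- rbind(cancer = c(2145, 2845, 2955),
                  `non-cancer` = c(2891, 2166, 2403))
  n <- sum(counts)
  labels <- rep(rownames(counts), rowSums(counts))
  fracs <- counts / rowSums(counts)
  colnames(fracs) <- NULL
  sp <- make_split(labels, fracs, seed = 9)
  got <- sapply(sp, function(ix) c(sum(labels[ix] == "cancer"),
                                   sum(labels[ix] == "non-cancer")))
  expect_true(all(abs(got - rbind(counts[1, ], counts[2, ])) <= 1))
})

test_that("invalid dataset parameters are rejected", {
  expect_error(generate_dataset(5), ">= 10")
  expect_error(generate_dataset(20, prevalence = 0), "prevalence")
  expect_error(generate_dataset(20, split_fracs = c(0.5, 0.5, 0.5)), "summing to 1")
})
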