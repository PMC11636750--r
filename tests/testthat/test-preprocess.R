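test_that("average filter matches hand arithmetic and the brute-force oracle", {
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_equal(average_filter(m, 3)[2, 2], 1)

  const <- matrix(4, 7, 7)
  expect_equal(average_filter(const, 3)[3:5, 3:5], matrix(4, 3, 3))

  expect_error(average_filter(m, 4), "odd")

  set.seed(1)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    out <- average_filter(img, 3)
    pad <- matrix(0, 18, 18); pad[2:17, 2:17] <- img
    for (i in c(1, 7, 16)) for (j in c(1, 9, 16)) {
      expect_equal(out[i, j], mean(pad[i:(i + 2), j:(j + 2)]))
    }
  }
})

test_that("median filter equals the sorted-neighborhood oracle exhaustively", {
  f <- matrix(10, 5, 5); f[3, 3] <- 255
  expect_equal(median_filter3(f)[3, 3], 10)

  ones <- matrix(1, 5, 5)
  expect_equal(median_filter3(ones)[1, 1], 0)  # median of {0 x5, 1 x4}
  expect_equal(median_filter3(ones)[3, 3], 1)

  set.seed(2)
  for (rep in 1:10) {
    img <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
    out <- median_filter3(img)
    pad <- matrix(0, 7, 7); pad[2:6, 2:6] <- img
    for (i in 1:5) for (j in 1:5) {
      expect_equal(out[i, j], median(pad[i:(i + 2), j:(j + 2)]))
    }
  }
})

test_that("adaptive median passes non-extreme pixels through unchanged", {
  g <- matrix(seq(0.2, 0.8, length.out = 49), 7, 7)
  out <- adaptive_median_filter(g, 5)
  expect_equal(out[2:6, 2:6], g[2:6, 2:6])
})

test_that("adaptive median cleans salt-and-pepper better than it hurts", {
  clean <- generate_phantom(small_phantom_cfg(gaussian_sigma = 0, sp_density = 0),
                            seed = 5)$image
  noisy <- add_noise(clean, 0, 0.10, seed = 9)
  filt <- adaptive_median_filter(noisy, 7)
  expect_lt(mean(abs(filt - clean)), mean(abs(noisy - clean)))

  # at 20% impulses the growing window corrects more than the plain 3x3
  noisy2 <- add_noise(clean, 0, 0.20, seed = 10)
  resid <- function(img) sum((img %in% c(0, 1)) & !(clean %in% c(0, 1)))
  expect_lt(resid(adaptive_median_filter(noisy2, 7)),
            resid(median_filter3(noisy2)))
})

test_that("histogram equalization reproduces the two-level hand computation", {
  const <- matrix(7L, 8, 8)
  expect_true(all(histogram_equalize(const) ==
                    histogram_equalize(const)[1, 1]))

  img <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  he <- histogram_equalize(img)
  expect_setequal(unique(as.vector(he)), c(127, 255))
  expect_equal(he[img == 0][1], 127)   # round-half-down of 0.5 * 255
  expect_equal(he[img == 255][1], 255)
})

test_that("gray-level probabilities normalize to one", {
  set.seed(3)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(sum(gray_level_probs(img)), 1)
  }
})

test_that("equalized histogram is uniform up to the largest input bin", {
  set.seed(4)
  img <- matrix(sample(0:63, 4096, replace = TRUE, prob = runif(64)^2), 64, 64)
  he <- histogram_equalize(img, n_levels = 64L)
  p_in <- gray_level_probs(img, 64L)
  p_out <- gray_level_probs(he, 64L)
  # classical bound: output CDF deviates from uniform by at most max bin mass
  dev <- max(abs(cumsum(p_out) - (1:64) / 64))
  expect_lte(dev, max(p_in) + 1e-12)
})
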