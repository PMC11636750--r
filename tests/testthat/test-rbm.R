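test_that("energy matches hand arithmetic and is linear in the weights", {
  p0 <- structure(list(WT = matrix(0, 2, 2), b_vis = c(0, 0), b_hid = c(0, 0),
                       kind = "BB"), class = "rbm_params")
  expect_equal(rbm_energy(c(0, 0), c(0, 0), p0), 0)

  p1 <- structure(list(WT = matrix(2, 1, 1), b_vis = 0.5, b_hid = -1,
                       kind = "BB"), class = "rbm_params")
  expect_equal(rbm_energy(1, 1, p1), -1.5)

  # energy is linear in WT at fixed (v, h): slope is -v * h
  p2 <- p1; p2$WT <- matrix(5, 1, 1)
  expect_equal(rbm_energy(1, 1, p2) - rbm_energy(1, 1, p1), -(5 - 2))

  expect_error(rbm_energy(c(1, 0), 1, p1), "mismatch")
  expect_error(rbm_energy(0.5, 1, p1), "binary")
})

test_that("conditionals match brute-force enumeration on all small RBMs", {
  expect_equal(cond_hidden(c(0, 0, 0), rbm_params(3, 2, "BB", init_sd = 0)),
               c(0.5, 0.5))
  set.seed(10)
  for (nv in 2:5) for (nh in 2:4) {
    if (nv + nh > 12) next
    p <- rbm_params(nv, nh, "BB", init_sd = 1, seed = nv * 10 + nh)
    p$b_vis <- rnorm(nv); p$b_hid <- rnorm(nh)
    v <- sample(0:1, nv, replace = TRUE)
    expect_equal(cond_hidden(v, p), enum_cond_hidden(v, p), tolerance = 1e-10)
    h <- sample(0:1, nh, replace = TRUE)
    expect_equal(cond_visible(h, p), enum_cond_visible(h, p), tolerance = 1e-10)
  }
  # Gaussian-visible machines: hidden conditional against hidden enumeration
  for (nv in 2:4) {
    p <- rbm_params(nv, 3, "GB", init_sd = 0.7, seed = nv)
    p$b_vis <- rnorm(nv); p$b_hid <- rnorm(3)
    v <- rnorm(nv)
    expect_equal(cond_hidden(v, p), enum_cond_hidden(v, p), tolerance = 1e-10)
  }
})

test_that("hidden conditionals increase with the connecting weight", {
  p <- rbm_params(2, 2, "BB", init_sd = 0.3, seed = 1)
  base <- cond_hidden(c(1, 0), p)[1]
  p$WT[1, 1] <- p$WT[1, 1] + 1
  expect_gt(cond_hidden(c(1, 0), p)[1], base)
})

test_that("partition function and joint distribution behave exactly", {
  p0 <- rbm_params(3, 2, "BB", init_sd = 0)
  expect_equal(partition_bruteforce(p0), 32)  # 2^5 states at energy 0

  set.seed(11)
  for (rep in 1:5) {
    p <- rbm_params(3, 3, "BB", init_sd = 1, seed = rep)
    p$b_vis <- rnorm(3); p$b_hid <- rnorm(3)
    V <- lungct:::binary_states(3); H <- lungct:::binary_states(3)
    total <- sum(vapply(seq_len(nrow(V)), function(i) {
      sum(vapply(seq_len(nrow(H)), function(j) joint_prob(V[i, ], H[j, ], p),
                 numeric(1)))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-10)
  }

  # relabeling hidden units (permuting weights and biases) leaves the joint
  # probability of the correspondingly permuted configuration unchanged
  p <- rbm_params(3, 3, "BB", init_sd = 1, seed = 6)
  p$b_hid <- rnorm(3)
  perm <- c(2, 3, 1)
  pp <- p; pp$WT <- p$WT[, perm]; pp$b_hid <- p$b_hid[perm]
  v <- c(1, 0, 1); h <- c(1, 1, 0)
  expect_equal(joint_prob(v, h[perm], pp), joint_prob(v, h, p),
               tolerance = 1e-12)

  expect_error(partition_bruteforce(rbm_params(15, 10, "BB")), "too many")
})

test_that("contrastive divergence lowers the exact likelihood deficit", {
  teacher <- rbm_params(4, 3, "BB", init_sd = 1.5, seed = 99)
  data <- sample_rbm_visibles(teacher, 300, seed = 123)
  student <- rbm_params(4, 3, "BB", init_sd = 0.05, seed = 7)
  cfg <- train_config(learning_rate = 0.05, epochs = 10, seed = 5)
  trained <- cd_train(student, data, cfg, monitor_nll = TRUE)
  nll <- attr(trained, "nll")
  expect_length(nll, 11)
  expect_lt(nll[11], nll[1])                 # decreasing from start to end
  expect_true(all(nll[-1] < nll[1]))         # every epoch beats the start
})

test_that("training is deterministic and reduces reconstruction error", {
  teacher <- rbm_params(4, 3, "BB", init_sd = 1.5, seed = 99)
  data <- sample_rbm_visibles(teacher, 200, seed = 21)
  cfg <- train_config(learning_rate = 0.05, epochs = 5, seed = 9)
  t1 <- cd_train(rbm_params(4, 3, "BB", seed = 2), data, cfg)
  t2 <- cd_train(rbm_params(4, 3, "BB", seed = 2), data, cfg)
  expect_identical(t1, t2)

  # 4x4 bars-and-stripes patches: mean-field reconstruction improves
  bars <- do.call(rbind, lapply(0:15, function(code) {
    bits <- as.integer(intToBits(code))[1:4]
    as.vector(matrix(rep(bits, each = 4), 4))
  }))
  init <- rbm_params(16, 8, "BB", seed = 3)
  recon_err <- function(p) {  # mean-field reconstruction through the hiddens
    vh <- cond_visible(cond_hidden(bars, p), p)
    mean((bars - vh)^2)
  }
  trained <- cd_train(init, bars, train_config(learning_rate = 0.05,
                                               epochs = 10, batch = 4, seed = 4))
  expect_lt(recon_err(trained), recon_err(init))

  expect_error(cd_train(init, matrix(numeric(0), 0, 16), train_config()),
               "non-empty")
})
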