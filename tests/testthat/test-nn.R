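# Neural regressors: sampling, augmentation, architecture, training
# mechanics, prediction invariances.  (Recovery accuracy at the published
# scaled-down schedule is exercised in the acceptance tests.)

test_that("training parameters are drawn uniformly over the stated ranges", {
  p <- sample_training_params("muscle", 100000, seed = 4)
  expect_equal(nrow(p), 100000L)
  expect_true(all(p$t2f_ms >= 50 & p$t2f_ms <= 250))
  expect_true(all(p$t2w_ms >= 10 & p$t2w_ms <= 80))
  expect_true(all(p$ff >= 0 & p$ff <= 1))
  expect_true(all(p$b1 >= 0.4 & p$b1 <= 1.2))
  # empirical extremes approach the range endpoints (uniform sampling)
  expect_lt(min(p$t2w_ms) - 10, 0.01 * 70)
  expect_lt(80 - max(p$t2w_ms), 0.01 * 70)
  expect_lt(min(p$b1) - 0.4, 0.01 * 0.8)

  pf <- sample_training_params("fat", 1000, seed = 4)
  expect_true(all(pf$ff == 0.9))
  expect_true(all(pf$t2w_ms <= 110))

  # reproducible under the seed
  expect_identical(sample_training_params("muscle", 50, seed = 7),
                   sample_training_params("muscle", 50, seed = 7))
})

test_that("training signals are the two-component EPG trains", {
  sq <- seq_preset(32)
  p <- sample_training_params("muscle", 10, seed = 3)
  s <- simulate_training_signals(p, sq)
  for (i in c(1, 5, 10)) {
    tp <- tissue_params(p$t2w_ms[i], p$t2f_ms[i], p$ff[i], p$b1[i])
    expect_equal(s[i, ], mese_two_component(tp, sq), tolerance = 1e-12)
  }
})

test_that("augmentation normalizes to unit norm; zero noise is exact", {
  sq <- seq_preset(32)
  s <- simulate_training_signals(sample_training_params("muscle", 20, seed = 1), sq)
  a0 <- augment_and_normalize(s, NULL)
  expect_equal(a0, s / sqrt(rowSums(s^2)), tolerance = 1e-12)
  set.seed(2)
  an <- augment_and_normalize(s, noise_spec("variance_range", 1e-7, 5e-5))
  expect_equal(sqrt(rowSums(an^2)), rep(1, 20), tolerance = 1e-9)
  expect_error(noise_spec("variance_range", 0, 1), "lo")
})

test_that("the two-channel magnitude noise reproduces the Rician mean", {
  # closed-form Rician mean via the Laguerre half polynomial
  rice_mean <- function(nu, sigma) {
    x <- -nu^2 / (2 * sigma^2)
    sigma * sqrt(pi / 2) * exp(x / 2) *
      ((1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
         x * besselI(-x / 2, 1, expon.scaled = TRUE))
  }
  sigma <- sqrt(5e-5)
  n <- 1e5
  set.seed(8)
  for (nu in c(0, 0.005, 0.02)) {
    draws <- sqrt((nu + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    expect_equal(mean(draws), rice_mean(nu, sigma), tolerance = 0.05)
  }
  # the same floor must appear in the augmentation pipeline: a tiny echo
  # acquires the Rayleigh-like floor before normalization
  s <- matrix(c(rep(0.5, 16), 0.001), n, 17, byrow = TRUE)
  set.seed(9)
  a <- augment_and_normalize(s, noise_spec("variance_range", 5e-5, 5e-5))
  nrm <- sqrt(sum(c(rep(0.5, 16), 0.001)^2))
  expect_equal(mean(a[, 17]) * nrm, rice_mean(0.001, sigma), tolerance = 0.05)
})

test_that("the architecture is a 6-weighted-layer bottleneck", {
  m <- build_model("muscle", etl = 17, layer_sizes = c(256, 128, 64, 32, 16))
  expect_length(m$W, 6)                       # 5 hidden + 1 linear output
  expect_equal(ncol(m$W[[6]]), 3L)
  expect_equal(nrow(m$W[[1]]), 18L)           # etl + scaled T2f input
  f <- build_model("fat", etl = 17, layer_sizes = c(256, 128, 64, 32, 16))
  expect_equal(nrow(f$W[[1]]), 17L)

  # closed-form parameter count: sum(w_i * w_{i+1} + w_{i+1})
  dims <- c(18, 256, 128, 64, 32, 16, 3)
  expect_equal(n_parameters(m),
               sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1]))

  # forward pass on zero input is finite
  out <- myowater:::nn_forward(m, matrix(0, 2, 18))
  expect_true(all(is.finite(out)))

  expect_error(build_model("muscle", layer_sizes = c(64, 128)),
               "non-increasing")
})

test_that("a short training run reduces the loss and records history", {
  sq <- seq_ideal
  m <- build_model("muscle", 17, layer_sizes = c(64, 32, 16, 8, 8), seed = 1)
  m <- train_regressor(m, sq, n_train = 3000, epochs = 4,
                       steps_per_epoch = 60, batch = 128, seed = 5)
  expect_true(m$trained)
  expect_length(m$loss_history, 4)
  expect_lt(m$loss_history[4], m$loss_history[1])
  expect_equal(m$seq_hash, seq_hash(sq))

  # predictions are invariant under positive rescaling of the signal
  p <- sample_training_params("muscle", 5, seed = 12)
  s <- simulate_training_signals(p, sq)
  pr1 <- predict_muscle(m, s, p$t2f_ms)
  pr2 <- predict_muscle(m, 7.7 * s, p$t2f_ms)
  expect_equal(pr1$t2w_ms, pr2$t2w_ms, tolerance = 1e-12)
  expect_equal(pr1$ff, pr2$ff, tolerance = 1e-12)

  # outputs are clipped to the training ranges
  expect_true(all(pr1$t2w_ms >= 10 & pr1$t2w_ms <= 80))
  expect_true(all(pr1$ff >= 0 & pr1$ff <= 1))

  # preconditions
  expect_error(predict_muscle(m, s, 300), "training range")
  expect_error(predict_muscle(m, s[, 1:10], 150), "length")
  expect_error(predict_fat(m, s), "fat")

  # broom-style accessors
  expect_equal(nrow(tidy(m)), 4L)
  expect_equal(glance(m)$epochs, 4L)
})

test_that("trained bundles survive a save/load round trip", {
  sq <- seq_ideal
  m <- build_model("fat", 17, layer_sizes = c(32, 16, 8, 8, 8), seed = 2)
  m <- train_regressor(m, sq, n_train = 1000, epochs = 2,
                       steps_per_epoch = 30, batch = 64, seed = 6)
  dir <- tempfile()
  save_regressor(m, dir)
  m2 <- load_regressor(dir)
  p <- sample_training_params("fat", 8, seed = 3)
  s <- simulate_training_signals(p, sq)
  expect_equal(predict_fat(m2, s)$t2f_ms, predict_fat(m, s)$t2f_ms,
               tolerance = 1e-9)
  expect_equal(m2$seq_hash, m$seq_hash)
})
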