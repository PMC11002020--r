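# Digital thigh phantom.

test_that("the default layout has ten in-range compartments", {
  spec <- default_thigh_phantom()
  expect_equal(nrow(spec$compartments), 10L)
  expect_true(all(spec$compartments$t2w_ms >= 25 &
                    spec$compartments$t2w_ms <= 45))
  expect_true(all(spec$compartments$ff >= 0 & spec$compartments$ff <= 0.8))
  expect_setequal(spec$compartments$ff,
                  c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  expect_true(spec$t2f_ms >= 50 && spec$t2f_ms <= 250)
  # t2w assignment deliberately uncorrelated with ff
  expect_lt(abs(cor(spec$compartments$t2w_ms, spec$compartments$ff)), 0.2)
})

test_that("overlapping compartments are rejected", {
  comp <- tibble::tibble(label = c("a", "b"), cx = c(80, 82), cy = c(80, 80),
                         rx = 8, ry = 8, t2w_ms = 35, ff = 0.2)
  expect_error(phantom_spec(compartments = comp), "overlap")
})

test_that("phantom generation is exactly reproducible under the seed", {
  sq <- seq_ideal
  spec <- default_thigh_phantom(snr = 80)
  p1 <- make_phantom(spec, sq, seed = 3)
  p2 <- make_phantom(spec, sq, seed = 3)
  expect_identical(p1$stack, p2$stack)
  # a different seed changes only the noise, not the geometry/truth
  p3 <- make_phantom(spec, sq, seed = 4)
  expect_false(identical(p1$stack, p3$stack))
  expect_identical(p1$t2w, p3$t2w)
  expect_identical(p1$masks$ring, p3$masks$ring)
})

test_that("a noiseless fat-free ideal-profile phantom decays as pure CPMG", {
  comp <- tibble::tibble(label = "m", cx = 80, cy = 80, rx = 10, ry = 8,
                         t2w_ms = 40, ff = 0)
  spec <- phantom_spec(compartments = comp, snr = Inf,
                       b1_range = c(1, 1))
  ph <- make_phantom(spec, seq_ideal, seed = 1)
  idx <- which(ph$masks$m, arr.ind = TRUE)[1, ]
  decay <- ph$stack[idx[1], idx[2], 1, ]
  expect_equal(decay, exp(-(1:17) * 7.5 / 40), tolerance = 1e-6)
})

test_that("the background noise level matches the requested SNR", {
  sq <- seq_ideal
  ph <- make_phantom(default_thigh_phantom(snr = 100), sq, seed = 6)
  bg <- !ph$masks$foreground
  # background magnitudes are Rayleigh(sigma): mean = sigma * sqrt(pi/2)
  sigma_hat <- mean(ph$stack[, , 1, 1][bg]) / sqrt(pi / 2)
  expect_equal(sigma_hat, ph$sigma, tolerance = 0.05)
  # and sigma corresponds to the stated first-echo SNR
  s1 <- mean(ph$stack[, , 1, 1][ph$masks$foreground])
  expect_equal(s1 / ph$sigma, 100, tolerance = 0.1)
})

test_that("dictionary matching on a noiseless phantom recovers the truth", {
  sq <- seq_preset(32)
  ph <- make_phantom(default_thigh_phantom(snr = Inf), sq, seed = 1)
  truth <- phantom_truth(ph)
  muscle <- truth$label != "ring"
  set.seed(2)
  take <- sample(which(muscle), 300)
  sigs <- sapply(take, function(i) ph$stack[truth$x[i], truth$y[i], 1, ])
  d <- build_dictionary(build_grid("muscle", t2f_ms = 150), sq)
  m <- dict_match(t(sigs), d)
  dt <- abs(m$t2w_ms - truth$t2w_ms[take])
  ffv <- truth$ff[take]
  # grid-coupling grows with fat fraction: tight where water dominates
  expect_gte(mean(dt[ffv <= 0.6] <= 1 + 1e-9), 0.95)
  expect_gte(mean(dt <= 2 + 1e-9), 0.9)
  expect_lte(median(dt), 0.45)
})

test_that("phantoms round-trip through NIfTI output", {
  sq <- seq_ideal
  ph <- make_phantom(default_thigh_phantom(snr = 50), sq, seed = 2)
  dir <- tempfile()
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "mese.nii.gz")))
  back <- read_nifti_array(file.path(dir, "mese.nii.gz"))
  expect_equal(dim(back), dim(ph$stack))
  expect_equal(max(abs(back - ph$stack)), 0, tolerance = 1e-6)
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$snr, 50)
})
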