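# SLR pulse design and slice-profile computation.

test_that("SLR designs hit the nominal center flip for both roles", {
  ex <- design_slr_pulse(90, time_bandwidth = 4, n_samples = 128,
                         pulse_role = "excitation")
  pe <- compute_slice_profile(ex, n_bins = 65, truncate_deg = 0)
  expect_equal(pe$flip_deg[33], 90, tolerance = 1)
  expect_lt(pe$flip_deg[1], 10)          # edge bins essentially untouched

  rf <- design_slr_pulse(180, time_bandwidth = 4, n_samples = 128,
                         pulse_role = "refocusing")
  pr <- compute_slice_profile(rf, n_bins = 65, truncate_deg = 0)
  expect_equal(pr$flip_deg[33], 180, tolerance = 1)
  expect_lt(pr$flip_deg[1], 10)
})

test_that("design is deterministic and the SLR recursions invert each other", {
  a <- design_slr_pulse(90, 4, 128, "excitation")
  b <- design_slr_pulse(90, 4, 128, "excitation")
  expect_identical(a$samples, b$samples)

  # forward(inverse) round trip through the Cayley-Klein polynomials
  fb <- myowater:::slr_forward(a$samples)
  rf2 <- myowater:::slr_inverse(fb$a[1:128], fb$b[1:128])
  expect_equal(rf2, a$samples, tolerance = 1e-8)
})

test_that("profiles of real symmetric pulses are symmetric", {
  ex <- design_slr_pulse(90, 4, 128, "excitation")
  p <- compute_slice_profile(ex, n_bins = 64, truncate_deg = 0)
  expect_equal(p$flip_deg, rev(p$flip_deg), tolerance = 1e-8)
})

test_that("a hard pulse under a weak gradient gives a flat profile", {
  hp <- rf_waveform(rep(1, 128), duration_ms = 1, nominal_flip_deg = 90,
                    pulse_role = "excitation", time_bandwidth = 0.02)
  p <- compute_slice_profile(hp, n_bins = 16, truncate_deg = 0)
  expect_true(all(abs(p$flip_deg - 90) < 1))
})

test_that("aliasing (support beyond the simulated FOV) is rejected", {
  wf <- design_slr_pulse(90, 4, 64, "excitation")
  expect_error(compute_slice_profile(wf, n_bins = 16, support = 20),
               "aliasing")
})

test_that("echo trains converge in the slice-profile bin count", {
  p <- tissue_params(35, 150, 0.3, 0.9)
  e64 <- mese_two_component(p, seq_preset(64))
  e128 <- mese_two_component(p, seq_preset(128))
  expect_lt(max(abs(e64 - e128) / e128), 1e-3)
})

test_that("waveform files round-trip and parse errors name the line", {
  wf <- design_slr_pulse(90, 4, 64, "excitation")
  f <- tempfile(fileext = ".csv")
  save_waveform(wf, f)
  wf2 <- load_waveform(f, duration_ms = wf$duration_ms, nominal_flip_deg = 90,
                       pulse_role = "excitation",
                       time_bandwidth = wf$time_bandwidth)
  expect_equal(wf2$samples, wf$samples, tolerance = 1e-12)

  # constant one-column file becomes a hard pulse
  f2 <- tempfile()
  writeLines(rep("1.0", 128), f2)
  hp <- load_waveform(f2, 1, 90, "excitation", time_bandwidth = 0.1)
  expect_equal(Mod(sum(hp$samples)) * 180 / pi, 90, tolerance = 1e-9)
  expect_equal(length(unique(Re(hp$samples))), 1)

  # NaN row is rejected with its line number
  f3 <- tempfile()
  writeLines(c("1.0", "2.0", "NaN", "1.0"), f3)
  expect_error(load_waveform(f3, 1, 90, "excitation"), "line 3")

  # empty file
  f4 <- tempfile(); writeLines(character(0), f4)
  expect_error(load_waveform(f4, 1, 90, "excitation"), "empty")
})

test_that("waveform validation enforces the invariants", {
  expect_error(rf_waveform(rep(1, 8), 1, 90, "excitation"), ">= 16")
  expect_error(rf_waveform(c(rep(1, 31), NA), 1, 90, "excitation"), "finite")
  expect_error(design_slr_pulse(90, 1.5, 128, "excitation"), "time_bandwidth")
  expect_error(design_slr_pulse(90, 4, 32, "excitation"), "n_samples")
})

test_that("presets provide matched profile pairs with quadrature weights", {
  prof <- slice_profile_preset("generic-siemens-like", n_bins = 48)
  expect_length(prof$ex_profile, 48)
  expect_length(prof$ref_profile, 48)
  expect_length(prof$weights, 48)
  expect_true(all(prof$weights > 0))
  # the excitation plateau reaches the nominal flip; for refocusing the
  # physically meaningful quantity is the efficiency sin^2(flip/2), which
  # sits at essentially 1 across the passband even though the flip-angle
  # representation magnifies the tiny beta ripple near 180 degrees
  expect_gt(max(prof$ex_profile), 85)
  expect_gt(max(sin(prof$ref_profile * pi / 360)^2), 0.98)
  sq <- sequence_preset("philips", n_bins = 32)
  expect_equal(sq$te_ms, 7.6)
  expect_equal(sq$etl, 17L)
})
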