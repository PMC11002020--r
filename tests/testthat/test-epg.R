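# EPG operators and echo-train simulation.

test_that("elementary RF rotations behave like the textbook operators", {
  st <- epg_state_init(5)

  # identity rotation leaves any state untouched
  st2 <- epg_rf_rotation(st, 0, 37)
  expect_equal(st2$f_plus, st$f_plus)
  expect_equal(st2$z, st$z)

  # 90 deg pulse converts all longitudinal magnetization to transverse
  ex <- epg_rf_rotation(st, 90, 90)
  expect_equal(Mod(ex$f_plus[1]), 1, tolerance = 1e-12)
  expect_equal(Mod(ex$z[1]), 0, tolerance = 1e-12)

  # 180 deg pulse fully refocuses a pure F1+ state; longitudinal
  # magnitudes are untouched (the rotation inverts, never mixes, Z)
  st$f_plus[2] <- 1 + 0i
  rf <- epg_rf_rotation(st, 180, 0)
  expect_equal(Mod(rf$f_minus[2]), 1, tolerance = 1e-12)
  expect_equal(Mod(rf$z), Mod(st$z))


  expect_error(epg_rf_rotation(st, NaN), "finite")
})

test_that("relaxation and gradient shift follow the closed forms", {
  st <- epg_state_init(5)
  st <- epg_rf_rotation(st, 90, 90)   # F0 = 1
  ev <- epg_relax_shift(st, t1_ms = 1400, t2_ms = 50, dt_ms = 3.75)
  # transverse decay exp(-3.75/50) lands in order 1 after the shift
  expect_equal(Mod(ev$f_plus[2]), exp(-0.075), tolerance = 1e-9)
  # Z0 regrows toward equilibrium from 0
  expect_equal(Re(ev$z[1]), 1 - exp(-3.75 / 1400), tolerance = 1e-12)

  # dt = 0: amplitudes unchanged, orders advanced
  ev0 <- epg_relax_shift(st, 1400, 50, 0)
  expect_equal(Mod(ev0$f_plus[2]), 1, tolerance = 1e-12)
  expect_equal(Mod(ev0$f_plus[1]), Mod(ev0$f_minus[1]))

  expect_error(epg_relax_shift(st, 1400, 50, -1), ">= 0")
})

test_that("ideal-profile CPMG reduces to a monoexponential decay", {
  set.seed(42)
  for (t2 in runif(50, 10, 250)) {
    e <- mese_single_component(t2, b1 = 1, seq = seq_ideal)
    expect_equal(e, exp(-(1:17) * 7.5 / t2), tolerance = 1e-6)
  }
  # frozen spot values
  e <- mese_single_component(50, 1, seq_ideal)
  expect_equal(e[1], 0.86071, tolerance = 1e-5)
  expect_equal(e[17], 0.07808, tolerance = 1e-4)
})

test_that("EPG echoes match an independent isochromat Bloch simulation", {
  # reduced refocusing creates stimulated echoes; the EPG must agree with
  # a brute-force time-domain simulation
  e <- mese_single_component(50, b1 = 0.8, seq = seq_ideal)
  o <- iso_mese(90, 180, b1 = 0.8, t2 = 50, niso = 2000)
  expect_lt(max(abs(e - o) / o), 1e-4)

  # smooth multi-bin profile
  sq <- seq_preset(32)
  set.seed(7)
  for (i in 1:3) {
    t2 <- runif(1, 15, 200); b1 <- runif(1, 0.4, 1.2)
    e <- mese_single_component(t2, b1, sq)
    o <- iso_mese(sq$ex_profile, sq$ref_profile, sq$profile_weights,
                  b1 = b1, t2 = t2, niso = 2000)
    expect_lt(max(abs(e - o) / pmax(o, 1e-6)), 1e-3)
  }
})

test_that("the two-component signal is exactly linear in the fat fraction", {
  sq <- seq_preset(32)
  s0 <- mese_two_component(tissue_params(35, 150, 0, 0.9), sq)
  s1 <- mese_two_component(tissue_params(35, 150, 1, 0.9), sq)
  for (ff in c(0.2, 0.5, 0.77)) {
    sf <- mese_two_component(tissue_params(35, 150, ff, 0.9), sq)
    expect_equal(sf, ff * s1 + (1 - ff) * s0, tolerance = 1e-12)
  }
  # ff = 0 / 1 equal the pure single-component trains
  expect_equal(s0, mese_single_component(35, 0.9, sq, t1_ms = 1400))
  expect_equal(s1, mese_single_component(150, 0.9, sq, t1_ms = 365))
})

test_that("CPMG-limit superposition has the closed form", {
  p <- tissue_params(t2w_ms = 35, t2f_ms = 150, ff = 0.5, b1 = 1)
  s <- mese_two_component(p, seq_ideal)
  expect_equal(s, 0.5 * exp(-(1:17) * 7.5 / 35) + 0.5 * exp(-(1:17) * 7.5 / 150),
               tolerance = 1e-6)
})

test_that("echo amplitudes are bounded, positive and decay monotonically", {
  set.seed(3)
  for (i in 1:10) {
    p <- tissue_params(runif(1, 10, 80), runif(1, 50, 250), runif(1),
                       runif(1, 0.4, 1.2))
    s <- mese_two_component(p, seq_preset(32))
    expect_true(all(s >= 0 & s <= 1))
  }
  # strict monotone decay in the ideal-profile case
  s <- mese_single_component(45, 1, seq_ideal)
  expect_true(all(diff(s) < 0))
  # no-decay limit
  s <- mese_single_component(1e9, 1, seq_ideal)
  expect_equal(s, rep(1, 17), tolerance = 1e-6)
})

test_that("batched table simulation matches per-voxel calls", {
  sq <- seq_preset(32)
  set.seed(11)
  tab <- tibble::tibble(t2w_ms = runif(5, 15, 70), t2f_ms = runif(5, 60, 240),
                        ff = runif(5), b1 = runif(5, 0.5, 1.1))
  m <- mese_simulate_table(tab, sq)
  for (i in 1:5) {
    p <- tissue_params(tab$t2w_ms[i], tab$t2f_ms[i], tab$ff[i], tab$b1[i])
    expect_equal(m[i, ], mese_two_component(p, sq), tolerance = 1e-12)
  }
})

test_that("sequence configuration validates its invariants", {
  expect_error(sequence_config(0, 17), "te_ms")
  expect_error(sequence_config(7.5, 17, ex_profile = c(90, 90),
                               ref_profile = 180), "equal length")
  expect_error(sequence_config(7.5, 17, profile_weights = -1), "positive")
  expect_error(tissue_params(-5, 150, 0.5, 1), "relaxation")
  expect_error(tissue_params(35, 150, 1.2, 1), "ff")
  # hash distinguishes acquisitions
  expect_false(seq_hash(seq_ideal) ==
                 seq_hash(sequence_config(7.6, 17, 2870)))
})
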