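# Parameter grids, dictionary building, matching, SVD compression.

test_that("the published grids have the expected axis counts", {
  fat <- build_grid("fat")
  expect_equal(fat$axes$n[fat$axes$name == "t2f_ms"], 801L)
  expect_equal(fat$axes$n[fat$axes$name == "t2w_ms"], 201L)
  expect_equal(fat$axes$n[fat$axes$name == "b1"], 33L)
  expect_equal(fat$fixed$ff, 0.9)

  mus <- build_grid("muscle", t2f_ms = 151)
  expect_equal(mus$axes$n[mus$axes$name == "t2w_ms"], 351L)
  expect_equal(mus$axes$n[mus$axes$name == "b1"], 33L)
  expect_equal(mus$fixed$t2f_ms, 151)

  # an override whose step equals the range gives a 2-point axis
  g <- build_grid("muscle", t2f_ms = 151,
                  overrides = list(t2w_ms = c(10, 80, 70)))
  expect_equal(g$axes$n[g$axes$name == "t2w_ms"], 2L)
  pts <- grid_points(g)
  expect_setequal(unique(pts$t2w_ms), c(10, 80))

  expect_error(build_grid("muscle"), "t2f_ms")
  expect_error(build_grid("muscle", t2f_ms = 300), "50")
  expect_error(build_grid("fat", overrides = list(t2w_ms = c(10, 80, -1))),
               "step")
})

test_that("toy dictionaries have unit-norm atoms and deterministic order", {
  g <- build_grid("muscle", t2f_ms = 150, overrides = list(
    ff = c(0, 0.5, 0.5), t2w_ms = c(20, 60, 40), b1 = c(0.8, 1.2, 0.4)))
  d <- build_dictionary(g, seq_ideal)
  expect_equal(nrow(d$atoms), 8L)
  expect_equal(sqrt(rowSums(d$atoms^2)), rep(1, 8), tolerance = 1e-9)
  d2 <- build_dictionary(g, seq_ideal)
  expect_identical(d$atoms, d2$atoms)
  # lexicographic over axes as listed: first axis (ff) varies slowest
  expect_equal(d$params$ff, rep(c(0, 0.5), each = 4))

  # the ff = 0, b1 = 1 atoms are normalized CPMG decays
  g3 <- build_grid("muscle", t2f_ms = 150, overrides = list(
    ff = c(0, 0, 1), t2w_ms = c(50, 50, 1), b1 = c(1, 1, 1)))
  d3 <- build_dictionary(g3, seq_ideal)
  ref <- exp(-(1:17) * 7.5 / 50)
  expect_equal(as.vector(d3$atoms[1, ]), ref / sqrt(sum(ref^2)),
               tolerance = 1e-6)

  expect_error(build_dictionary(build_grid("fat"), seq_ideal, atom_limit = 10),
               "atom_limit")
})

test_that("matching retrieves atoms, ignores scale, and quantizes off-grid", {
  d <- toy_muscle_dict()
  m <- dict_match(d$atoms[17, ], d)
  expect_equal(m$atom, 17L)
  expect_equal(m$score, 1, tolerance = 1e-9)
  expect_equal(m$t2w_ms, d$params$t2w_ms[17])

  # positive scaling changes nothing
  m2 <- dict_match(5.3 * d$atoms[17, ], d)
  expect_equal(m2$atom, 17L)

  # every atom self-retrieves
  ms <- dict_match(d$atoms, d)
  expect_equal(ms$atom, seq_len(nrow(d$atoms)))
  expect_true(all(ms$score > 1 - 1e-9))

  # noiseless off-grid signal snaps to the nearest grid value (fine grid)
  gf <- build_grid("muscle", t2f_ms = 150, overrides = list(
    ff = c(0.3, 0.3, 1), t2w_ms = c(45, 55, 0.2), b1 = c(0.9, 0.9, 1)))
  df <- build_dictionary(gf, seq_ideal)
  sig <- mese_two_component(tissue_params(50.07, 150, 0.3, 0.9), seq_ideal)
  mf <- dict_match(sig, df)
  expect_equal(mf$t2w_ms, 50.0)

  # degenerate voxels are flagged, not matched
  mz <- dict_match(rep(0, 17), d)
  expect_false(mz$valid)
  expect_true(is.na(mz$t2w_ms))
})

test_that("off-grid quantization error stays small in the physiological box", {
  # the t2w picked by the dot-product metric absorbs the rounding of the
  # coupled ff/b1 axes, so the error is typically a few grid steps, not
  # one; on a physiological parameter box it stays near a millisecond
  sq <- seq_preset(32)
  d <- build_dictionary(build_grid("muscle", t2f_ms = 150), sq)
  set.seed(5)
  n <- 120
  tab <- tibble::tibble(t2w_ms = runif(n, 12, 78), t2f_ms = 150,
                        ff = runif(n, 0, 0.8), b1 = runif(n, 0.7, 1.15))
  sig <- mese_simulate_table(tab, sq)
  m <- dict_match(sig, d)
  ae <- abs(m$t2w_ms - tab$t2w_ms)
  expect_lte(median(ae), 1)
  expect_gte(mean(ae <= 5), 0.95)
  expect_lte(median(abs(m$ff - tab$ff)), 0.03)
})

test_that("SVD compression is lossless at full rank and ordered in variance", {
  d <- toy_muscle_dict()
  cd <- compress_svd(d, k = 17)
  expect_true(all(diff(cd$all_variance_ratio) <= 1e-12))
  expect_equal(sum(cd$all_variance_ratio), 1, tolerance = 1e-9)

  set.seed(2)
  sig <- matrix(abs(rnorm(50 * 17)), 50)
  full <- dict_match(sig, d)
  comp <- match_compressed(sig, cd)
  expect_equal(comp$atom, full$atom)
  expect_equal(comp$score, full$score, tolerance = 1e-9)

  # rank-1 dictionary: first component carries everything
  r1 <- d
  r1$atoms <- matrix(rep(d$atoms[1, ], 6), 6, byrow = TRUE)
  c1 <- compress_svd(r1, 1)
  expect_equal(c1$explained_variance_ratio[1], 1, tolerance = 1e-9)

  expect_error(compress_svd(d, 0), "k must")
  expect_error(compress_svd(d, 18), "k must")
})

test_that("three components suffice on a well-separated toy grid", {
  # echo-train atoms are so strongly correlated that for dense grids the
  # argmax ranking in a rank-3 subspace can differ from full matching
  # even though >99% of the variance is retained; on a well-separated
  # grid the compressed match is faithful
  sq <- seq_preset(32)
  g <- build_grid("muscle", t2f_ms = 150, overrides = list(
    ff = c(0, 0.8, 0.4), t2w_ms = c(20, 60, 20), b1 = c(0.7, 1.2, 0.25)))
  d <- build_dictionary(g, sq)
  cd <- compress_svd(d, 3)
  expect_gt(sum(cd$explained_variance_ratio), 0.99)
  m <- match_compressed(d$atoms, cd)
  expect_gte(mean(m$atom == seq_len(nrow(d$atoms))), 0.85)
  # one extra component resolves the residual confusions exactly
  m4 <- match_compressed(d$atoms, compress_svd(d, 4))
  expect_equal(m4$atom, seq_len(nrow(d$atoms)))

  set.seed(9)
  truth_idx <- sample.int(nrow(d$atoms), 300, replace = TRUE)
  truth <- d$atoms[truth_idx, ]
  noisy <- sqrt((truth + matrix(rnorm(300 * 17, 0, 0.01), 300))^2 +
                  matrix(rnorm(300 * 17, 0, 0.01), 300)^2)
  t2w_full <- dict_match(noisy, d)$t2w_ms
  t2w_comp <- match_compressed(noisy, cd)$t2w_ms
  expect_gte(mean(abs(t2w_full - t2w_comp) <= 20 + 1e-9), 0.95)
})

test_that("dictionaries survive a save/load round trip", {
  d <- toy_muscle_dict(n = 4)
  dir <- tempfile()
  save_dictionary(d, dir)
  d2 <- load_dictionary(dir)
  expect_equal(d2$atoms, d$atoms, tolerance = 1e-12)
  expect_equal(d2$params$t2w_ms, d$params$t2w_ms)
  expect_equal(d2$seq_hash, d$seq_hash)
  m <- dict_match(d$atoms[5, ], d2)
  expect_equal(m$atom, 5L)
})

test_that("signals of the wrong length are rejected", {
  d <- toy_muscle_dict(n = 4)
  expect_error(dict_match(rep(0.5, 10), d), "length")
})
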