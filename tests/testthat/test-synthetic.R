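test_that("ideal helix has canonical geometry", {
  h <- build_ideal_helix(12)
  ca <- h$coords[, 2, , 1]
  dca <- sqrt(rowSums((ca[-1, ] - ca[-12, ])^2))
  expect_true(all(abs(dca - 3.8) < 0.1))
  # alpha-helical O(i)...N(i+4) hydrogen-bond distances
  don <- vapply(1:8, function(i)
    sqrt(sum((h$coords[i, 4, , 1] - h$coords[i + 4, 1, , 1])^2)), numeric(1))
  expect_true(all(don < 3.5))
  rise <- sqrt(sum((ca[12, ] - ca[1, ])^2)) / 11
  expect_true(abs(rise - 1.5) < 0.2)
  expect_equal(n_residues(build_ideal_helix(2)), 2L)
  expect_error(build_ideal_helix(1), "at least 2")
})

test_that("zero-noise generator reproduces the base in every frame", {
  base <- build_ideal_helix(6)
  tr <- generate_fluctuating_trajectory(
    base, fluctuation_spec(6, 4, base_sigma = 0, seed = 1))
  for (f in 1:4) expect_equal(tr$coords[, , , f], base$coords[, , , 1])
})

test_that("empirical per-coordinate SD matches the specified sigma", {
  base <- build_ideal_helix(5)
  tr <- generate_fluctuating_trajectory(
    base, fluctuation_spec(5, 4000, base_sigma = 0.5, seed = 11))
  dev <- tr$coords - array(base$coords[, , , 1], dim(tr$coords))
  sds <- apply(dev, c(1, 2, 3), sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.1))
  # per-residue override
  tr2 <- generate_fluctuating_trajectory(
    base, fluctuation_spec(5, 4000, base_sigma = 0.2,
                           residue_sigma_overrides = c("3" = 0.6), seed = 2))
  dev2 <- tr2$coords - array(base$coords[, , , 1], dim(tr2$coords))
  sds2 <- apply(dev2, 1, sd)
  expect_true(abs(sds2[3] - 0.6) < 0.05)
  expect_true(all(abs(sds2[-3] - 0.2) < 0.05))
})

test_that("generators are pure functions of (spec, seed)", {
  base <- build_ideal_helix(8)
  sp <- fluctuation_spec(8, 10, 0.3,
                         correlated_blocks = list(list(residues = c(2, 6),
                                                       weight = 0.5)),
                         seed = 99)
  expect_identical(generate_fluctuating_trajectory(base, sp)$coords,
                   generate_fluctuating_trajectory(base, sp)$coords)
  ds <- decay_spec(2, noise_fraction = 0.05, seed = 5)
  expect_identical(generate_decay_series(ds), generate_decay_series(ds))
  ps <- peaklist_spec(10, noise_sd_ppm = 0.01, seed = 4)
  expect_identical(generate_peak_list_pair(ps), generate_peak_list_pair(ps))
})

test_that("block displacement-magnitude correlation grows with latent weight", {
  base <- build_ideal_helix(12)
  members <- c(3, 7)
  corr_at <- function(w) {
    tr <- generate_fluctuating_trajectory(
      base, fluctuation_spec(12, 5000, 0.1,
                             correlated_blocks = list(list(residues = members,
                                                           weight = w)),
                             seed = 21))
    dev <- tr$coords - array(base$coords[, , , 1], dim(tr$coords))
    mag <- apply(dev[members, , , ]^2, c(1, 4), sum)
    cor(sqrt(mag[1, ]), sqrt(mag[2, ]))
  }
  cs <- vapply(c(0, 0.5, 0.9), corr_at, numeric(1))
  expect_lt(abs(cs[1]), 0.1)
  expect_gt(cs[2], cs[1])
  expect_gt(cs[3], cs[2])
})

test_that("correlated blocks must be disjoint with weights in [0, 1]", {
  expect_error(fluctuation_spec(10, 5, correlated_blocks = list(
    list(residues = 1:3, weight = 1.2))), "weight")
  expect_error(fluctuation_spec(10, 5, correlated_blocks = list(
    list(residues = 1:3, weight = 0.5),
    list(residues = 3:5, weight = 0.5))), "disjoint")
  expect_error(generate_fluctuating_trajectory(
    build_ideal_helix(4), fluctuation_spec(5, 3)), "residues")
})

test_that("peak-list pair honors perturbations, broadening, and scaling", {
  pk <- generate_peak_list_pair(peaklist_spec(
    12, shift_perturbations = list(`10` = c(0.1, 0.5)),
    broadened_set = 3, attenuation = 0.2, global_intensity_scale = 2,
    seed = 6))
  expect_true(all(pk$wt$dH >= 6.5 & pk$wt$dH <= 10.5))
  expect_true(all(pk$wt$dN >= 105 & pk$wt$dN <= 135))
  csp <- composite_csp(pk$wt, pk$variant)
  expect_equal(csp$delta[csp$resid == 10], 0.1, tolerance = 1e-12)
  expect_equal(max(csp$delta[csp$resid != 10]), 0)
  br <- classify_broadened(pk$wt, pk$variant)
  expect_identical(br$broadened, 3L)
  expect_equal(unname(br$ratios["3"]), 0.2, tolerance = 1e-12)
})

test_that("decay series follows the closed form with duplicates", {
  s <- generate_decay_series(decay_spec(
    2, initial_height = 100, delay_schedule = c(0, 100, 500, 1000, 2000),
    duplicate_delays = numeric(0), noise_fraction = 0, seed = 1))
  expect_equal(s$height[s$delay_ms == 0], 100)
  expect_equal(s$height[s$delay_ms == 500], 100 * exp(-1))
  s2 <- generate_decay_series(decay_spec(1, noise_fraction = 0.02, seed = 2))
  expect_equal(sum(s2$delay_ms == 20), 2L)  # duplicate delays appear twice
  expect_equal(sum(s2$delay_ms == 600), 2L)
  expect_false(s2$height[s2$delay_ms == 20][1] ==
                 s2$height[s2$delay_ms == 20][2])  # independent noise
  expect_error(decay_spec(-1), "true_rate")
  expect_error(decay_spec(1, delay_schedule = c(10, 20, 30, 40)), "include 0")
})

test_that("AR(1) noise keeps the stationary SD and adds autocorrelation", {
  base <- build_ideal_helix(5)
  tr <- generate_fluctuating_trajectory(
    base, fluctuation_spec(5, 4000, base_sigma = 0.3, ar1_phi = 0.7,
                           seed = 13))
  dev <- tr$coords - array(base$coords[, , , 1], dim(tr$coords))
  x <- dev[3, 2, 1, ]  # one coordinate's time series
  expect_lt(abs(sd(x) - 0.3) / 0.3, 0.1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.7), 0.1)
  # phi = 0 reproduces the independent-noise path draw for draw
  s0 <- fluctuation_spec(5, 10, 0.3, seed = 4)
  s0b <- fluctuation_spec(5, 10, 0.3, ar1_phi = 0, seed = 4)
  expect_identical(generate_fluctuating_trajectory(base, s0)$coords,
                   generate_fluctuating_trajectory(base, s0b)$coords)
  expect_error(fluctuation_spec(5, 10, ar1_phi = 1), "ar1_phi")
})
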