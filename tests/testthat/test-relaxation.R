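test_that("noiseless decays are recovered essentially exactly", {
  s <- generate_decay_series(decay_spec(2, initial_height = 100,
                                        noise_fraction = 0, seed = 1))
  f <- fit_monoexponential(s)
  expect_true(f$ok)
  expect_lt(abs(f$rate - 2) / 2, 1e-8)
  expect_lt(abs(f$initial_height - 100) / 100, 1e-8)
})

test_that("fit is scale-equivariant in height and rejects degenerate series", {
  s <- generate_decay_series(decay_spec(0.87, noise_fraction = 0.02, seed = 3))
  f1 <- fit_monoexponential(s)
  s2 <- s
  s2$height <- s$height * 1000
  f2 <- fit_monoexponential(s2)
  expect_equal(f2$rate, f1$rate, tolerance = 1e-9)
  expect_equal(f2$initial_height, 1000 * f1$initial_height, tolerance = 1e-6)
  expect_error(relaxation_series(c(0, 0, 100), c(1, 1, 0.5)), "4 distinct")
})

test_that("rate recovery bias vanishes as noise vanishes", {
  med_err <- vapply(c(0, 0.01, 0.02, 0.05), function(nf) {
    errs <- vapply(1:40, function(i) {
      s <- generate_decay_series(decay_spec(0.87, noise_fraction = nf,
                                            seed = 1000 + i))
      abs(fit_monoexponential(s)$rate - 0.87) / 0.87
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[1], 1e-9)
  expect_true(all(diff(med_err) >= -0.005))  # grows with noise, to tolerance
  expect_lt(med_err[3], 0.02)                # 2 percent noise, <2 percent error
})

test_that("duplicate-based uncertainty is near zero without noise and seeded", {
  s <- generate_decay_series(decay_spec(1.5, noise_fraction = 0, seed = 2))
  u <- estimate_rate_uncertainty(s, n_draws = 50, seed = 7)
  expect_lt(u$rate_uncertainty, 1e-8)
  s2 <- generate_decay_series(decay_spec(1.5, noise_fraction = 0.05, seed = 2))
  u1 <- estimate_rate_uncertainty(s2, n_draws = 100, seed = 7)
  u2 <- estimate_rate_uncertainty(s2, n_draws = 100, seed = 7)
  expect_identical(u1, u2)
  # no duplicates -> covariance fallback with warning
  s3 <- generate_decay_series(decay_spec(1.5, duplicate_delays = numeric(0),
                                         noise_fraction = 0.05, seed = 2))
  expect_warning(u3 <- estimate_rate_uncertainty(s3, seed = 1), "fallback|falling back")
  expect_equal(u3$method, "fit-covariance")
})

test_that("NOE is the saturated/unsaturated height ratio", {
  unsat <- peak_list(1:6, rep(8, 6), rep(120, 6), height = c(10, 8, 6, 5, 4, 2))
  expect_true(all(compute_noe(unsat, unsat)$noe == 1))
  sat <- unsat
  sat$height <- unsat$height * 0.8
  expect_true(all(abs(compute_noe(sat, unsat)$noe - 0.8) < 1e-12))
  sat2 <- sat; sat2$height <- sat$height * 5
  unsat2 <- unsat; unsat2$height <- unsat$height * 5
  expect_equal(compute_noe(sat2, unsat2)$noe, compute_noe(sat, unsat)$noe)
})

test_that("delta profiles flag constructed outliers with correct direction", {
  set.seed(42)
  n <- 100
  wt <- list(R1 = data.frame(resid = 1:n, rate = rnorm(n, 1.2, 0.01)),
             R2 = data.frame(resid = 1:n, rate = rnorm(n, 20, 0.3)),
             NOE = data.frame(resid = 1:n, noe = rnorm(n, 0.8, 0.005)))
  var <- wt
  spiked <- c(10, 30, 50, 70, 90)
  var$R2$rate[spiked] <- var$R2$rate[spiked] + 3
  var$NOE$noe[spiked] <- var$NOE$noe[spiked] - 0.2
  d <- delta_relaxation(wt, var)
  expect_equal(d$R2$resid[d$R2$significant], spiked)
  expect_true(all(d$R2$direction[spiked] == "mutant more flexible"))
  expect_true(all(d$NOE$direction[spiked] == "mutant more flexible"))
  # identical inputs: all zero, nothing significant
  d0 <- delta_relaxation(wt, wt)
  expect_true(all(d0$R1$delta == 0))
  expect_false(any(d0$R1$significant))
  # band is symmetric about its center
  b <- attr(d$R2, "band")
  ctr <- attr(d$R2, "center")
  expect_equal(b[["upper"]] - ctr, ctr - b[["lower"]])
  # antisymmetry under swapping wt/variant
  dr <- delta_relaxation(var, wt)
  expect_equal(dr$R2$delta, -d$R2$delta)
})

test_that("rate summaries reproduce known inputs and tau_c behavior", {
  mk <- function(rates) {
    tb <- data.frame(resid = seq_along(rates), rate = rates,
                     rate_se = 0, rate_uncertainty = NA, ok = TRUE)
    class(tb) <- c("rate_result", "data.frame")
    tb
  }
  sm <- summarize_rates(mk(rep(1, 10)), mk(rep(20, 10)))
  expect_equal(sm$t1_mean_ms, 1000)
  expect_equal(sm$t1_sd_ms, 0)
  expect_equal(sm$t2_mean_ms, 50)
  # tau_c increases with the T1/T2 ratio
  taus <- vapply(c(10, 20, 40), function(r2)
    summarize_rates(mk(rep(1, 10)), mk(rep(r2, 10)))$tau_c_ns, numeric(1))
  expect_true(all(diff(taus) > 0))
  # ratio below 7/6: undefined
  expect_true(is.na(summarize_rates(mk(rep(1, 10)),
                                    mk(rep(1.1, 10)))$tau_c_ns))
})

test_that("whole-table fitting flags unfit residues and feeds deltas", {
  decays <- do.call(rbind, lapply(1:6, function(r) {
    s <- generate_decay_series(decay_spec(0.8 + 0.1 * r,
                                          noise_fraction = 0.02,
                                          seed = 300 + r))
    data.frame(resid = r, delay_ms = s$delay_ms, height = s$height)
  }))
  rates <- fit_relaxation_rates(decays)
  expect_true(all(rates$ok))
  expect_equal(rates$resid, 1:6)
  expect_true(all(abs(rates$rate - (0.8 + 0.1 * rates$resid)) < 0.15))
})
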