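test_that("radiant energy is the power-exposure product and R their ratio", {
  expect_equal(radiant_energy(1, 1), 1)
  expect_equal(radiant_energy(2, 3), 6)
  expect_equal(radiant_energy(2 * 5, 3 * 5), 6 * 25)  # bilinear in (P, t)
  expect_error(radiant_energy(0, 1), "> 0")
  expect_equal(illumination_ratio(4, 4), 1)
  expect_equal(illumination_ratio(1, 4), 0.25)
  expect_equal(illumination_ratio(1 * 7, 4 * 7), 0.25)  # scale invariant
  expect_error(illumination_ratio(1, 0), "> 0")
})

test_that("the crosstalk slope fit recovers exact lines and reports diagnostics", {
  pairs <- data.frame(f_on = c(100, 200, 300, 400), f_off = 0.05 * c(100, 200, 300, 400))
  fit <- fit_crosstalk_ratio(pairs)
  expect_equal(fit$c, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 4L)
  expect_error(fit_crosstalk_ratio(pairs[1, , drop = FALSE]), "pairs")
  expect_error(fit_crosstalk_ratio(data.frame(f_on = c(1, 1), f_off = c(1, 2))),
               "degenerate")
})

test_that("noiseless synthetic series yield the analytic C(R) = eff_ratio * R exactly", {
  eff <- list(mapple = c("470" = 0.03, "565" = 1.0))
  s <- generate_calibration_series(eff, powers_mw = c(1, 2, 4, 8, 16),
                                   exposures_ms = c(1, 2, 4, 8, 16))
  rs <- c(0.25, 0.5, 1, 2)
  curve <- build_crosstalk_curve(s, "mapple", 470, 565, rs)
  expect_equal(curve$c, 0.03 * rs, tolerance = 1e-10)
  expect_equal(curve$n_pairs, rep(20L, 4))  # 20 pairs per target R
  # interpolation at an untested R matches the linear forward model
  expect_equal(interpolate_crosstalk(curve, 0.7),
               approx(log(rs), 0.03 * rs, log(0.7))$y, tolerance = 1e-12)
  expect_error(interpolate_crosstalk(curve, 10), "extrapolate")
  # single target R -> curve of length 1
  one <- build_crosstalk_curve(s, "mapple", 470, 565, 1)
  expect_equal(nrow(one), 1L)
  expect_equal(interpolate_crosstalk(one, 1), one$c)
})

test_that("fitted C is accurate to 2% under 1% multiplicative noise", {
  eff <- list(mapple = c("470" = 0.05, "565" = 0.8))
  s <- generate_calibration_series(eff, powers_mw = c(1, 2, 4, 8, 16),
                                   exposures_ms = c(1, 2, 4, 8, 16),
                                   noise_frac = 0.01, seed = 11)
  rs <- c(0.25, 0.5, 1, 2)
  curve <- build_crosstalk_curve(s, "mapple", 470, 565, rs)
  analytic <- 0.05 / 0.8 * rs
  expect_lt(max(abs(curve$c - analytic) / analytic), 0.02)
})

test_that("C is invariant to fluorescence rescaling and to the (P,t) decomposition", {
  eff <- list(m = c("470" = 0.04, "565" = 1))
  s <- generate_calibration_series(eff, powers_mw = c(1, 2, 4, 8),
                                   exposures_ms = c(1, 2, 4, 8))
  c1 <- build_crosstalk_curve(s, "m", 470, 565, 1)$c
  s2 <- s; s2$fluorescence <- s2$fluorescence * 123.4
  expect_equal(build_crosstalk_curve(s2, "m", 470, 565, 1)$c, c1,
               tolerance = 1e-12)
  # doubling all efficiencies leaves C unchanged
  s3 <- generate_calibration_series(list(m = c("470" = 0.08, "565" = 2)),
                                    powers_mw = c(1, 2, 4, 8),
                                    exposures_ms = c(1, 2, 4, 8))
  expect_equal(build_crosstalk_curve(s3, "m", 470, 565, 1)$c, c1,
               tolerance = 1e-12)
  # restricting to different (P,t) decompositions of the same energies
  # leaves the fitted slope unchanged (fluorescence depends on E only)
  for (split in list(c(1, 4), c(2, 8), c(1, 8))) {
    sub <- s[s$power_mW %in% split, , drop = FALSE]
    class(sub) <- class(s)
    expect_equal(build_crosstalk_curve(sub, "m", 470, 565, 1,
                                       n_pairs = 6)$c, c1,
                 tolerance = 1e-10)
  }
})

test_that("a weakly off-peak-excited fluorophore has the flatter C-vs-R curve", {
  effs <- list(egfp = c("565" = 0.002, "470" = 1.0),
               mapple = c("470" = 0.03, "565" = 0.8))
  s <- generate_calibration_series(effs, powers_mw = c(1, 2, 4, 8),
                                   exposures_ms = c(1, 2, 4, 8))
  rs <- c(0.5, 1, 2)
  c_egfp <- build_crosstalk_curve(s, "egfp", 565, 470, rs)$c
  c_map <- build_crosstalk_curve(s, "mapple", 470, 565, rs)$c
  slope <- function(cs) (cs[3] - cs[1]) / (rs[3] - rs[1])
  expect_lt(slope(c_egfp), slope(c_map))
  expect_true(all(diff(c_egfp) >= 0))  # C non-decreasing in R
  expect_true(all(diff(c_map) >= 0))
})

test_that("zero-lag cross-correlation behaves on trivial and independent traces", {
  a <- sin(seq(0, 10, by = 0.01))
  expect_equal(zero_lag_crosscorrelation(a, a)$r0, 1)
  expect_equal(zero_lag_crosscorrelation(a, -a)$r0, -1)
  set.seed(5)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(zero_lag_crosscorrelation(x, y)$r0), 0.05)
  expect_error(zero_lag_crosscorrelation(x, y[1:10]), "equal length")
})

test_that("over-subtraction flips the sign of the corrected-green/red correlation", {
  c0 <- 0.03
  # calcium-indicator-scale red transients; green and red driven by
  # exactly orthogonal sinusoids, i.e. independent source signals
  n <- 200; k <- seq_len(n)
  sc <- small_scene(crosstalk_c = c0, hbo_amp_m = 0, hbr_amp_m = 0,
                    n_cycles = n,
                    s_green_tc = 0.05 * sin(2 * pi * 8 * k / n),
                    s_red_tc = 0.4 * sin(2 * pi * 14 * k / n))
  ch <- demultiplex(sc$acq)
  blob <- apply(abs(sc$truth$s_red), c(1, 2), max) > 0.01
  roi_trace <- function(a) apply(a, 3, function(fr) mean(fr[blob]))
  f565 <- roi_trace(ch[["565"]]$data)
  r0 <- vapply(c(0, 0.03, 0.05, 0.10), function(cc) {
    corr <- correct_crosstalk(ch[["470"]], ch[["565"]], cc)
    zero_lag_crosscorrelation(roi_trace(corr$data), f565)$r0
  }, numeric(1))
  expect_gt(r0[1], 0.05)            # under-correction: positive
  expect_lt(abs(r0[2]), 0.01)       # at the true ratio: ~zero
  expect_lt(r0[3], -0.01)           # over-correction: negative
  expect_lt(r0[4], r0[3])           # and increasingly so
})
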