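test_that("trial alignment interpolates onto the relative grid and drops incomplete trials", {
  # 20 trains at 25-s spacing inside a long record
  time_s <- seq(0, 520, by = 0.1)
  x <- sin(2 * pi * 0.2 * time_s)
  onsets <- 5 + (0:19) * 25
  tt <- align_trials(x, onsets, pre_s = 2, post_s = 10, time_s = time_s)
  expect_equal(dim(tt$data)[1], 20L)
  expect_equal(tt$rel_time_s, seq(-2, 10, by = 0.1))
  # samples already on the grid: interpolation is the identity; rows match
  # the analytic sinusoid
  for (tr in c(1, 10, 20)) {
    expect_equal(tt$data[tr, ],
                 sin(2 * pi * 0.2 * (onsets[tr] + tt$rel_time_s)),
                 tolerance = 1e-12)
  }
  # windows beyond the record are dropped with a warning
  expect_warning(
    tt2 <- align_trials(x, c(1, 100, 519), pre_s = 2, post_s = 10,
                        time_s = time_s),
    "dropping 2")
  expect_equal(dim(tt2$data)[1], 1L)
  expect_error(
    suppressWarnings(align_trials(x, c(1), pre_s = 2, post_s = 10,
                                  time_s = time_s)),
    "no complete trials")
})

test_that("alignment preserves constant traces and stack alignment matches trace alignment", {
  time_s <- seq(0, 100, by = 0.1)
  const <- rep(4.2, length(time_s))
  tt <- align_trials(const, c(10, 30, 50), 1, 5, time_s = time_s)
  expect_equal(as.vector(tt$data), rep(4.2, length(tt$data)))
  # a 1x1 stack must align identically to the same data as a trace
  x <- cumsum(rnorm(201))
  st <- structure(list(data = array(x, c(1, 1, 201)), dt_s = 0.1),
                  class = "dff_stack")
  t_tr <- align_trials(x, c(5, 10), 1, 5, time_s = (0:200) * 0.1)
  t_st <- align_trials(st, c(5, 10), 1, 5)
  expect_equal(t_st$data[, 1, 1, ], t_tr$data, tolerance = 1e-12)
})

test_that("trial averaging is permutation-invariant and converges on noisy trials", {
  truth <- sin(seq(0, 2 * pi, length.out = 50))
  set.seed(9)
  data <- t(replicate(200, truth + rnorm(50, sd = 0.5)))
  tt <- structure(list(data = data, rel_time_s = seq_len(50) * 0.1 - 0.1,
                       onsets_s = seq_len(200), quantity = "x"),
                  class = "trial_tensor")
  avg <- trial_average(tt)
  expect_equal(avg$n_trials, 200L)
  # peak recovered within 3 standard errors
  peak_i <- which.max(truth)
  expect_lt(abs(avg$mean[peak_i] - truth[peak_i]), 3 * avg$se[peak_i])
  # permutation invariance
  perm <- tt; perm$data <- perm$data[sample(200), ]
  expect_equal(trial_average(perm)$mean, avg$mean)
  # identical trials: mean equals any trial, single trial flagged
  same <- tt; same$data <- matrix(rep(truth, 3), 3, byrow = TRUE)
  expect_equal(trial_average(same)$mean, truth)
  one <- tt; one$data <- matrix(truth, 1)
  expect_warning(a1 <- trial_average(one), "single trial")
  expect_true(all(is.na(a1$sd)))
})

test_that("ratio maps localize a synthetic activation blob and interpolate latencies", {
  sc <- generate_stimulus_scene(
    build_stimulus_train(2, 3, n_repetitions = 4, isi_s = 12,
                         first_onset_s = 5),
    params = scene_params(height = 16, width = 16, n_cycles = 550,
                          noise = list(type = "gaussian", sd = 1)),
    seed = 21)
  ch <- demultiplex(sc$acq)
  d <- compute_dff(ch[["565"]], compute_baseline(ch[["565"]]))
  tt <- align_trials(d, sc$truth$onsets_s, pre_s = 2, post_s = 8)
  m <- ratio_map(tt, latency_s = 0.1)
  peak <- which(m == max(m), arr.ind = TRUE)
  expect_true(all(abs(peak - c(8.5, 8.5)) <= 1.5))  # generator blob center
  # latency between grid points = linear interpolation of adjacent frames
  m17 <- ratio_map(tt, 1.7)
  m175 <- ratio_map(tt, 1.75)
  m18 <- ratio_map(tt, 1.8)
  expect_equal(m175, (m17 + m18) / 2, tolerance = 1e-10)
  expect_error(ratio_map(tt, 100), "outside trial window")
})

test_that("pupil pixel counts track disc area, threshold and radius monotonically", {
  v <- generate_pupil_video(20, height = 100, width = 100,
                            center = c(50, 50))
  roi <- list(cx = 50, cy = 50, a = 45, b = 45)
  n <- pupil_size(v$video[, , 1], roi, threshold = 100)
  expect_lt(abs(n - pi * 20^2) / (pi * 20^2), 0.03)
  # threshold below the global minimum -> zero
  expect_equal(pupil_size(v$video[, , 1], roi, threshold = 0), 0)
  # monotone in radius
  radii <- c(5, 10, 15, 20, 25)
  vv <- generate_pupil_video(radii, height = 100, width = 100,
                             center = c(50, 50))
  counts <- vapply(seq_along(radii), function(i)
    pupil_size(vv$video[, , i], roi, 100), numeric(1))
  expect_true(all(diff(counts) > 0))
  # monotone in threshold
  th <- vapply(c(25, 100, 250), function(t)
    pupil_size(v$video[, , 1], roi, t), numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_error(pupil_size(v$video[, , 1],
                          list(cx = 2, cy = 50, a = 45, b = 45), 100),
               "outside")
})

test_that("normalized pupil traces are invariant to affine rescaling of raw counts", {
  radii <- 20 + 6 * sin(seq(0, 4 * pi, length.out = 40))
  v <- generate_pupil_video(radii, height = 80, width = 80, center = c(40, 40))
  roi <- list(cx = 40, cy = 40, a = 35, b = 35)
  p <- pupil_trace(v$video, roi, 100)
  expect_true(all(p$norm >= 0 & p$norm <= 1))
  expect_equal(p$norm, (p$raw_px - min(p$raw_px)) / diff(range(p$raw_px)))
  # counts track pi r^2 within 3%
  expect_lt(max(abs(p$raw_px - pi * radii^2) / (pi * radii^2)), 0.03)
  # affine rescaling of the raw series leaves norm unchanged
  q <- p; q$raw_px <- 3 * p$raw_px + 17
  rng <- range(q$raw_px)
  expect_equal((q$raw_px - rng[1]) / diff(rng), p$norm)
})

test_that("transition ratios are 1 for flat traces and detect a 30% constriction", {
  dt <- 0.05
  n_tr <- 20
  spacing <- 15
  time_s <- seq(0, (n_tr + 1) * spacing, by = dt)
  ons <- spacing * seq_len(n_tr)
  flat <- list(norm = rep(0.8, length(time_s)), time_s = time_s)
  expect_equal(transition_ratios(flat, ons), rep(1, n_tr))
  # condition A: 30% step drop after each transition; B: no change
  set.seed(31)
  mk <- function(drop) {
    v <- rep(1, length(time_s))
    for (on in ons) v[time_s >= on & time_s < on + 8] <- 1 - drop
    list(norm = v + rnorm(length(v), sd = 0.02), time_s = time_s)
  }
  ra <- transition_ratios(mk(0.3), ons)
  rb <- transition_ratios(mk(0), ons)
  expect_equal(mean(ra), 0.7, tolerance = 0.02)
  expect_equal(mean(rb), 1.0, tolerance = 0.02)
  tst <- compare_transition_groups(ra, rb)
  expect_lt(tst$p.value, 0.001)
  expect_error(compare_transition_groups(ra[1], rb), ">= 2")
})

test_that("transition_analysis compares on- and off-transition groups of one trace", {
  dt <- 0.05
  spacing <- 30
  time_s <- seq(0, 20 * spacing, by = dt)
  on_times <- spacing * seq(1, 19, by = 2)
  off_times <- spacing * seq(2, 18, by = 2)
  v <- rep(1, length(time_s))
  for (i in seq_along(on_times)) {
    v[time_s >= on_times[i] & time_s < off_times[i]] <- 0.6
  }
  set.seed(8)
  p <- list(norm = v + rnorm(length(v), sd = 0.01), time_s = time_s)
  res <- transition_analysis(p, on_times, off_times)
  expect_lt(mean(res$on_ratios), 0.8)   # pupil constricts at light onset
  expect_gt(mean(res$off_ratios), 1.2)  # and dilates again at offset
  expect_s3_class(res$test, "htest")
  expect_lt(res$test$p.value, 0.001)
})
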