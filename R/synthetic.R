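# Forward-model phantom generator.  Every input the processing pipeline
# consumes can be synthesized with known ground truth; the forward model
# shares the log base and unit conventions of the hemodynamics module, so
# noiseless scenes are exactly invertible.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scene parameters for the phantom generator
#'
#' Defaults emulate a typical recording: a 4-wavelength 100-ms cycle
#' (10 Hz per channel), micromolar-scale hemoglobin transients confined to
#' a Gaussian cortical activation blob, a few-percent fluorescence signal,
#' and a smooth illumination profile.  The first `baseline_fraction` of
#' cycles carry no dynamics, providing an exact baseline window.
#'
#' @param height,width image size (pixels).
#' @param n_cycles number of acquisition cycles.
#' @param cycle_nm wavelength cycle (nm).
#' @param exposure_ms per-wavelength exposures (ms).
#' @param cycle_period_ms cycle duration (ms).
#' @param pixel_size_um sample-plane resolution (um/pixel).
#' @param i0_counts named baseline count levels per channel.
#' @param baseline_fraction fraction of initial cycles with zero dynamics.
#' @param hbo_amp_m,hbr_amp_m peak concentration changes (M).
#' @param s_green_amp,s_red_amp peak fractional fluorescence signals.
#' @param freq_hemo_hz,freq_green_hz,freq_red_hz temporal frequencies of
#'   the default sinusoidal dynamics (Hz).
#' @param blob_sigma_px spatial SD of the activation blob (pixels).
#' @param crosstalk_c red-into-green mixing coefficient (>= 0; default 0).
#' @param red_hemo apply hemodynamic attenuation to the red channel too
#'   (default `FALSE`).
#' @param lambda_ex,lambda_em green excitation/emission wavelengths (nm).
#' @param noise list(type = "none"|"gaussian"|"poisson", sd = counts);
#'   applied to detector counts after interleaving.
#' @param eps extinction table (default the bundled one).
#' @param paths a [pathlength_set()].
#' @param log_base attenuation log base shared with the inversion.
#' @param hbo_tc,hbr_tc,s_green_tc,s_red_tc optional explicit time courses
#'   (length `n_cycles`) overriding the default sinusoids.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(height = 64, width = 64, n_cycles = 100,
                         cycle_nm = c(470, 565, 525, 625),
                         exposure_ms = c(5, 5, 3, 3),
                         cycle_period_ms = 100, pixel_size_um = 20,
                         i0_counts = c("470" = 2000, "565" = 1600,
                                       "525" = 3000, "625" = 2500),
                         baseline_fraction = 0.2,
                         hbo_amp_m = 1e-6, hbr_amp_m = -4e-7,
                         s_green_amp = 0.05, s_red_amp = 0.08,
                         freq_hemo_hz = 0.1, freq_green_hz = 0.4,
                         freq_red_hz = 0.7,
                         blob_sigma_px = width / 6,
                         crosstalk_c = 0, red_hemo = FALSE,
                         lambda_ex = 470, lambda_em = 523,
                         noise = list(type = "none", sd = 0),
                         eps = NULL, paths = pathlength_set(),
                         log_base = 10,
                         hbo_tc = NULL, hbr_tc = NULL,
                         s_green_tc = NULL, s_red_tc = NULL) {
  p <- as.list(environment())
  class(p) <- "scene_params"
  p
}

# default temporal modulation: zero during the baseline window, then a
# smooth sinusoid
.default_tc <- function(n, n_base, dt, freq) {
  t <- (seq_len(n) - 1L) * dt
  w <- numeric(n)
  act <- seq_len(n) > n_base
  w[act] <- sin(2 * pi * freq * (t[act] - t[n_base + 1L]))
  w
}

#' Generate a synthetic interleaved acquisition with known ground truth
#'
#' Applies the full forward model: reflectance channels are attenuated by
#' Beer-Lambert absorption of the ground-truth hemoglobin transients,
#' `I(lambda,t) = I0(lambda) * 10^(-X_lambda * (eps_HbO*dHbO + eps_HbR*dHbR))`;
#' the red fluorescence channel is `F0_r * (1 + s_red)`; the green channel
#' is darkened by the hemodynamic absorption factor on its excitation and
#' emission paths and receives a fraction `crosstalk_c` of the red
#' channel's fluorescence; channels are interleaved per cycle; noise is
#' applied last.
#'
#' @param params a [scene_params()].
#' @param seed RNG seed; output is bitwise-identical for a fixed seed.
#' @return List with `acq` (a [raw_acquisition()]) and `truth` (class
#'   `scene_truth`): arrays `hbo`, `hbr` (M), `s_green`, `s_red`
#'   (fractional), per-channel baseline images `i0`, the
#'   `baseline_cycles` index range, and the generating parameters.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  if (is.null(p$eps)) p$eps <- default_extinction_table()
  h <- p$height; w <- p$width; n <- p$n_cycles
  dt <- p$cycle_period_ms / 1000
  n_base <- max(1L, ceiling(p$baseline_fraction * n))
  tc <- function(user, freq) {
    if (!is.null(user)) {
      if (length(user) != n) .stopf("explicit time course must have length n_cycles")
      as.numeric(user)
    } else .default_tc(n, n_base, dt, freq)
  }
  w_h <- tc(p$hbo_tc, p$freq_hemo_hz)
  w_h2 <- tc(p$hbr_tc, p$freq_hemo_hz)
  w_g <- tc(p$s_green_tc, p$freq_green_hz)
  w_r <- tc(p$s_red_tc, p$freq_red_hz)
  amp_h <- if (is.null(p$hbo_tc)) p$hbo_amp_m else 1
  amp_h2 <- if (is.null(p$hbr_tc)) p$hbr_amp_m else 1
  amp_g <- if (is.null(p$s_green_tc)) p$s_green_amp else 1
  amp_r <- if (is.null(p$s_red_tc)) p$s_red_amp else 1
  # spatial profiles: activation blob for dynamics, smooth vignette for i0
  xs <- matrix(rep(seq_len(w) - (w + 1) / 2, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - (h + 1) / 2, times = w), h, w)
  blob <- exp(-(xs^2 + ys^2) / (2 * p$blob_sigma_px^2))
  vignette <- 0.8 + 0.2 * exp(-(xs^2 + ys^2) / (2 * (max(h, w) / 2)^2))
  outer3 <- function(img, tcv) {
    a <- array(rep(img, length(tcv)), c(h, w, length(tcv)))
    sweep(a, 3L, tcv, "*")
  }
  hbo <- outer3(blob, amp_h * w_h)
  hbr <- outer3(blob, amp_h2 * w_h2)
  s_g <- outer3(blob, amp_g * w_g)
  s_r <- outer3(blob, amp_r * w_r)
  if (any(1 + s_g <= 0) || any(1 + s_r <= 0))
    .stopf("fluorescence dynamics imply negative intensities")
  e525 <- ext_coef(p$eps, 525); e625 <- ext_coef(p$eps, 625)
  e_ex <- ext_coef(p$eps, p$lambda_ex); e_em <- ext_coef(p$eps, p$lambda_em)
  e565 <- ext_coef(p$eps, 565)
  base <- .resolve_log_base(p$log_base)
  i0 <- lapply(p$i0_counts, function(level) level * vignette)
  names(i0) <- names(p$i0_counts)
  att_refl <- function(e, x)
    base^(-(x * (e[["hbo"]] * hbo + e[["hbr"]] * hbr)))
  i525 <- as.vector(i0[["525"]]) * att_refl(e525, p$paths$x525)
  i625 <- as.vector(i0[["625"]]) * att_refl(e625, p$paths$x625)
  mua_ex <- log(10) * (e_ex[["hbo"]] * hbo + e_ex[["hbr"]] * hbr)
  mua_em <- log(10) * (e_em[["hbo"]] * hbo + e_em[["hbr"]] * hbr)
  green_att <- exp(-(mua_ex * p$paths$x_ex + mua_em * p$paths$x_em))
  f565 <- as.vector(i0[["565"]]) * (1 + s_r)
  if (p$red_hemo) {
    mua_ex_r <- log(10) * (e565[["hbo"]] * hbo + e565[["hbr"]] * hbr)
    f565 <- f565 * exp(-mua_ex_r * p$paths$x_em)
  }
  f470 <- as.vector(i0[["470"]]) * (1 + s_g) * green_att +
    p$crosstalk_c * f565
  channels <- list("470" = f470, "565" = f565, "525" = i525, "625" = i625)
  L <- length(p$cycle_nm)
  frames <- array(0, c(h, w, n * L))
  for (k in seq_len(L))
    frames[, , seq(k, n * L, by = L)] <-
      channels[[as.character(p$cycle_nm[k])]]
  frames <- .with_seed(seed, {
    if (identical(p$noise$type, "gaussian")) {
      frames + stats::rnorm(length(frames), sd = p$noise$sd)
    } else if (identical(p$noise$type, "poisson")) {
      array(stats::rpois(length(frames), lambda = frames), dim(frames))
    } else frames
  })
  frames[frames < 0] <- 0
  acq <- raw_acquisition(frames, cycle_nm = p$cycle_nm,
                         exposure_ms = p$exposure_ms,
                         cycle_period_ms = p$cycle_period_ms,
                         pixel_size_um = p$pixel_size_um)
  truth <- structure(list(hbo = hbo, hbr = hbr, s_green = s_g, s_red = s_r,
                          i0 = i0, baseline_cycles = seq_len(n_base),
                          crosstalk_c = p$crosstalk_c, seed = seed,
                          dt_s = dt, params = p),
                     class = "scene_truth")
  list(acq = acq, truth = truth)
}

#' Hemodynamic response kernel parameters
#'
#' Difference-of-gamma kernel emulating the canonical shape of the
#' stimulus-evoked hemodynamic response: a broad peak (default 1.7 s after
#' onset, matching a typical map latency) followed by a poststimulus
#' undershoot.  Pure test scaffolding; the processing pipeline never fits
#' an HRF.
#'
#' @param peak_s time-to-peak of the positive lobe (s).
#' @param undershoot_s time-to-peak of the undershoot (s).
#' @param undershoot_ratio undershoot amplitude relative to the peak.
#' @param shape gamma shape parameter of the positive lobe.
#' @return List of class `hrf_params`.
#' @export
hrf_params <- function(peak_s = 1.7, undershoot_s = 5.5,
                       undershoot_ratio = 0.3, shape = 6) {
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 undershoot_ratio = undershoot_ratio, shape = shape),
            class = "hrf_params")
}

.hrf_kernel <- function(t, hrf) {
  scale1 <- hrf$peak_s / (hrf$shape - 1)
  scale2 <- hrf$undershoot_s / (hrf$shape - 1)
  k <- stats::dgamma(t, shape = hrf$shape, scale = scale1) -
    hrf$undershoot_ratio * stats::dgamma(t, shape = hrf$shape, scale = scale2)
  if (max(k) > 0) k / max(k) else k
}

#' Generate a stimulus-evoked scene with trial structure
#'
#' The red (calcium-like) signal contains one fast transient per stimulus
#' pulse (a 2-s, 3-Hz train yields 6 transients per trial); the green
#' (neuromodulator-like) signal follows a slower filtered version of the
#' stimulus envelope; hemodynamics are the stimulus envelope convolved
#' with a difference-of-gamma kernel.
#'
#' @param stim a stimulus train from [build_stimulus_train()].
#' @param hrf an [hrf_params()].
#' @param params a [scene_params()]; its `n_cycles`/`cycle_period_ms`
#'   must cover the stimulus train (pre/post padding included by caller).
#' @param calcium_tau_s decay constant of a single calcium transient (s).
#' @param green_tau_s decay constant of the green impulse response (s).
#' @param seed RNG seed.
#' @return As [generate_scene()]; `truth` additionally carries
#'   `onsets_s` and the per-timepoint ground-truth time courses.
#' @export
generate_stimulus_scene <- function(stim, hrf = hrf_params(),
                                    params = scene_params(),
                                    calcium_tau_s = 0.3,
                                    green_tau_s = 1.0, seed = 1L) {
  p <- params
  n <- p$n_cycles
  dt <- p$cycle_period_ms / 1000
  t <- (seq_len(n) - 1L) * dt
  envelope <- numeric(n)
  for (on in stim$onsets_s)
    envelope[t >= on & t < on + stim$duration_s] <- 1
  kern_t <- seq(0, 15, by = dt)
  hemo <- stats::convolve(envelope, rev(.hrf_kernel(kern_t, hrf)),
                          type = "open")[seq_len(n)] * dt
  if (max(abs(hemo)) > 0) hemo <- hemo / max(abs(hemo))
  s_red <- numeric(n)
  for (tp in stim$pulse_times_s) {
    after <- t >= tp
    s_red[after] <- s_red[after] + exp(-(t[after] - tp) / calcium_tau_s)
  }
  if (max(s_red) > 0) s_red <- s_red / max(s_red)
  gk <- exp(-kern_t / green_tau_s)
  s_green <- stats::convolve(envelope, rev(gk), type = "open")[seq_len(n)] * dt
  if (max(s_green) > 0) s_green <- s_green / max(s_green)
  p$hbo_tc <- p$hbo_amp_m * hemo
  p$hbr_tc <- p$hbr_amp_m * hemo
  p$s_green_tc <- p$s_green_amp * s_green
  p$s_red_tc <- p$s_red_amp * s_red
  out <- generate_scene(p, seed = seed)
  out$truth$onsets_s <- stim$onsets_s
  # quiescent window = the pre-stimulus period, not the generic fraction
  out$truth$baseline_cycles <- which(t < min(stim$onsets_s))
  out$truth$tc <- list(hemo = hemo, s_green = p$s_green_tc,
                       s_red = p$s_red_tc, time_s = t)
  out
}

#' Generate an in-vitro crosstalk calibration series
#'
#' Fluorescence strictly linear in radiant energy with fluorophore- and
#' wavelength-specific efficiencies, optionally with multiplicative
#' Gaussian noise; blank (buffer-only) rows are included with zero mean.
#' The analytic crosstalk ratio at illumination ratio R is
#' `C(R) = (eff_off / eff_on) * R`.
#'
#' @param efficiencies named list per fluorophore, each a named numeric
#'   vector of counts/uJ per excitation wavelength, e.g.
#'   `list(egfp = c("470" = 1.0, "565" = 0.002),
#'         mapple = c("470" = 0.03, "565" = 0.8))`.
#' @param powers_mw,exposures_ms grids of LED powers and exposures; the
#'   full cross product is measured for every fluorophore and wavelength.
#' @param noise_frac multiplicative noise SD (fraction of the signal).
#' @param seed RNG seed.
#' @param include_blank add buffer-only rows (default `TRUE`).
#' @return A [calibration_series()].
#' @export
generate_calibration_series <- function(efficiencies,
                                        powers_mw = c(1, 2, 4, 8),
                                        exposures_ms = c(1, 2, 4, 8),
                                        noise_frac = 0, seed = 1L,
                                        include_blank = TRUE) {
  rows <- list()
  for (fl in names(efficiencies)) {
    eff <- efficiencies[[fl]]
    for (wl in names(eff)) {
      g <- expand.grid(power_mW = powers_mw, exposure_ms = exposures_ms)
      g$fluorophore <- fl
      g$excitation_nm <- as.numeric(wl)
      g$fluorescence <- eff[[wl]] * radiant_energy(g$power_mW, g$exposure_ms)
      rows[[length(rows) + 1L]] <- g
    }
  }
  d <- do.call(rbind, rows)
  d <- .with_seed(seed, {
    if (noise_frac > 0)
      d$fluorescence <- d$fluorescence *
        (1 + stats::rnorm(nrow(d), sd = noise_frac))
    d
  })
  if (include_blank) {
    b <- expand.grid(power_mW = powers_mw, exposure_ms = exposures_ms,
                     excitation_nm = c(470, 565))
    b$fluorophore <- "blank"
    b$fluorescence <- 0
    d <- rbind(d[, c("fluorophore", "excitation_nm", "power_mW",
                     "exposure_ms", "fluorescence")],
               b[, c("fluorophore", "excitation_nm", "power_mW",
                     "exposure_ms", "fluorescence")])
  } else {
    d <- d[, c("fluorophore", "excitation_nm", "power_mW", "exposure_ms",
               "fluorescence")]
  }
  calibration_series(d)
}

#' Generate a phantom pupil video
#'
#' A dark disc of (possibly time-varying) radius on a bright background,
#' with optional Gaussian noise: the minimal phantom exercising the
#' ellipse-ROI / intensity-threshold pupil measurement.
#'
#' @param radius_px disc radius per frame (pixels); length sets the frame
#'   count.
#' @param height,width frame size (pixels).
#' @param center disc center `c(cx, cy)` (0-based pixel coordinates);
#'   default frame center.
#' @param bg_level,pupil_level background and pupil intensities (counts).
#' @param noise_sd additive Gaussian noise SD (counts).
#' @param seed RNG seed.
#' @return List with `video` (height x width x n array) and `truth`
#'   (radii and the generating levels).
#' @export
generate_pupil_video <- function(radius_px, height = 120, width = 160,
                                 center = c(width / 2, height / 2),
                                 bg_level = 200, pupil_level = 30,
                                 noise_sd = 0, seed = 1L) {
  n <- length(radius_px)
  if (any(radius_px < 0)) .stopf("radii must be >= 0")
  cx <- rep(seq_len(width) - 0.5, each = height) - center[1L]
  cy <- rep(seq_len(height) - 0.5, times = width) - center[2L]
  r2 <- matrix(cx^2 + cy^2, height, width)
  video <- array(bg_level, c(height, width, n))
  for (i in seq_len(n)) {
    fr <- video[, , i]
    fr[r2 <= radius_px[i]^2] <- pupil_level
    video[, , i] <- fr
  }
  video <- .with_seed(seed, {
    if (noise_sd > 0)
      video + stats::rnorm(length(video), sd = noise_sd)
    else video
  })
  list(video = video,
       truth = list(radius_px = radius_px, bg_level = bg_level,
                    pupil_level = pupil_level, center = center))
}
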