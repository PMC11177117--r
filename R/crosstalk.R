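#' Radiant energy of an illumination condition
#'
#' Product of illumination power (mW) and exposure time (ms); with these
#' units the result is in microjoules.
#'
#' @param power_mw illumination power at the sample (mW), > 0.
#' @param exposure_ms camera exposure / illumination time (ms), > 0.
#' @return Radiant energy (uJ).
#' @export
radiant_energy <- function(power_mw, exposure_ms) {
  if (any(power_mw <= 0) || any(exposure_ms <= 0))
    .stopf("power and exposure must be > 0")
  power_mw * exposure_ms
}

#' Illumination ratio R
#'
#' Radiant energy at off-peak excitation divided by radiant energy at
#' on-peak excitation.  Every value of R can be realized by different
#' (power, exposure) combinations; R collapses them into one variable.
#'
#' @param e_offpeak radiant energy at off-peak excitation (uJ).
#' @param e_onpeak radiant energy at on-peak excitation (uJ), > 0.
#' @return R (dimensionless).
#' @export
illumination_ratio <- function(e_offpeak, e_onpeak) {
  if (any(e_onpeak <= 0)) .stopf("on-peak energy must be > 0")
  e_offpeak / e_onpeak
}

#' In-vitro calibration series
#'
#' Tidies a table of blank-subtracted mean fluorescence measurements of a
#' purified fluorophore under alternating 470-/565-nm illumination across
#' a grid of LED powers and exposure times.
#'
#' @param records data frame with columns `fluorophore`, `excitation_nm`,
#'   `power_mW`, `exposure_ms`, `fluorescence`.
#' @return An object of class `calibration_series` (a data frame with an
#'   added `energy_uJ` column).
#' @export
calibration_series <- function(records) {
  need <- c("fluorophore", "excitation_nm", "power_mW", "exposure_ms",
            "fluorescence")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stopf("calibration records missing column(s): %s",
           paste(miss, collapse = ", "))
  if (any(records$power_mW <= 0) || any(records$exposure_ms <= 0))
    .stopf("power and exposure must be > 0")
  records$energy_uJ <- radiant_energy(records$power_mW, records$exposure_ms)
  structure(records, class = c("calibration_series", "data.frame"))
}

#' Read a calibration series from CSV
#'
#' @param path CSV with header
#'   `fluorophore,excitation_nm,power_mW,exposure_ms,fluorescence`.
#' @return A [calibration_series()].
#' @export
read_calibration_series <- function(path) {
  if (!file.exists(path)) .stopf("calibration CSV not found: %s", path)
  calibration_series(utils::read.csv(path))
}

#' Fit the crosstalk ratio C from measurement pairs
#'
#' For a fixed illumination ratio R, off-peak fluorescence is proportional
#' to on-peak fluorescence across (power, exposure) decompositions; C is
#' the slope of the ordinary least-squares fit of F_off against F_on.  The
#' intercept is fitted freely (blank subtraction may be imperfect) and
#' reported alongside the slope.
#'
#' @param pairs data frame with columns `f_off`, `f_on` (blank-subtracted
#'   counts), one row per measurement pair.
#' @param n_required minimum number of pairs (default 2).
#' @return List with `c` (slope), `intercept`, `slope_se`, `r_squared`,
#'   `n_pairs`.
#' @export
fit_crosstalk_ratio <- function(pairs, n_required = 2L) {
  if (nrow(pairs) < max(2L, n_required))
    .stopf("need >= %d measurement pairs, have %d",
           max(2L, n_required), nrow(pairs))
  if (stats::var(pairs$f_on) == 0)
    .stopf("degenerate fit: all on-peak fluorescence values identical")
  fit <- stats::lm(f_off ~ f_on, data = pairs)
  # summary() warns on exact (noiseless) fits; the slope/SE are still valid
  s <- suppressWarnings(summary(fit))
  list(c = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       slope_se = s$coefficients[2L, 2L],
       r_squared = s$r.squared,
       n_pairs = nrow(pairs))
}

# Enumerate (off, on) measurement pairs whose energy ratio matches target_r
# within rel_tol, ranked by closeness; at most n_pairs are kept.
.match_pairs <- function(off, on, target_r, rel_tol, n_pairs) {
  grid <- expand.grid(i = seq_len(nrow(off)), j = seq_len(nrow(on)))
  r_pair <- off$energy_uJ[grid$i] / on$energy_uJ[grid$j]
  keep <- abs(r_pair - target_r) <= rel_tol * target_r
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  ord <- order(abs(r_pair[keep] - target_r))
  grid <- grid[ord, , drop = FALSE][seq_len(min(n_pairs, nrow(grid))), , drop = FALSE]
  data.frame(f_off = off$fluorescence[grid$i],
             f_on = on$fluorescence[grid$j],
             r_pair = off$energy_uJ[grid$i] / on$energy_uJ[grid$j])
}

#' Build the crosstalk-ratio curve C(R) for one fluorophore
#'
#' For each target illumination ratio R, selects up to `n_pairs` pairs of
#' (off-peak, on-peak) measurements whose energy ratio matches R within
#' `pair_tolerance` (relative), fits C by OLS, and assembles the C-vs-R
#' curve.  The curve is queryable by piecewise-linear interpolation in
#' log(R) via [interpolate_crosstalk()]; extrapolation outside the
#' calibrated range is an error.
#'
#' @param series a [calibration_series()].
#' @param fluorophore fluorophore label to calibrate.
#' @param off_nm,on_nm off-peak and on-peak excitation wavelengths (nm);
#'   e.g. for an mApple-like red fluorophore off = 470, on = 565.
#' @param target_rs illumination ratios at which to fit C.
#' @param pair_tolerance relative tolerance on R when matching pairs
#'   (default 0.01).
#' @param n_pairs pairs per fit (default 20).
#' @return An object of class `crosstalk_curve`: data frame with columns
#'   `r`, `c`, `intercept`, `slope_se`, `r_squared`, `n_pairs`.
#' @export
build_crosstalk_curve <- function(series, fluorophore, off_nm, on_nm,
                                  target_rs, pair_tolerance = 0.01,
                                  n_pairs = 20L) {
  stopifnot(inherits(series, "calibration_series"))
  if (any(target_rs <= 0)) .stopf("illumination ratios must be > 0")
  sel <- series$fluorophore == fluorophore
  off <- series[sel & series$excitation_nm == off_nm, , drop = FALSE]
  on  <- series[sel & series$excitation_nm == on_nm, , drop = FALSE]
  if (!nrow(off) || !nrow(on))
    .stopf("no records for fluorophore '%s' at %g/%g nm",
           fluorophore, off_nm, on_nm)
  rows <- lapply(target_rs, function(r) {
    pairs <- .match_pairs(off, on, r, pair_tolerance, n_pairs)
    if (is.null(pairs))
      .stopf("no measurement pairs match R = %g within %.1f%%",
             r, 100 * pair_tolerance)
    fit <- fit_crosstalk_ratio(pairs)
    data.frame(r = r, c = fit$c, intercept = fit$intercept,
               slope_se = fit$slope_se, r_squared = fit$r_squared,
               n_pairs = fit$n_pairs)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$r), , drop = FALSE]
  attr(out, "fluorophore") <- fluorophore
  class(out) <- c("crosstalk_curve", "data.frame")
  out
}

#' Interpolate a crosstalk curve at new illumination ratios
#'
#' Piecewise-linear interpolation of C in log(R) (R spans decades in a
#' typical calibration).  Querying outside the calibrated range raises an
#' error; the curve is never silently extrapolated.
#'
#' @param curve a `crosstalk_curve`.
#' @param r illumination ratio(s) to query.
#' @return Interpolated crosstalk ratio(s) C.
#' @export
interpolate_crosstalk <- function(curve, r) {
  stopifnot(inherits(curve, "crosstalk_curve"))
  if (any(r <= 0)) .stopf("illumination ratios must be > 0")
  rng <- range(curve$r)
  if (any(r < rng[1L]) || any(r > rng[2L]))
    .stopf("R outside calibrated range [%g, %g]; refusing to extrapolate",
           rng[1L], rng[2L])
  if (nrow(curve) == 1L) return(rep(curve$c, length(r)))
  stats::approx(log(curve$r), curve$c, log(r))$y
}

#' Write a crosstalk curve to CSV plus JSON diagnostics
#'
#' @param curve a `crosstalk_curve`.
#' @param csv_path output CSV path (columns `r,c`).
#' @param json_path optional path for full per-R fit diagnostics (JSON).
#' @return Invisibly, `csv_path`.
#' @export
write_crosstalk_curve <- function(curve, csv_path, json_path = NULL) {
  utils::write.csv(curve[, c("r", "c")], csv_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(curve), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Zero-lag cross-correlation of two traces
#'
#' Pearson correlation at lag zero of the mean-removed traces, plus the
#' surrounding lag profile.  Used to detect crosstalk overcorrection: for
#' independent source signals, subtracting more than the true mixing
#' fraction from the green channel makes the corrected green trace
#' negatively correlated with the red trace at lag zero.
#'
#' @param a,b numeric traces of equal length >= 3, finite.
#' @param max_lag half-width of the reported lag profile (samples,
#'   default 20, clipped to the available length).
#' @return List with `r0` (zero-lag Pearson correlation), `lags` and
#'   `profile` (correlation per lag).
#' @export
zero_lag_crosscorrelation <- function(a, b, max_lag = 20L) {
  if (length(a) != length(b)) .stopf("traces must have equal length")
  if (length(a) < 3L) .stopf("traces must have length >= 3")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    .stopf("traces must be finite")
  max_lag <- min(as.integer(max_lag), length(a) - 2L)
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)
  list(r0 = stats::cor(a, b),
       lags = as.vector(cc$lag),
       profile = as.vector(cc$acf))
}
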