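#' Fractional fluorescence change (dF/F)
#'
#' Divides each frame by the baseline image and subtracts one, so 0 means
#' "at baseline" and 0.01 is a 1% increase (ratio-minus-one convention,
#' used consistently for both fluorescence channels).
#'
#' @param stack a [channel_stack()].
#' @param baseline baseline image from [compute_baseline()].
#' @return An object of class `dff_stack`: fields `data` (dimensionless
#'   3-D array), `wavelength_nm`, `dt_s`, `mask`, `detrended` flag.
#' @export
compute_dff <- function(stack, baseline) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$data)
  if (!all(dim(baseline) == d[1:2]))
    .stopf("baseline image does not match frame shape")
  valid <- stack$mask & baseline > 0
  v <- attr(baseline, "valid")
  if (!is.null(v)) valid <- valid & v
  if (any(stack$mask & baseline <= 0))
    .warnf("%d pixel(s) with nonpositive fluorescence baseline masked",
           sum(stack$mask & baseline <= 0))
  b <- as.vector(baseline)
  b[!valid] <- NA_real_
  data <- stack$data / b - 1  # baseline recycled over time
  structure(list(data = data, wavelength_nm = stack$wavelength_nm,
                 dt_s = stack$dt_s, mask = valid, detrended = FALSE),
            class = "dff_stack")
}

#' Remove per-pixel linear trends
#'
#' Subtracts, for every pixel, the ordinary least-squares straight line
#' fitted to its time course (removing both mean and slope), the standard
#' slow-drift removal step applied after dF/F.
#'
#' @param dff a `dff_stack` (or any object with a 3-D `data` field).
#' @return The input with detrended `data` and `detrended = TRUE`.
#' @export
detrend_linear <- function(dff) {
  d <- dim(dff$data)
  if (d[3L] < 2L) .stopf("detrending needs >= 2 timepoints")
  y <- t(.as_pixel_matrix(dff$data))          # T x P
  x <- cbind(1, seq_len(d[3L]))
  beta <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% beta
  dff$data <- .from_pixel_matrix(t(res), d[1L], d[2L])
  dff$detrended <- TRUE
  dff
}

#' Correct green fluorescence for hemodynamic absorption
#'
#' Time-varying hemoglobin concentrations absorb both the excitation and
#' the emission light of the green indicator, darkening the measured
#' fluorescence when hemoglobin levels rise.  With the absorption
#' coefficient change
#' \deqn{\Delta\mu_a(\lambda,t) = \ln(10)\,[\epsilon_{HbO}(\lambda)\,
#'   \Delta[HbO](t) + \epsilon_{HbR}(\lambda)\,\Delta[HbR](t)]}
#' the measured fluorescence ratio relates to the artifact-free one as
#' \deqn{1 + dff_{corr} = (1 + dff_{meas})\,
#'   e^{\Delta\mu_a(\lambda_{ex})X_{ex} + \Delta\mu_a(\lambda_{em})X_{em}}}
#' i.e. the correction multiplies the measured ratio by the inverse of the
#' attenuation the photons suffered on the excitation and emission paths.
#'
#' @param dff a `dff_stack` (measured, typically the 470-nm channel).
#' @param maps a `hemodynamic_maps` object time-aligned with `dff`.
#' @param eps an [extinction_table()] covering `lambda_ex` and `lambda_em`.
#' @param paths a [pathlength_set()]; `x_ex`/`x_em` are used.
#' @param lambda_ex excitation wavelength (nm, default 470).
#' @param lambda_em emission-band center (nm, default 523, the center of a
#'   500-540 nm green detection band; configurable).
#' @return The corrected `dff_stack`.
#' @export
correct_hemodynamics <- function(dff, maps, eps, paths,
                                 lambda_ex = 470, lambda_em = 523) {
  stopifnot(inherits(maps, "hemodynamic_maps"), inherits(paths, "pathlength_set"))
  if (!all(dim(dff$data) == dim(maps$hbo)))
    .stopf("dff and hemodynamic maps differ in shape")
  e_ex <- ext_coef(eps, lambda_ex)
  e_em <- ext_coef(eps, lambda_em)
  mua_ex <- log(10) * (e_ex[["hbo"]] * maps$hbo + e_ex[["hbr"]] * maps$hbr)
  mua_em <- log(10) * (e_em[["hbo"]] * maps$hbo + e_em[["hbr"]] * maps$hbr)
  factor <- exp(mua_ex * paths$x_ex + mua_em * paths$x_em)
  dff$data <- (1 + dff$data) * factor - 1
  dff$mask <- dff$mask & maps$valid
  dff
}

#' Subtract red-fluorophore crosstalk from the 470-nm channel
#'
#' Off-peak excitation of the red fluorophore at 470 nm contributes a
#' fraction `c` of its 565-nm fluorescence to the 470-nm measurement.
#' The correction subtracts that contribution frame by frame:
#' `F_corrected470(t) = F_measured470(t) - c * F565(t)`.  It operates on
#' raw intensities and precedes dF/F; frames acquired within one cycle are
#' treated as simultaneous.  The calibrated crosstalk ratio `c` comes from
#' [build_crosstalk_curve()] evaluated at the in-vivo illumination ratio;
#' `c = 0` (no correction) is the pipeline default.
#'
#' @param f470 the 470-nm channel: a [channel_stack()] or 3-D array of raw
#'   intensities.
#' @param f565 the 565-nm channel, same type and shape.
#' @param c crosstalk ratio, >= 0 (dimensionless).
#' @return Same type as `f470`, corrected.
#' @export
correct_crosstalk <- function(f470, f565, c) {
  .assert_scalar_num(c, "c")
  if (c < 0) .stopf("crosstalk ratio must be >= 0 (got %g)", c)
  a470 <- if (inherits(f470, "channel_stack")) f470$data else f470
  a565 <- if (inherits(f565, "channel_stack")) f565$data else f565
  if (!all(dim(a470) == dim(a565)))
    .stopf("channels differ in shape")
  corrected <- a470 - c * a565
  if (inherits(f470, "channel_stack")) {
    f470$data <- corrected
    f470
  } else corrected
}
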