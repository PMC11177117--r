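#' Baseline image of a channel stack
#'
#' Baseline intensity I0 per pixel, estimated as the temporal average of
#' the channel over the full record or over a configured frame range.
#' Pixels whose baseline is zero or negative (dead or saturated-inverted
#' pixels, or regions outside the illuminated field) are flagged invalid
#' with a warning; downstream log-domain computations mask them out.
#'
#' @param stack a [channel_stack()].
#' @param frames optional integer vector of timepoint indices to average
#'   over (default: all).
#' @return Numeric matrix (height x width) with attribute `valid`, a
#'   logical matrix marking pixels with positive baseline.
#' @export
compute_baseline <- function(stack, frames = NULL) {
  stopifnot(inherits(stack, "channel_stack") || (is.array(stack$data)))
  d <- dim(stack$data)
  if (d[3L] < 1L) .stopf("stack has no timepoints")
  idx <- if (is.null(frames)) seq_len(d[3L]) else as.integer(frames)
  if (any(idx < 1L) || any(idx > d[3L]))
    .stopf("baseline frame range outside record (1..%d)", d[3L])
  m <- .as_pixel_matrix(stack$data)
  b <- rowMeans(m[, idx, drop = FALSE])
  valid <- b > 0 & stack$mask
  if (any(!valid & stack$mask))
    .warnf("%d pixel(s) with nonpositive baseline marked invalid",
           sum(!valid & stack$mask))
  b <- matrix(b, d[1L], d[2L])
  attr(b, "valid") <- matrix(valid, d[1L], d[2L])
  b
}

#' Precompute the explicit Beer-Lambert solver constants
#'
#' The two-wavelength modified Beer-Lambert system
#' \deqn{\Delta OD_{525} = \epsilon_{525}^{HbO}\Delta[HbO] +
#'       \epsilon_{525}^{HbR}\Delta[HbR]}
#' \deqn{\Delta OD_{625} = \epsilon_{625}^{HbO}\Delta[HbO] +
#'       \epsilon_{625}^{HbR}\Delta[HbR]}
#' with \eqn{\Delta OD_\lambda = -\log(I_\lambda^t/I_\lambda^0)/X_\lambda}
#' admits an explicit solution in which all quantities constant over time
#' and/or space are folded into four scalar coefficients and two per-pixel
#' offset images:
#' \deqn{\Delta[HbO] = A_0^{HbO} + C_{525}^{HbO*}\log I_{525}^t -
#'       C_{625}^{HbO*}\log I_{625}^t}
#' and analogously for \eqn{\Delta[HbR]}.  Precomputing these makes the
#' per-frame work two multiplies and two adds per pixel.
#'
#' @param eps an [extinction_table()].
#' @param paths a [pathlength_set()] (cm).
#' @param baseline_i525,baseline_i625 baseline intensity images from
#'   [compute_baseline()].
#' @param log_base `10` (default, OD convention matching tabulated molar
#'   extinction coefficients) or `"e"`.
#' @return An object of class `solver_constants` with scalar coefficients
#'   `c525_hbo`, `c625_hbo`, `c525_hbr`, `c625_hbr` (M per log-intensity
#'   unit) and per-pixel offset images `a0_hbo`, `a0_hbr` (M).
#' @export
precompute_constants <- function(eps, paths, baseline_i525, baseline_i625,
                                 log_base = 10) {
  stopifnot(inherits(paths, "pathlength_set"))
  e525 <- ext_coef(eps, 525); e625 <- ext_coef(eps, 625)
  e525o <- e525[["hbo"]]; e525r <- e525[["hbr"]]
  e625o <- e625[["hbo"]]; e625r <- e625[["hbr"]]
  den_hbo <- e625o * e525r - e625r * e525o
  den_hbr <- e625r * e525o - e625o * e525r
  if (abs(den_hbo) < .Machine$double.eps * max(abs(c(e525o, e525r, e625o, e625r)))^2)
    .stopf(paste0("degenerate extinction matrix: determinant ",
                  "e625HbO*e525HbR - e625HbR*e525HbO = %g"), den_hbo)
  c525_hbo <- e625r / den_hbo / paths$x525
  c625_hbo <- e525r / den_hbo / paths$x625
  c625_hbr <- e525o / den_hbr / paths$x625
  c525_hbr <- e625o / den_hbr / paths$x525
  if (!all(dim(baseline_i525) == dim(baseline_i625)))
    .stopf("baseline images must share dimensions")
  valid <- baseline_i525 > 0 & baseline_i625 > 0
  v525 <- attr(baseline_i525, "valid"); v625 <- attr(baseline_i625, "valid")
  if (!is.null(v525)) valid <- valid & v525
  if (!is.null(v625)) valid <- valid & v625
  l0_525 <- l0_625 <- matrix(NA_real_, nrow(baseline_i525), ncol(baseline_i525))
  l0_525[valid] <- .log_b(baseline_i525[valid], log_base)
  l0_625[valid] <- .log_b(baseline_i625[valid], log_base)
  structure(list(
    c525_hbo = c525_hbo, c625_hbo = c625_hbo,
    c525_hbr = c525_hbr, c625_hbr = c625_hbr,
    a0_hbo = c625_hbo * l0_625 - c525_hbo * l0_525,
    a0_hbr = c625_hbr * l0_625 - c525_hbr * l0_525,
    valid = valid, log_base = log_base,
    eps525 = e525, eps625 = e625, paths = paths),
    class = "solver_constants")
}

#' Estimate hemoglobin concentration changes from two-wavelength reflectance
#'
#' Applies the explicit solution prepared by [precompute_constants()] to
#' the 525- and 625-nm reflectance channels:
#' `hbo = a0_hbo + c525_hbo*log(I525t) - c625_hbo*log(I625t)` per pixel and
#' timepoint, analogously for `hbr`; `hbt = hbo + hbr`.  Outputs are
#' concentration changes from baseline, in mol/L.
#'
#' @param i525,i625 [channel_stack()]s of the 525- and 625-nm channels,
#'   co-registered and on the same time axis.
#' @param consts a `solver_constants` object.
#' @return An object of class `hemodynamic_maps` with 3-D arrays `hbo`,
#'   `hbr`, `hbt` (M), `dt_s`, the baseline-derived valid-pixel mask, and
#'   the offset images used.
#' @export
estimate_hemodynamics <- function(i525, i625, consts) {
  stopifnot(inherits(consts, "solver_constants"))
  d5 <- dim(i525$data); d6 <- dim(i625$data)
  if (!all(d5 == d6))
    .stopf("channel stacks differ in shape (%s vs %s)",
           paste(d5, collapse = "x"), paste(d6, collapse = "x"))
  if (!all(d5[1:2] == dim(consts$a0_hbo)))
    .stopf("solver constants were built for a %s image, data are %s",
           paste(dim(consts$a0_hbo), collapse = "x"),
           paste(d5[1:2], collapse = "x"))
  valid <- consts$valid & i525$mask & i625$mask
  nonpos <- valid &
    (apply(i525$data <= 0, c(1, 2), any) | apply(i625$data <= 0, c(1, 2), any))
  if (any(nonpos)) {
    .warnf("%d valid pixel(s) with nonpositive intensity masked", sum(nonpos))
    valid <- valid & !nonpos
  }
  l525 <- .log_b(pmax(i525$data, .Machine$double.xmin), consts$log_base)
  l625 <- .log_b(pmax(i625$data, .Machine$double.xmin), consts$log_base)
  hbo <- consts$c525_hbo * l525 - consts$c625_hbo * l625
  hbr <- consts$c525_hbr * l525 - consts$c625_hbr * l625
  hbo <- hbo + as.vector(consts$a0_hbo)  # a0 recycled over time
  hbr <- hbr + as.vector(consts$a0_hbr)
  if (any(!valid)) {
    na_img <- array(rep(!valid, d5[3L]), d5)
    hbo[na_img] <- NA_real_
    hbr[na_img] <- NA_real_
  }
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 dt_s = i525$dt_s, valid = valid,
                 a0_hbo = consts$a0_hbo, a0_hbr = consts$a0_hbr),
            class = "hemodynamic_maps")
}

#' Per-sample linear-solve reference for the hemoglobin inversion
#'
#' Solves the 2x2 extinction system directly for each (pixel, time) sample
#' from changes in optical density per unit pathlength.  This is the
#' brute-force reference implementation against which the precomputed
#' explicit solver ([estimate_hemodynamics()]) is validated; it performs
#' one `solve()` of the shared 2x2 matrix applied to all samples.
#'
#' @param dod525,dod625 numeric vectors/arrays of optical-density changes
#'   per unit pathlength (cm^-1), i.e. `-log10(I/I0)/X`.
#' @param eps an [extinction_table()].
#' @return List with numeric `hbo` and `hbr` (M), same shape as the input.
#' @export
solve_bruteforce <- function(dod525, dod625, eps) {
  if (length(dod525) != length(dod625))
    .stopf("dOD inputs must have equal length")
  e525 <- ext_coef(eps, 525); e625 <- ext_coef(eps, 625)
  a <- rbind(c(e525[["hbo"]], e525[["hbr"]]),
             c(e625[["hbo"]], e625[["hbr"]]))
  if (abs(det(a)) < .Machine$double.eps * max(abs(a))^2)
    .stopf("degenerate extinction matrix: determinant = %g", det(a))
  x <- solve(a, rbind(as.vector(dod525), as.vector(dod625)))
  hbo <- x[1L, ]; hbr <- x[2L, ]
  if (!is.null(dim(dod525))) { dim(hbo) <- dim(dod525); dim(hbr) <- dim(dod525) }
  list(hbo = hbo, hbr = hbr)
}

#' Optical-density change per unit pathlength
#'
#' `dOD = -log(I/I0) / X` in the configured log base; the quantity entering
#' the two-wavelength extinction system.
#'
#' @param intensity intensities I(t) (counts).
#' @param baseline baseline intensities I0 (counts), recycled.
#' @param pathlength_cm effective pathlength X (cm).
#' @param log_base `10` (default) or `"e"`.
#' @return Numeric, same shape as `intensity` (cm^-1).
#' @export
delta_od <- function(intensity, baseline, pathlength_cm, log_base = 10) {
  .assert_scalar_num(pathlength_cm, "pathlength_cm", positive = TRUE)
  -(.log_b(intensity, log_base) - .log_b(as.vector(baseline), log_base)) /
    pathlength_cm
}
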