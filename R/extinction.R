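#' Hemoglobin extinction-coefficient tables
#'
#' An extinction table holds molar extinction coefficients (base-10
#' convention, cm^-1 M^-1) of oxyhemoglobin (HbO) and deoxyhemoglobin (HbR)
#' on a wavelength grid.  Coefficients at intermediate wavelengths are
#' obtained by linear interpolation; querying outside the tabulated range is
#' an error, never a silent extrapolation.
#'
#' @param wavelength_nm numeric vector of wavelengths (nm), strictly
#'   increasing.
#' @param eps_hbo,eps_hbr molar extinction coefficients of HbO and HbR
#'   (cm^-1 M^-1), all > 0.
#' @return An object of class `extinction_table` (a data frame with columns
#'   `wavelength_nm`, `eps_hbo`, `eps_hbr`).
#' @seealso [read_extinction_table()], [default_extinction_table()],
#'   [ext_coef()]
#' @export
extinction_table <- function(wavelength_nm, eps_hbo, eps_hbr) {
  if (length(wavelength_nm) != length(eps_hbo) ||
      length(wavelength_nm) != length(eps_hbr))
    .stopf("wavelength, eps_hbo and eps_hbr must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    .stopf("wavelength_nm must be strictly increasing")
  if (any(eps_hbo <= 0) || any(eps_hbr <= 0))
    .stopf("all extinction coefficients must be > 0")
  structure(
    data.frame(wavelength_nm = as.numeric(wavelength_nm),
               eps_hbo = as.numeric(eps_hbo),
               eps_hbr = as.numeric(eps_hbr)),
    class = c("extinction_table", "data.frame"))
}

#' Read an extinction table from CSV
#'
#' Expects columns `wavelength_nm,eps_hbo,eps_hbr`.
#'
#' @param path path to a CSV file.
#' @return An [extinction_table()].
#' @export
read_extinction_table <- function(path) {
  if (!file.exists(path)) .stopf("extinction table not found: %s", path)
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo", "eps_hbr")
  if (!all(need %in% names(d)))
    .stopf("extinction CSV must have columns %s", paste(need, collapse = ","))
  extinction_table(d$wavelength_nm, d$eps_hbo, d$eps_hbr)
}

#' Bundled representative extinction table
#'
#' Returns the extinction table shipped with the package
#' (`inst/extdata/hemoglobin_extinction_synthetic.csv`).  The bundled
#' spectra are *synthetic*: smooth curves constructed to reproduce the
#' qualitative shape and magnitude of the standard compiled hemoglobin
#' spectra (Soret and Q bands, near-isosbestic behavior around 525 nm,
#' HbR dominating HbO above 600 nm).  They are intended for simulation and
#' testing; quantitative analysis of real data should use a measured
#' compilation supplied via [read_extinction_table()].
#'
#' @return An [extinction_table()].
#' @export
default_extinction_table <- function() {
  path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                      package = "mesowide", mustWork = TRUE)
  read_extinction_table(path)
}

#' Interpolate extinction coefficients at a wavelength
#'
#' @param eps an [extinction_table()].
#' @param wavelength_nm wavelength to query (nm); must lie inside the
#'   tabulated range.
#' @return Named numeric vector `c(hbo = ..., hbr = ...)` (cm^-1 M^-1).
#' @export
ext_coef <- function(eps, wavelength_nm) {
  stopifnot(inherits(eps, "extinction_table"))
  .assert_scalar_num(wavelength_nm, "wavelength_nm", positive = TRUE)
  rng <- range(eps$wavelength_nm)
  if (wavelength_nm < rng[1L] || wavelength_nm > rng[2L])
    .stopf("wavelength %g nm outside tabulated range [%g, %g] nm",
           wavelength_nm, rng[1L], rng[2L])
  c(hbo = stats::approx(eps$wavelength_nm, eps$eps_hbo, wavelength_nm)$y,
    hbr = stats::approx(eps$wavelength_nm, eps$eps_hbr, wavelength_nm)$y)
}

#' Effective optical pathlengths
#'
#' Effective pathlengths (cm) of detected photons in tissue at the two
#' reflectance wavelengths and at the fluorescence excitation and emission
#' wavelengths.  These are inputs, typically taken from published
#' Monte-Carlo photon-transport estimates; the defaults are representative
#' placeholders and should be replaced for quantitative work.
#'
#' @param x525,x625 pathlengths at the reflectance wavelengths (cm).
#' @param x_ex,x_em pathlengths at the fluorescence excitation and emission
#'   wavelengths (cm).
#' @return An object of class `pathlength_set`.
#' @export
pathlength_set <- function(x525 = 0.06, x625 = 0.4,
                           x_ex = 0.056, x_em = 0.057) {
  for (nm in c("x525", "x625", "x_ex", "x_em"))
    .assert_scalar_num(get(nm), nm, positive = TRUE)
  structure(list(x525 = x525, x625 = x625, x_ex = x_ex, x_em = x_em),
            class = "pathlength_set")
}
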