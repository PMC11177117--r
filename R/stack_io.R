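#' Raw interleaved acquisition
#'
#' Container for an interleaved multi-wavelength frame stack as it comes off
#' the detector: one LED per frame, cycling through `cycle_nm`.  Frames are
#' stored height x width x n_frames in detector counts.  Pixel coordinates
#' are 0-based, row-major, origin top-left throughout the package.
#'
#' @param frames 3-D numeric array (height x width x n_frames), counts >= 0.
#' @param cycle_nm ordered wavelength labels of one cycle (nm), e.g.
#'   `c(470, 565, 525, 625)`.
#' @param exposure_ms per-wavelength exposure durations (ms), recycled to
#'   the cycle length.
#' @param cycle_period_ms duration of one full cycle (ms); the effective
#'   per-channel sampling interval.
#' @param pixel_size_um sample-plane resolution (um/pixel).
#' @param timestamps optional per-frame acquisition times (s), strictly
#'   increasing; derived from the cycle timing when omitted.
#' @param trim if `TRUE` (default), frames of an incomplete trailing cycle
#'   are dropped with a warning; if `FALSE`, an incomplete cycle is an
#'   error.
#' @return An object of class `raw_acquisition`.
#' @export
raw_acquisition <- function(frames, cycle_nm, exposure_ms,
                            cycle_period_ms, pixel_size_um = 20,
                            timestamps = NULL, trim = TRUE) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    .stopf("`frames` must be a 3-D array (height x width x n_frames)")
  if (any(frames < 0, na.rm = TRUE))
    .stopf("intensities must be >= 0")
  L <- length(cycle_nm)
  if (L < 1L) .stopf("cycle must contain at least one wavelength")
  .assert_scalar_num(cycle_period_ms, "cycle_period_ms", positive = TRUE)
  .assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  exposure_ms <- rep_len(as.numeric(exposure_ms), L)
  n <- dim(frames)[3L]
  extra <- n %% L
  if (extra != 0L) {
    if (!trim)
      .stopf("%d frames is not a multiple of the %d-label cycle", n, L)
    .warnf("trimming %d trailing frame(s) of an incomplete cycle", extra)
    frames <- frames[, , seq_len(n - extra), drop = FALSE]
    if (!is.null(timestamps)) timestamps <- timestamps[seq_len(n - extra)]
    n <- n - extra
  }
  if (is.null(timestamps)) {
    slot <- cycle_period_ms / L / 1000
    timestamps <- (seq_len(n) - 1L) * slot
  }
  if (length(timestamps) != n || any(diff(timestamps) <= 0))
    .stopf("timestamps must be strictly increasing, one per frame")
  structure(list(frames = frames,
                 cycle_nm = as.numeric(cycle_nm),
                 exposure_ms = exposure_ms,
                 cycle_period_ms = cycle_period_ms,
                 pixel_size_um = pixel_size_um,
                 timestamps = as.numeric(timestamps)),
            class = "raw_acquisition")
}

#' @export
print.raw_acquisition <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "raw_acquisition: %d x %d px, %d frames (%d cycles of [%s] nm), %g-ms cycle\n",
    d[1], d[2], d[3], d[3] %/% length(x$cycle_nm),
    paste(x$cycle_nm, collapse = ","), x$cycle_period_ms))
  invisible(x)
}

#' Per-wavelength channel stack
#'
#' One demultiplexed wavelength channel: height x width x n_timepoints, with
#' the effective sampling interval `dt_s` equal to the acquisition cycle
#' period and a boolean mask of valid pixels (default: all valid).
#'
#' @param data 3-D numeric array (height x width x n_timepoints).
#' @param wavelength_nm wavelength label (nm).
#' @param dt_s sampling interval (s).
#' @param mask logical matrix matching the frame shape; `TRUE` = valid.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(data, wavelength_nm, dt_s, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("`data` must be a 3-D array")
  .assert_scalar_num(dt_s, "dt_s", positive = TRUE)
  d <- dim(data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    .stopf("mask must be a logical matrix matching the frame shape")
  structure(list(data = data, wavelength_nm = wavelength_nm,
                 dt_s = dt_s, mask = mask),
            class = "channel_stack")
}

#' Demultiplex an interleaved acquisition into channel stacks
#'
#' Frame k of the cycle, and every L-th frame after it (L = cycle length),
#' belong to wavelength `cycle_nm[k]`.  Each channel therefore samples the
#' scene once per cycle: `dt_s = cycle_period_ms / 1000`.
#'
#' @param acq a [raw_acquisition()].
#' @return Named list of [channel_stack()] objects, one per cycle label, in
#'   cycle order; names are the wavelengths in nm.
#' @export
demultiplex <- function(acq) {
  stopifnot(inherits(acq, "raw_acquisition"))
  L <- length(acq$cycle_nm)
  n <- dim(acq$frames)[3L]
  dt_s <- acq$cycle_period_ms / 1000
  out <- lapply(seq_len(L), function(k) {
    idx <- seq(k, n, by = L)
    channel_stack(acq$frames[, , idx, drop = FALSE],
                  wavelength_nm = acq$cycle_nm[k], dt_s = dt_s)
  })
  names(out) <- as.character(acq$cycle_nm)
  out
}

#' Field of view of an acquisition
#'
#' Image extent at the sample plane: pixel count times sample-plane pixel
#' size.  A 460 x 360-pixel acquisition at 20 um/pixel covers
#' 9.2 x 7.2 mm.
#'
#' @param acq a [raw_acquisition()], or a numeric vector of pixel counts
#'   if `pixel_size_um` is given.
#' @param pixel_size_um pixel size (um), only for bare pixel counts.
#' @return Numeric vector of extents (mm), same order as the pixel
#'   dimensions supplied.
#' @export
field_of_view_mm <- function(acq, pixel_size_um = NULL) {
  if (inherits(acq, "raw_acquisition"))
    return(dim(acq$frames)[1:2] * acq$pixel_size_um / 1000)
  .assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  acq * pixel_size_um / 1000
}

#' Re-interleave channel stacks into a frame stack
#'
#' Inverse of [demultiplex()]: concatenates the channels in cycle order so
#' that `interleave(demultiplex(acq)) == acq$frames`.
#'
#' @param channels named list of [channel_stack()] objects in cycle order.
#' @return 3-D array of interleaved frames.
#' @export
interleave <- function(channels) {
  L <- length(channels)
  nt <- dim(channels[[1L]]$data)[3L]
  d <- dim(channels[[1L]]$data)
  frames <- array(0, c(d[1L], d[2L], nt * L))
  for (k in seq_len(L))
    frames[, , seq(k, nt * L, by = L)] <- channels[[k]]$data
  frames
}

#' Read an acquisition from disk
#'
#' Reads a multipage TIFF stack or a flat raw binary file, described by a
#' JSON or YAML sidecar with keys `dtype`, `height`, `width`, `n_frames`,
#' `cycle_nm`, `exposure_ms`, `cycle_period_ms`, `pixel_size_um` (and
#' `byte_order` for raw binary, default little-endian; frame-major layout).
#' Vendor-specific metadata dialects are deliberately not parsed.
#'
#' @param path path to a `.tif`/`.tiff` stack or a raw binary file.
#' @param sidecar path to the JSON (`.json`) or YAML (`.yml`/`.yaml`)
#'   metadata sidecar.
#' @param trim trim incomplete trailing cycles (default `TRUE`).
#' @return A [raw_acquisition()].
#' @export
read_acquisition <- function(path, sidecar, trim = TRUE) {
  if (!file.exists(path)) .stopf("image file not found: %s", path)
  if (!file.exists(sidecar)) .stopf("sidecar not found: %s", sidecar)
  meta <- if (grepl("\\.(yml|yaml)$", sidecar, ignore.case = TRUE))
    yaml::read_yaml(sidecar)
  else jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("dtype", "height", "width", "n_frames", "cycle_nm",
            "exposure_ms", "cycle_period_ms", "pixel_size_um")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    .stopf("sidecar is missing required key(s): %s", paste(miss, collapse = ", "))
  h <- as.integer(meta$height); w <- as.integer(meta$width)
  nf <- as.integer(meta$n_frames)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != nf)
      .stopf("TIFF has %d frames but sidecar declares %d", length(pages), nf)
    if (!all(dim(pages[[1L]])[1:2] == c(h, w)))
      .stopf("TIFF frame is %dx%d but sidecar declares %dx%d",
             dim(pages[[1L]])[1L], dim(pages[[1L]])[2L], h, w)
    frames <- array(0, c(h, w, nf))
    for (i in seq_len(nf)) frames[, , i] <- pages[[i]]
  } else {
    dtype <- tolower(meta$dtype)
    size <- switch(dtype,
                   uint16 = 2L, int16 = 2L, uint8 = 1L,
                   int32 = 4L, float32 = 4L, float64 = 8L,
                   .stopf("unsupported dtype '%s'", meta$dtype))
    what <- if (dtype %in% c("float32", "float64")) "numeric" else "integer"
    endian <- if (is.null(meta$byte_order)) "little" else meta$byte_order
    n_vals <- h * w * nf
    con <- file(path, "rb"); on.exit(close(con))
    vals <- readBin(con, what = what, n = n_vals, size = size,
                    signed = !(dtype %in% c("uint8", "uint16")),
                    endian = endian)
    if (length(vals) != n_vals)
      .stopf("raw file holds %d values; sidecar declares %d (%dx%dx%d)",
             length(vals), n_vals, h, w, nf)
    # frame-major layout: each frame stored row-major (row index fastest
    # within a column-major R array after transposition)
    frames <- aperm(array(as.numeric(vals), c(w, h, nf)), c(2L, 1L, 3L))
  }
  raw_acquisition(frames,
                  cycle_nm = unlist(meta$cycle_nm),
                  exposure_ms = unlist(meta$exposure_ms),
                  cycle_period_ms = meta$cycle_period_ms,
                  pixel_size_um = meta$pixel_size_um,
                  trim = trim)
}

#' Write an acquisition to disk
#'
#' Writes the frame stack as a multipage 16-bit TIFF (or raw binary when
#' `path` does not end in `.tif(f)`) plus a JSON sidecar, the format
#' [read_acquisition()] reads back.
#'
#' @param acq a [raw_acquisition()].
#' @param path output image path (`.tif`, `.tiff`, or raw binary).
#' @param sidecar output sidecar path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_acquisition <- function(acq, path, sidecar) {
  stopifnot(inherits(acq, "raw_acquisition"))
  d <- dim(acq$frames)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  meta <- list(dtype = if (is_tiff) "uint16" else "float64",
               height = d[1L], width = d[2L], n_frames = d[3L],
               cycle_nm = acq$cycle_nm, exposure_ms = acq$exposure_ms,
               cycle_period_ms = acq$cycle_period_ms,
               pixel_size_um = acq$pixel_size_um)
  if (is_tiff) {
    mx <- max(acq$frames)
    if (mx > 65535) .stopf("counts exceed 16-bit range; write raw binary instead")
    pages <- lapply(seq_len(d[3L]), function(i)
      round(acq$frames[, , i]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(aperm(acq$frames, c(2L, 1L, 3L))), con,
             size = 8L, endian = "little")
    close(con)
    meta$byte_order <- "little"
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon mask
#'
#' Converts a polygon (e.g. a manually drawn hemisphere outline) into a
#' logical pixel mask using the pixel-center inclusion rule: a pixel is
#' inside when its center (0-based coordinates x+0.5, y+0.5 from the
#' top-left origin) falls inside the polygon.
#'
#' @param height,width mask dimensions (pixels).
#' @param poly_x,poly_y polygon vertex coordinates (0-based pixel units,
#'   x = column, y = row).
#' @return Logical matrix `height x width`; `TRUE` = inside.
#' @export
rasterize_mask <- function(height, width, poly_x, poly_y) {
  if (length(poly_x) != length(poly_y) || length(poly_x) < 3L)
    .stopf("polygon needs >= 3 vertices with matching x/y")
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, times = width)
  n <- length(poly_x)
  inside <- rep(FALSE, length(cx))
  j <- n
  for (i in seq_len(n)) {  # even-odd ray casting
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > cy) != (yj > cy)) &
      (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, height, width)
}

#' Persist result stacks and traces
#'
#' Writes 3-D result stacks (hemoglobin maps, dF/F stacks) to an HDF5 file
#' with datasets `/hbo`, `/hbr`, `/hbt`, `/dff_<wavelength>` and a `units`
#' attribute per dataset, and writes 1-D traces to CSV with a
#' `time_s,<quantity>` header.  The round trip through [read_results()] is
#' lossless (float64).
#'
#' @param stacks named list of 3-D arrays (names become dataset names).
#' @param path output `.h5` path.
#' @param units named character vector of unit strings per dataset
#'   (default "a.u.").
#' @return Invisibly, `path`.
#' @export
write_results <- function(stacks, path, units = NULL) {
  if (!length(stacks)) .stopf("no datasets to write")
  for (nm in names(stacks))
    if (!is.array(stacks[[nm]]) || length(dim(stacks[[nm]])) != 3L ||
        prod(dim(stacks[[nm]])) == 0L)
      .stopf("dataset '%s' must be a non-empty 3-D array", nm)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) .stopf("cannot create HDF5 file at %s", path)
  for (nm in names(stacks)) {
    rhdf5::h5write(stacks[[nm]], path, nm)
    u <- if (!is.null(units) && nm %in% names(units)) units[[nm]] else "a.u."
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, nm)
    rhdf5::h5writeAttribute(u, did, "units")
    rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read back stacks written by [write_results()]
#'
#' @param path an HDF5 file written by [write_results()].
#' @return Named list of arrays.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  info <- rhdf5::h5ls(path)
  nms <- info$name[info$otype == "H5I_DATASET"]
  out <- lapply(nms, function(nm) rhdf5::h5read(path, nm))
  rhdf5::h5closeAll()
  names(out) <- nms
  out
}

#' Write a time-series trace to CSV
#'
#' @param time_s time vector (s).
#' @param values numeric vector or named list/data.frame of columns.
#' @param path output CSV path.
#' @param quantity column name used when `values` is a bare vector.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(time_s, values, path, quantity = "value") {
  if (is.numeric(values)) {
    d <- data.frame(time_s = time_s, v = values)
    names(d)[2L] <- quantity
  } else {
    d <- data.frame(time_s = time_s, values, check.names = FALSE)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
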