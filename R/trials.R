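#' Align a trace or stack to stimulus onsets
#'
#' Cuts the record into trials and linearly interpolates each trial onto a
#' fixed relative-time grid (default 100-ms step) spanning `[-pre_s,
#' post_s]` around each onset.  Trials whose window extends beyond the
#' record are dropped with a warning.
#'
#' @param x either a numeric vector (ROI trace) or a 3-D array /
#'   [channel_stack()] / `dff_stack` (height x width x time).
#' @param onsets_s stimulus onset times (s).
#' @param pre_s,post_s window before/after onset (s), both >= 0.
#' @param dt relative-time grid step (s, default 0.1).
#' @param time_s sample times of `x` (s); defaults to a uniform grid at
#'   `dt_s` starting at 0 for stack-like inputs, and is required for bare
#'   vectors.
#' @param quantity label carried into the result.
#' @return An object of class `trial_tensor`: `data` is trials x time for
#'   traces or trials x height x width x time for stacks, plus
#'   `rel_time_s`, `onsets_s` (of the kept trials) and `quantity`.
#' @export
align_trials <- function(x, onsets_s, pre_s, post_s, dt = 0.1,
                         time_s = NULL, quantity = "signal") {
  rel <- seq(-pre_s, post_s, by = dt)
  is_stack <- inherits(x, c("channel_stack", "dff_stack")) ||
    (is.array(x) && length(dim(x)) == 3L)
  if (is_stack) {
    a <- if (is.list(x)) x$data else x
    if (is.null(time_s)) {
      if (!is.list(x) || is.null(x$dt_s))
        .stopf("time_s is required for bare arrays")
      time_s <- (seq_len(dim(a)[3L]) - 1L) * x$dt_s
    }
  } else {
    if (is.null(time_s)) .stopf("time_s is required for trace input")
    if (length(time_s) != length(x))
      .stopf("time_s and trace differ in length")
  }
  t0 <- min(time_s); t1 <- max(time_s)
  keep <- onsets_s - pre_s >= t0 & onsets_s + post_s <= t1
  if (any(!keep))
    .warnf("dropping %d trial(s) whose window exceeds the record", sum(!keep))
  onsets_s <- onsets_s[keep]
  if (!length(onsets_s)) .stopf("no complete trials remain")
  if (is_stack) {
    a <- if (is.list(x)) x$data else x
    d <- dim(a)
    m <- .as_pixel_matrix(a)                       # P x T
    data <- array(NA_real_, c(length(onsets_s), d[1L], d[2L], length(rel)))
    for (tr in seq_along(onsets_s)) {
      tq <- onsets_s[tr] + rel
      # shared linear-interpolation weights across all pixels
      idx <- findInterval(tq, time_s, rightmost.closed = TRUE)
      idx <- pmin(pmax(idx, 1L), length(time_s) - 1L)
      w <- (tq - time_s[idx]) / (time_s[idx + 1L] - time_s[idx])
      frame <- m[, idx, drop = FALSE] * rep(1 - w, each = nrow(m)) +
        m[, idx + 1L, drop = FALSE] * rep(w, each = nrow(m))
      data[tr, , , ] <- array(frame, c(d[1L], d[2L], length(rel)))
    }
  } else {
    data <- t(vapply(onsets_s, function(on)
      stats::approx(time_s, x, on + rel)$y, numeric(length(rel))))
  }
  structure(list(data = data, rel_time_s = rel, onsets_s = onsets_s,
                 quantity = quantity),
            class = "trial_tensor")
}

#' Average a trial tensor across trials
#'
#' @param t a `trial_tensor`.
#' @return List with `mean`, `sd` and `se` over trials (same trailing shape
#'   as one trial), `n_trials`, and `rel_time_s`.  With a single trial the
#'   dispersion fields are `NA` and a warning is issued.
#' @export
trial_average <- function(t) {
  stopifnot(inherits(t, "trial_tensor"))
  nd <- length(dim(t$data))
  n <- dim(t$data)[1L]
  mean_ <- apply(t$data, seq(2L, nd), mean)
  if (n < 2L) {
    .warnf("single trial: dispersion undefined")
    sd_ <- array(NA_real_, dim(t$data)[-1L])
  } else {
    sd_ <- apply(t$data, seq(2L, nd), stats::sd)
  }
  list(mean = mean_, sd = sd_, se = sd_ / sqrt(n),
       n_trials = n, rel_time_s = t$rel_time_s)
}

#' Trial-averaged response map at a fixed post-stimulus latency
#'
#' Normalizes each trial to its pre-stimulus window (subtracting the
#' window mean for dF/F-type quantities, or dividing for raw intensities),
#' averages across trials, and returns the averaged frame at the requested
#' latency; latencies between grid points are linearly interpolated from
#' the two adjacent averaged frames.
#'
#' @param t a `trial_tensor` holding image trials (4-D data).
#' @param latency_s latency after stimulus onset (s).
#' @param normalize `"subtract"` (default, for fractional-change inputs),
#'   `"divide"` (raw intensity ratio maps), or `"none"`.
#' @param baseline_window relative-time window used as the per-trial
#'   baseline (default: the full pre-stimulus span).
#' @return Numeric matrix (height x width).
#' @export
ratio_map <- function(t, latency_s,
                      normalize = c("subtract", "divide", "none"),
                      baseline_window = NULL) {
  stopifnot(inherits(t, "trial_tensor"))
  normalize <- match.arg(normalize)
  if (length(dim(t$data)) != 4L)
    .stopf("ratio_map needs image trials (trial x H x W x time)")
  rel <- t$rel_time_s
  if (latency_s < min(rel) || latency_s > max(rel))
    .stopf("latency %g s outside trial window [%g, %g] s",
           latency_s, min(rel), max(rel))
  data <- t$data
  if (normalize != "none") {
    bw <- if (is.null(baseline_window)) c(min(rel), 0) else baseline_window
    bsel <- rel >= bw[1L] & rel <= bw[2L]
    if (!any(bsel)) .stopf("baseline window contains no grid points")
    base <- apply(data[, , , bsel, drop = FALSE], c(1, 2, 3), mean)
    data <- if (normalize == "subtract") {
      sweep(data, c(1, 2, 3), base, "-")
    } else sweep(data, c(1, 2, 3), base, "/")
  }
  avg <- apply(data, c(2, 3, 4), mean)           # H x W x time
  i <- findInterval(latency_s, rel, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(rel) - 1L)
  w <- (latency_s - rel[i]) / (rel[i + 1L] - rel[i])
  (1 - w) * avg[, , i] + w * avg[, , i + 1L]
}
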