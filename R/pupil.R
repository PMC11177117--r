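#' Pupil size of a single frame
#'
#' The pupil appears as the darkest structure inside a manually drawn
#' elliptical eye region; its size is quantified as the number of pixels
#' inside the ellipse whose intensity falls below a manually chosen
#' threshold (an area proxy; see [equivalent_diameter()]).  Pixel-center
#' inclusion is used for the ellipse.
#'
#' @param frame numeric matrix (one video frame).
#' @param roi list with `cx`, `cy` (ellipse center, 0-based pixel
#'   coordinates; x = column, y = row), `a`, `b` (semi-axes, pixels) and
#'   optional `theta` (rotation, radians, default 0).
#' @param threshold intensity cutoff (counts); pixels strictly below it
#'   count as pupil.
#' @return Integer pixel count.
#' @export
pupil_size <- function(frame, roi, threshold) {
  if (is.null(roi$theta)) roi$theta <- 0
  h <- nrow(frame); w <- ncol(frame)
  if (roi$cx - roi$a < 0 || roi$cx + roi$a > w ||
      roi$cy - roi$b < 0 || roi$cy + roi$b > h)
    .stopf("ellipse ROI extends outside the %dx%d frame", h, w)
  cx <- rep(seq_len(w) - 0.5, each = h) - roi$cx
  cy <- rep(seq_len(h) - 0.5, times = w) - roi$cy
  u <- cx * cos(roi$theta) + cy * sin(roi$theta)
  v <- -cx * sin(roi$theta) + cy * cos(roi$theta)
  inside <- (u / roi$a)^2 + (v / roi$b)^2 <= 1
  sum(inside & as.vector(frame) < threshold)
}

#' Pupil-size trace of a video
#'
#' Applies [pupil_size()] to every frame and normalizes the resulting
#' series to its own minimum and maximum within the recording:
#' `norm = (raw - min) / (max - min)`, so any affine rescaling of the raw
#' counts maps to the same normalized trace.
#'
#' @param video 3-D array (height x width x n_frames).
#' @param roi,threshold as in [pupil_size()].
#' @param time_s per-frame times (s); default frame index at `dt_s`.
#' @param dt_s frame interval (s) used when `time_s` is missing
#'   (default 1/30).
#' @return An object of class `pupil_trace` with fields `raw_px`, `norm`,
#'   `time_s`, `roi`, `threshold`.
#' @export
pupil_trace <- function(video, roi, threshold, time_s = NULL, dt_s = 1 / 30) {
  stopifnot(is.array(video), length(dim(video)) == 3L)
  n <- dim(video)[3L]
  raw <- vapply(seq_len(n), function(i)
    pupil_size(video[, , i], roi, threshold), numeric(1))
  if (is.null(time_s)) time_s <- (seq_len(n) - 1L) * dt_s
  rng <- range(raw)
  norm <- if (diff(rng) == 0) rep(0.5, n) else (raw - rng[1L]) / diff(rng)
  structure(list(raw_px = raw, norm = norm, time_s = time_s,
                 roi = roi, threshold = threshold),
            class = "pupil_trace")
}

#' Equivalent pupil diameter from a pixel count
#'
#' `2 * sqrt(count / pi)`: the diameter of a disc with the counted area.
#'
#' @param count pupil pixel count.
#' @return Equivalent diameter (pixels).
#' @export
equivalent_diameter <- function(count) 2 * sqrt(count / pi)

#' Per-transition pupil-size ratios
#'
#' For each illumination transition at time `t`, the ratio of the mean
#' normalized pupil size in a post window (default 2 to 3 s after `t`) to
#' the mean in a pre window (default 1.5 to 0.5 s before `t`).  A ratio of
#' 1 means the transition left the pupil unchanged; 0.7 is a 30%
#' constriction.
#'
#' @param p a `pupil_trace` (or list with `norm` and `time_s`).
#' @param times transition times (s).
#' @param pre_window,post_window windows relative to the transition (s).
#' @return Numeric vector of ratios, one per transition (with a warning
#'   for windows overlapping the neighboring transition).
#' @export
transition_ratios <- function(p, times,
                              pre_window = c(-1.5, -0.5),
                              post_window = c(2, 3)) {
  if (length(times) && any(diff(sort(times)) < diff(range(c(pre_window, post_window)))))
    .warnf("analysis windows overlap adjacent transitions")
  vapply(times, function(t0) {
    pre_sel <- p$time_s >= t0 + pre_window[1L] & p$time_s <= t0 + pre_window[2L]
    post_sel <- p$time_s >= t0 + post_window[1L] & p$time_s <= t0 + post_window[2L]
    if (!any(pre_sel) || !any(post_sel))
      .stopf("transition at %g s has a window outside the record", t0)
    mean(p$norm[post_sel]) / mean(p$norm[pre_sel])
  }, numeric(1))
}

#' Pupil response to illumination transitions
#'
#' Computes per-transition ratios ([transition_ratios()]) for the off-to-on
#' and on-to-off transitions of one recording and compares the two groups
#' with a two-sample t test (Student's equal-variance test by default,
#' Welch optional).
#'
#' @param p a `pupil_trace`.
#' @param on_times illumination-onset times (s).
#' @param off_times illumination-offset times (s); may be `NULL` to only
#'   compute the on-transition ratios.
#' @param var_equal `TRUE` (default) for Student's t test, `FALSE` for
#'   Welch.
#' @param ... passed to [transition_ratios()].
#' @return List with `on_ratios`, `off_ratios`, and `test` (an `htest`, or
#'   `NULL` with fewer than 2 transitions in either group).
#' @export
transition_analysis <- function(p, on_times, off_times = NULL,
                                var_equal = TRUE, ...) {
  on_r <- transition_ratios(p, on_times, ...)
  off_r <- if (length(off_times)) transition_ratios(p, off_times, ...) else numeric(0)
  test <- NULL
  if (length(on_r) >= 2L && length(off_r) >= 2L)
    test <- stats::t.test(on_r, off_r, var.equal = var_equal)
  else if (length(off_times))
    .warnf("fewer than 2 transitions per group: test skipped")
  list(on_ratios = on_r, off_ratios = off_r, test = test)
}

#' Compare transition ratios between two recordings
#'
#' Two-sample t test between the transition-ratio groups of two conditions
#' (e.g. illumination shielding present vs absent).
#'
#' @param ratios_a,ratios_b numeric ratio vectors from
#'   [transition_ratios()].
#' @param var_equal `TRUE` (default) for Student's t test, `FALSE` for
#'   Welch.
#' @return An `htest` object.
#' @export
compare_transition_groups <- function(ratios_a, ratios_b, var_equal = TRUE) {
  if (length(ratios_a) < 2L || length(ratios_b) < 2L)
    .stopf("need >= 2 transitions per group")
  stats::t.test(ratios_a, ratios_b, var.equal = var_equal)
}
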