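#' Build an LED/camera trigger schedule
#'
#' Simulates the acquisition trigger logic of a rolling-shutter sCMOS
#' camera with strobed LEDs: each frame slot carries an exposure window;
#' the FIRE-ALL signal is high while all sensor rows expose simultaneously
#' (the exposure window minus the row-readout span); and each LED turns on
#' exactly during the AND of FIRE-ALL with its wavelength-selection window,
#' so the sample is only illuminated while every row is collecting light.
#' Gate and driver latencies (nanoseconds to tens of microseconds) are
#' negligible against millisecond exposures and are modeled as zero.
#' Frame slots are spaced uniformly at `cycle_period_ms / L`.
#'
#' @param cycle_nm wavelength labels of one cycle (nm).
#' @param exposures_ms per-wavelength exposure durations (ms), recycled.
#' @param cycle_period_ms duration of one cycle (ms).
#' @param readout_ms rolling-shutter row-readout span (ms); must be
#'   smaller than every exposure.
#' @param n_cycles number of cycles.
#' @return An object of class `trigger_schedule`: a data frame with one
#'   row per frame (`frame`, `cycle`, `slot`, `wavelength_nm`,
#'   `exp_start_ms`, `exp_end_ms`, `fire_start_ms`, `fire_end_ms`,
#'   `led_start_ms`, `led_end_ms`, `captured`) and attributes
#'   `cycle_period_ms`, `readout_ms`.
#' @export
build_schedule <- function(cycle_nm, exposures_ms, cycle_period_ms,
                           readout_ms, n_cycles = 1L) {
  L <- length(cycle_nm)
  if (L < 1L) .stopf("cycle must contain at least one wavelength")
  .assert_scalar_num(cycle_period_ms, "cycle_period_ms", positive = TRUE)
  .assert_scalar_num(readout_ms, "readout_ms", positive = TRUE)
  exposures_ms <- rep_len(as.numeric(exposures_ms), L)
  slot_ms <- cycle_period_ms / L
  if (any(exposures_ms <= readout_ms))
    .stopf("infeasible schedule: exposure (%s ms) must exceed readout (%g ms)",
           paste(exposures_ms, collapse = ","), readout_ms)
  if (any(exposures_ms > slot_ms))
    .stopf("exposures exceed the %g-ms frame slot", slot_ms)
  cyc <- rep(seq_len(n_cycles), each = L)
  slot <- rep(seq_len(L), times = n_cycles)
  start <- (cyc - 1L) * cycle_period_ms + (slot - 1L) * slot_ms
  exp_end <- start + exposures_ms[slot]
  s <- data.frame(frame = seq_len(L * n_cycles), cycle = cyc, slot = slot,
                  wavelength_nm = rep(as.numeric(cycle_nm), n_cycles),
                  exp_start_ms = start, exp_end_ms = exp_end,
                  fire_start_ms = start + readout_ms, fire_end_ms = exp_end,
                  led_start_ms = start + readout_ms, led_end_ms = exp_end,
                  captured = TRUE)
  attr(s, "cycle_period_ms") <- cycle_period_ms
  attr(s, "readout_ms") <- readout_ms
  class(s) <- c("trigger_schedule", "data.frame")
  s
}

#' Effective per-channel frame rate of a schedule
#'
#' Every channel is sampled once per cycle, so the effective rate is
#' `1000 / cycle_period_ms` Hz regardless of cycle length.
#'
#' @param s a `trigger_schedule`.
#' @return Rate (Hz).
#' @export
effective_channel_rate <- function(s) {
  stopifnot(inherits(s, "trigger_schedule"))
  1000 / attr(s, "cycle_period_ms")
}

#' Build a photoswitching-protocol schedule
#'
#' Interleaves two cycle variants used to probe blue-light photoswitching
#' of red indicators: type 1 keeps the 470-nm illumination window but
#' disables image capture during it (camera exposure trigger withheld, the
#' LED driven through the FIRE-ALL bypass); type 2 omits the 470-nm window
#' entirely while the remaining channels are captured normally.  Pattern
#' code 0 gives a normal cycle.
#'
#' @param cycle_nm,exposures_ms,cycle_period_ms,readout_ms as in
#'   [build_schedule()].
#' @param pattern integer vector of cycle types (0 = normal,
#'   1 = illuminate-470-without-capture, 2 = omit 470); its length sets
#'   the number of cycles.
#' @param switch_nm the wavelength the pattern acts on (default 470).
#' @return A `trigger_schedule`; frames of omitted slots are removed and
#'   non-captured 470 frames have `captured = FALSE` with `NA` exposure
#'   windows.
#' @export
build_photoswitching_schedule <- function(cycle_nm, exposures_ms,
                                          cycle_period_ms, readout_ms,
                                          pattern, switch_nm = 470) {
  if (!all(pattern %in% 0:2)) .stopf("pattern codes must be 0, 1 or 2")
  if (!switch_nm %in% cycle_nm)
    .stopf("switch wavelength %g nm is not part of the cycle", switch_nm)
  s <- build_schedule(cycle_nm, exposures_ms, cycle_period_ms, readout_ms,
                      n_cycles = length(pattern))
  type <- pattern[s$cycle]
  is_sw <- s$wavelength_nm == switch_nm
  # type 1: LED on via bypass, no exposure / FIRE-ALL
  sel1 <- is_sw & type == 1L
  s$captured[sel1] <- FALSE
  s$exp_start_ms[sel1] <- s$exp_end_ms[sel1] <- NA_real_
  s$fire_start_ms[sel1] <- s$fire_end_ms[sel1] <- NA_real_
  # type 2: slot dropped entirely
  keep <- !(is_sw & type == 2L)
  out <- s[keep, , drop = FALSE]
  out$frame <- seq_len(nrow(out))
  attr(out, "cycle_period_ms") <- attr(s, "cycle_period_ms")
  attr(out, "readout_ms") <- attr(s, "readout_ms")
  attr(out, "pattern") <- pattern
  class(out) <- c("trigger_schedule", "data.frame")
  out
}

#' Generate a stimulus pulse train
#'
#' Stimuli are defined by pulse-train duration, pulse rate, number of
#' repetitions and interstimulus interval; e.g. a 2-s, 3-Hz train contains
#' 6 pulses.  Returns both the train onsets (consumed by [align_trials()])
#' and the absolute times of every pulse.
#'
#' @param duration_s train duration (s).
#' @param rate_hz pulse rate within a train (Hz).
#' @param n_repetitions number of trains.
#' @param isi_s interstimulus (train-onset-to-train-onset) interval (s).
#' @param first_onset_s time of the first train onset (s, default 0).
#' @return List with `onsets_s`, `pulse_times_s`, `n_pulses_per_train` and
#'   the input parameters.
#' @export
build_stimulus_train <- function(duration_s, rate_hz, n_repetitions = 1L,
                                 isi_s = duration_s, first_onset_s = 0) {
  .assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  .assert_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  if (n_repetitions < 1L) .stopf("need >= 1 repetition")
  n_pulses <- floor(duration_s * rate_hz + 1e-9)
  if (n_pulses < 1L) .stopf("train too short for a single pulse")
  onsets <- first_onset_s + (seq_len(n_repetitions) - 1L) * isi_s
  within <- (seq_len(n_pulses) - 1L) / rate_hz
  list(onsets_s = onsets,
       pulse_times_s = as.vector(outer(within, onsets, `+`)),
       n_pulses_per_train = n_pulses,
       duration_s = duration_s, rate_hz = rate_hz,
       n_repetitions = n_repetitions, isi_s = isi_s)
}

#' Validate a trigger schedule
#'
#' Checks every schedule invariant: each LED window lies inside its
#' frame's FIRE-ALL window, each FIRE-ALL window inside the exposure
#' window with duration exactly exposure minus readout (> 0), and no two
#' LED windows overlap at any instant.
#'
#' @param s a `trigger_schedule`.
#' @return Character vector of violations naming the offending frames;
#'   empty when the schedule is valid.
#' @export
validate_schedule <- function(s) {
  stopifnot(inherits(s, "trigger_schedule"))
  v <- character(0)
  readout <- attr(s, "readout_ms")
  tol <- 1e-9
  for (i in seq_len(nrow(s))) {
    r <- s[i, ]
    has_led <- !is.na(r$led_start_ms)
    if (r$captured) {
      if (is.na(r$exp_start_ms) || is.na(r$fire_start_ms)) {
        v <- c(v, sprintf("frame %d: captured frame lacks exposure/FIRE-ALL window", r$frame))
        next
      }
      fire_dur <- r$fire_end_ms - r$fire_start_ms
      if (fire_dur <= 0)
        v <- c(v, sprintf("frame %d: nonpositive FIRE-ALL duration", r$frame))
      if (abs(fire_dur - (r$exp_end_ms - r$exp_start_ms - readout)) > tol)
        v <- c(v, sprintf("frame %d: FIRE-ALL duration != exposure - readout", r$frame))
      if (r$fire_start_ms < r$exp_start_ms - tol ||
          r$fire_end_ms > r$exp_end_ms + tol)
        v <- c(v, sprintf("frame %d: FIRE-ALL window outside exposure window", r$frame))
      if (has_led && (r$led_start_ms < r$fire_start_ms - tol ||
                      r$led_end_ms > r$fire_end_ms + tol))
        v <- c(v, sprintf("frame %d: LED window outside FIRE-ALL window", r$frame))
    }
    if (has_led && r$led_end_ms <= r$led_start_ms)
      v <- c(v, sprintf("frame %d: empty LED window", r$frame))
  }
  led <- s[!is.na(s$led_start_ms), , drop = FALSE]
  if (nrow(led) > 1L) {
    o <- order(led$led_start_ms)
    led <- led[o, ]
    for (i in seq_len(nrow(led) - 1L)) {
      if (led$led_start_ms[i + 1L] < led$led_end_ms[i] - tol)
        v <- c(v, sprintf("frames %d,%d: overlapping LED windows",
                          led$frame[i], led$frame[i + 1L]))
    }
  }
  v
}

#' Export a schedule to CSV
#'
#' Columns `frame,channel_nm,exp_start_ms,exp_end_ms,led_start_ms,
#' led_end_ms,captured`.
#'
#' @param s a `trigger_schedule`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_schedule <- function(s, path) {
  stopifnot(inherits(s, "trigger_schedule"))
  d <- data.frame(frame = s$frame, channel_nm = s$wavelength_nm,
                  exp_start_ms = s$exp_start_ms, exp_end_ms = s$exp_end_ms,
                  led_start_ms = s$led_start_ms, led_end_ms = s$led_end_ms,
                  captured = s$captured)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
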