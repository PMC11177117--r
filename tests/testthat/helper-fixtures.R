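# Shared fixtures, built in code.

# Toy extinction matrix with simple integer entries; its 2x2 system
# [[1,2],[3,4]] is invertible by hand.
toy_eps <- function() extinction_table(c(525, 625), c(1, 3), c(2, 4))

unit_paths <- function() pathlength_set(1, 1, 1, 1)

# Small noiseless scene used across modules (8x8, 40 cycles).
small_scene <- function(seed = 7, ...) {
  args <- utils::modifyList(list(height = 8, width = 8, n_cycles = 40),
                            list(...))
  generate_scene(do.call(scene_params, args), seed = seed)
}

# Baselines taken over the scene's guaranteed-quiescent cycles.
scene_baseline <- function(scene, channel) {
  ch <- demultiplex(scene$acq)[[channel]]
  compute_baseline(ch, scene$truth$baseline_cycles)
}

# Independently coded per-pixel OLS detrend used as an oracle for
# detrend_linear(): literal lm() per pixel.
lm_detrend <- function(a) {
  d <- dim(a)
  tt <- seq_len(d[3])
  out <- a
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- stats::residuals(stats::lm(a[i, j, ] ~ tt))
  out
}

# Brute-force schedule checker used as the oracle for validate_schedule():
# pairwise interval intersection over every LED window pair plus direct
# containment tests, written without reusing the package's logic.
oracle_schedule_ok <- function(s) {
  readout <- attr(s, "readout_ms")
  for (i in seq_len(nrow(s))) {
    r <- s[i, ]
    if (r$captured) {
      if (is.na(r$exp_start_ms)) return(FALSE)
      if (!((r$exp_end_ms - r$exp_start_ms) - (r$fire_end_ms - r$fire_start_ms)
            - readout < 1e-9 &&
            (r$exp_end_ms - r$exp_start_ms) - (r$fire_end_ms - r$fire_start_ms)
            - readout > -1e-9)) return(FALSE)
      if (r$fire_end_ms <= r$fire_start_ms) return(FALSE)
      if (r$fire_start_ms < r$exp_start_ms - 1e-9 ||
          r$fire_end_ms > r$exp_end_ms + 1e-9) return(FALSE)
      if (!is.na(r$led_start_ms) &&
          (r$led_start_ms < r$fire_start_ms - 1e-9 ||
           r$led_end_ms > r$fire_end_ms + 1e-9)) return(FALSE)
    }
    if (!is.na(r$led_start_ms) && r$led_end_ms <= r$led_start_ms) return(FALSE)
  }
  led <- s[!is.na(s$led_start_ms), , drop = FALSE]
  if (nrow(led) > 1L) {
    for (i in seq_len(nrow(led) - 1L))
      for (j in seq(i + 1L, nrow(led)))
        if (max(led$led_start_ms[i], led$led_start_ms[j]) <
            min(led$led_end_ms[i], led$led_end_ms[j]) - 1e-9) return(FALSE)
  }
  TRUE
}

# Randomly corrupt a valid schedule in one of several ways.
corrupt_schedule <- function(s) {
  i <- sample(nrow(s), 1L)
  mode <- if (nrow(s) < 2L) sample(2L, 1L) else sample(3L, 1L)
  if (mode == 1L) {        # LED spills past FIRE-ALL
    s$led_end_ms[i] <- s$fire_end_ms[i] + 0.5
  } else if (mode == 2L) { # LED starts before FIRE-ALL
    s$led_start_ms[i] <- s$fire_start_ms[i] - 0.5
  } else {                 # two LED windows overlap
    j <- if (i < nrow(s)) i + 1L else i - 1L
    span <- s$led_end_ms[i] - s$led_start_ms[i]
    s$led_start_ms[j] <- s$led_start_ms[i] + span / 2
    s$led_end_ms[j] <- s$led_start_ms[j] + span
  }
  s
}
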