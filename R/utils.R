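# Internal helpers shared across modules.

# Single source of truth for the attenuation log base.  Base 10 keeps
# Prahl-style molar extinction coefficients (OD convention) directly
# applicable; the forward model in generate_scene() uses the same constant.
.resolve_log_base <- function(log_base) {
  if (identical(log_base, "e")) exp(1) else as.numeric(log_base)
}

.log_b <- function(x, base = 10) log(x, base = .resolve_log_base(base))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0)
    .stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Flatten a H x W x T array to a (H*W) x T matrix of pixel time courses.
.as_pixel_matrix <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L], d[3L])
  a
}

.from_pixel_matrix <- function(m, h, w) {
  dim(m) <- c(h, w, ncol(m))
  m
}
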