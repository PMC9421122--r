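# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and one or more
# integer-ish keys. Stays below 2^31 so it is always a valid R RNG seed.
derive_seed <- function(master, ...) {
  keys <- c(...)
  x <- as.numeric(master) %% 2147483647
  for (k in keys) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    x <- (x * 48271 + kk * 16807 + 12345) %% 2147483647
  }
  as.integer(x %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# signal::filtfilt loses names / attributes; thin wrappers keep call sites tidy.
butter_filter <- function(x, order, w, type) {
  flt <- signal::butter(order, w, type = type)
  signal::filtfilt(flt, x)
}

rms_internal <- function(x) sqrt(mean(x^2))

stopifnot_scalar_label <- function(label) {
  if (!(length(label) == 1 && label %in% c(0, 1))) {
    abort("`label` must be 0 (normal) or 1 (abnormal).", class = "pcgaug_config_error")
  }
}

config_error <- function(msg) abort(msg, class = "pcgaug_config_error")
degenerate_error <- function(msg) abort(msg, class = "pcgaug_degenerate_error")
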