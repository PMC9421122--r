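#' Spectral band diagnostics for recordings
#'
#' `band_power_fraction()` integrates the periodogram and returns the
#' fraction of total spectral power falling inside `band`. It is used to
#' check that generated heart sounds keep their energy in the physiological
#' 20–500 Hz range, and (over the murmur band) as the simple band-energy
#' statistic that separates normal from abnormal recordings.
#'
#' @param rec a `pcg_recording`, or a numeric vector of samples (then
#'   `sample_rate` is required).
#' @param band length-2 Hz interval.
#' @param sample_rate Hz; ignored when `rec` is a `pcg_recording`.
#' @return a single number in \eqn{[0, 1]}.
#' @export
band_power_fraction <- function(rec, band, sample_rate = NULL) {
  if (inherits(rec, "pcg_recording")) {
    x <- rec$samples
    sr <- rec$sample_rate
  } else {
    x <- rec
    sr <- sample_rate
    if (is.null(sr)) config_error("`sample_rate` required for raw samples.")
  }
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) / n * sr
  half <- freqs <= sr / 2
  p <- p[half]
  freqs <- freqs[half]
  sum(p[freqs >= band[1] & freqs <= band[2]]) / sum(p)
}

#' @rdname band_power_fraction
#' @details `band_power()` returns the absolute per-sample spectral power in
#'   `band` (Parseval-scaled periodogram integral). On peak-normalised
#'   recordings it is the band-energy statistic used to separate murmur
#'   recordings from normals.
#' @export
band_power <- function(rec, band, sample_rate = NULL) {
  if (inherits(rec, "pcg_recording")) {
    x <- rec$samples
    sr <- rec$sample_rate
  } else {
    x <- rec
    sr <- sample_rate
    if (is.null(sr)) config_error("`sample_rate` required for raw samples.")
  }
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) / n * sr
  sum(p[freqs >= band[1] & freqs <= band[2] & freqs <= sr / 2])
}

#' Estimate heart rate from the signal envelope
#'
#' Smooths the rectified signal into an amplitude envelope and locates the
#' dominant cardiac periodicity as the highest autocorrelation peak in the
#' lag range corresponding to `bpm_range`.
#'
#' @param rec a `pcg_recording`.
#' @param bpm_range beats/min search interval.
#' @return estimated heart rate in beats/min.
#' @examples
#' rec <- generate_recording(0, pcg_config(heart_rate_range = c(80, 80),
#'                                         duration_range = c(15, 15)), seed = 2)
#' estimate_heart_rate(rec)
#' @export
estimate_heart_rate <- function(rec, bpm_range = c(50, 110)) {
  x <- rec$samples
  sr <- rec$sample_rate
  win <- max(1L, as.integer(round(0.04 * sr)))
  env <- stats::filter(abs(x), rep(1 / win, win), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env) - mean(env, na.rm = TRUE)
  n <- length(env)
  lag_max <- as.integer(ceiling(60 / bpm_range[1] * sr))
  if (n < 2 * lag_max) {
    degenerate_error("recording too short for heart-rate estimation in this range")
  }
  nf <- stats::nextn(2L * n, 2)
  sp <- fft(c(env, numeric(nf - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(lag_max + 1L)]
  lag_min <- as.integer(floor(60 / bpm_range[2] * sr))
  lags <- lag_min:lag_max
  best <- lags[which.max(ac[lags + 1L])]
  60 / (best / sr)
}
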