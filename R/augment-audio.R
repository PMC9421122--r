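#' Root-mean-square amplitude
#'
#' \eqn{RMS = \sqrt{\sum_i x_i^2 / n}}.
#'
#' @param x numeric sample vector (non-empty).
#' @return a non-negative scalar.
#' @examples
#' compute_rms(c(3, 4))  # sqrt(12.5)
#' @export
compute_rms <- function(x) {
  if (length(x) < 1) abort("empty sample sequence.", class = "pcgaug_domain_error")
  sqrt(sum(x^2) / length(x))
}

#' Inject additive white Gaussian noise at 0 dB SNR
#'
#' Draws i.i.d. noise from \eqn{N(0, \sigma^2)} with \eqn{\sigma} equal to
#' the RMS of the signal (so the nominal signal-to-noise ratio is 0 dB),
#' adds it element-wise, and re-normalises the sum by its peak so samples
#' stay in \eqn{[-1, 1]}. The label is preserved. The realised noise RMS is
#' recorded in the provenance (`noise_rms`, alongside `sigma`), so the
#' empirical SNR \eqn{20 \log_{10}(RMS_{signal} / RMS_{noise})} can be read
#' off the output.
#'
#' @param rec a `pcg_recording` with positive RMS.
#' @param seed integer seed; a fixed seed reproduces the identical noise
#'   realisation (the noise vector is the first and only random draw).
#' @return the noisy recording, provenance marked as
#'   `augmented(method = "noise")`.
#' @export
inject_awgn <- function(rec, seed = 1L) {
  sigma <- compute_rms(rec$samples)
  if (sigma == 0) degenerate_error("zero-RMS input: AWGN level undefined.")
  noise <- with_seed(seed, rnorm(length(rec$samples), 0, sigma))
  rec$samples <- rec$samples + noise
  rec <- normalize_amplitude(rec)
  rec$provenance <- list(
    type = "augmented", method = "noise", source = rec$record_id,
    params = list(seed = as.integer(seed), sigma = sigma,
                  noise_rms = compute_rms(noise))
  )
  rec
}

# Phase vocoder: stretch the duration of x by `t` while preserving pitch.
# Hann analysis/synthesis windows of `win` samples, synthesis hop win/4,
# standard phase propagation with per-bin instantaneous frequency.
phase_vocoder <- function(x, t, sr, win = 512L) {
  n_in <- length(x)
  hs <- win %/% 4L
  ha <- hs / t
  n_out <- as.integer(round(n_in * t))
  n_frames <- as.integer(ceiling((n_out + win) / hs)) + 1L
  pad <- c(numeric(win), x, numeric(win + as.integer(ceiling((n_frames - 1) * ha))))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  omega <- 2 * pi * (0:(win - 1)) / win

  pos <- 1 + round((seq_len(n_frames) - 1) * ha)
  frames <- matrix(0, win, n_frames)
  for (j in seq_len(n_frames)) {
    frames[, j] <- pad[pos[j] + 0:(win - 1)] * hann
  }
  spec <- stats::mvfft(frames)
  mag <- Mod(spec)
  phase <- Arg(spec)

  syn_phase <- matrix(0, win, n_frames)
  syn_phase[, 1] <- phase[, 1]
  for (j in 2:n_frames) {
    dt <- pos[j] - pos[j - 1]
    dphi <- phase[, j] - phase[, j - 1] - omega * dt
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    inst_freq <- omega + dphi / dt
    syn_phase[, j] <- syn_phase[, j - 1] + hs * inst_freq
  }
  syn <- Re(stats::mvfft(mag * complex(modulus = 1, argument = syn_phase),
                         inverse = TRUE)) / win

  out <- numeric(n_out + 2L * win)
  norm <- numeric(n_out + 2L * win)
  wsq <- hann^2
  for (j in seq_len(n_frames)) {
    at <- (j - 1L) * hs + 1L
    idx <- at:(at + win - 1L)
    ok <- idx <= length(out)
    out[idx[ok]] <- out[idx[ok]] + syn[ok, j] * hann[ok]
    norm[idx[ok]] <- norm[idx[ok]] + wsq[ok]
  }
  out <- out / pmax(norm, 1e-8)
  # analysis started one window into the padding; drop it
  out[(win + 1):(win + n_out)]
}

#' Time stretch or compress a recording
#'
#' Phase-vocoder time scaling: the output lasts `t` times the input while
#' the pitch is unchanged (a 30 s recording becomes 60 s at `t = 2`, 15 s at
#' `t = 0.5`). The label is preserved.
#'
#' @param rec a `pcg_recording`.
#' @param t stretch factor (> 0); sampled values live in \eqn{[0.5, 2]}.
#' @return the stretched recording.
#' @export
time_stretch <- function(rec, t) {
  if (!is.finite(t) || t <= 0) abort("`t` must be positive.", class = "pcgaug_domain_error")
  if (length(rec$samples) < 1) degenerate_error("empty signal.")
  if (t != 1) {
    rec$samples <- phase_vocoder(rec$samples, t, rec$sample_rate)
  }
  rec$provenance <- list(
    type = "augmented", method = "time_stretch", source = rec$record_id,
    params = list(t = t)
  )
  rec
}

#' Pitch shift a recording by whole semitones
#'
#' Scales every frequency by \eqn{2^{p/12}} while preserving the duration:
#' the signal is phase-vocoder stretched by the frequency ratio and then
#' resampled back to the original length. The label is preserved.
#'
#' @param rec a `pcg_recording`.
#' @param p signed semitone count (integer; sampled values have
#'   \eqn{|p| \in \{1, \dots, 10\}}; `p = 0` returns the input unchanged).
#' @return the shifted recording.
#' @export
pitch_shift <- function(rec, p) {
  if (length(rec$samples) < 1) degenerate_error("empty signal.")
  if (p == 0) return(rec)
  r <- 2^(p / 12)
  y <- phase_vocoder(rec$samples, r, rec$sample_rate)
  n <- length(rec$samples)
  pos <- 1 + (seq_len(n) - 1) * (length(y) - 1) / (n - 1)
  rec$samples <- approx(seq_along(y), y, xout = pos, rule = 2)$y
  rec$provenance <- list(
    type = "augmented", method = "pitch_shift", source = rec$record_id,
    params = list(p = p)
  )
  rec
}

#' Sample the pitch/time augmentation parameters
#'
#' `p` is a uniformly drawn integer magnitude 1-10 with an up/down sign of
#' equal probability; `t` is uniform on \eqn{[0.5, 2]}.
#'
#' @param seed integer seed.
#' @return a list with `p` (signed semitones) and `t` (stretch factor).
#' @export
sample_pitch_time_params <- function(seed = 1L) {
  with_seed(seed, {
    p <- sample(1:10, 1) * sample(c(-1L, 1L), 1)
    t <- runif(1, 0.5, 2.0)
    list(p = p, t = t)
  })
}

#' Method-1 audio augmentation: pitch shift then time stretch
#'
#' Applies [pitch_shift()] followed by [time_stretch()] with parameters from
#' [sample_pitch_time_params()].
#'
#' @param rec a `pcg_recording`.
#' @param seed integer seed.
#' @return the augmented recording with the sampled parameters recorded in
#'   its provenance.
#' @export
pitch_time_augment <- function(rec, seed = 1L) {
  pars <- sample_pitch_time_params(seed)
  src <- rec$record_id
  out <- time_stretch(pitch_shift(rec, pars$p), pars$t)
  out$provenance <- list(
    type = "augmented", method = "pitch_time", source = src,
    params = c(pars, list(seed = as.integer(seed)))
  )
  out
}
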