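#' Spectrogram and Mel-scale parameters
#'
#' Parameters of the short-time Fourier analysis and Mel-scale image
#' rendering: a Hann window of 512 samples with hop 256 and a 512-point FFT,
#' a triangular Mel filterbank whose scale is
#' \eqn{Mel = 2595 \log_{10}(1 + f / b)} with break frequency `b` printed as
#' 500 Hz here (the textbook value 700 is available via `mel_break_hz`), dB
#' conversion referenced to the maximum amplitude (0 dB), and rendering to a
#' fixed 100 x 180 three-channel image by bicubic interpolation.
#'
#' @param window_length Hann window length in samples.
#' @param hop hop length in samples (must not exceed `window_length`).
#' @param n_fft FFT length (must be >= `window_length`).
#' @param n_mels number of Mel channels.
#' @param mel_break_hz break frequency of the Mel map (500 as printed;
#'   set 700 for the conventional variant).
#' @param db_floor lower clamp of the dB scale (default -80 dB); bounds the
#'   colour mapping.
#' @param image_height,image_width rendered image size in pixels
#'   (frequency x time; default 100 x 180).
#' @param colormap a palette name accepted by [grDevices::hcl.colors()];
#'   the default "Inferno" is a perceptually uniform dark-to-yellow map, so
#'   the signal maximum renders yellow.
#' @return a list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_length = 512, hop = 256, n_fft = 512,
                               n_mels = 128, mel_break_hz = 500,
                               db_floor = -80,
                               image_height = 100, image_width = 180,
                               colormap = "Inferno") {
  if (hop > window_length) config_error("`hop` must not exceed `window_length`.")
  if (n_fft < window_length) config_error("`n_fft` must be >= `window_length`.")
  if (mel_break_hz <= 0) config_error("`mel_break_hz` must be positive.")
  if (db_floor >= 0) config_error("`db_floor` must be negative.")
  if (!colormap %in% grDevices::hcl.pals()) {
    config_error(paste0("unknown colormap: ", colormap))
  }
  structure(
    list(
      window_length = as.integer(window_length), hop = as.integer(hop),
      n_fft = as.integer(n_fft), n_mels = as.integer(n_mels),
      mel_break_hz = mel_break_hz, db_floor = db_floor,
      image_height = as.integer(image_height),
      image_width = as.integer(image_width), colormap = colormap
    ),
    class = "spectrogram_params"
  )
}

#' Hz to Mel conversion
#'
#' \eqn{Mel = 2595 \log_{10}(1 + f / b)} with the configured break
#' frequency `b`.
#'
#' @param f frequency in Hz (non-negative).
#' @param p a [spectrogram_params()] (only `mel_break_hz` is used).
#' @return Mel value(s).
#' @examples
#' hz_to_mel(500, spectrogram_params())  # 2595 * log10(2)
#' @export
hz_to_mel <- function(f, p = spectrogram_params()) {
  if (any(f < 0)) abort("frequencies must be non-negative.", class = "pcgaug_domain_error")
  2595 * log10(1 + f / p$mel_break_hz)
}

#' @rdname hz_to_mel
#' @param mel Mel value(s).
#' @export
mel_to_hz <- function(mel, p = spectrogram_params()) {
  p$mel_break_hz * (10^(mel / 2595) - 1)
}

#' Linear-scale power spectrogram
#'
#' Frames the signal with a Hann window (no padding: frame count is
#' `floor((n - window) / hop) + 1`), applies the FFT, and returns the
#' squared-magnitude spectrum of each frame.
#'
#' @param rec a `pcg_recording`.
#' @param p a [spectrogram_params()].
#' @return a numeric matrix, `n_fft/2 + 1` frequency bins x frames, with
#'   attributes `freqs` (Hz per bin) and `times` (frame centres, s).
#' @export
power_spectrogram <- function(rec, p = spectrogram_params()) {
  x <- rec$samples
  n <- length(x)
  win <- p$window_length
  if (n < win) degenerate_error("signal shorter than one analysis window.")
  n_frames <- (n - win) %/% p$hop + 1L
  starts <- (seq_len(n_frames) - 1L) * p$hop
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  frames <- matrix(0, p$n_fft, n_frames)
  for (j in seq_len(n_frames)) {
    frames[seq_len(win), j] <- x[starts[j] + seq_len(win)] * hann
  }
  sp <- stats::mvfft(frames)
  n_bins <- p$n_fft %/% 2L + 1L
  pw <- Mod(sp[seq_len(n_bins), , drop = FALSE])^2
  attr(pw, "freqs") <- (seq_len(n_bins) - 1) / p$n_fft * rec$sample_rate
  attr(pw, "times") <- (starts + win / 2) / rec$sample_rate
  pw
}

# Triangular Mel filterbank on the configured Mel scale: n_mels rows by
# n_fft/2+1 frequency-bin columns.
mel_filterbank <- function(p, sample_rate) {
  n_bins <- p$n_fft %/% 2L + 1L
  bin_freqs <- (seq_len(n_bins) - 1) / p$n_fft * sample_rate
  edges_mel <- seq(0, hz_to_mel(sample_rate / 2, p), length.out = p$n_mels + 2L)
  edges_hz <- mel_to_hz(edges_mel, p)
  fb <- matrix(0, p$n_mels, n_bins)
  for (m in seq_len(p$n_mels)) {
    lo <- edges_hz[m]; ce <- edges_hz[m + 1]; hi <- edges_hz[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-spectrogram in decibels
#'
#' Applies the triangular Mel filterbank to a linear power spectrogram and
#' converts amplitudes to dB with the maximum as the 0 dB reference:
#' \eqn{20 \log_{10}(A / A_{max})} with \eqn{A = \sqrt{P}} (identically
#' \eqn{10 \log_{10}(P / P_{max})}), clamped below at `db_floor`.
#'
#' @param spec a linear power spectrogram from [power_spectrogram()].
#' @param p a [spectrogram_params()].
#' @param sample_rate Hz (needed to place the filterbank; taken from the
#'   `freqs` attribute when present).
#' @return an object of class `mel_spectrogram`: a `n_mels` x frames matrix
#'   of dB values (max exactly 0), with attributes `mel_centers`,
#'   `frame_times` and `db_floor`. Row 1 is the lowest Mel channel.
#' @export
to_mel_db <- function(spec, p = spectrogram_params(), sample_rate = NULL) {
  if (is.null(sample_rate)) {
    fr <- attr(spec, "freqs")
    if (is.null(fr)) config_error("`sample_rate` required when `spec` has no freqs attribute.")
    sample_rate <- fr[length(fr)] * 2
  }
  if (max(spec) <= 0) degenerate_error("spectrogram has no positive entry.")
  fb <- mel_filterbank(p, sample_rate)
  melp <- fb %*% spec
  amax <- max(melp)
  db <- 10 * log10(pmax(melp / amax, 10^(p$db_floor / 10)))
  edges_mel <- seq(0, hz_to_mel(sample_rate / 2, p), length.out = p$n_mels + 2L)
  structure(
    db,
    mel_centers = edges_mel[2:(p$n_mels + 1L)],
    frame_times = attr(spec, "times"),
    db_floor = p$db_floor,
    class = c("mel_spectrogram", "matrix", "array")
  )
}

# 256-entry RGB lookup table (3 x 256, values 0-255) for a palette.
colormap_lut <- function(colormap) {
  if (!colormap %in% grDevices::hcl.pals()) {
    config_error(paste0("unknown colormap: ", colormap))
  }
  grDevices::col2rgb(grDevices::hcl.colors(256, colormap, rev = TRUE))
}

#' Render a Mel-spectrogram as a fixed-size colour image
#'
#' Maps dB values through a monotone colormap (dB floor = darkest, 0 dB =
#' brightest) and bicubic-resizes the result to the configured image size.
#' Row 1 of the image is the highest frequency (low frequencies at the
#' bottom, as spectrograms are displayed).
#'
#' @param mel a `mel_spectrogram`.
#' @param p a [spectrogram_params()] (image size, dB floor, colormap).
#' @param colormap optional palette name overriding `p$colormap`.
#' @return an object of class `spectrogram_image`: an integer array
#'   `image_height x image_width x 3` with intensities in 0-255 and
#'   attribute `colormap`.
#' @export
render_image <- function(mel, p = spectrogram_params(), colormap = NULL) {
  if (length(mel) == 0) degenerate_error("empty Mel-spectrogram.")
  colormap <- colormap %||% p$colormap
  lut <- colormap_lut(colormap)
  floor_db <- attr(mel, "db_floor") %||% p$db_floor
  m <- unclass(mel)
  s <- (m - floor_db) / (0 - floor_db)
  s <- pmin(pmax(s, 0), 1)
  idx <- matrix(as.integer(round(s * 255)) + 1L, nrow(m), ncol(m))
  out <- array(0L, c(p$image_height, p$image_width, 3L))
  for (ch in 1:3) {
    chan <- matrix(lut[ch, idx], nrow(idx), ncol(idx))
    chan <- chan[rev(seq_len(nrow(chan))), , drop = FALSE]  # high freq on top
    rs <- resize_bicubic(chan, p$image_height, p$image_width)
    out[, , ch] <- as.integer(round(pmin(255, pmax(0, rs))))
  }
  structure(out, colormap = colormap, class = "spectrogram_image")
}

#' Full audio-to-image rendering
#'
#' Convenience composition: [power_spectrogram()] then [to_mel_db()] then
#' [render_image()]. Deterministic: identical audio gives identical pixels.
#'
#' @param rec a `pcg_recording`.
#' @param p a [spectrogram_params()].
#' @return a `spectrogram_image`.
#' @export
spectrogram_image <- function(rec, p = spectrogram_params()) {
  render_image(to_mel_db(power_spectrogram(rec, p), p, rec$sample_rate), p)
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d channels x %d frames, max %.1f dB\n",
              nrow(x), ncol(x), max(x)))
  invisible(x)
}

#' @export
print.spectrogram_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectrogram_image> %d x %d x %d, colormap %s\n",
              d[1], d[2], d[3], attr(x, "colormap")))
  invisible(x)
}

#' Write a spectrogram image as PNG
#'
#' @param img a `spectrogram_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG files.")
  }
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
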