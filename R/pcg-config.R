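#' Configuration for the synthetic phonocardiogram generator
#'
#' Defines the physiological envelope the generator works inside: heart rates
#' of 60–100 beats/min and principal heart-sound energy in 20–500 Hz, with S1
#' and S2 valve-closure transients, murmur-band noise for the abnormal class,
#' and low-frequency S3/S4 gallop transients.
#'
#' @param sample_rate sampling rate in Hz. Default 2000 Hz, the convention of
#'   the PhysioNet/CinC 2016 heart-sound corpus.
#' @param heart_rate_range beats/min interval the per-recording heart rate is
#'   drawn from (uniform).
#' @param duration_range seconds interval the recording length is drawn from
#'   (uniform).
#' @param s1_band,s2_band Hz intervals for the S1 / S2 burst centre frequency.
#' @param murmur_band Hz interval of murmur noise (systolic or diastolic).
#' @param murmur_snr murmur energy relative to the combined S1/S2 component,
#'   in dB (RMS ratio). Murmurs are audibly quieter than the valve sounds.
#' @param abnormal_component_mix named probabilities over the single abnormal
#'   component a pathological recording receives:
#'   `c(systolic, diastolic, s3, s4)`. Must sum to 1. The default is
#'   murmur-dominated: murmurs are the chief discriminator of the abnormal
#'   class and gallop-only recordings are comparatively rare.
#' @param class_ratio normal:abnormal ratio used when only a total dataset
#'   size is given (default ~3.9:1, mirroring a 2189:560 class split).
#' @param noise_floor level of the white background noise relative to the
#'   S1/S2 component, in dB (RMS ratio).
#' @return a validated list of class `pcg_config`.
#' @examples
#' cfg <- pcg_config(heart_rate_range = c(75, 75))
#' cfg$sample_rate
#' @export
pcg_config <- function(sample_rate = 2000,
                       heart_rate_range = c(60, 100),
                       duration_range = c(6, 60),
                       s1_band = c(30, 100),
                       s2_band = c(50, 150),
                       murmur_band = c(150, 400),
                       murmur_snr = -6,
                       abnormal_component_mix = c(
                         systolic = 0.65, diastolic = 0.33,
                         s3 = 0.01, s4 = 0.01
                       ),
                       class_ratio = 2189 / 560,
                       noise_floor = -50) {
  check_interval <- function(x, name, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || !is.numeric(x) || x[1] > x[2]) {
      config_error(paste0("`", name, "` must be a non-decreasing length-2 numeric interval."))
    }
    if (x[1] < lo || x[2] > hi) {
      config_error(paste0("`", name, "` must lie within [", lo, ", ", hi, "]."))
    }
  }
  check_interval(heart_rate_range, "heart_rate_range")
  check_interval(duration_range, "duration_range")
  if (duration_range[1] <= 0) config_error("`duration_range` must be positive.")
  check_interval(s1_band, "s1_band", 20, 500)
  check_interval(s2_band, "s2_band", 20, 500)
  check_interval(murmur_band, "murmur_band", 20, 500)
  mix <- abnormal_component_mix
  if (length(mix) != 4 || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    config_error("`abnormal_component_mix` must be 4 non-negative probabilities summing to 1.")
  }
  names(mix) <- c("systolic", "diastolic", "s3", "s4")
  if (sample_rate <= 2 * 500) {
    config_error("`sample_rate` must exceed twice the 500 Hz upper band edge.")
  }
  structure(
    list(
      sample_rate = sample_rate,
      heart_rate_range = heart_rate_range,
      duration_range = duration_range,
      s1_band = s1_band,
      s2_band = s2_band,
      murmur_band = murmur_band,
      murmur_snr = murmur_snr,
      abnormal_component_mix = mix,
      class_ratio = class_ratio,
      noise_floor = noise_floor
    ),
    class = "pcg_config"
  )
}

#' @export
print.pcg_config <- function(x, ...) {
  cat("<pcg_config>\n")
  cat("  sample rate:", x$sample_rate, "Hz\n")
  cat("  heart rate :", x$heart_rate_range[1], "-", x$heart_rate_range[2], "bpm\n")
  cat("  duration   :", x$duration_range[1], "-", x$duration_range[2], "s\n")
  cat("  murmur band:", x$murmur_band[1], "-", x$murmur_band[2], "Hz at",
      x$murmur_snr, "dB\n")
  invisible(x)
}
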