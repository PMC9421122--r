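test_that("frame count follows the no-padding convention", {
  rec <- tone_recording(100, 2)
  rec$samples <- rec$samples[1:2048]
  expect_equal(ncol(power_spectrogram(rec)), 7)  # floor((2048-512)/256)+1
  rec$samples <- rec$samples[1:511]
  expect_error(power_spectrogram(rec), class = "pcgaug_degenerate_error")
})

test_that("a bin-centred tone peaks at its bin in every frame", {
  sr <- 2000
  k <- 64                     # bin-centre frequency k * sr / 512 = 250 Hz
  rec <- tone_recording(k * sr / 512, 4, sr)
  pw <- power_spectrogram(rec)
  for (j in seq_len(ncol(pw))) {
    expect_equal(which.max(pw[, j]) - 1L, k)
  }
  zero <- tone_recording(100, 2)
  zero$samples <- zero$samples * 0
  expect_true(all(power_spectrogram(zero) == 0))
})

test_that("the Mel map matches its formula and is monotone", {
  p <- spectrogram_params()
  expect_equal(hz_to_mel(0, p), 0)
  expect_equal(hz_to_mel(500, p), 2595 * log10(2), tolerance = 1e-12)
  expect_equal(hz_to_mel(500, p), 781.13, tolerance = 1e-4)
  grid <- seq(0, 1000, by = 10)
  expect_true(all(diff(hz_to_mel(grid, p)) > 0))
  expect_equal(mel_to_hz(hz_to_mel(123.4, p), p), 123.4, tolerance = 1e-9)
  expect_error(hz_to_mel(-1, p), class = "pcgaug_domain_error")
  # configurable break frequency (conventional 700 Hz variant)
  p700 <- spectrogram_params(mel_break_hz = 700)
  expect_equal(hz_to_mel(500, p700), 2595 * log10(1 + 500 / 700), tolerance = 1e-12)
})

test_that("dB conversion is referenced to the maximum and clamped", {
  p <- spectrogram_params()
  rec <- tone_recording(250, 4)
  pw <- power_spectrogram(rec, p)
  mel <- to_mel_db(pw, p, rec$sample_rate)
  expect_equal(max(mel), 0)
  expect_gte(min(mel), p$db_floor)
  expect_equal(nrow(mel), p$n_mels)
  # a column scaled to 1/100 of the maximum power sits exactly -20 dB below
  pw2 <- cbind(pw[, 1], pw[, 1] / 100)
  attr(pw2, "freqs") <- attr(pw, "freqs")
  mel2 <- to_mel_db(pw2, p, rec$sample_rate)
  ch <- which.max(mel2[, 1])
  expect_equal(mel2[ch, 1], 0)
  expect_equal(mel2[ch, 2], -20)
  expect_error(to_mel_db(pw * 0, p, rec$sample_rate),
               class = "pcgaug_degenerate_error")
})

test_that("the Mel filterbank covers the band with positive rows", {
  p <- spectrogram_params()
  fb <- pcgaug:::mel_filterbank(p, 2000)
  expect_equal(dim(fb), c(p$n_mels, p$n_fft / 2 + 1))
  expect_true(all(rowSums(fb) > 0))
  freqs <- (seq_len(ncol(fb)) - 1) / p$n_fft * 2000
  in_band <- freqs >= 20 & freqs <= 500
  expect_true(all(rowSums(fb[, in_band]) + rowSums(fb[, !in_band]) > 0))
})

test_that("rendering produces the fixed image contract", {
  p <- spectrogram_params()
  rec <- generate_recording(0, pcg_config(duration_range = c(9, 9)), 5)
  mel <- to_mel_db(power_spectrogram(rec, p), p, rec$sample_rate)
  img <- render_image(mel, p)
  expect_equal(dim(img), c(100, 180, 3))
  expect_true(min(img) >= 0 && max(img) <= 255)
  expect_true(is.integer(img))
  # determinism: identical audio -> identical pixels
  expect_identical(unclass(img), unclass(render_image(mel, p)))
  # a constant matrix renders to a constant image
  const <- mel
  const[] <- -40
  cimg <- render_image(const, p)
  for (ch in 1:3) expect_equal(length(unique(as.vector(cimg[, , ch]))), 1)
  # monotone scalar mapping: higher dB -> higher colormap position
  s <- function(db) round((db - p$db_floor) / (0 - p$db_floor) * 255)
  expect_gt(s(-10), s(-60))
  expect_error(render_image(mel, p, colormap = "NoSuchMap"),
               class = "pcgaug_config_error")
})

test_that("bicubic resize has interpolation fixed points", {
  m <- matrix(rnorm(30 * 40), 30, 40)
  expect_equal(resize_bicubic(m, 30, 40), m, tolerance = 1e-12)  # identity
  const <- matrix(3.7, 10, 11)
  out <- resize_bicubic(const, 100, 180)
  expect_equal(dim(out), c(100, 180))
  expect_equal(range(out), c(3.7, 3.7), tolerance = 1e-12)
})
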