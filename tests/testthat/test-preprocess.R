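test_that("WAV round trip preserves samples to quantisation accuracy", {
  x <- sin(2 * pi * 50 * seq(0, 2, by = 1 / 2000)) * 0.7
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 2000, f)
  w <- read_wav(f)
  expect_equal(w$sample_rate, 2000)
  expect_equal(length(w$samples), length(x))
  expect_lt(max(abs(w$samples - x)), 1 / 32767)
  expect_error(write_wav(numeric(0), 2000, f), class = "pcgaug_degenerate_error")
})

test_that("band-pass gains match the Butterworth design", {
  cfg <- preprocess_config()
  mid <- tone_recording(250, 10)   # mid-passband: gain ~ 1
  out <- bandpass_filter(mid, cfg)
  expect_lt(abs(20 * log10(compute_rms(out$samples) / compute_rms(mid$samples))), 1)
  low <- tone_recording(5, 10)     # far below the 20 Hz edge
  outl <- bandpass_filter(low, cfg)
  expect_lt(20 * log10(compute_rms(outl$samples) / compute_rms(low$samples)), -10)
  zero <- tone_recording(50, 5)
  zero$samples <- zero$samples * 0
  expect_equal(bandpass_filter(zero, cfg)$samples, zero$samples)
  expect_equal(length(out$samples), length(mid$samples))
  bad <- tone_recording(100, 5)
  expect_error(bandpass_filter(bad, preprocess_config(passband = c(20, 1000))),
               class = "pcgaug_config_error")
})

test_that("length policy discards, truncates and keeps at the boundaries", {
  cfg <- preprocess_config()
  expect_null(apply_length_policy(tone_recording(100, 7.9), cfg))
  tr <- apply_length_policy(tone_recording(100, 45), cfg)
  expect_equal(length(tr$samples) / tr$sample_rate, 30)
  keep <- tone_recording(100, 8)
  keep$samples <- keep$samples[1:(8 * 2000)]  # exactly 8.0 s
  expect_identical(apply_length_policy(keep, cfg)$samples, keep$samples)
  exact30 <- tone_recording(100, 40)
  exact30$samples <- exact30$samples[1:(30 * 2000)]
  expect_identical(apply_length_policy(exact30, cfg)$samples, exact30$samples)
})

test_that("amplitude normalisation follows the peak rule", {
  rec <- tone_recording(100, 1)
  rec$samples <- c(2, -4, 1)
  expect_equal(normalize_amplitude(rec)$samples, c(0.5, -1, 0.25))
  norm <- normalize_amplitude(tone_recording(123, 3))
  expect_equal(max(abs(norm$samples)), 1)
  expect_equal(normalize_amplitude(norm)$samples, norm$samples)  # idempotent
  zero <- rec
  zero$samples <- c(0, 0, 0)
  expect_error(normalize_amplitude(zero), class = "pcgaug_degenerate_error")
})

test_that("the pipeline composes filter, length policy and normalisation", {
  src <- withr::local_tempdir()
  out <- withr::local_tempdir()
  durs <- c(5, 9, 40)
  rows <- lapply(seq_along(durs), function(i) {
    p <- file.path(src, sprintf("r%02d.wav", i))
    x <- 0.5 * sin(2 * pi * 80 * seq_len(durs[i] * 2000) / 2000)
    write_wav(x, 2000, p)
    tibble::tibble(record_id = sprintf("r%02d", i), path = p,
                   label = i %% 2L, duration_s = durs[i], provenance = "synthetic")
  })
  manifest <- dplyr::bind_rows(rows)
  res <- suppressMessages(preprocess_pipeline(manifest, preprocess_config(), out))
  expect_equal(nrow(res), 2)
  expect_setequal(round(res$duration_s, 3), c(9, 30))
  expect_identical(attr(res, "discarded"), "r01")
  # survivors are peak-normalised
  for (p in res$path) expect_equal(max(abs(read_wav(p)$samples)), 1, tolerance = 1e-4)
  # empty manifest passes through
  empty <- suppressMessages(preprocess_pipeline(manifest[0, ], preprocess_config(), out))
  expect_equal(nrow(empty), 0)
})

test_that("pipeline survivor count equals a brute-force duration scan", {
  src <- withr::local_tempdir()
  out <- withr::local_tempdir()
  cfg <- pcg_config(duration_range = c(6, 12))
  manifest <- generate_dataset(14, 4, cfg, seed = 3, out_dir = src)
  res <- suppressMessages(preprocess_pipeline(manifest, preprocess_config(), out))
  expect_equal(nrow(res), sum(manifest$duration_s >= 8))
  counts <- attr(res, "class_counts")
  expect_equal(unname(counts["0"]), sum(res$label == 0))
  expect_equal(unname(counts["1"]), sum(res$label == 1))
})
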