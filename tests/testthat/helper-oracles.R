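# Shared fixtures and independent oracles, built in code at test time.

# A pure-tone recording at frequency f Hz.
tone_recording <- function(f, dur, sr = 2000, amp = 0.8) {
  structure(
    list(
      samples = amp * sin(2 * pi * f * seq(0, dur, by = 1 / sr)),
      sample_rate = sr, label = 0L, record_id = paste0("tone", f),
      provenance = list(type = "synthetic")
    ),
    class = "pcg_recording"
  )
}

# Periodogram peak frequency (n-point FFT oracle).
peak_freq <- function(x, sr, n = length(x)) {
  x <- x[seq_len(min(n, length(x)))]
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) / length(x) * sr
  half <- freqs <= sr / 2
  freqs[half][which.max(p[half])]
}

# Pairwise concordance statistic: (concordant + 0.5 * ties) / (n_pos * n_neg).
# Brute-force oracle for the ROC AUC.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Exhaustive-threshold oracle for specificity at a sensitivity target.
spec_at_sens_oracle <- function(scores, labels, target = 0.9) {
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    if (sens >= target) { best <- spec; break }
  }
  best
}

# Cyclic Jacobi eigensolver for a symmetric 3x3 matrix; independent of
# base::eigen. Returns values (descending) and sign-fixed vectors.
jacobi_eigen3 <- function(a, iters = 50) {
  v <- diag(3)
  for (it in seq_len(iters)) {
    for (p in 1:2) for (q in (p + 1):3) {
      if (abs(a[p, q]) < 1e-14) next
      theta <- 0.5 * atan2(2 * a[p, q], a[q, q] - a[p, p])
      c <- cos(theta); s <- sin(theta)
      g <- diag(3); g[p, p] <- c; g[q, q] <- c; g[p, q] <- s; g[q, p] <- -s
      a <- t(g) %*% a %*% g
      v <- v %*% g
    }
  }
  ord <- order(diag(a), decreasing = TRUE)
  vals <- diag(a)[ord]
  vecs <- v[, ord, drop = FALSE]
  for (j in 1:3) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs)
}

# Envelope peak-picking oracle: count S1-like onsets as local maxima of the
# smoothed envelope above half its 95th percentile, separated by >= 0.35 s.
count_envelope_peaks <- function(x, sr) {
  win <- round(0.05 * sr)
  env <- as.numeric(stats::filter(abs(x), rep(1 / win, win), sides = 2))
  env[is.na(env)] <- 0
  thr <- 0.5 * stats::quantile(env, 0.95)
  min_gap <- round(0.35 * sr)
  peaks <- 0L
  last <- -min_gap
  for (i in 2:(length(env) - 1)) {
    if (env[i] >= thr && env[i] >= env[i - 1] && env[i] > env[i + 1] &&
        i - last >= min_gap) {
      peaks <- peaks + 1L
      last <- i
    }
  }
  peaks
}

# Pixel data of an image, attributes stripped.
img_data <- function(x) array(as.integer(x), dim(x))

# A small deterministic pseudo-random test image.
random_image <- function(seed = 1, h = 20, w = 30) {
  withr::with_seed(seed, {
    structure(
      array(as.integer(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3)),
      class = "spectrogram_image"
    )
  })
}

# A small in-memory records table for augmentation tests.
make_records <- function(n_normal = 4, n_abnormal = 2, seed = 5,
                         dur = c(8, 10), sp = spectrogram_params()) {
  cfg <- pcg_config(duration_range = dur)
  labels <- c(rep(0L, n_normal), rep(1L, n_abnormal))
  rows <- lapply(seq_along(labels), function(i) {
    rec <- generate_recording(labels[i], cfg, seed + i)
    rec <- normalize_amplitude(rec)
    mel <- to_mel_db(power_spectrogram(rec), spectrogram_params(), rec$sample_rate)
    img <- render_image(mel, sp)
    tibble::tibble(record_id = rec$record_id, label = labels[i],
                   rec = list(rec), mel = list(mel), img = list(img))
  })
  dplyr::bind_rows(rows)
}
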