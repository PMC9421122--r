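#' Preprocessing configuration
#'
#' Signal conditioning applied to every recording before spectral analysis:
#' a third-order Butterworth band-pass over the physiological 20–500 Hz
#' range, a length policy (recordings shorter than `min_duration` seconds are
#' discarded, longer than `max_duration` are truncated), and peak amplitude
#' normalisation \eqn{x / \max|x|}.
#'
#' @param filter_order Butterworth design order (default 3).
#' @param passband Hz interval (default 20–500).
#' @param min_duration,max_duration length policy bounds in seconds
#'   (defaults 8 and 30). Boundary convention: a recording of exactly
#'   `min_duration` is kept, exactly `max_duration` is kept untruncated.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 3, passband = c(20, 500),
                              min_duration = 8, max_duration = 30) {
  if (length(passband) != 2 || passband[1] <= 0 || passband[1] >= passband[2]) {
    config_error("`passband` must satisfy 0 < low < high.")
  }
  if (min_duration > max_duration) {
    config_error("`min_duration` must not exceed `max_duration`.")
  }
  structure(
    list(
      filter_order = filter_order, passband = passband,
      min_duration = min_duration, max_duration = max_duration
    ),
    class = "preprocess_config"
  )
}

#' Band-pass filter a recording
#'
#' Applies the configured Butterworth band-pass as a zero-phase
#' (forward-backward) filter, so S1/S2 onsets are not shifted by group
#' delay. The effective magnitude response is the squared design response.
#'
#' @param rec a `pcg_recording`.
#' @param cfg a [preprocess_config()].
#' @return the filtered recording (same length).
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  nyq <- rec$sample_rate / 2
  if (cfg$passband[2] >= nyq) {
    config_error("passband upper edge must be below the Nyquist frequency.")
  }
  rec$samples <- butter_filter(rec$samples, cfg$filter_order,
                               cfg$passband / nyq, "pass")
  rec
}

#' Apply the length policy
#'
#' @inheritParams bandpass_filter
#' @return the recording, truncated to `max_duration` if longer, or `NULL`
#'   (the discard sentinel) if shorter than `min_duration`.
#' @export
apply_length_policy <- function(rec, cfg = preprocess_config()) {
  dur <- length(rec$samples) / rec$sample_rate
  if (dur < cfg$min_duration) return(NULL)
  if (dur > cfg$max_duration) {
    rec$samples <- rec$samples[seq_len(as.integer(cfg$max_duration * rec$sample_rate))]
  }
  rec
}

#' Normalise peak amplitude
#'
#' Divides every sample by the maximum absolute amplitude, so the output
#' peak is exactly 1. Undefined (errors) for an all-zero signal.
#'
#' @param rec a `pcg_recording`.
#' @return the normalised recording.
#' @export
normalize_amplitude <- function(rec) {
  m <- max(abs(rec$samples))
  if (!is.finite(m) || m == 0) {
    degenerate_error("cannot normalise an all-zero signal (max |x| = 0).")
  }
  rec$samples <- rec$samples / m
  rec
}

#' Preprocess every recording in a manifest
#'
#' Runs filter, then length policy, then normalisation, over each record of
#' a dataset manifest, writing surviving recordings as WAV files. Discarded
#' records (shorter than `min_duration`) are dropped from the returned
#' manifest.
#'
#' @param manifest a dataset manifest tibble (see [generate_dataset()]).
#' @param cfg a [preprocess_config()].
#' @param out_dir directory for the processed WAV files.
#' @param on_error `"abort"` (default) or `"skip"`: what to do when a file
#'   cannot be read.
#' @return the surviving manifest tibble (columns as the input, updated
#'   `path`/`duration_s`), with attributes `discarded` (record ids) and
#'   `class_counts`.
#' @export
preprocess_pipeline <- function(manifest, cfg = preprocess_config(), out_dir,
                                on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (nrow(manifest) == 0) {
    attr(manifest, "discarded") <- character()
    attr(manifest, "class_counts") <- c(`0` = 0L, `1` = 0L)
    return(manifest)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  keep <- vector("list", nrow(manifest))
  discarded <- character()
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch(
      read_recording(manifest$path[i], manifest$label[i], manifest$record_id[i]),
      error = function(e) {
        if (on_error == "abort") stop(e)
        warn(paste0("skipping unreadable file: ", manifest$path[i]))
        NULL
      }
    )
    if (is.null(rec)) next
    rec <- preprocess_recording(rec, cfg)
    if (is.null(rec)) {
      discarded <- c(discarded, manifest$record_id[i])
      next
    }
    path <- file.path(out_dir, paste0(manifest$record_id[i], ".wav"))
    write_wav(rec$samples, rec$sample_rate, path)
    row <- manifest[i, ]
    row$path <- path
    row$duration_s <- length(rec$samples) / rec$sample_rate
    keep[[i]] <- row
  }
  out <- bind_rows(keep[!vapply(keep, is.null, logical(1))])
  if (nrow(out) == 0) out <- manifest[0, ]
  counts <- c(`0` = sum(out$label == 0), `1` = sum(out$label == 1))
  message(sprintf(
    "preprocess: %d survived (%d normal / %d abnormal), %d discarded",
    nrow(out), counts[1], counts[2], length(discarded)
  ))
  attr(out, "discarded") <- discarded
  attr(out, "class_counts") <- counts
  out
}

#' Preprocess a single in-memory recording
#'
#' Filter, length policy, normalisation, in that order.
#'
#' @inheritParams bandpass_filter
#' @return the processed recording, or `NULL` if discarded by length.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- bandpass_filter(rec, cfg)
  rec <- apply_length_policy(rec, cfg)
  if (is.null(rec)) return(NULL)
  normalize_amplitude(rec)
}
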