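#' Build a manifest from a directory of labelled WAV recordings
#'
#' Ingestion path for real heart-sound corpora: a directory of mono WAV
#' files plus a label table. The label file must have two columns (record
#' name without extension, label); labels may be coded 0/1 or -1/1 (the
#' PhysioNet/CinC 2016 convention, -1 = normal), with or without a header.
#'
#' @param dir directory containing `.wav` files.
#' @param labels_csv path to the label CSV; defaults to a file named
#'   `REFERENCE.csv`, `reference.csv` or `labels.csv` inside `dir`.
#' @return a manifest tibble (`record_id`, `path`, `label`, `duration_s`,
#'   `provenance = "real"`).
#' @export
read_wav_directory <- function(dir, labels_csv = NULL) {
  if (!dir.exists(dir)) abort(paste0("no such directory: ", dir),
                              class = "pcgaug_io_error")
  if (is.null(labels_csv)) {
    cands <- file.path(dir, c("REFERENCE.csv", "reference.csv", "labels.csv"))
    labels_csv <- cands[file.exists(cands)][1]
    if (is.na(labels_csv)) {
      abort("no label file found (REFERENCE.csv / labels.csv).",
            class = "pcgaug_io_error")
    }
  }
  first <- utils::read.csv(labels_csv, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- suppressWarnings(is.na(as.numeric(first[[2]])))
  lab <- utils::read.csv(labels_csv, header = has_header,
                         stringsAsFactors = FALSE)[, 1:2]
  names(lab) <- c("record_id", "label")
  if (all(lab$label %in% c(-1, 1))) {
    lab$label <- ifelse(lab$label == -1, 0L, 1L)
  }
  if (!all(lab$label %in% c(0, 1))) {
    abort("labels must be coded 0/1 or -1/1.", class = "pcgaug_io_error")
  }
  paths <- file.path(dir, paste0(lab$record_id, ".wav"))
  ok <- file.exists(paths)
  if (!any(ok)) abort("no labelled WAV files found.", class = "pcgaug_io_error")
  durations <- vapply(paths[ok], function(p) {
    w <- read_wav(p)
    length(w$samples) / w$sample_rate
  }, numeric(1))
  tibble(
    record_id = lab$record_id[ok],
    path = paths[ok],
    label = as.integer(lab$label[ok]),
    duration_s = unname(durations),
    provenance = "real"
  )
}
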