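#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE support for the formats this package produces and
#' consumes: uncompressed PCM, 16 bits per sample, one channel. Samples are
#' exchanged as doubles in \eqn{[-1, 1]}.
#'
#' @param path file path.
#' @param samples numeric vector of samples in \eqn{[-1, 1]}; values outside
#'   the range are clipped before quantisation.
#' @param sample_rate sampling rate in Hz.
#' @return `read_wav()` returns a list with elements `samples` and
#'   `sample_rate`; `write_wav()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 100 * seq(0, 1, by = 1 / 2000)), 2000, f)
#' w <- read_wav(f)
#' w$sample_rate
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (!is.numeric(samples) || length(samples) < 1 || any(!is.finite(samples))) {
    degenerate_error("`samples` must be a non-empty finite numeric vector.")
  }
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(paste0("Not a RIFF/WAVE file: ", path), class = "pcgaug_io_error")
  }
  sample_rate <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || bits != 16L) {
        abort("Only mono 16-bit PCM WAV is supported.", class = "pcgaug_io_error")
      }
      skip <- size - 16L
      if (skip > 0) readBin(con, "raw", skip)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little")
      samples <- pcm / 32768
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples)) abort(paste0("No data chunk in ", path), class = "pcgaug_io_error")
  list(samples = samples, sample_rate = sample_rate)
}
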