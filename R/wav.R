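# Minimal mono PCM-16 WAV reader/writer (RIFF little-endian).

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped.
#' @param ts an [time_series()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav <- function(ts, path) {
  stopifnot(inherits(ts, "mmb_ts"))
  x <- pmax(pmin(ts$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(ts$fs))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path
#' @param label channel label for the returned series
#' @return an [time_series()] with samples scaled to `[-1, 1]`
#' @export
read_wav <- function(path, label = "audio") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAV file: ", path)
  fs <- NULL; nchan <- NULL; bits <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1) stop("only PCM WAV is supported")
      nchan <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM WAV is supported")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(pcm)) stop("no data chunk in WAV file")
  if (!is.null(nchan) && nchan != 1) stop("only mono WAV is supported")
  time_series(pcm / 32767, fs = fs, label = label)
}
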