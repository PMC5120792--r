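# Minimal RIFF/WAVE reader and writer (mono, PCM16 or IEEE float32).
# No audio package is declared as a dependency; the format is simple enough
# to handle with readBin/writeBin, and only mono files are supported.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit mono files. Samples are returned
#' as doubles; PCM data is scaled to \[-1, 1) by 1/32768.
#'
#' @param path file path.
#' @param expect_rate if non-`NULL`, error unless the file's sample rate
#'   matches (the synthesizer is rate-sensitive end to end).
#' @return A [waveform].
#' @export
read_wav <- function(path, expect_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported, got ",
                                   fmt$channels, " channels")
      if (fmt$format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", sz / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits)")
      }
      if (!is.null(expect_rate) && fmt$rate != expect_rate)
        stop("sample rate ", fmt$rate, " != expected ", expect_rate)
      return(waveform(x, fmt$rate))
    } else {
      readBin(con, "raw", sz + sz %% 2) # skip unknown chunk (word-aligned)
    }
  }
}

#' Write a mono WAV file
#'
#' @param wave a [waveform].
#' @param path output file path.
#' @param format `"pcm16"` (samples clipped to \[-1, 1)) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  wave <- as_waveform(wave)
  n <- length(wave$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(wave$rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")     # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(wave$samples * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(wave$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
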