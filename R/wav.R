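#' Write a mono waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer (no audio package ships with the supported
#' toolchain). Samples are written as IEEE float32 (`format = "float"`,
#' the default, no clipping) or 16-bit PCM (`format = "pcm16"`, values
#' clipped to \[-1, 1\]).
#'
#' @param samples numeric vector of sample amplitudes.
#' @param path output file path.
#' @param fs sample rate in Hz.
#' @param format `"float"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs, format = c("float", "pcm16")) {
  format <- match.arg(format)
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bits <- if (format == "float") 32L else 16L
  bytes_per <- bits / 8L
  data_bytes <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float") 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads float32 or PCM16 mono WAV files written by [write_wav()] (or any
#' conforming writer). PCM samples are rescaled to \[-1, 1\].
#'
#' @param path file path.
#' @return list with `samples` (numeric) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; fs <- NULL; bits <- NULL; audio_fmt <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_fmt <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (identical(id, "data")) {
      if (is.null(audio_fmt)) stop("data chunk before fmt chunk in ", path)
      if (channels != 1) stop("only mono WAV supported")
      if (audio_fmt == 3 && bits == 32) {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      } else if (audio_fmt == 1 && bits == 16) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (fmt ", audio_fmt, ", ", bits, " bit)")
      }
      return(list(samples = samples, fs = fs))
    } else {
      readBin(con, "raw", n = size + size %% 2) # skip unknown chunk (padded)
    }
  }
}
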