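#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to \code{[-1, 1]} and quantized to signed 16-bit.
#'
#' @param samples Numeric vector of amplitudes in \code{[-1, 1]}.
#' @param path Output file path.
#' @param sample_rate Sampling frequency in Hz.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path File path.
#' @return List with \code{samples} (amplitudes in \code{[-1, 1]}) and
#'   \code{sample_rate}.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sample_rate <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only PCM mono is supported", call. = FALSE)
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
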