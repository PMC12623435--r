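#' Write a mono waveform to a 16-bit PCM RIFF/WAVE file
#'
#' Minimal canonical-format writer (RIFF header + "fmt " + "data" chunks).
#' Samples are expected in `[-1, 1]`; values outside that range are clipped
#' with a warning before quantization.
#'
#' @param samples numeric vector of audio samples in `[-1, 1]`.
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 48000) {
  stopifnot(is.numeric(samples), length(samples) > 0L)
  if (any(abs(samples) > 1)) {
    warning("samples outside [-1, 1] clipped before 16-bit quantization")
    samples <- pmin(1, pmax(-1, samples))
  }
  pcm <- as.integer(round(samples * 32767))
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono RIFF/WAVE file
#'
#' Counterpart of [write_wav()]. Only uncompressed 16-bit mono files are
#' supported; the "fmt " and "data" chunks are located by scanning the chunk
#' list, so files with extra chunks (e.g. "LIST") still load.
#'
#' @param path file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono WAV supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit WAV supported")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      samples <- pcm / 32767
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = sample_rate)
}
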