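#' Write a mono IEEE-float WAV file
#'
#' Serializes one channel of real-valued samples as a RIFF/WAVE file with
#' 32-bit IEEE float encoding (format code 3), the interchange format used
#' for simulated cohort recordings.
#'
#' @param samples Numeric vector of samples (arbitrary units; stored as
#'   single-precision floats).
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per_sample <- 4L
  data_bytes <- n * bytes_per_sample
  # RIFF header
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  # fmt chunk: format 3 = IEEE float, 1 channel
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * bytes_per_sample, con, size = 4, endian = "little")
  writeBin(bytes_per_sample, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  # data chunk
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono WAV file
#'
#' Parses RIFF/WAVE chunks and returns the sample vector and sampling rate.
#' Supports 32-bit IEEE float (format 3) and 16/32-bit PCM (format 1), mono.
#'
#' @param path Path to a WAV file.
#' @return List with elements `samples` (numeric) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fcon <- rawConnection(raw_fmt)
      fmt <- list(
        code = readBin(fcon, "integer", 1, size = 2, endian = "little"),
        channels = readBin(fcon, "integer", 1, size = 2, endian = "little"),
        fs = readBin(fcon, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(fcon, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(fcon, "integer", 1, size = 2, endian = "little"),
        bits = readBin(fcon, "integer", 1, size = 2, endian = "little")
      )
      close(fcon)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported: ", path)
      if (fmt$code == 3L) {
        samples <- readBin(con, "double", size / 4, size = 4,
                           endian = "little")
      } else if (fmt$code == 1L && fmt$bits %in% c(16L, 32L)) {
        b <- fmt$bits / 8L
        ints <- readBin(con, "integer", size / b, size = b, signed = TRUE,
                        endian = "little")
        samples <- ints / 2^(fmt$bits - 1)
      } else {
        stop("unsupported WAV encoding (format ", fmt$code, ", ",
             fmt$bits, " bit): ", path)
      }
    } else {
      readBin(con, "raw", size + (size %% 2))  # skip unknown chunk (padded)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, fs = fmt$fs)
}
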