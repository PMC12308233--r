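#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for single-channel recordings as produced by
#' autonomous PAM recorders: PCM 16- or 24-bit, or IEEE float 32-bit.
#' Integer samples are returned normalized to `[-1, 1)` (division by
#' 2^(bits-1)); float samples are assumed to be already normalized.
#'
#' @param path path to a `.wav` file.
#' @return A list with `samples` (normalized numeric vector), `sample_rate`,
#'   `bits` and `format` (`"pcm"` or `"float"`).
#' @seealso [write_wav()], [calibrate()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = as.integer(body[1]) + 256L * as.integer(body[2]),
        n_channels   = as.integer(body[3]) + 256L * as.integer(body[4]),
        sample_rate  = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits         = as.integer(body[15]) + 256L * as.integer(body[16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2)) # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort(paste0("missing fmt/data chunk: ", path))
  if (fmt$n_channels != 1L) abort("only mono WAV files are supported")

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", n = length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
    samples <- v / 2^15
    format <- "pcm"
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    i <- 3 * (seq_len(n) - 1L)
    v <- b[i + 1L] + 256 * b[i + 2L] + 65536 * b[i + 3L]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    samples <- v / 2^23
    format <- "pcm"
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    samples <- readBin(data_raw, "double", n = length(data_raw) / 4, size = 4,
                       endian = "little")
    format <- "float"
  } else {
    abort(sprintf("unsupported WAV encoding (format %d, %d bit)",
                  fmt$audio_format, fmt$bits))
  }
  list(samples = samples, sample_rate = fmt$sample_rate, bits = fmt$bits,
       format = format)
}

#' Write a mono WAV file
#'
#' Writes normalized samples in `[-1, 1)` as mono PCM (16- or 24-bit) or
#' IEEE float 32-bit. PCM samples are rounded to the nearest code and
#' clamped at full scale.
#'
#' @param samples normalized numeric vector.
#' @param path output path.
#' @param sample_rate sample rate in Hz.
#' @param bits 16, 24 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bits = 24) {
  stopifnot(bits %in% c(16, 24, 32))
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  audio_format <- if (bits == 32) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")

  if (bits == 16) {
    v <- pmin(pmax(round(samples * 2^15), -2^15), 2^15 - 1)
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else if (bits == 24) {
    v <- pmin(pmax(round(samples * 2^23), -2^23), 2^23 - 1)
    v <- ifelse(v < 0, v + 2^24, v)
    b <- integer(3 * length(v))
    b[seq(1, length(b), 3)] <- v %% 256
    b[seq(2, length(b), 3)] <- (v %/% 256) %% 256
    b[seq(3, length(b), 3)] <- (v %/% 65536) %% 256
    writeBin(as.raw(b), con)
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
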