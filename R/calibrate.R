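#' Recorder specification
#'
#' Describes the recording chain needed to map normalized WAV samples back to
#' sound pressure in micropascal: hydrophone sensitivity (dB re 1 V/uPa,
#' negative), amplifier gain (dB), ADC full-scale voltage and the native
#' sample rate. Sensitivity and gain act end to end, so only their sum
#' matters for calibration. Typical reef-PAM deployments use either a
#' duty-cycled protocol (a few minutes recorded at the top of each hour) or
#' continuous recording; `duty_cycle` carries that metadata.
#'
#' The ADC full-scale voltage is rarely reported for autonomous recorders;
#' the default of 1 V makes sensitivity + gain fully determine the pressure
#' mapping.
#'
#' @param sensitivity_db hydrophone sensitivity in dB re 1 V/uPa (negative).
#' @param gain_db amplifier gain in dB.
#' @param adc_fullscale_volts ADC full-scale voltage (default 1).
#' @param native_rate native sample rate in Hz. Rates other than 44100 or
#'   48000 are accepted with a warning.
#' @param duty_cycle either `"continuous"` or a list
#'   `list(record_minutes =, usable_minutes =)` per hour.
#' @return A `reefpam_recorder` object.
#' @examples
#' recorder_spec(-181, 10, native_rate = 48000,
#'               duty_cycle = list(record_minutes = 5, usable_minutes = 4.4))
#' recorder_spec(-170, 2, native_rate = 44100)
#' @export
recorder_spec <- function(sensitivity_db, gain_db = 0, adc_fullscale_volts = 1,
                          native_rate = 44100, duty_cycle = "continuous") {
  if (sensitivity_db >= 0) abort("`sensitivity_db` must be negative (dB re 1 V/uPa)")
  if (adc_fullscale_volts <= 0) abort("`adc_fullscale_volts` must be positive")
  if (!native_rate %in% c(44100, 48000)) {
    warn(sprintf("unusual native rate %g Hz", native_rate))
  }
  structure(
    list(sensitivity_db = sensitivity_db, gain_db = gain_db,
         adc_fullscale_volts = adc_fullscale_volts, native_rate = native_rate,
         duty_cycle = duty_cycle),
    class = "reefpam_recorder"
  )
}

# full-scale pressure in uPa: pressure at raw = 1.0
recorder_fullscale_upa <- function(spec) {
  spec$adc_fullscale_volts / 10^((spec$sensitivity_db + spec$gain_db) / 20)
}

#' Calibrated pressure segment
#'
#' Container for a timestamped sound-pressure series in micropascal at a
#' known sample rate for one site. Created by [calibrate()] or by the
#' synthetic soundscape generator.
#'
#' @param pressure numeric pressure series in uPa (finite).
#' @param sample_rate sample rate in Hz.
#' @param site_id site identifier.
#' @param start_time segment start as local civil `POSIXct` (diel windows are
#'   local-clock based; no timezone arithmetic is applied).
#' @param clipped logical flag set by [calibrate()] when the raw input was
#'   near full scale.
#' @return A `reefpam_segment` object.
#' @export
calibrated_segment <- function(pressure, sample_rate, site_id = NA_character_,
                               start_time = as.POSIXct(NA), clipped = FALSE) {
  if (!all(is.finite(pressure))) abort("pressure samples must all be finite")
  if (sample_rate <= 0) abort("`sample_rate` must be positive")
  structure(
    list(site_id = site_id, start_time = start_time,
         sample_rate = sample_rate, pressure = pressure, clipped = clipped),
    class = "reefpam_segment"
  )
}

#' @export
print.reefpam_segment <- function(x, ...) {
  cat(sprintf("<reefpam_segment> site %s, %s, %.1f s @ %g Hz%s\n",
              x$site_id, format(x$start_time), length(x$pressure) / x$sample_rate,
              x$sample_rate, if (isTRUE(x$clipped)) " [clipped]" else ""))
  invisible(x)
}

segment_duration <- function(segment) length(segment$pressure) / segment$sample_rate

#' Convert raw WAV samples to calibrated pressure
#'
#' Maps normalized samples in `[-1, 1]` to sound pressure in micropascal via
#' `pressure = raw * V_fs / 10^((S + G) / 20)` where `S` is the hydrophone
#' sensitivity and `G` the gain (both dB), then removes the segment mean
#' (DC offset). If more than 0.1% of samples sit at or above 99.9% of full
#' scale the segment is flagged as clipped (with a warning).
#'
#' @param raw normalized samples in `[-1, 1]`, or the list returned by
#'   [read_wav()].
#' @param spec a [recorder_spec()].
#' @param sample_rate sample rate in Hz; defaults to `spec$native_rate` (or
#'   the WAV header rate when `raw` comes from [read_wav()]).
#' @param site_id,start_time segment metadata.
#' @return A [calibrated_segment()] in uPa.
#' @examples
#' seg <- calibrate(c(0, 0.5, -0.5, 0), recorder_spec(-170, 0), sample_rate = 4)
#' @export
calibrate <- function(raw, spec, sample_rate = NULL, site_id = NA_character_,
                      start_time = as.POSIXct(NA)) {
  if (is.list(raw)) {
    if (is.null(sample_rate)) sample_rate <- raw$sample_rate
    raw <- raw$samples
  }
  if (is.null(sample_rate)) sample_rate <- spec$native_rate
  if (any(abs(raw) > 1 + 1e-9)) abort("raw samples must lie within [-1, 1]")
  clipped <- mean(abs(raw) >= 0.999) > 0.001
  if (clipped) warn("possible clipping: >0.1% of samples at >=99.9% full scale")
  pressure <- raw * recorder_fullscale_upa(spec)
  pressure <- pressure - mean(pressure)
  calibrated_segment(pressure, sample_rate, site_id = site_id,
                     start_time = start_time, clipped = clipped)
}

# -- resampling ---------------------------------------------------------------

# Kaiser-windowed sinc low-pass for polyphase resampling at rate fs_up,
# -6 dB cutoff at 0.9 x target Nyquist, transition 0.8-1.0 x target Nyquist,
# ~60 dB stopband. Cached per (p, q, source_rate).
.fir_cache <- new.env(parent = emptyenv())

design_resample_fir <- function(p, q, source_rate) {
  key <- paste(p, q, source_rate, sep = "_")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  fs_up <- source_rate * p
  nyq_t <- source_rate * p / q / 2
  atten <- 60
  beta <- 0.1102 * (atten - 8.7)
  d_omega <- 2 * pi * (0.2 * nyq_t) / fs_up
  n_taps <- ceiling((atten - 7.95) / (2.285 * d_omega))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1 # symmetric, integer group delay
  fc <- 0.9 * nyq_t
  k <- seq_len(n_taps) - 1 - (n_taps - 1) / 2
  x <- 2 * fc / fs_up * k
  s <- ifelse(k == 0, 1, sin(pi * x) / (pi * x))
  h <- 2 * fc / fs_up * s * as.numeric(signal::kaiser(n_taps, beta)) * p
  .fir_cache[[key]] <- h
  h
}

#' Resample a calibrated segment
#'
#' Polyphase rational resampling (upsample by p, Kaiser-windowed sinc FIR,
#' downsample by q) with the anti-alias low-pass cut at 0.9 x the target
#' Nyquist frequency. Only downsampling is supported: the analysis never
#' upsamples. Output length is `round(n * target / source)`; the start
#' timestamp is preserved (the filter group delay is compensated).
#'
#' @param segment a [calibrated_segment()].
#' @param target_rate target sample rate in Hz (must not exceed the current
#'   rate).
#' @return A [calibrated_segment()] at `target_rate`.
#' @examples
#' seg <- calibrated_segment(sin(2 * pi * 440 * (0:47999) / 48000), 48000)
#' resample_segment(seg, 44100)
#' @export
resample_segment <- function(segment, target_rate) {
  source_rate <- segment$sample_rate
  if (target_rate > source_rate) {
    abort("upsampling is not supported (target rate above source rate)")
  }
  if (target_rate == source_rate) return(segment)
  g <- gcd_int(round(target_rate), round(source_rate))
  p <- round(target_rate) / g
  q <- round(source_rate) / g
  h <- design_resample_fir(p, q, source_rate)
  y <- as.numeric(cpp_upfirdn(segment$pressure, h, as.integer(p), as.integer(q)))
  calibrated_segment(y, target_rate, site_id = segment$site_id,
                     start_time = segment$start_time, clipped = segment$clipped)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# -- corpus scanning ----------------------------------------------------------

# WAV header only (no sample data): sample rate and duration
wav_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF")) abort("not RIFF")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) abort("not WAVE")
  rate <- NA_real_; bits <- NA_integer_; data_size <- NA_real_
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      rate <- sum(as.integer(body[5:8]) * 256^(0:3))
      bits <- as.integer(body[15]) + 256L * as.integer(body[16])
    } else if (identical(id, "data")) {
      data_size <- sz
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (!is.finite(rate) || !is.finite(data_size)) abort("malformed WAV header")
  list(sample_rate = rate, duration = data_size / (bits / 8) / rate)
}

#' Scan a corpus directory into an inventory
#'
#' Walks a directory of WAV files named `<site>_<YYYYMMDD>_<HHMMSS>.wav`,
#' joins site metadata, and returns one inventory row per parseable file,
#' sorted by site and start time. Files whose names cannot be parsed are
#' collected in the `rejects` attribute (the scan continues); overlapping
#' duplicate timestamps for one site are flagged in the `duplicate` column.
#' A file whose site is missing from `metadata` is an error naming the file.
#'
#' @param directory directory containing `.wav` files (searched recursively).
#' @param metadata a data frame with columns `site`, `protection`,
#'   `location`, and optionally `year` per site.
#' @return A tibble with columns `site`, `start_time`, `duration`,
#'   `sample_rate`, `path`, `duplicate` plus the metadata columns, with a
#'   `rejects` attribute (tibble of `path`, `reason`).
#' @export
scan_corpus <- function(directory, metadata) {
  paths <- list.files(directory, pattern = "\\.wav$", recursive = TRUE,
                      full.names = TRUE)
  rejects <- tibble(path = character(), reason = character())
  rows <- list()
  rx <- "^(.+)_([0-9]{8})_([0-9]{6})\\.wav$"
  for (p in paths) {
    fn <- basename(p)
    if (!grepl(rx, fn)) {
      rejects <- dplyr::bind_rows(rejects, tibble(path = p, reason = "unparseable filename"))
      next
    }
    site <- sub(rx, "\\1", fn)
    ts <- as.POSIXct(paste0(sub(rx, "\\2", fn), sub(rx, "\\3", fn)),
                     format = "%Y%m%d%H%M%S", tz = "UTC")
    if (is.na(ts)) {
      rejects <- dplyr::bind_rows(rejects, tibble(path = p, reason = "malformed timestamp"))
      next
    }
    info <- tryCatch(wav_info(p), error = function(e) NULL)
    if (is.null(info)) {
      rejects <- dplyr::bind_rows(rejects, tibble(path = p, reason = "unreadable WAV header"))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      site = site, start_time = ts, duration = info$duration,
      sample_rate = info$sample_rate, path = p
    )
  }
  inv <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(site = character(), start_time = as.POSIXct(character()),
           duration = numeric(), sample_rate = numeric(), path = character())
  missing_sites <- setdiff(inv$site, metadata$site)
  if (length(missing_sites)) {
    f <- inv$path[inv$site %in% missing_sites][1]
    abort(sprintf("site '%s' (file %s) missing from metadata", missing_sites[1], f))
  }
  inv <- inv |>
    dplyr::arrange(.data$site, .data$start_time) |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(duplicate = duplicated(.data$start_time) |
                    duplicated(.data$start_time, fromLast = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::left_join(as_tibble(metadata), by = "site")
  attr(inv, "rejects") <- rejects
  inv
}

#' @rdname scan_corpus
#' @param inventory an inventory returned by [scan_corpus()].
#' @export
corpus_rejects <- function(inventory) {
  attr(inventory, "rejects") %||% tibble(path = character(), reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
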