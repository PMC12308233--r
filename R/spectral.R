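#' Assign a timestamp to a diel analysis period
#'
#' Reef soundscape analyses compare daytime (07:00 to 17:00) with nighttime
#' (19:00 to 05:00) on the local clock. A night is one replicate anchored to
#' the calendar date on which it starts: the night of date D spans D 19:00
#' through D+1 05:00, so a 03:30 timestamp belongs to the previous date's
#' night. Timestamps in neither window (crepuscular hours) are excluded.
#'
#' @param timestamp a `POSIXct` vector (local civil time).
#' @return A tibble with columns `period` (`"day"`, `"night"` or
#'   `"excluded"`) and `anchor_date` (`Date`; `NA` when excluded).
#' @examples
#' assign_period(as.POSIXct("2021-02-03 03:30:00", tz = "UTC"))
#' @export
assign_period <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  date <- as.Date(format(timestamp, "%Y-%m-%d"))
  period <- dplyr::case_when(
    hour >= 7 & hour < 17 ~ "day",
    hour >= 19 ~ "night",
    hour < 5 ~ "night",
    TRUE ~ "excluded"
  )
  anchor <- dplyr::case_when(
    period == "day" ~ date,
    period == "night" & hour >= 19 ~ date,
    period == "night" & hour < 5 ~ date - 1L,
    TRUE ~ as.Date(NA)
  )
  tibble(period = period, anchor_date = anchor)
}

#' Per-frame power spectral density
#'
#' Splits a calibrated segment into Kaiser-windowed frames of
#' `band$fft_len` samples advanced by `band$hop` (the trailing partial frame
#' is dropped; frames never straddle file boundaries) and computes the
#' one-sided PSD of each frame in linear units (uPa^2/Hz):
#' `PSD_k = |FFT_k|^2 * 2 / (rate * sum(w^2))`, without the doubling at DC
#' and Nyquist. The number of frames is `floor((n - fft_len) / hop) + 1`.
#'
#' @param segment a [calibrated_segment()] already at `band$analysis_rate`.
#' @param band a [band_config()].
#' @return A list with `freqs` (Hz) and `psd` (linear one-sided PSD matrix,
#'   bins x frames).
#' @export
compute_psd_frames <- function(segment, band) {
  if (!isTRUE(all.equal(segment$sample_rate, band$analysis_rate))) {
    abort(sprintf("segment rate %g Hz does not match band analysis rate %g Hz",
                  segment$sample_rate, band$analysis_rate))
  }
  n <- length(segment$pressure)
  if (n < band$fft_len) abort("segment shorter than one FFT frame")
  w <- as.numeric(signal::kaiser(band$fft_len, band$kaiser_beta))
  pw <- cpp_frame_power(segment$pressure, w, band$hop)
  psd <- pw * psd_scale_vec(band, w)
  list(freqs = band_freqs(band), psd = psd)
}

# per-bin one-sided PSD scale: 2/(rate * sum(w^2)), no doubling at DC/Nyquist
psd_scale_vec <- function(band, w) {
  scale <- rep(2 / (band$analysis_rate * sum(w^2)), band$fft_len / 2 + 1)
  scale[1] <- scale[1] / 2
  scale[length(scale)] <- scale[length(scale)] / 2
  scale
}

#' Median spectrum of a site x calendar day x diel period cell
#'
#' Per-bin median over all frames of a cell, computed in the linear power
#' domain and then converted to dB re 1 uPa^2/Hz. An even frame count uses
#' the midpoint of the two central values (in the linear domain). Bins with
#' zero power are floored at `floor_db`.
#'
#' @param frames a linear PSD matrix (bins x frames) from
#'   [compute_psd_frames()], or a list of such matrices (e.g. several files
#'   of one cell) which are concatenated frame-wise.
#' @param band the [band_config()] the frames were computed under.
#' @param site,date,period cell labels carried into the result.
#' @param floor_db dB floor for zero-power bins (default -200).
#' @return A `reefpam_median_spectrum` object with `freqs`,
#'   `median_psd_db`, `n_frames` and the cell labels.
#' @export
median_psd <- function(frames, band, site = NA_character_, date = as.Date(NA),
                       period = NA_character_, floor_db = -200) {
  if (is.list(frames) && !is.matrix(frames)) {
    if ("psd" %in% names(frames)) frames <- frames$psd
    else frames <- do.call(cbind, lapply(frames, function(f)
      if (is.list(f)) f$psd else f))
  }
  if (!is.matrix(frames) || ncol(frames) < 1) abort("need at least one frame")
  med <- as.numeric(cpp_row_medians(frames))
  structure(
    list(band = band, freqs = band_freqs(band),
         median_psd_db = power_to_db(med, floor_db = floor_db),
         n_frames = ncol(frames), site = site, date = date, period = period),
    class = "reefpam_median_spectrum"
  )
}

#' @export
print.reefpam_median_spectrum <- function(x, ...) {
  cat(sprintf("<reefpam_median_spectrum> %s %s %s band %s, %d frames\n",
              x$site, format(x$date), x$period, x$band$name, x$n_frames))
  invisible(x)
}

#' Peak level and peak frequency of a median spectrum
#'
#' Extracts the two headline soundscape features from a median spectrum:
#' `psd_fpeak_db`, the highest median PSD value in the band (dB re
#' 1 uPa^2/Hz), and `gamma_fpeak_hz`, the frequency at which that maximum
#' occurs. The search is restricted to the band's peak-search bins (the LF
#' convention excludes the DC bin, where mooring noise accumulates); ties
#' break toward the lowest frequency.
#'
#' @param ms a `reefpam_median_spectrum` from [median_psd()].
#' @return A one-row tibble: `site`, `date`, `period`, `band`,
#'   `psd_fpeak_db`, `gamma_fpeak_hz`, `n_frames`.
#' @export
extract_band_features <- function(ms) {
  mask <- band_mask(ms$band, ms$freqs)
  if (sum(mask) < 2) abort("band mask selects fewer than 2 bins")
  f <- ms$freqs[mask]
  v <- ms$median_psd_db[mask]
  i <- which.max(v) # first maximum = lowest-frequency tie-break
  tibble(site = ms$site, date = ms$date, period = ms$period,
         band = ms$band$name, psd_fpeak_db = v[i], gamma_fpeak_hz = f[i],
         n_frames = ms$n_frames)
}

#' dB-versus-linear averaging audit
#'
#' Difference between averaging levels in the linear power domain and
#' averaging them directly in dB:
#' `Delta = 10*log10(mean(10^(v/10))) - mean(v)`. By Jensen's inequality
#' Delta is always >= 0, with equality exactly when all values are equal;
#' reporting it alongside arithmetic dB means quantifies how much the
#' averaging convention matters.
#'
#' @param values numeric vector of levels in dB.
#' @return Delta in dB (a scalar >= 0).
#' @examples
#' average_db_audit(c(60, 70)) # 2.404
#' @export
average_db_audit <- function(values) {
  if (length(values) < 1) abort("need at least one value")
  10 * log10(mean(10^(values / 10))) - mean(values)
}

#' Moon phase fraction
#'
#' Fraction of the synodic cycle elapsed at a given date, from the mean
#' synodic month (29.530588853 days) anchored at the new moon of
#' 2000-01-06 18:14 UTC. 0 is new moon, 0.5 full moon. A mean-cycle
#' approximation is adequate for use as a statistical covariate.
#'
#' @param date a `Date` or `POSIXct` vector.
#' @return Phase fraction(s) in `[0, 1)`.
#' @export
moon_phase <- function(date) {
  epoch <- as.numeric(ISOdatetime(2000, 1, 6, 18, 14, 0, tz = "UTC"))
  t <- as.numeric(as.POSIXct(date, tz = "UTC"))
  ((t - epoch) / 86400 / 29.530588853) %% 1
}
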