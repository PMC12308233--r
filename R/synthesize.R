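#' Snap waveform kernel
#'
#' Model waveform for a single snapping-shrimp snap: an exponentially damped
#' sinusoid `p(t) = exp(-t/tau) * sin(2 pi fc t)`, sampled until the
#' envelope falls below 1% of its peak (`ceil(tau * ln(100) * rate)`
#' samples) and normalized to unit peak amplitude. The real broadband
#' transient is not modelled in detail; what matters downstream is a
#' millisecond-scale impulse whose energy concentrates near `fc`.
#'
#' @param fc centre frequency in Hz; must be below the Nyquist frequency.
#' @param tau envelope decay time constant in seconds.
#' @param sample_rate sample rate in Hz.
#' @return Numeric waveform with `max(abs(.)) == 1`.
#' @examples
#' length(make_snap_kernel(5000, 2e-4, 44100)) # 41 samples
#' @export
make_snap_kernel <- function(fc, tau, sample_rate) {
  if (fc <= 0 || fc >= sample_rate / 2) {
    abort(sprintf("fc = %g Hz would alias: need 0 < fc < %g", fc, sample_rate / 2))
  }
  if (tau <= 0) abort("`tau` must be positive")
  n <- ceiling(tau * log(100) * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  p <- exp(-t / tau) * sin(2 * pi * fc * t)
  m <- max(abs(p))
  if (m == 0) abort("degenerate kernel (all zero)")
  p / m
}

# one-sided ambient PSD (uPa^2/Hz): power law in dB/decade around 1 kHz,
# flattened below 10 Hz to avoid a DC blow-up
ambient_psd <- function(f, level_db, slope_db_per_decade) {
  db_to_power(level_db + slope_db_per_decade * log10(pmax(f, 10) / 1000))
}

# one-sided chorus PSD: Gaussian bump, `bandwidth` = full width at half max
chorus_psd <- function(f, f0, bandwidth, peak_level_db) {
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))
  db_to_power(peak_level_db) * exp(-(f - f0)^2 / (2 * sigma^2))
}

# synthesize Gaussian noise with one-sided PSD `psd_fun(f)` at rate fs.
# Frequency-domain overlap-add; exact PSD in expectation.
synth_shaped_noise <- function(n, fs, psd_fun, block = 65536L) {
  half <- block / 2
  f <- (0:half) * fs / block
  s_two <- psd_fun(f) / 2
  amp <- sqrt(block * fs * s_two)
  amp[1] <- 0
  as.numeric(cpp_shaped_noise(as.integer(n), amp))
}

# Poisson snap train added in place: returns pressure vector
add_snap_train <- function(pressure, fs, rate_per_s, fc_mean, fc_sd, tau,
                           amp_scale, amp_sdlog) {
  n <- length(pressure)
  dur <- n / fs
  count <- rpois(1, rate_per_s * dur)
  if (count == 0) return(list(pressure = pressure, count = 0L))
  pos <- sort(ceiling(runif(count) * n))
  fc <- rnorm(count, fc_mean, fc_sd)
  fc <- pmin(pmax(fc, 1), fs / 2 - 1) # keep inside (0, Nyquist)
  amp <- rlnorm(count, meanlog = log(amp_scale), sdlog = amp_sdlog)
  out <- as.numeric(cpp_add_snaps(pressure, pos, fc, amp, tau, fs))
  list(pressure = out, count = as.integer(count))
}

#' Simulate one recording segment
#'
#' Generates the calibrated pressure series of one site x date x diel-period
#' cell: power-law ambient noise plus a band-limited Gaussian fish chorus
#' (level per period plus the matching LF group offset) plus a Poisson train
#' of snap transients (rate per period; per-snap centre frequency
#' `Normal(fc_mean, fc_sd)`; lognormal amplitudes scaled by the HF group
#' offset). The segment is generated at the native rate of the year's
#' protocol; a duty-cycled protocol yields only the usable fraction of the
#' nominal duration (the unusable tail is discarded).
#'
#' Determinism: the RNG state is derived from the scenario seed and the
#' (site, date, period) key, so any cell can be regenerated independently.
#'
#' @param scenario a [scenario_config()].
#' @param site_id one of `scenario$sites$site_id`.
#' @param date recording date (`Date`); its year selects the protocol.
#' @param period `"day"` or `"night"`.
#' @return A list with `segment` (a [calibrated_segment()]), `ground_truth`
#'   (tibble, one row per band: nominal peak frequency and level plus the
#'   applied group offset) and `snap_count`.
#' @export
simulate_segment <- function(scenario, site_id, date, period) {
  if (!period %in% c("day", "night")) abort("`period` must be 'day' or 'night'")
  site_row <- scenario$sites[scenario$sites$site_id == site_id, ]
  if (nrow(site_row) != 1) abort(sprintf("unknown site '%s'", site_id))
  date <- as.Date(date)
  year <- format(date, "%Y")
  if (!year %in% scenario$years) abort(sprintf("no protocol for year %s", year))
  proto <- scenario$year_protocols[[year]]
  fs <- proto$rate

  minutes <- scenario$segment_minutes_per_period
  if (is.list(proto$duty)) {
    minutes <- minutes * proto$duty$usable_minutes / proto$duty$record_minutes
  }
  n <- round(minutes * 60 * fs)

  off_lf <- group_offset(scenario, site_row$protection, year, "LF", period)
  off_hf <- group_offset(scenario, site_row$protection, year, "HF", period)
  chorus_level <- switch(period, day = scenario$chorus_level_day,
                         night = scenario$chorus_level_night) + off_lf
  snap_rate <- switch(period, day = scenario$shrimp_rate_day,
                      night = scenario$shrimp_rate_night)
  snap_scale <- scenario$snap_amp_scale * 10^(off_hf / 20)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(scenario$seed, paste(site_id, date, period)))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  psd_fun <- function(f) {
    ambient_psd(f, scenario$ambient_level, scenario$ambient_slope) +
      chorus_psd(f, scenario$chorus_f0, scenario$chorus_bandwidth, chorus_level)
  }
  pressure <- synth_shaped_noise(n, fs, psd_fun)
  snaps <- add_snap_train(pressure, fs, snap_rate, scenario$shrimp_fc_mean,
                          scenario$shrimp_fc_sd, scenario$snap_tau,
                          snap_scale, scenario$snap_amp_sdlog)

  start_hms <- if (period == "day") "10:00:00" else "21:00:00"
  start_time <- as.POSIXct(paste(format(date), start_hms), tz = "UTC")
  segment <- calibrated_segment(snaps$pressure, fs, site_id = site_id,
                                start_time = start_time)

  # nominal snap-train peak PSD via Campbell's theorem: one-sided level
  # 2 * rate * E[A^2] * (tau/2)^2 at the resonance
  e_a2 <- snap_scale^2 * exp(2 * scenario$snap_amp_sdlog^2)
  hf_level <- power_to_db(2 * snap_rate * e_a2 * (scenario$snap_tau / 2)^2)
  gt <- tibble(
    site = site_id, date = date, period = period, band = c("LF", "HF"),
    true_peak_freq_hz = c(scenario$chorus_f0, scenario$shrimp_fc_mean),
    true_peak_level_db = c(chorus_level, hf_level),
    offset_db = c(off_lf, off_hf),
    protection = site_row$protection, location = site_row$location, year = year
  )
  list(segment = segment, ground_truth = gt, snap_count = snaps$count)
}

# recording dates of one year for a scenario
scenario_dates <- function(scenario, year) {
  start <- as.Date(scenario$year_start_dates[[year]])
  start + seq_len(scenario$n_days_per_site) - 1
}

# site x date x period grid of a scenario
scenario_grid <- function(scenario) {
  cells <- tidyr::expand_grid(
    site_id = scenario$sites$site_id,
    year = scenario$years,
    day_index = seq_len(scenario$n_days_per_site),
    period = c("day", "night")
  )
  cells$date <- as.Date(vapply(
    seq_len(nrow(cells)),
    function(i) as.numeric(scenario_dates(scenario, cells$year[i])[cells$day_index[i]]),
    numeric(1)
  ), origin = "1970-01-01")
  cells[, c("site_id", "date", "period", "year")]
}

#' Simulate a full recording campaign to disk
#'
#' Generates one WAV file per site x year x day x diel period
#' (24-bit PCM mono at the year's protocol rate, named
#' `<site>_<YYYYMMDD>_<HHMMSS>.wav`), together with the ground-truth table,
#' a site survey table and the recorder specifications that exactly invert
#' the encoding. Everything is deterministic under the scenario seed.
#' Waveforms are encoded so that pressure maps well below half of full
#' scale under the default source levels; the generator warns if a
#' configuration drives peaks above half scale.
#'
#' @param scenario a [scenario_config()].
#' @param dir output directory (created if needed).
#' @param survey_effect passed to [simulate_survey()].
#' @return A list: `inventory` (tibble of written files),
#'   `ground_truth`, `survey`, `recorders`.
#' @export
simulate_campaign <- function(scenario, dir, survey_effect = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recorders <- scenario_recorders(scenario)
  grid <- scenario_grid(scenario)
  gt <- list()
  rows <- list()
  written <- character()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sim <- simulate_segment(scenario, g$site_id, g$date, g$period)
    seg <- sim$segment
    spec <- recorders[[g$year]]
    raw <- seg$pressure / recorder_fullscale_upa(spec)
    if (max(abs(raw)) > 0.5) {
      warn(sprintf("segment %s %s %s peaks above half full scale",
                   g$site_id, format(g$date), g$period))
    }
    fn <- sprintf("%s_%s_%s.wav", g$site_id, format(g$date, "%Y%m%d"),
                  format(seg$start_time, "%H%M%S"))
    if (fn %in% written) abort(sprintf("output filename collision: %s", fn))
    written <- c(written, fn)
    path <- file.path(dir, fn)
    write_wav(raw, path, seg$sample_rate, bits = 24)
    gt[[i]] <- sim$ground_truth
    rows[[i]] <- tibble(site = g$site_id, date = g$date, period = g$period,
                        year = g$year, path = path,
                        sample_rate = seg$sample_rate,
                        duration = segment_duration(seg),
                        snap_count = sim$snap_count)
  }
  survey <- simulate_survey(scenario, effect = survey_effect)
  list(inventory = dplyr::bind_rows(rows),
       ground_truth = dplyr::bind_rows(gt),
       survey = survey, recorders = recorders)
}
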