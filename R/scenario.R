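#' Synthetic campaign scenario
#'
#' A scenario fixes every generative parameter of a synthetic reef-soundscape
#' campaign: the site design (protected/unprotected couplets across
#' locations), the recording protocols per survey year, the acoustic sources
#' (snapping-shrimp transient trains, a low-frequency fish chorus, power-law
#' ambient noise), diel level cycles and group-level dB offsets, plus the
#' seed that makes the whole corpus reproducible.
#'
#' Defaults emulate a Moorea-style design: eight sites in four MPA/nMPA
#' couplets (West, Northwest, North, East); a duty-cycled 48 kHz protocol for
#' "2015" (5 min recorded per hour of which 4.4 min usable) and a continuous
#' 44.1 kHz protocol for "2021"; a fish chorus peaking near 300 Hz (stronger
#' at night); nocturnal snap trains with per-snap centre frequencies around
#' 5 kHz. Source levels in uPa are not documented for the field recordings,
#' so the defaults are chosen to place median-PSD outputs in realistic reef
#' ranges (ambient 62 dB re 1 uPa^2/Hz at 1 kHz, chorus peaks 85-90 dB,
#' snap-train peaks in the mid-60s to low-70s) while keeping waveforms well inside the
#' 24-bit recorder full scale. Snap rates are crackle-like aggregate rates
#' (hundreds of snaps per second across the whole reef within range of the
#' hydrophone): the median-PSD statistic only registers the snapping hump
#' once most millisecond-scale analysis frames contain snap energy.
#'
#' @param sites tibble with columns `site_id`, `protection`
#'   (`"MPA"`/`"nMPA"`) and `location`.
#' @param years character vector of year labels; each must have an entry in
#'   `year_protocols` and `year_start_dates`.
#' @param year_protocols named list per year:
#'   `list(rate =, duty = "continuous" | list(record_minutes =, usable_minutes =),
#'   sensitivity_db =, gain_db =)`.
#' @param year_start_dates named character/Date vector: first recording day
#'   per year.
#' @param n_days_per_site recording days per site and year.
#' @param segment_minutes_per_period minutes of audio generated per diel
#'   period (before duty-cycle trimming).
#' @param shrimp_rate_day,shrimp_rate_night snap rates in snaps/s.
#' @param shrimp_fc_mean,shrimp_fc_sd per-snap centre frequency distribution
#'   (Hz); `fc_mean - 3 fc_sd > 0` and `fc_mean + 3 fc_sd < 22050` required.
#' @param snap_tau snap envelope decay time constant (s).
#' @param snap_amp_scale lognormal scale (median) of snap peak amplitudes in
#'   uPa; `snap_amp_sdlog` the lognormal sigma.
#' @param snap_amp_sdlog lognormal sigma of snap amplitudes.
#' @param chorus_f0 chorus peak frequency (Hz, below 2 kHz).
#' @param chorus_bandwidth chorus full width at half maximum (Hz).
#' @param chorus_level_day,chorus_level_night chorus peak PSD levels
#'   (dB re 1 uPa^2/Hz).
#' @param ambient_level ambient PSD at 1 kHz (dB re 1 uPa^2/Hz).
#' @param ambient_slope ambient spectral slope (dB/decade).
#' @param group_offsets tibble with columns `protection`, `year`, `band`,
#'   `period`, `offset_db`; `"*"` in a key column matches every level. LF
#'   offsets shift the chorus level, HF offsets scale snap amplitudes.
#' @param seed integer seed; identical scenarios (including seed) generate
#'   bit-identical corpora.
#' @return A `reefpam_scenario` object.
#' @export
scenario_config <- function(
    sites = default_sites(),
    years = c("2015", "2021"),
    year_protocols = default_year_protocols(),
    year_start_dates = c("2015" = "2015-02-01", "2021" = "2021-02-01"),
    n_days_per_site = 3,
    segment_minutes_per_period = 5,
    shrimp_rate_day = 1000, shrimp_rate_night = 2000,
    shrimp_fc_mean = 5000, shrimp_fc_sd = 300,
    snap_tau = 2e-4, snap_amp_scale = 6e5, snap_amp_sdlog = 0.8,
    chorus_f0 = 300, chorus_bandwidth = 150,
    chorus_level_day = 85, chorus_level_night = 90,
    ambient_level = 62, ambient_slope = -8,
    group_offsets = NULL,
    seed = 1L) {
  sites <- as_tibble(sites)
  stopifnot(all(c("site_id", "protection", "location") %in% names(sites)))
  if (!all(sites$protection %in% c("MPA", "nMPA"))) {
    abort("`protection` must be 'MPA' or 'nMPA'")
  }
  if (shrimp_rate_day < 0 || shrimp_rate_night < 0) abort("snap rates must be >= 0")
  if (shrimp_fc_mean - 3 * shrimp_fc_sd <= 0 ||
      shrimp_fc_mean + 3 * shrimp_fc_sd >= 22050) {
    abort("shrimp_fc_mean +- 3 sd must lie within (0, 22050) Hz")
  }
  if (chorus_f0 <= 0 || chorus_f0 >= 2000) abort("`chorus_f0` must be in (0, 2000) Hz")
  if (segment_minutes_per_period <= 0) abort("`segment_minutes_per_period` must be > 0")
  if (snap_tau <= 0) abort("`snap_tau` must be > 0")
  missing_proto <- setdiff(years, names(year_protocols))
  if (length(missing_proto)) abort(paste0("no protocol for year ", missing_proto[1]))
  if (is.null(group_offsets)) {
    group_offsets <- tibble(protection = character(), year = character(),
                            band = character(), period = character(),
                            offset_db = numeric())
  }
  group_offsets <- as_tibble(group_offsets)
  structure(
    list(sites = sites, years = years, year_protocols = year_protocols,
         year_start_dates = year_start_dates,
         n_days_per_site = n_days_per_site,
         segment_minutes_per_period = segment_minutes_per_period,
         shrimp_rate_day = shrimp_rate_day, shrimp_rate_night = shrimp_rate_night,
         shrimp_fc_mean = shrimp_fc_mean, shrimp_fc_sd = shrimp_fc_sd,
         snap_tau = snap_tau, snap_amp_scale = snap_amp_scale,
         snap_amp_sdlog = snap_amp_sdlog,
         chorus_f0 = chorus_f0, chorus_bandwidth = chorus_bandwidth,
         chorus_level_day = chorus_level_day,
         chorus_level_night = chorus_level_night,
         ambient_level = ambient_level, ambient_slope = ambient_slope,
         group_offsets = group_offsets, seed = as.integer(seed)),
    class = "reefpam_scenario"
  )
}

#' @rdname scenario_config
#' @export
default_sites <- function() {
  tibble(
    site_id = c("MPA_West", "nMPA_West", "MPA_Northwest", "nMPA_Northwest",
                "MPA_North", "nMPA_North", "MPA_East", "nMPA_East"),
    protection = rep(c("MPA", "nMPA"), 4),
    location = rep(c("West", "Northwest", "North", "East"), each = 2)
  )
}

#' @rdname scenario_config
#' @export
default_year_protocols <- function() {
  list(
    "2015" = list(rate = 48000,
                  duty = list(record_minutes = 5, usable_minutes = 4.4),
                  sensitivity_db = -181, gain_db = 10),
    "2021" = list(rate = 44100, duty = "continuous",
                  sensitivity_db = -170, gain_db = 2)
  )
}

#' @export
print.reefpam_scenario <- function(x, ...) {
  cat(sprintf(
    "<reefpam_scenario> %d sites, years %s, %d day(s)/site, %g min/period, seed %d\n",
    nrow(x$sites), paste(x$years, collapse = "/"), x$n_days_per_site,
    x$segment_minutes_per_period, x$seed
  ))
  if (nrow(x$group_offsets)) {
    cat("group offsets:\n"); print(x$group_offsets)
  }
  invisible(x)
}

#' Recorder specifications implied by a scenario
#'
#' One [recorder_spec()] per scenario year, keyed by year label. Written
#' alongside a simulated corpus so that calibration exactly inverts
#' generation.
#'
#' @param scenario a [scenario_config()].
#' @return Named list of [recorder_spec()] objects.
#' @export
scenario_recorders <- function(scenario) {
  out <- lapply(scenario$years, function(y) {
    p <- scenario$year_protocols[[y]]
    recorder_spec(p$sensitivity_db, p$gain_db, native_rate = p$rate,
                  duty_cycle = p$duty)
  })
  setNames(out, scenario$years)
}

# summed dB offset matching (protection, year, band, period); "*" wildcards
group_offset <- function(scenario, protection, year, band, period) {
  g <- scenario$group_offsets
  if (!nrow(g)) return(0)
  hit <- (g$protection == "*" | g$protection == protection) &
    (g$year == "*" | g$year == year) &
    (g$band == "*" | g$band == band) &
    (g$period == "*" | g$period == period)
  sum(g$offset_db[hit])
}

# fingerprint for provenance and determinism checks
scenario_hash <- function(scenario) {
  fnv1a32(paste(deparse(unclass(scenario)), collapse = ""))
}
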