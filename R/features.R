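# bring a calibrated segment to a band's analysis rate
segment_at_band_rate <- function(segment, band) {
  if (isTRUE(all.equal(segment$sample_rate, band$analysis_rate))) return(segment)
  resample_segment(segment, band$analysis_rate)
}

# features of one site x date x period cell from its calibrated segments.
# With a single segment the framing, PSD scaling and per-bin median run
# fused in compiled code; multi-file cells concatenate frames first.
cell_band_features <- function(segments, band, site, date, period,
                               floor_db = -200) {
  if (length(segments) == 1L) {
    seg <- segment_at_band_rate(segments[[1]], band)
    if (length(seg$pressure) < band$fft_len) abort("segment shorter than one FFT frame")
    w <- as.numeric(signal::kaiser(band$fft_len, band$kaiser_beta))
    med <- as.numeric(cpp_frame_psd_median(seg$pressure, w, band$hop, psd_scale_vec(band, w)))
    nf <- (length(seg$pressure) - band$fft_len) %/% band$hop + 1L
    ms <- structure(
      list(band = band, freqs = band_freqs(band),
           median_psd_db = power_to_db(med, floor_db = floor_db),
           n_frames = nf, site = site, date = date, period = period),
      class = "reefpam_median_spectrum")
  } else {
    mats <- lapply(segments, function(seg) {
      compute_psd_frames(segment_at_band_rate(seg, band), band)$psd
    })
    ms <- median_psd(do.call(cbind, mats), band, site = site, date = date,
                     period = period, floor_db = floor_db)
  }
  extract_band_features(ms)
}

#' Aggregate a corpus into the per-cell feature table
#'
#' Builds one feature row per site x calendar day x diel period x band from
#' a scanned corpus: each file is calibrated to micropascal, brought to the
#' band's analysis rate, framed into Kaiser-windowed PSDs, and all frames of
#' a cell (across its files; frames never straddle file boundaries) are
#' reduced to a median spectrum from which the peak level and peak frequency
#' are extracted. Each calendar day per site is one replicate; nights anchor
#' to the date they start. Files outside the diel windows and cells without
#' audio are omitted with a log message.
#'
#' @param inventory corpus inventory from [scan_corpus()] (with `protection`
#'   and `location` metadata joined).
#' @param specs a [recorder_spec()], or a named list of them keyed by year
#'   label (`"2015"`, ...) when protocols differ between years.
#' @param bands list of [band_config()]s (default LF and HF).
#' @param floor_db dB floor for zero-power bins.
#' @return A feature-table tibble: `site`, `date`, `period`, `band`,
#'   `psd_fpeak_db`, `gamma_fpeak_hz`, `n_frames`, `protection`, `location`,
#'   `year`, `moon_phase`.
#' @export
aggregate_features <- function(inventory, specs,
                               bands = list(lf_band(), hf_band()),
                               floor_db = -200) {
  if (nrow(inventory) == 0) abort("empty corpus inventory")
  per <- assign_period(inventory$start_time)
  inv <- dplyr::mutate(inventory, period = per$period, date = per$anchor_date)
  excluded <- dplyr::filter(inv, .data$period == "excluded")
  if (nrow(excluded)) {
    message(sprintf("omitting %d file(s) outside the diel windows", nrow(excluded)))
  }
  inv <- dplyr::filter(inv, .data$period != "excluded")
  if (nrow(inv) == 0) abort("no files inside the diel analysis windows")

  spec_for <- function(year) {
    if (inherits(specs, "reefpam_recorder")) return(specs)
    s <- specs[[year]]
    if (is.null(s)) abort(sprintf("no recorder spec for year %s", year))
    s
  }

  cells <- inv |>
    dplyr::group_by(.data$site, .data$date, .data$period) |>
    dplyr::group_split()
  rows <- purrr::map(cells, function(cell) {
    year <- format(cell$start_time[1], "%Y")
    segs <- purrr::map(seq_len(nrow(cell)), function(i) {
      wav <- read_wav(cell$path[i])
      calibrate(wav, spec_for(year), site_id = cell$site[i],
                start_time = cell$start_time[i])
    })
    feats <- purrr::map(bands, function(b) {
      cell_band_features(segs, b, cell$site[1], cell$date[1], cell$period[1],
                         floor_db = floor_db)
    })
    meta <- tibble(protection = cell$protection[1], location = cell$location[1],
                   year = year, moon_phase = moon_phase(cell$date[1]))
    dplyr::bind_cols(dplyr::bind_rows(feats),
                     meta[rep(1, length(bands)), ])
  })
  dplyr::bind_rows(rows)
}

#' Simulate a campaign and extract its feature table in one pass
#'
#' Streams the full synthetic campaign through the analysis chain without
#' writing WAV files: each site x date x period segment is generated,
#' resampled to the band analysis rates, framed, reduced to a median
#' spectrum, and summarized as peak level and peak frequency. Results are
#' identical in distribution to writing the corpus with
#' [simulate_campaign()] and analysing it with [aggregate_features()] (the
#' only difference is the 24-bit encoding round trip, which is exact to
#' within quantization).
#'
#' @param scenario a [scenario_config()].
#' @param bands list of [band_config()]s.
#' @param progress print one line per processed cell?
#' @return A list: `features` (the feature-table tibble) and `ground_truth`.
#' @export
simulate_campaign_features <- function(scenario,
                                       bands = list(lf_band(), hf_band()),
                                       progress = FALSE) {
  grid <- scenario_grid(scenario)
  site_meta <- scenario$sites
  gt <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sim <- simulate_segment(scenario, g$site_id, g$date, g$period)
    seg <- sim$segment
    feats <- purrr::map(bands, function(b) {
      cell_band_features(list(seg), b, g$site_id, g$date, g$period)
    })
    meta <- site_meta[site_meta$site_id == g$site_id, ]
    fr <- dplyr::bind_rows(feats)
    fr$protection <- meta$protection
    fr$location <- meta$location
    fr$year <- g$year
    fr$moon_phase <- moon_phase(g$date)
    rows[[i]] <- fr
    gt[[i]] <- sim$ground_truth
    if (progress) {
      message(sprintf("[%d/%d] %s %s %s: %d frames", i, nrow(grid), g$site_id,
                      format(g$date), g$period, fr$n_frames[1]))
    }
  }
  list(features = dplyr::bind_rows(rows), ground_truth = dplyr::bind_rows(gt))
}

#' Read and write feature tables
#'
#' Feature tables are exchanged as plain CSV with one header row and columns
#' `site`, `date`, `period`, `band`, `psd_fpeak_db`, `gamma_fpeak_hz`,
#' `n_frames`, `protection`, `location`, `year`, `moon_phase`.
#'
#' @param features a feature-table tibble.
#' @param path CSV path.
#' @return `read_feature_table()` returns the tibble; `write_feature_table()`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$year <- as.character(df$year)
  as_tibble(df)
}
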