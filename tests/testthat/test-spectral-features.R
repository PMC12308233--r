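test_that("diel periods follow the local-clock windows with night anchoring", {
  ts <- as.POSIXct(c("2021-02-03 07:00:00", "2021-02-03 16:59:59",
                     "2021-02-03 17:00:00", "2021-02-03 18:00:00",
                     "2021-02-03 19:00:00", "2021-02-04 03:30:00",
                     "2021-02-04 05:00:00", "2021-02-04 04:59:59"), tz = "UTC")
  out <- assign_period(ts)
  expect_equal(out$period, c("day", "day", "excluded", "excluded",
                             "night", "night", "excluded", "night"))
  expect_equal(out$anchor_date[1], as.Date("2021-02-03"))
  expect_equal(out$anchor_date[5], as.Date("2021-02-03"))
  expect_equal(out$anchor_date[6], as.Date("2021-02-03")) # previous date
  expect_equal(out$anchor_date[8], as.Date("2021-02-03"))
  expect_true(is.na(out$anchor_date[3]))
})

test_that("per-frame PSDs satisfy Parseval for white noise", {
  set.seed(3)
  for (beta in c(3, 5, 8)) {
    seg <- calibrated_segment(rnorm(4000 * 10, sd = 2), 4000)
    band <- lf_band(kaiser_beta = beta)
    fr <- compute_psd_frames(seg, band)
    frame_power <- colSums(fr$psd) * band$bin_width
    expect_equal(mean(frame_power), 4, tolerance = 0.05)
  }
})

test_that("frame counts and short-segment errors follow the framing contract", {
  seg <- calibrated_segment(rnorm(1000), 4000)
  fr <- compute_psd_frames(seg, lf_band())
  expect_equal(ncol(fr$psd), (1000 - 256) %/% 64 + 1)
  expect_error(compute_psd_frames(calibrated_segment(rnorm(100), 4000), lf_band()),
               "shorter")
  expect_error(compute_psd_frames(calibrated_segment(rnorm(1000), 8000), lf_band()),
               "match")
})

test_that("a 5 kHz tone falls in HF bin 7, the nearest bin centre", {
  seg <- tone_segment(5000, 44100, dur = 1)
  fr <- compute_psd_frames(seg, hf_band())
  avg <- rowMeans(fr$psd)
  expect_equal(which.max(avg) - 1, 7) # 5000 / 689.0625 = 7.26 -> bin 7
  expect_equal(fr$freqs[which.max(avg)], 4823.4375)
  ms <- median_psd(fr$psd, hf_band())
  expect_equal(extract_band_features(ms)$gamma_fpeak_hz, 4823.4375)
})

test_that("zero signal floors at the configured dB floor", {
  seg <- calibrated_segment(rep(0, 4000), 4000)
  ms <- median_psd(compute_psd_frames(seg, lf_band())$psd, lf_band())
  expect_true(all(ms$median_psd_db == -200))
  ms2 <- median_psd(compute_psd_frames(seg, lf_band())$psd, lf_band(),
                    floor_db = -120)
  expect_true(all(ms2$median_psd_db == -120))
})

test_that("median spectra use linear-domain medians with midpoint ties", {
  band <- band_config("t", 8, 4, 0, f_lo = 0, f_hi = 4)
  m <- matrix(c(1, 3, 100), nrow = 1)[rep(1, 3), , drop = FALSE]
  ms <- median_psd(m, band)
  expect_equal(ms$median_psd_db, rep(10 * log10(3), 3), tolerance = 1e-12)

  one <- matrix(c(2, 5, 9), ncol = 1)
  expect_equal(median_psd(one, band)$median_psd_db, 10 * log10(c(2, 5, 9)))

  even <- matrix(c(2, 4), nrow = 1)[rep(1, 3), , drop = FALSE]
  expect_equal(median_psd(even, band)$median_psd_db, rep(10 * log10(3), 3))

  expect_error(median_psd(matrix(nrow = 3, ncol = 0), band), "frame")
})

test_that("median_psd matches a brute-force per-bin median on random frames", {
  band <- band_config("t", 4000, 64, 0.5, f_lo = 0, f_hi = 2000)
  set.seed(4)
  for (nf in c(1, 2, 7, 33, 50)) {
    m <- matrix(rexp(33 * nf), nrow = 33, ncol = nf)
    got <- median_psd(m, band)$median_psd_db
    want <- 10 * log10(apply(m, 1, stats::median))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("peak extraction restricts to the band and breaks ties low", {
  band <- band_config("t", 800, 8, 0, f_lo = 0, f_hi = 400, lo_open = TRUE)
  ms <- structure(list(band = band, freqs = c(0, 100, 200, 300, 400),
                       median_psd_db = c(99, 50, 60, 55, 40),
                       n_frames = 1, site = "s", date = Sys.Date(),
                       period = "day"),
                  class = "reefpam_median_spectrum")
  ft <- extract_band_features(ms)
  expect_equal(ft$psd_fpeak_db, 60) # DC bin 99 dB excluded
  expect_equal(ft$gamma_fpeak_hz, 200)

  ms$median_psd_db <- c(0, 60, 60, 55, 40)
  expect_equal(extract_band_features(ms)$gamma_fpeak_hz, 100) # tie -> lowest

  band$f_hi <- 50
  ms$band <- band
  expect_error(extract_band_features(ms), "fewer than 2")
})

test_that("tone gamma-peak recovery is within half a bin in both chains", {
  lf <- tone_segment(300, 44100, dur = 1)
  lf4 <- resample_segment(lf, 4000)
  ft <- extract_band_features(
    median_psd(compute_psd_frames(lf4, lf_band())$psd, lf_band()))
  expect_lt(abs(ft$gamma_fpeak_hz - 300), lf_band()$bin_width / 2)

  hf <- tone_segment(5000, 44100, dur = 1)
  ft2 <- extract_band_features(
    median_psd(compute_psd_frames(hf, hf_band())$psd, hf_band()))
  expect_lt(abs(ft2$gamma_fpeak_hz - 5000), hf_band()$bin_width / 2)
})

test_that("scaling pressure shifts the peak level by exactly 20 log10(a)", {
  seg <- tone_segment(300, 4000, dur = 2)
  a <- 3.7
  seg2 <- calibrated_segment(a * seg$pressure, 4000)
  f1 <- extract_band_features(
    median_psd(compute_psd_frames(seg, lf_band())$psd, lf_band()))
  f2 <- extract_band_features(
    median_psd(compute_psd_frames(seg2, lf_band())$psd, lf_band()))
  expect_equal(f2$psd_fpeak_db - f1$psd_fpeak_db, 20 * log10(a),
               tolerance = 1e-6)
})

test_that("duplicating every frame leaves the median spectrum unchanged", {
  set.seed(6)
  m <- matrix(rexp(129 * 21), nrow = 129)
  band <- lf_band()
  ms1 <- median_psd(m, band)
  ms2 <- median_psd(m[, rep(seq_len(21), 2)], band)
  expect_equal(ms1$median_psd_db, ms2$median_psd_db, tolerance = 1e-12)
})

test_that("the dB averaging audit matches hand values and Jensen", {
  expect_equal(average_db_audit(c(60, 70)),
               10 * log10(5.5e6) - 65, tolerance = 1e-12) # 2.4036
  expect_equal(average_db_audit(c(55, 55, 55)), 0)
  expect_equal(average_db_audit(42), 0)
  set.seed(7)
  for (i in 1:1000) {
    v <- rnorm(sample(2:20, 1), mean = 60, sd = runif(1, 0.1, 10))
    expect_gte(average_db_audit(v), 0)
  }
  expect_error(average_db_audit(numeric(0)), "one value")
})

test_that("moon phase is periodic and anchored at the 2000 new moon", {
  p0 <- moon_phase(as.Date("2000-01-06"))
  expect_lt(min(p0, 1 - p0), 0.05)
  d <- as.POSIXct("2014-03-02 12:00:00", tz = "UTC")
  expect_lt(abs(moon_phase(d + 29.530588853 * 86400) - moon_phase(d)), 1e-9)
  half <- as.POSIXct("2000-01-06 18:14:00", tz = "UTC") + 14.765294 * 86400
  expect_lt(abs(moon_phase(half) - 0.5), 0.01)
})

test_that("feature aggregation yields one row per cell and logs omissions", {
  sc <- tiny_scenario(n_sites = 4, n_days = 2, minutes = 0.02, years = "2021",
                      seed = 21)
  d <- withr::local_tempdir()
  simulate_campaign(sc, d)
  md <- dplyr::rename(sc$sites, site = "site_id")
  inv <- scan_corpus(d, md)
  ft <- aggregate_features(inv, scenario_recorders(sc))
  expect_equal(nrow(ft), 4 * 2 * 2 * 2) # sites x days x periods x bands
  expect_setequal(names(ft), c("site", "date", "period", "band", "psd_fpeak_db",
                               "gamma_fpeak_hz", "n_frames", "protection",
                               "location", "year", "moon_phase"))
  expect_true(all(ft$gamma_fpeak_hz[ft$band == "LF"] < 2000))
  expect_true(all(ft$gamma_fpeak_hz[ft$band == "HF"] >= 2000 &
                    ft$gamma_fpeak_hz[ft$band == "HF"] <= 22000))

  # drop one site-night: two band rows disappear
  night_files <- inv$path[grepl("^MPA_West_20210201_21", basename(inv$path))]
  file.remove(night_files)
  inv2 <- scan_corpus(d, md)
  ft2 <- aggregate_features(inv2, scenario_recorders(sc))
  expect_equal(nrow(ft2), nrow(ft) - 2)

  # duty-cycled 48 kHz input flows through the same schema with fewer frames
  sc15 <- tiny_scenario(n_sites = 2, n_days = 1, minutes = 0.05, years = "2015",
                        seed = 22)
  d15 <- withr::local_tempdir()
  simulate_campaign(sc15, d15)
  inv15 <- scan_corpus(d15, dplyr::rename(sc15$sites, site = "site_id"))
  ft15 <- aggregate_features(inv15, scenario_recorders(sc15))
  expect_equal(nrow(ft15), 2 * 1 * 2 * 2)
  expect_true(all(ft15$year == "2015"))
})

test_that("streamed campaign features match the disk path to quantization", {
  sc <- tiny_scenario(n_sites = 2, n_days = 1, minutes = 0.05, years = "2021",
                      seed = 23)
  stream <- simulate_campaign_features(sc)$features
  d <- withr::local_tempdir()
  simulate_campaign(sc, d)
  inv <- scan_corpus(d, dplyr::rename(sc$sites, site = "site_id"))
  disk <- aggregate_features(inv, scenario_recorders(sc))
  key <- c("site", "date", "period", "band")
  m <- dplyr::inner_join(stream, disk, by = key, suffix = c("_s", "_d"))
  expect_equal(nrow(m), nrow(stream))
  expect_equal(m$gamma_fpeak_hz_s, m$gamma_fpeak_hz_d)
  expect_lt(max(abs(m$psd_fpeak_db_s - m$psd_fpeak_db_d)), 0.01)
})
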