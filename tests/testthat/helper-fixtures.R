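# Shared fixtures and independent oracles for the test suite.

# pure-tone calibrated segment
tone_segment <- function(freq, rate = 44100, dur = 2, amp = 1e4,
                         site = "tone", when = as.POSIXct("2021-02-01 10:00:00",
                                                          tz = "UTC")) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  calibrated_segment(amp * sin(2 * pi * freq * t), rate, site_id = site,
                     start_time = when)
}

# small scenario for fast campaign tests
tiny_scenario <- function(n_sites = 4, n_days = 1, minutes = 0.1, seed = 11,
                          years = c("2015", "2021"), ...) {
  scenario_config(sites = default_sites()[seq_len(n_sites), ],
                  years = years,
                  n_days_per_site = n_days,
                  segment_minutes_per_period = minutes, seed = seed, ...)
}

# independent periodogram peak (plain fft, no package spectral code)
oracle_peak_freq <- function(x, rate, f_lo = 0, f_hi = rate / 2,
                             smooth_bins = 1) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]^2
  if (smooth_bins > 1) p <- stats::filter(p, rep(1, smooth_bins) / smooth_bins,
                                          sides = 2)
  f <- (0:(n %/% 2)) * rate / n
  sel <- which(f > f_lo & f <= f_hi & !is.na(p))
  f[sel[which.max(p[sel])]]
}

# ter Braak CCA by explicit generalized-eigenproblem / SVD construction;
# independent of vegan and of run_cca
oracle_cca <- function(community, constraints) {
  x <- as.matrix(community)
  p <- x / sum(x)
  r <- rowSums(p)
  c_ <- colSums(p)
  qbar <- (p - outer(r, c_)) / sqrt(outer(r, c_))
  total <- sum(qbar^2)
  eig_ca <- svd(qbar)$d^2
  z <- as.matrix(constraints)
  zc <- sweep(z, 2, colSums(z * r) / sum(r)) # weighted centering
  zw <- zc * sqrt(r)
  qr_z <- qr(zw)
  h <- tcrossprod(qr.Q(qr_z)[, seq_len(qr_z$rank), drop = FALSE])
  eig_cca <- svd(h %*% qbar)$d^2
  list(total_inertia = total,
       eig_unconstrained = eig_ca[eig_ca > 1e-12],
       eig_constrained = eig_cca[eig_cca > 1e-12],
       rank = qr_z$rank)
}

# random community fixture with guaranteed non-degenerate rows/cols
random_community <- function(n_sites, n_taxa, seed) {
  set.seed(seed)
  m <- matrix(rpois(n_sites * n_taxa, 6), n_sites, n_taxa)
  m[m == 0 & row(m) == col(m)] <- 1
  m + 1 # strictly positive: no degenerate margins
}
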