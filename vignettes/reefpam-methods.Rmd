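---
title: "Soundscape models and design choices in reefpam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soundscape models and design choices in reefpam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reefpam)
```

# Scope

reefpam implements the full analysis chain of a passive-acoustic reef
monitoring study — calibration, band-specific PSD estimation, diel feature
extraction, and the mixed-model/ordination statistics — together with a
synthetic soundscape generator that stands in for field recordings. This
vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what validation on synthetic data does
and does not demonstrate about real recordings.

# Calibration model

A recording chain is summarized by hydrophone sensitivity $S$ (dB re
1 V/µPa, negative), gain $G$ (dB) and ADC full-scale voltage $V_{fs}$.
Normalized samples $x \in [-1, 1)$ map to pressure as

$$ p = x \, V_{fs} \, 10^{-(S+G)/20} \quad [\mu\text{Pa}], $$

followed by per-segment mean subtraction. Design choices:

* **$V_{fs}$ defaults to 1 V.** Recorder data sheets rarely state it; with
  this convention $S+G$ fully determines the mapping, and a corpus written
  by the generator is inverted exactly by `calibrate()`.
* **Gain is additive to sensitivity in dB**; no frequency-dependent response
  is modelled. Reef PAM comparisons hinge on *relative* levels, for which a
  flat end-to-end response is the standard working assumption.
* **DC removal is plain mean subtraction** — the simplest scheme that keeps
  bin 0 from leaking into the low bins.
* Timestamps are local civil time throughout; the diel windows are
  clock-based, so no timezone arithmetic is wanted.

# Resampling

Analysis rates are 44.1 kHz (HF band; 48 kHz recordings are brought down by
147/160) and 4 kHz (LF band). `resample_segment()` performs polyphase
rational resampling with a Kaiser-windowed sinc FIR designed at the
upsampled rate: ~60 dB stopband, transition spanning 0.8–1.0 of the target
Nyquist with the −6 dB cutoff at 0.9 × Nyquist, group delay compensated so
timestamps are preserved, output length `round(n · p/q)`. The branch
decomposition runs in compiled code; a 5-minute 44.1 kHz segment decimates
to 4 kHz in a fraction of a second, which is what makes campaign-scale
simulation studies practical. Upsampling is refused: the analysis never
needs it, and silently interpolating data would only mask rate mismatches.

# Spectral estimation

Frames of `fft_len` samples (LF 256, HF 64) advance by
`fft_len·(1−overlap)` (LF 75%, HF 50% overlap) under a Kaiser window; the
trailing partial frame is dropped and frames never straddle file
boundaries. The one-sided PSD of each frame is
$|\mathrm{FFT}_k|^2 \cdot 2 / (f_s \sum w^2)$, without the factor 2 at DC
and Nyquist.

* **Kaiser β defaults to 5** (first sidelobe ≈ −37 dB). The shape parameter
  is a free choice here; all level and peak checks in the test suite pass
  for β ∈ {3, 5, 8}, so results are not sensitive to it within the range a
  practitioner would pick.
* **Median, not mean.** The per-cell spectrum is the per-bin *median* over
  all frames of a site × calendar-day × diel-period cell, taken in the
  linear power domain and then converted to dB. The median suppresses
  sparse transients (boat passes, close snaps) and is the robust choice for
  characterizing the persistent soundscape. For Gaussian noise the median
  of the per-bin power (an exponential variate) sits at ln 2 of the mean,
  i.e. −1.6 dB; this bias is common to all cells and cancels in every
  between-group comparison the pipeline makes. Quantities that must satisfy
  Parseval exactly (variance checks) therefore use the *mean* over frames.
* An even frame count takes the midpoint of the two central values; bins
  with zero power are floored at −200 dB re 1 µPa² Hz⁻¹ (configurable).
* **Peak search**: `psd_fpeak_db` is the maximum of the median spectrum
  inside the band, `gamma_fpeak_hz` its frequency; ties break toward the
  lowest frequency. The LF search excludes the DC bin (and anything below
  the first non-DC bin) because mooring noise accumulates there; the lower
  bound is configurable via the band's `f_lo`.
* **Night anchoring**: the night of date D spans D 19:00 → D+1 05:00 and is
  one replicate anchored to D. Timestamps in 05:00–07:00 and 17:00–19:00
  are excluded as crepuscular.
* The dB-averaging audit `average_db_audit()` reports
  $\Delta = 10\log_{10}\overline{10^{v/10}} - \bar v \ge 0$ alongside every
  arithmetic dB mean, quantifying how much the averaging convention
  matters for that cell.

# Moon phase

The covariate is the fraction of the mean synodic month (29.530588853 d)
elapsed since the new moon of 2000-01-06 18:14 UTC. True phase deviates
from the mean cycle by up to ±0.6 d; as a linear nuisance covariate this
accuracy is ample. A circular (sin/cos) encoding was considered and left
out of the default model: with ≤ 14-day windows per deployment the linear
fraction is locally monotone and the simpler term matches the original
analysis intent.

# Synthetic soundscape generator

The generator emulates exactly the structure the analysis relies on:

* **Ambient noise** — a power law, `ambient_level` dB re 1 µPa² Hz⁻¹ at
  1 kHz with `ambient_slope` dB/decade (default 62 dB, −8 dB/decade),
  flattened below 10 Hz. This approximates pink sea noise; it has no
  weather, vessel or flow-noise components.
* **Fish chorus** — Gaussian-bump-shaped noise centred at `chorus_f0`
  (default 300 Hz, within the range of observed reef chorus peaks) with
  FWHM `chorus_bandwidth` (150 Hz), peak level per diel period (85 dB day,
  90 dB night). Only the PSD of the chorus matters downstream, so the bump
  model replaces any attempt to sum individual fish calls.
* **Snap train** — a Poisson process of damped-sinusoid kernels
  $e^{-t/\tau}\sin(2\pi f_c t)$ (τ = 0.2 ms), per-snap centre frequency
  Normal(`shrimp_fc_mean` = 5 kHz, sd 300 Hz), lognormal peak amplitudes
  (σ = 0.8, heavy-ish tail mimicking the spread of snap source levels).
  Rates are *crackle-scale aggregates* — 1000 s⁻¹ by day, 2000 s⁻¹ by
  night across the whole reef within range — because the median-PSD
  statistic only registers the snapping hump once most millisecond frames
  contain snap energy; sparse trains of loud snaps are exactly what the
  median rejects.
* **Group offsets** — a table keyed by (protection, year, band, period)
  with `"*"` wildcards. LF offsets shift the chorus peak level in dB; HF
  offsets scale snap amplitudes by the equivalent factor. Offsets are
  recorded verbatim in the ground-truth table, which is what recovery
  tests compare against.
* **Source levels are a modelling choice, not a calibration.** No published
  µPa source levels exist for these components; the defaults place median
  PSD outputs in realistic reef ranges (ambient floor ~60 dB, chorus peaks
  85–90 dB, snap humps mid-60s to low-70s dB re 1 µPa² Hz⁻¹) while keeping
  encoded waveforms under half of the 24-bit full scale of the default
  recorder specs.

Noise components are synthesized in the frequency domain by overlap-add of
sqrt-Hann-windowed 65536-sample blocks whose bin magnitudes follow the
target PSD exactly and whose phases are drawn uniformly through the R RNG.
Summation over ~32k phased bins makes the samples Gaussian for every
practical purpose while halving the random-number cost of a two-Gaussian
spectral draw; an incidental benefit is that each block realizes the target
PSD exactly rather than in expectation. All randomness passes through R's
RNG with per-cell seeds derived from the scenario seed and the
(site, date, period) key, so any cell regenerates independently and a
scenario is bit-reproducible.

The "2015"-style protocol is duty-cycled: 5 min recorded per hour of which
4.4 min are usable, emulated by discarding the final 12% of each nominal
segment; the "2021"-style protocol is continuous at 44.1 kHz.

**What passing on synthetic data shows** — that the pipeline's arithmetic
is right: calibration inverts encoding, the estimator satisfies Parseval,
peaks land on the correct bins, injected group effects of known size are
recovered, and the statistical layer holds its nominal error rates on data
whose generating model matches the fitted model. **What it does not show** —
robustness to everything real recordings add: vessel noise and rain,
recorder self-noise, propagation and site geometry, non-stationarity within
a diel window, chorus species turnover, or model misspecification in the
mixed ANCOVA. Those need field validation.

# Survey generator

Fish counts are lognormal-Poisson: a fixed species-level log-abundance
profile, per-site lognormal heterogeneity, Poisson counts per transect. A
`richness` effect adds MPA-only species; benthic cover is Dirichlet over
the ten point-intercept categories scaled to 100%, and a `cover` offset
raises one category for MPA sites while rescaling the others, so the
expected group difference equals the offset exactly (clipping at 0% is
renormalized with a warning).

# Statistical layer

* `fit_ancova()` fits `response ~ year * protection + moon_phase +
  (1 | location)` by REML (lme4) and tests each fixed term with a type-II
  Wald χ² (car). Type-II means each term is tested after all others at its
  order with interactions respected; the Wald χ² on the mixed fit is the
  standard computational realization. df per term equals the number of
  parameters it contributes. A singular fit (location variance at the
  boundary) is reported but returned — its fixed-term tests coincide with
  OLS, which a dedicated test verifies to 10⁻³. A covariate aliased with
  the design (e.g. one recording date per year makes moon phase redundant)
  is dropped with a warning rather than silently destabilizing the fit.
* `apply_3db_rule()` encodes the instrument-error margin: a level
  difference is *significant* only when p < α (0.05) **and** |Δ| > 3 dB.
  The conjunction is deliberately conservative — a cross-system comparison
  cannot attribute sub-margin changes to the environment no matter how
  small p is.
* `run_cca()` delegates to `vegan::cca` — the canonical engine for the ter
  Braak chi-square formulation — behind a cleaning layer (all-zero
  rows/columns dropped with warnings, aliased constraints reported) and a
  tidy result container. The test suite cross-checks it against an
  explicit generalized-eigenproblem solve written from scratch. Because
  CCA operates on row profiles, counts and relative abundances per site
  give identical ordinations. One documented ambiguity: ordination figures
  for such data are sometimes captioned in terms of Bray–Curtis
  dissimilarity, but CCA is intrinsically chi-square-metric; reefpam
  performs standard CCA and leaves distance-based alternatives
  (db-RDA/PERMANOVA) out of scope.
* 95% ordination ellipses are computed from the score covariance per group
  and exported as numbers (`cca_ellipses()`), not just drawn.

## Calibration of the null — design of the validation simulations

The type-I-error simulations pair the fitted model with a matching
generator: eight sites in four location couplets with protection balanced
*within* location, a location random effect (sd 1 dB), and i.i.d.
replicate noise (sd 2 dB) — 14 days per site for the acoustic table,
9 transect replicates for the survey table. With the protection contrast
identified within locations and ~100 residual df, the Wald χ² is expected
to reject at 5–6% at α = 0.05; 1000-replicate runs land inside
[0.035, 0.065]. With few random-effect levels and a between-site effect of
interest the Wald test would be anticonservative — a known limitation of
Wald tests in small mixed designs, inherited from the original analysis
choice rather than introduced here.

# Problem sizes used in validation

The effect-recovery campaigns use the full study-style design — 8 sites in
4 MPA/nMPA couplets × 3 days × 5-minute segments per diel period × two
protocol years — for the level-offset checks (run on the LF band, the band
the injected offset lives in), and a 4-site × 2-day × 1-minute design for
the HF snap-frequency shift, where the effect is an order of magnitude
larger than the bin width. Null calibrations use 1000 replicates; oracle
comparisons (median spectra, CCA eigenvalues) use dozens of random
fixtures. These sizes were chosen so the entire validation battery runs in
minutes on a single core while leaving every check far from its tolerance
boundary.

# Known limitations

* No acoustic propagation, directionality, recorder self-noise or
  anthropophony in the generator; group offsets are imposed, not emergent.
* The frequency response of real hydrophone chains is assumed flat.
* Wald χ² inference is asymptotic; for designs with very few locations a
  parametric-bootstrap or Kenward–Roger approach would be more exact.
* The duty-cycle emulation discards the unusable tail deterministically;
  real duty-cycled recorders scatter recording windows across the hour.
* WAV support covers mono PCM 16/24-bit and float-32 — the formats
  autonomous reef recorders actually produce.
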