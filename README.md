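# reefpam

Passive acoustic monitoring (PAM) analysis of coral-reef soundscapes in R:
from raw hydrophone WAV files to calibrated sound pressure, band-specific
median power spectral densities, diel acoustic features, and the mixed-model
and ordination statistics used to compare protected and unprotected reefs
across years.

The package is written for ecoacousticians and reef ecologists who deploy
autonomous recorders and want a reproducible, testable version of the
standard analysis chain — plus a fully synthetic soundscape generator so the
whole pipeline can be validated against known ground truth without any field
data.

## What it computes

A reef soundscape is analysed in two bands:

* **LF (fish band, < 2 kHz)** — dominated by fish choruses ("mass
  phenomena"); analysed at 4 kHz with 256-point Kaiser-windowed FFTs at 75%
  overlap (bin width 15.625 Hz).
* **HF (invertebrate band, 2–22 kHz)** — dominated by snapping-shrimp
  broadband transients; analysed at 44.1 kHz with 64-point FFTs at 50%
  overlap (bin width 689.0625 Hz).

For every site × calendar day × diel period (day 07:00–17:00, night
19:00–05:00, local clock) the per-frame one-sided PSDs

    PSD_k = |FFT_k|^2 · 2 / (f_s · Σ w²)       [µPa² Hz⁻¹]

are reduced to a **median spectrum** (per-bin median in the linear domain,
then 10·log₁₀), from which two features are extracted:

* **PSD_Fpeak** — the highest median PSD value in the band
  (dB re 1 µPa² Hz⁻¹);
* **γFpeak** — the frequency at which that maximum occurs.

The statistical layer fits a linear mixed ANCOVA per response
(`year × protection` fixed, location random, moon phase covariate) with
type-II Wald χ² tests, applies the **|3| dB instrument-error rule** (a level
difference is significant only when *p* < α **and** |Δ| > 3 dB), runs survey
ANOVAs (fish abundance, species richness, benthic cover), and relates
community composition to benthic and acoustic features by canonical
correspondence analysis (CCA).

The synthetic generator produces WAV corpora with the statistical structure
this analysis assumes: Poisson snap trains (damped-sinusoid kernels,
lognormal amplitudes, configurable centre frequency), a Gaussian-bump fish
chorus, power-law ambient noise, diel level cycles, group-level dB offsets,
and matching ground-truth and survey tables — all bit-reproducible under a
seed.

## Worked example

```r
library(reefpam)
library(dplyr)

# a campaign with a known +4 dB nocturnal fish-chorus offset in 2021
scenario <- scenario_config(
  group_offsets = tibble::tibble(protection = "*", year = "2021",
                                 band = "LF", period = "night",
                                 offset_db = 4),
  n_days_per_site = 1, segment_minutes_per_period = 0.5, seed = 7)

res <- simulate_campaign_features(scenario)
lf_night <- filter(res$features, band == "LF", period == "night")

summarize_group_differences(lf_night, "psd_fpeak_db", "year")
#> # A tibble: 1 x 10
#>   scope   level_a level_b mean_a_db mean_b_db diff_db delta_a_db delta_b_db
#> 1 overall 2015    2021         88.5      92.6    4.05    0.00101    0.00141

fit <- fit_ancova(lf_night, "psd_fpeak_db")
tidy(fit)
#> # A tibble: 3 x 4
#>   term                 chisq    df p.value
#> 1 year            4709.          1 0
#> 2 protection         0.00687     1 0.934
#> 3 year:protection    0.0666      1 0.796

apply_3db_rule(4.05, 1e-10)
#> # A tibble: 1 x 5
#>   difference_db     p margin alpha verdict
#> 1          4.05 1e-10      3  0.05 significant
```

The recovered difference (4.05 dB) matches the injected +4 dB offset; the
year term dominates the ANCOVA; and the 3 dB rule confirms the call. With a
+2 dB offset the same chain reports a statistically detectable but
*non-significant* change — the instrument margin correctly blocks it.

For file-based work the same chain runs from disk:

```r
simulate_campaign(scenario, "corpus/")          # WAV + ground truth + survey
inv <- scan_corpus("corpus/", metadata)         # inventory + rejects
ft  <- aggregate_features(inv, recorder_specs)  # feature table
rep <- run_stats(ft, survey)                    # ANCOVAs, 3 dB calls, CCA
```

or from the shell via the thin CLI installed under `exec/`:

```sh
reefpam=$(Rscript -e 'cat(system.file("exec", "reefpam", package = "reefpam"))')
Rscript "$reefpam" simulate --config run.yaml
Rscript "$reefpam" report   --config run.yaml
```

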