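---
title: "Methods: heatwave, synchrony, acoustic and energetics indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heatwave, synchrony, acoustic and energetics indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagicsync)
```

This vignette documents the models implemented in `pelagicsync`, the
assumptions behind them, the defaults and why they were chosen, what the
synthetic-data generators do and do not emulate, and the numerical
decisions that matter for reproducibility.

## Marine heatwave detection

A heatwave climatology is built per day of year (doy) on a fixed 366-day
calendar with 29 February at index 60. For each doy, SST values from all
baseline years within ±`window_halfwidth` days (default 5, an 11-day
window) are pooled; the pool's mean is the climatological mean and its
empirical 90th percentile the event threshold. Both curves are smoothed
with a centered moving average (`smooth_width`, default 31 days) that
wraps across the year boundary. Events are maximal runs of days with SST
strictly above the threshold, of length ≥ `min_duration` (default 5);
two qualifying runs separated by ≤ `max_gap` (default 2) below-threshold
days merge into one event whose intensity statistics (anomalies relative
to the climatological mean) include the gap days. These four defaults
are the values in widespread use for daily-SST heatwave climatologies;
all are exposed as arguments.

Numerical decisions:

- **Percentile convention.** Empirical quantiles use the
  linear-interpolation (type 7) convention, fixed for bit
  reproducibility.
- **Leap days.** Index 60 is interpolated from indices 59 and 61 rather
  than estimated from the 1-in-4-years sample, avoiding a sample-size
  artifact.
- **Missing data.** Missing SST days are treated as below threshold
  during detection (with a warning) and ignored in the climatology; a
  baseline with more than 25% missing values is refused. This is
  conservative: gaps can split but never create events.
- **Baseline.** Defaults to the full series span, configurable as a
  year range; summaries over a period (e.g. 2014–2016) use calendar
  bounds, inclusive. Event-boundary summarization would be the
  alternative; calendar bounds were chosen because period totals are
  then directly comparable across cells.

A caveat worth knowing: on a noise-free seasonal cycle, the 31-day
smoothing slightly damps the seasonal peak of both curves, so the raw
series can exceed the smoothed threshold near the summer maximum. With
realistic daily noise the 90th-percentile threshold sits well clear of
this artifact; the package's own noise-free tests therefore use an
unsmoothed climatology.

## Diet indices and portfolio effects

Frequency of occurrence is `F = (samples containing the species) /
(samples)`, per year × guild × species; empty year-guild cells are
omitted with a warning rather than imputed. Synchrony across the
forage-species set (default capelin, sand lance, herring) is measured by
the variance ratio

$$\mathrm{VR} = \frac{\operatorname{var}\left(\sum_i F_i\right)}
                    {\sum_i \operatorname{var}(F_i)},$$

computed on the frequencies themselves (not anomalies; an optional
detrending step was deliberately left out to keep the statistic as
commonly reported) in centered rolling windows (default 3 years), with
the portfolio effect PE = 1 − VR. Sample variances (n − 1) are used
throughout; the convention cancels in the ratio, which tests assert
numerically. Windows in which every species is constant have an
undefined VR and are returned as missing — returning 0 or 1 would
fabricate stability. Windows missing any species-year are skipped
entirely; imputing zeros for absent species would be the alternative,
but it conflates "not sampled" with "absent". For two species the
implementation must agree with the closed form
VR = 1 + 2·cov(A,B)/(var A + var B) to 1e-12.

## Acoustic classification and NASC

Echograms are co-registered 38/120 kHz Sv grids (dB re 1 m⁻¹) with
surface-referenced, half-open depth bins. Classification cells are
5 pings × 5 m; within a cell, Sv is averaged in the linear domain
(sᵥ = 10^(Sv/10)) and converted back to dB, the standard
echo-integration reading of a "mean Sv" — the dB difference is then
taken *between cell means*. A `--mean-domain log` alternative (averaging
dB directly) was considered and rejected as the default because linear
averaging is what echo-integration hardware and software report.
Further conventions:

- Cell means below the −80 dB floor are raised to the floor before
  differencing (preventing noise-driven ΔSv); cells floored at both
  frequencies are `below_threshold` and excluded from classification.
- Bins above 4 m depth or within 1 m of the per-ping bottom are
  excluded; cells with no valid bins are `masked`.
- A trailing along-track cell is kept when it has at least half the
  nominal pings.
- ΔSv ∈ [8, 30] dB (inclusive) ⇒ macrozooplankton; fluid-like scatterers
  backscatter relatively more at 120 kHz, swim-bladdered fish near or
  below 0 dB.

NASC per export cell (0.5 km × 5 m) is 4π·1852² × (mean over pings of
Σ sᵥ Δz) over the cell's depth range, restricted to the 120 kHz data in
macrozooplankton-classified cells; other backscatter contributes zero.
Only classified samples are integrated (an "integrate everything"
sensitivity variant is possible but is then an all-scatterer index, not
a macrozooplankton index). Export cells wholly outside the valid domain
are missing, and regional indices are plain means over export cells per
region-year.

## Lognormal mixture size structure

Length frequencies are decomposed per year into K lognormal components
(default K = 3, matching the three biological size groups: age-0 below
100 mm, and two older groups) by EM on log-lengths. The E-step uses
normal log-densities with a log-sum-exp guard; the M-step uses weighted
moment updates (maximum-likelihood, population-variance convention —
the K = 1 fit is exactly the sample mean and population SD of
log-lengths). Initialization seeds component means at the
(k − ½)/K quantiles plus Gaussian jitter; the best of `n_starts`
(default 10) seeded restarts wins, ties broken by the lowest start
index, and components are reported in ascending `meanlog`, making the
fit a deterministic function of (data, K, n_starts, seed). A component
SD floor of 1e-3 (log scale) aborts collapsing starts; if every start
collapses the per-year wrapper retries with K − 1, down to 1, logging
the reduction — years with few large fish genuinely support fewer
modes. Convergence is |Δ log-likelihood| < 1e-8; the per-iteration
trace is kept and tests assert it is non-decreasing. Fitting is per
year (pooling years with year-specific weights was the alternative;
per-year fits make no cross-year distributional assumption).

Size-class proportions integrate the fitted mixture over boundary-cut
intervals (default a single 100 mm boundary), so classes partition
(0, ∞) and proportions sum to one exactly; assignment by component
identity rather than boundaries is available by using the fitted
weights directly. Class proportions × annual CPUE give the size-scaled
abundance index.

## Energetics

Energy density (kJ g⁻¹ wet) is linear in the carbon:nitrogen atomic
ratio and the dry:wet mass ratio: ED = 0.103·CN + 32.6·(dry/wet) −
2.902. Non-positive predictions are physically impossible and flagged
as suspect records. Total energy is ED × mass with the basis (wet for
the C:N model, dry for calorimetric densities) required explicitly —
an error, not a default, prevents silent unit mixing. "Net wet weight"
is taken as whole-body wet mass as recorded; no gut-content correction
is applied. Juvenile herring records are filtered to 55–115 mm fork
length before modelling, with removals reported.

Annual comparisons use one-way ANOVA with Tukey HSD letters (computed
by insert-and-absorb from the studentized-range adjusted p-values).
Month-specific annual estimates come from
log(TE) ~ year + (1 | site-in-year) fitted by REML via lme4; when the
site variance is singular the model falls back to the fixed-effects
fit, flagged. Least-squares means are back-transformed by
exponentiating the log-scale estimate and its normal-theory 95% CI
endpoints (no bias correction — the estimate is a geometric-scale
mean, matching the usual "back-transformed LS mean" reading). Both
marginal and conditional R² (fixed-effects-only vs. fixed + random
variance fractions) are reported, since published R² values of such
models are frequently ambiguous between the two. The two-sample length
comparison defaults to Welch's t (group SDs of field length data are
rarely equal); the pooled test is a flag away.

## Standardized indices

Anomalies are z-scores with the sample SD, computed within groups
(default season × region, standardizing across years within each group
— the grouping is an argument, since "by season and year" conventions
also appear); degenerate groups are flagged and left missing. Extreme
flags use a strict > threshold (default 2 SD; the expected flag rate
under normality is 2.3%). Encounter rates are counts over effort, and
pooling must sum counts and effort before dividing. Percent change is
100·(first − second)/first. Region labels for biomass summaries are
input metadata; the package does not recompute bathymetric
classifications.

## What the generators emulate — and what they do not

Each generator is a pure function of its scenario (the seed included;
per-generator seed offsets keep the streams independent, so adding one
generator never perturbs another):

- `gen_sst()`: seasonal sinusoid (period 366 on the same day-of-year
  index the climatology uses, so a noise-free cycle is exactly
  representable) + AR(1) noise (marginal SD parameterization) + warm
  boxcar events. Default: 1982–2018, mean 8 °C, amplitude 4 °C,
  φ = 0.8, SD 0.6 °C, one +2.5 °C event of 1050 days starting
  January 2014 — a stylized persistent heatwave.
- `gen_diet()`: latent logit availability per species-year =
  base logit + σ·(ρ·common + (1 − ρ)·own) with standard-normal year
  shocks, Bernoulli samples given availability (default 150
  samples/year/guild over 1993–2018; base frequencies 0.50/0.35/0.12
  reflect a capelin-dominated, herring-light diet). ρ sweeps map
  directly onto the variance-ratio scale.
- `gen_echogram()`: layered scenes (default: a ΔSv = 16 dB
  macrozooplankton layer over a ΔSv = −2 dB fish layer in −95 dB empty
  water, flat 60 m bottom) with independent Gaussian dB noise per
  frequency; truth records each layer's column NASC.
- `gen_lengths()`: annual lognormal-mixture draws (default three modes
  at 65/130/190 mm); `gen_energetics()`: hierarchical log total energy
  (year, month, site-in-year, residual) with chemistry and masses
  back-solved so the ED formula round-trips exactly (default a −0.5
  log-unit 2015 trough and +0.3 2016 rebound).

The generators reproduce *structure*, not field magnitudes: real diet
samples are overdispersed and autocorrelated beyond AR-free logit
shocks, real echograms have range-dependent noise, bubble dropouts and
calibration error, and real length samples are gear-selective. Passing
recovery tests therefore demonstrates correctness of the estimators
under their assumed data-generating processes, not performance on any
particular survey.

## Validation problem sizes

The shipped test-suite exercises: 200 random short SST series × 28
(min-duration, gap) settings against a run-enumeration oracle; 1000
random windows for the two-species VR closed form and 500 independent
26-year datasets for the PE null; 200 replicate diet datasets for the
ρ ∈ {0, 0.5, 0.95} ordering; 50 random echograms against a per-bin
brute-force oracle; 50 seeds of K = 2 mixture recovery at n = 5000 and
100 BIC comparisons at n = 2000; 200 mixed-model coverage replicates
and 1000 null ANOVA replicates; and 10⁵ draws for anomaly flag rates.
These sizes keep each suite's Monte-Carlo error comfortably below the
asserted tolerances while the whole suite runs in minutes on one core.

## Known limitations

- The SST reader accepts the long CSV dialect only; gridded NetCDF
  sources should be flattened to `date,cell_id,lat,lon,sst` upstream.
- The acoustic module classifies a single macrozooplankton band; no
  multi-class inversion, target-strength modelling or calibration
  processing.
- The mixed model assumes lognormal residuals and site-in-year
  exchangeability; no temporal autocorrelation across years.
- Mixture fits assume independent lengths within a year; schooling
  introduces intra-haul correlation that effectively reduces n.
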