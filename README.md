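# actinpatches

Quantification of discrete presynaptic actin patch dynamics from
fluorescence timelapse movies.

At presynaptic terminals (the *Drosophila* larval NMJ being the model
system this package targets), F-actin assembles in transient ~0.6 µm
patches — the force-generating events of synaptic endocytosis — on top
of a diffuse fluorescent-reporter baseline. `actinpatches` measures
them. It is written for cell biologists analysing spinning-disc
timelapse data of actin reporters (GMA, Lifeact, GFP::actin) and for
anyone who needs a fully scripted, reproducible version of the
patch-tracking analysis.

## What it computes

**Patch tracking.** Sub-pixel spot detection by a contrast-calibrated
Laplacian-of-Gaussian filter (estimated patch diameter 0.6 µm, σ =
d/(2√2)), thresholded at 0.32 × the mean probe intensity in the
presynaptic area; globally optimal frame-to-frame linking (max distance
0.5 µm, no gap closing) by an in-package assignment solver; track
filtering by a 4-detection floor, a stationarity rule, and
tracking-path-overlap rejection. Headline statistics per movie:

- frequency *f* in patches / 10 µm² / min (10 µm² ≈ one bouton),
- lifetime distribution with 20-s bins, duration = n_spots × Δt
  (so the detectable range is 16–356 s at 0.25 Hz and 4–139 s at 1 Hz),
- relative amplitude (I<sub>max</sub> − I<sub>min</sub>)/I<sub>mean</sub>
  of the intensity trace at the patch site.

**Corrected frequency estimates.** A merged two-sampling-rate
estimator (mean of the shared 20–150 s range plus the regime-specific
4–16 s and 150–360 s terms) with lower/upper bounds from the rejection
report, and a self-consistent crowding (pile-up) correction for
concurrent patches closer than the pair-resolution radius.

**Tracking-free dynamics.** The per-pixel temporal coefficient of
variation CoV = σ/μ, with "highly variant" area fractions from
in-package Li (minimum cross-entropy) and Tsai (moment-preserving)
automatic thresholds, and a simulation-based calibration that inverts a
CoV difference between genotypes into an inferred percent change in
patch frequency.

**Synthetic movies.** A seeded generator of bouton-chain movies with
known ground truth (Poisson events, lognormal lifetimes, Gaussian
spots, shot + read noise, optional bleaching) used for validation and
as the calibration forward model.

**Supporting quantifications.** Masked 3-D Pearson colocalization,
rolling-ball background subtraction, translation registration, FRAP
double normalization and single-exponential recovery fitting.

## Worked example

Simulate a movie at the default study conditions (three ~12.6 µm²
boutons, f = 6 patches/10 µm²/min, lognormal lifetimes of mean 48 s,
amplitude ratio 0.68, 0.25 Hz for 89 frames, shot + read noise) and run
the full pipeline:

```r
library(actinpatches)

spec <- synthetic_spec(rng_seed = 11)
run  <- run_patch_pipeline(spec)

run$stats
#> <patch_stats> 95 tracks, 4.27 patches/10um^2/min, duration 52.6 +/- 33.2 s, amplitude 0.72 +/- 0.24

run$cov
#> <cov_result> mean CoV 0.2216 over 2218 masked pixels

crowding_corrected_count(run$filtered, run$mask, n_frames(run$movie))
#> # A tibble: 1 × 5
#>   n_counted n_corrected rho_obs   rho  loss
#>       <int>       <dbl>   <dbl> <dbl> <dbl>
#> 1        98        131.   0.380 0.508 0.252
```

Reading the numbers: 95 tracks pass all filters, giving a raw accepted
frequency of 4.27 patches/10 µm²/min; mean lifetime 52.6 s and mean
relative amplitude 0.72 recover the generator's 48 s / 0.68 inputs.
The raw frequency undercounts because concurrent patches within the
~0.66 µm resolution radius merge into one track: the crowding
correction estimates a 25% loss from the observed patch density and
corrects 98 counted (accepted + overlap-rejected) tracks to ~131 —
6.0 patches/10 µm²/min against the generating 6. `tidy()` /
`glance()` return the tables, `autoplot()` draws the duration
histogram, CoV map, calibration curve, or FRAP fit.

Real movies enter through `read_movie("movie.tif", pixel_size_um,
frame_interval_s)` (calibration always comes from you, not from TIFF
tags), with `register_translation()` and `make_presynaptic_mask()` as
the preprocessing steps, or in one call via
`run_patch_pipeline(movie, config)` with a `patch_config()` /
`load_config("run.yml")`.

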