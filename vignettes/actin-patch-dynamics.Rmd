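---
title: "Quantifying presynaptic actin patch dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic actin patch dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinpatches)
```

## The measurement problem

At presynaptic terminals such as the *Drosophila* larval neuromuscular
junction (NMJ), filamentous actin assembles in transient, sub-micron
patches -- the force-generating events behind synaptic vesicle
endocytosis. A fluorescent F-actin reporter (GMA, Lifeact, GFP::actin)
imaged by spinning-disc confocal timelapse shows these patches as
short-lived bright foci (~0.6 um across, tens of seconds) on top of a
diffuse baseline of unassembled probe. `actinpatches` turns such movies
into the three headline statistics of patch behaviour:

* **frequency** -- events per 10 um^2 of presynaptic area per minute
  (10 um^2 is roughly one bouton, which makes terminals of different
  size comparable),
* **duration** -- the distribution of patch lifetimes (20-s bins,
  reported at bin centres), and
* **relative amplitude** -- `(Imax - Imin) / Imean` of the intensity
  time course at the patch site.

It also provides a tracking-free counterpart (the per-pixel temporal
coefficient of variation, CoV), a simulation-based calibration that
converts CoV differences between genotypes into inferred
patch-frequency changes, and the supporting quantifications used around
such experiments (masked Pearson colocalization, FRAP double
normalization with recovery fitting).

## The tracking pipeline

The pipeline mirrors the classical particle-tracking recipe for
non-motile, blinking structures:

1. **Projection and registration.** 3-D stacks are reduced per time
   point by maximum projection; Z is never tracked. Frames are aligned
   to the first by FFT cross-correlation with parabolic sub-pixel
   refinement (translation only -- the preparation is fixed in place;
   `max_shift_px` bounds the search).
2. **Mask.** The presynaptic region is segmented once from the
   Gaussian-blurred maximum-over-time projection (`blur_sigma_px`,
   default 2, deliberately a tuning knob) with Otsu, Li, Moments, or a
   fixed threshold. One stable mask per movie is essential: the mask
   area is the denominator of every frequency.
3. **Detection.** Spot candidates are strict local maxima of a
   scale-normalized Laplacian-of-Gaussian response at
   `sigma = diameter / (2 * sqrt(2))` with `diameter = 0.6` um, with
   minimum separation of one spot radius and sub-pixel localization by
   quadratic interpolation. The kernel is contrast-calibrated so that a
   matched Gaussian blob of peak amplitude `A` scores quality `A`: the
   quality is a blob contrast in intensity units.
4. **Threshold.** A candidate is kept if its score exceeds
   `0.32 x` the mean probe intensity in the presynaptic area over the
   whole movie (one global threshold per movie). By default the score is
   the calibrated LoG quality. The alternative reading -- thresholding
   the raw aggregated peak intensity (`threshold_on = "intensity"`) --
   is degenerate on diffuse-baseline signal: inside a bouton the
   baseline itself always exceeds 0.32 x the mean, so an intensity test
   rejects nothing and the linker drowns in noise maxima. A contrast
   measure is the only scale on which a 0.32 x mean cut does useful
   work, and it is what blob detectors natively score.
5. **Linking.** Spots in consecutive frames are linked by the globally
   optimal assignment (an in-package Jonker--Volgenant solver)
   minimizing total squared displacement, links forbidden beyond
   `linking_max_um = 0.5`; no gap closing (`gap_frames = 0`): one
   missed frame terminates a track.
6. **Filtering.** Tracks are rejected if (a) shorter than
   `min_spots = 4` detections (`too_short`; 4 spots is the 16 s floor
   at 0.25 Hz and the 4 s floor at 1 Hz), (b) their median per-frame
   step exceeds `max_median_step_um = 0.15` (half a spot radius;
   `erratic` -- patches are stationary, so a wandering track is a
   tracking defect, typically noise walking along the bouton-edge
   intensity ridge), or (c) they conflict with a concurrent track
   within the linking distance (`overlap`; the shorter member is
   dropped, or both under `overlap_policy = "both"`). Rejection counts
   are reported -- they feed the upper bound of the corrected frequency
   estimate.

**Duration convention.** `duration = n_spots x frame_interval`. This is
the only convention consistent with both printed detection floors
(4 x 4 s = 16 s at 0.25 Hz; 4 x 1 s = 4 s at 1 Hz) and is used
everywhere, including the histogram bins. Censored tracks (touching the
first or last frame) count towards frequency but are excluded from
duration summaries, which their truncated lifetimes would bias
downward.

**Amplitude estimator.** The reported ratio is evaluated on the
disc-aggregated (radius 0.3 um) intensity trace at the track's median
position, smoothed by a 3-frame running median. The in-event level is
the *median* of the trace over the track's lifetime -- a plateau
estimate robust to single-frame noise excursions and to transient
fusion with a neighbouring event -- while `Imin` and `Imean` come from
the pre/post-event baseline (frames outside the track span plus one
flanking frame). Disc aggregation dilutes a diffraction-limited peak by
a computable geometric factor (~0.72 for a 0.255 um sd spot averaged
over a 0.3 um disc), so the excess is rescaled by that factor; for an
isolated noiseless event the estimator then returns the generating
amplitude ratio exactly.

## The merged two-rate frequency estimate

A single sampling rate sees only part of the lifetime distribution:
0.25 Hz acquisitions (89 frames) detect patches of 16--356 s, 1 Hz
acquisitions (139 frames) detect 4--139 s. `merged_frequency_estimate()`
combines paired acquisitions by averaging the frequencies over the
shared range (20--150 s) and adding the regime-specific terms (4--16 s
from the 1 Hz data, 150--360 s from the 0.25 Hz data). The merged value
from accepted tracks is the corrected lower bound; the upper bound adds
every rejected track back (overlap rejects with their measured
durations, sub-floor rejects into the short-range term). Two
conventions had to be fixed here: the ranges are half-open
(`[4,16), [20,150), [150,360)`), and the 16--20 s sliver between the
0.25 Hz floor and the shared range -- which the printed brackets leave
unassigned -- goes to the 1 Hz-only term, since only that regime
actually measures such patches.

## Crowding (pile-up) correction

At realistic event densities, concurrent patches closer than the
detector's pair-resolution radius coalesce into a single response
maximum and are counted once. With lognormal lifetimes of mean 48 s at
6 events/10 um^2/min, the concurrent density is ~0.5 events/um^2 and
this is the dominant counting loss (the same physics that forces the
rejected-track correction in real data). `crowding_corrected_count()`
estimates the loss from the data alone under a spatial Poisson model:
`loss = 0.5 * (1 - exp(-rho * pi * r_f^2))`, with
`r_f = 2 * sqrt(sigma_det^2 + sigma_spot^2)` (~0.66 um at the default
patch size) and the true concurrent density `rho` solved
self-consistently from the observed accepted spot-frame density. The
package's own closed-loop tests show the corrected count is unbiased to
within ~10% for generating frequencies of 3--9 events/10 um^2/min at
these imaging conditions; outside that range the pairwise model
degrades and the correction should be treated as indicative.

## The CoV statistic and its calibration to frequency changes

`cov_map()` computes, per masked pixel, the population standard
deviation of intensity over time divided by the temporal mean. It needs
no threshold and no tracking, is invariant to global intensity scaling,
and increases monotonically with event frequency (a property the test
suite checks on simulated movies). "Highly variant" pixels are defined
by automatic thresholding of the pooled masked CoV values with the Li
minimum-cross-entropy or the Tsai moment-preserving algorithm (both
implemented in-package on 256-bin histograms and verified against
exhaustive criterion scans); both area fractions are always reported,
never silently swapped, and thresholds are computed per movie
(per-NMJ-adaptive), matching how such data are analysed terminal by
terminal.

A CoV difference between genotypes is converted into an implied
patch-frequency change by simulation: `build_calibration_curve()`
simulates movies at several frequency multipliers of a base spec
matched to the experiment's imaging regime, records the mean CoV, and
fits a monotone map (isotonic regression of the per-multiplier means,
then a monotone Hermite cubic -- the response is concave in frequency,
so a piecewise-linear chord would systematically undershoot between
knots and bias the inversion upward). Within each replicate the
multipliers share common random numbers: one master event stream is
drawn at the largest multiplier and thinned to each multiplier by
uniform marks (marginally an exact draw at the reduced rate), and the
noise seed is reused, so the curve's local slopes are far better
determined than with independent draws. `infer_frequency_change()`
inverts the curve at the control and test statistics and reports
`100 * (m_test / m_control - 1)`; statistics outside the calibrated
range are clamped to the edge with a warning. Curves are never reused
across imaging regimes. Mean CoV is the default inversion statistic
(the variant-area fraction is available via config, but it is the CoV
magnitude, not the variant area, that separates genotypes in this kind
of data).

## The synthetic-movie generator

`synthetic_spec()` describes everything the analysis assumes about a
movie, and `simulate_movie()` realizes it with a ground-truth event
table. The defaults are the study conditions this package targets:

| parameter | default | meaning |
|---|---|---|
| geometry | 3 touching discs, r = 2 um | a bouton chain, ~38 um^2 |
| `pixel_size_um` | 0.13 | typical 100x spinning-disc sampling |
| `frame_interval_s`, `n_frames` | 4 s, 89 | the 0.25 Hz regime (356 s); 1 s / 139 frames for 1 Hz |
| `baseline` | 100 | diffuse probe level B inside the mask |
| `event_frequency` | 6 / 10 um^2 / min | resting endocytic-event rate scale |
| `duration_mean_s`, `duration_sd_s` | 48, 45.6 | lognormal lifetimes (positive support with mean >> sd-truncation behaviour) |
| `amplitude_ratio` | 0.68 | event peak added as 0.68 B |
| `spot_sigma_um` | 0.255 | 0.6 um FWHM / 2.355 |
| `edge_blur_um` | = `spot_sigma_um` | one optical train blurs the bouton edge and the patches alike |
| `noise_sigma`, `shot_noise` | 10, on | read noise plus Poisson shot noise |
| `bleach_rate` | 0 | exponential photobleaching, off by default |

Events have rectangular temporal profiles (instant on/off) -- the one
choice that makes ground-truth duration unambiguous -- and isotropic
Gaussian spatial profiles, superposed additively with no exclusion
radius, so the tracker must cope with spatial collisions as in real
data. Event counts are Poisson with mean
`f x (area/10) x minutes`; positions are uniform over the mask; start
frames uniform over the movie; drawn durations are rounded to at least
one frame and clipped at the movie end. A per-pixel flicker mode
(`pixel_mode = TRUE`) replaces spatial events by independently
blinking pixels (`dynamic_pixel_fraction`, `pixel_rate_per_min`) for
validating the CoV statistic against a known dynamic-pixel fraction.

What the generator does *not* emulate -- and what passing closed-loop
tests therefore cannot certify about real data: smooth assembly/
disassembly kinetics (real amplitude trajectories rise and fall),
probe-specific labelling artefacts, focus drift and Z-leakage through
the maximum projection, active-zone substructure, motile particles, and
spatially structured backgrounds beyond the blurred bouton step. The
closed loop certifies the estimators against the stated statistical
model, not against biology.

## Numerical choices and degenerate inputs

* Population (divide-by-n) SD in the CoV -- immaterial at >= 80 frames
  but fixed for exactness; pixels with non-positive temporal mean get
  CoV 0 and are excluded from the mean CoV.
* 256-bin histograms spanning the data range for both auto-thresholds;
  the Li iteration starts from the mean plus three quartile restarts
  and returns the candidate with the lowest cross-entropy (the
  criterion can have plateaus and secondary stationary points);
  degenerate (constant) inputs are errors, not silent zeros.
* The rolling-ball background is grayscale opening with a non-flat
  spherical-cap element; radii above 16 px use the classical
  shrink/process/enlarge speedup, and the background is capped at the
  input so `0 <= output <= input` always holds. Exact equality with any
  specific legacy implementation is not promised -- only the defining
  properties (flat maps to zero; features much smaller than the radius
  survive; idempotence within a small tolerance).
* Registration fills exposed borders with the frame median and clamps
  shifts at `max_shift_px` with a warning when the correlation peak
  sits on the search boundary.
* The LAP linker gives infeasible links a large finite cost; unlinked
  spots cost `linking_max^2`, the standard birth/death alternative.
* FRAP fitting is single-exponential
  (`N0 + (M - N0)(1 - exp(-(t - t0)/tau))`) via Levenberg--Marquardt;
  a flat postbleach trace or a rate constant at its bounds is flagged
  (`unidentifiable` / `fit_failed`), never silently returned. The
  model choice is deliberately simple; mobile fraction is
  `(M - N0)/(1 - N0)`.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` validate the closed loop at
the default study conditions with 20 simulated movies (frequency,
duration, amplitude recovery), 6 paired two-rate acquisitions (merged
estimate), a 6-multiplier x 10-replicate calibration curve with 20
evaluation movies per group (43% frequency-increase inference), 100
random histograms (threshold oracles), and exhaustive assignment
enumeration on frames of up to 4 spots (linking oracle). These sizes
give Monte-Carlo error comfortably inside each check's tolerance while
keeping a full run in the minutes range on one core.

## Known limitations

* Recovery of absolute frequency relies on the crowding correction at
  high event densities; at very low densities (<< 1 concurrent event
  per resolution area) the correction is negligible, and far above
  ~1 event/um^2 concurrent the pairwise model underestimates losses.
* The erratic-track filter assumes stationary patches; it would reject
  genuinely motile structures, which are out of scope here.
* The merged estimator's upper bound counts every rejected track as a
  patch and is exactly that -- an upper bound; at 1 Hz, short noise
  fragments make it loose.
* Masks come from the time-projection once per movie; preparations
  with gross shape change over the movie violate that assumption.
* The calibration inversion is only as good as the match between the
  base spec and the experiment (frame interval, movie length, noise,
  baseline); a curve must be rebuilt per regime.
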