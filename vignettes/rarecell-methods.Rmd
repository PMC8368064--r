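---
title: "Rare-cell analytics for trans-scale fluorescence movies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-cell analytics for trans-scale fluorescence movies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecell)
```

## The problem

Wide-field imaging systems built from a low-magnification machine-vision
lens and a very large CMOS sensor can watch on the order of 10^5^–10^6^
cells simultaneously at a few-micrometre resolution. At that throughput,
events that occur in fewer than one cell in ten thousand per frame become
statistically accessible: spontaneous calcium pulses in an unstimulated
epithelial monolayer, the first cAMP-relaying cells that nucleate
aggregation waves in a starving *Dictyostelium discoideum* population, or
entosis (live-cell engulfment) events. `rarecell` implements the analysis
chain such recordings need — flat-field compensation, nuclei cytometry
with in-phase spatial statistics, rare-pulse detection with a
nearest-neighbour spatial-randomness test, signal-relay tree inference,
and entosis detection — together with a synthetic-movie generator that
plants ground truth, so every stage can be validated by precision/recall
scoring even though raw recordings of this kind are rarely deposited.

## Optical geometry and flat-field compensation

All micrometre/pixel conversions derive from an `optical_config`: a
sensor of 29.2 mm x 20.2 mm with 2.2 um pixels behind a telecentric 2x
lens gives a sample-plane pitch of 1.1 um/px and a field of view (FOV) of
14.6 mm x 10.1 mm (17.8 mm diagonal) — room for ~1.47 million 10 um x
10 um cells. The diffraction-limited lateral resolution is taken as the
full width at half maximum (FWHM) of a Gaussian fitted to a bead profile;
the theoretical value is 0.51 λ/NA (2.21 um at λ = 520 nm, NA = 0.12).
`gaussian_fwhm()` fits offset + amplitude + centre + σ by
Levenberg–Marquardt least squares with deterministic initialisation
(centre at the argmax, σ from the second moment, offset at the minimum)
and returns 2√(2 ln 2) σ.

Illumination non-uniformity and position-dependent lens throughput
multiply the image by a smooth shading field; on a uniform fluorescent
plate their product can push the min/max intensity ratio below 0.6.
`flatfield_correct()` divides the raw image by the plate image normalised
by its **mean** (not its maximum), so corrected intensities keep the raw
scale — this matters for the DNA-content cytometry, where total
intensities across the field must stay comparable. Non-positive reference
pixels are masked to `NA` with a warning rather than silently clamped.

## Nuclei cytometry and in-phase spatial statistics

`segment_nuclei()` is a classical chain — Otsu (or absolute) threshold,
morphological opening/closing, hole filling, watershed on the distance
map, size-band filter — built on EBImage, measuring per nucleus the
intensity-weighted centroid, area, and total fluorescence. A
machine-learning pixel classifier is deliberately not used: no training
data is available, and the bespoke content of this package is the
statistics downstream of segmentation. An M-phase mask (from synthetic
truth, or any external source) can be supplied to `classify_phase()`;
M-phase cells are excluded from the spatial statistics.

Total nuclear fluorescence of a DNA stain is proportional to DNA content,
so an asynchronous population is bimodal: a G1 peak and a G2 peak at
twice its position, with S-phase cells in between.
`intensity_histogram()` finds the two tallest modes of a kernel density
(modes below 5% of the tallest are treated as shoulder wiggles), reports
them as G1/G2 peaks, and `classify_phase()` splits cells at the midpoint
of the two peaks — intensity below the midpoint is G1, at or above is G2
(deterministic half-open convention). S-phase cells necessarily fall into
one of the two groups; this is inherent to the midpoint rule, not an
error to be corrected.

Two statistics quantify whether cells in the same cycle phase cluster
spatially:

* `in_phase_rate_by_order()` — for sampled probe cells of one group, the
  fraction whose k-th nearest neighbour shares their phase, as a function
  of k. Under random labels this equals the group fraction at every k.
* `in_phase_rate_by_radius()` — the fraction of in-phase cells among all
  cells within radius r of a probe, averaged over probes. Its decay
  towards the group fraction carries the spatial scale of the clusters,
  which `cluster_length_fit()` extracts by least-squares fitting
  rate(r) = p~∞~ + A·exp(−r/ℓ).

The exponential-with-offset form is a package decision (the functional
form of such fits is rarely stated in the literature); the asymptote can
be fixed at the group fraction, which stabilises the fit considerably on
single scenes. The probe's own position is excluded from its
neighbourhood, and probes are drawn with a seeded RNG (1000 by default;
all members when the group is smaller).

## Rare calcium-pulse detection and the ANN randomness test

Per-pixel temporal profiles are flattened with a polynomial baseline fit
(order 3 by default; the order is configurable since drift shapes vary).
The fit is made robust by one re-fit pass that excludes frames with
positive residuals above 2σ, so a transient pulse is not absorbed into
the baseline. Candidate pulsing pixels are found by the **skewness map**:
a profile that is flat except for a few positive transients has large
positive third-moment skewness (m~3~/m~2~^3/2^). Pixels above the
skewness threshold (default 1.0, ≈ 6 σ of the null skewness distribution
at 200 frames) are merged into cell regions by connected components, and
local maxima of each region's flattened mean profile exceeding
`noise_k` × 1.4826·MAD (default `noise_k` = 5) become pulse events with
the region centroid and the peak frame.

Spatial randomness of the pulsing cells in frame *i* is tested with the
average nearest-neighbour (ANN) distance

$$W^{(i)} = \frac{1}{M_i}\sum_{j=1}^{M_i} d_j^{(i)},$$

normalised by its edge-free expectation under complete spatial
randomness (CSR), $E[W] \approx 1/(2\sqrt{M_i/S})$, where $S$ is the FOV
area. Under CSR, $W$ for $n$ points in a rectangle of area $S$ and
perimeter $L$ is approximately normal with mean
$0.500\sqrt{S/n} + 0.051\,L/n + 0.041\,L/(n\sqrt n)$. Two variance forms
are provided: the `"printed"` form $0.070\,S/n^2 + 0.037\sqrt{S/n^5}$,
whose second term is dimensionally inconsistent with the first (it lacks
a perimeter factor), and the classical Donnelly edge-corrected form
$0.070\,S/n^2 + 0.037\,L\sqrt S/n^{5/2}$. Monte-Carlo at the FOV
geometry shows the observed spread of $W$ matches the Donnelly form
closely at all $n$ down to $n = 3$ and exceeds the printed form by >20%
at small $n$; the printed form is the documented default for
`ann_null_params()`, and the distribution-level tests and the 3σ
clustering flag use the Donnelly form. Note also that the *empirical
mean* of $W$ contains the edge terms: it approaches the edge-free
$E[W]$ only for $n \gtrsim 500$ in this geometry (+11% at $n = 20$,
+1.9% at $n = 500$), which is why mean-recovery checks of the edge-free
form are run at large $n$.

`information_content()` scores non-randomness as $I(W) = -\log p(W)$
in nats (natural log; the base is a package decision), where $p(W)$ is
the lower-tail normal probability; $I = \ln 2$ at the null median, and
clustering drives $I$ up. `flag_clustered_frames()` flags frames whose
$W$ falls below the null mean minus 3 null standard deviations
(one-sided, clustering only); frames with fewer than two events are
skipped, matching the gaps such plots show. Cells pulsing in several
frames count in each of them.

## Pulse relay trees and wave origins

In the dual-channel reporter system, the signal-sensitive green channel
dims while a cell pulses and the insensitive red channel does not, so the
red/green ratio rises. `ratio_image()` evaluates the ratio only where
both channels exceed intensity thresholds. Candidate pulsing cells are
supra-threshold connected components above a minimum size
(`detect_active_particles()`), linked across consecutive frames within a
maximum migration distance of 16.5 um per 30-s frame
(`link_particles()`, greedy nearest-neighbour, closest pairs first), and
screened: a candidate present in a single frame is discarded, because a
true pulse stays elevated across frames (`screen_single_frame()`). Each
surviving track emits one event at its onset frame.

`build_tree()` infers who triggered whom: an event is a candidate parent
of any event that follows it by lag $F = 1..F_{max}$ frames within
$\sqrt F \cdot D'$, with the pseudo-diffusion coefficient $D' = 250$ um
and sustainment time $F_{max} = 3$ as defaults. A later event can be in
reach of several earlier ones; all candidate links are kept, and one
**primary parent** per child is designated deterministically (smallest
lag, then smallest distance, then lowest event id), which guarantees the
primary links form a forest. `find_wave_origins()` defines an origin as
an event with no candidate parent and at least one primary child — a
solitary pulse is pulsing but not an origin, so pulsing-cell counts and
origin counts are reported separately. Total cell numbers are estimated
by the quadrat method (`quadrat_estimate()`), scaling a count in a small
compartment to the FOV by the area ratio.

## Entosis detection

Entotic inclusions appear as small particles with a high red/green ratio
(the engulfed cell's green reporter is quenched in the acidic phagosome)
that persist far longer than a pulse. `detect_red_particles()` applies a
ratio threshold and a size band (too-small and too-large particles are
judged errors); `link_red_particles()` links within 11 um (10 px) per
frame, with any missed frame terminating the track; and
`classify_entosis()` keeps tracks lasting **more than 10 consecutive
frames**, read strictly as ≥ 11 frames. Since a cAMP pulse stays
elevated for only ~4 frames (~2 min at 30-s intervals), the persistence
rule alone separates the two phenomena and no extra classifier is used.
Durations are reported in frames and minutes, with `duration_histogram()`
and `occurrence_series()` (per-frame onsets plus a trailing rolling-window
sum, default 10 frames) for the population view.

## The synthetic-movie generator

Every detector in the package is validated against
`generate_nuclei_scene()`, `generate_calcium_movie()`,
`generate_dicty_movie()` and `generate_flatfield_pair()`, which plant
events and return truth tables in the same schema the detectors emit
(`score_events()` computes precision and recall by greedy one-to-one
matching). Design choices, and what they do and do not emulate:

* Cells are disks (radius 3 px) with optional σ = 1 px Gaussian blur —
  the blur scale of a low-NA system — not deformable textured cells.
  Noise is Gaussian read noise plus an optional signal-proportional
  variance term; a dark offset keeps the noise floor above zero as a
  camera offset does. Default pulse amplitude is 10x the read noise;
  real signal-to-noise is instrument-specific and the recovery tests
  state their own.
* Calcium movies: static cells, polynomial global drift, isolated pulses
  as per-cell-per-frame Bernoulli events at rarity ~10^−4^ (the regime of
  spontaneous pulsing), and optional propagation clusters in which a
  trigger cell's neighbours within a radius pulse at increasing frame
  lags. Pulses rise one frame before their peak and decay geometrically.
* Phase labels: a white-noise field is spectrally filtered to an
  exponential (Matérn ν = 1/2) autocorrelation, sampled at the cell
  centres, and thresholded at quantiles matching the phase fractions
  (50/15/30/5% for G1/S/G2/M). A Gaussian smoothing kernel was rejected
  because its squared-exponential correlation makes the fitted
  exponential length depend on the cluster scale. The requested
  `cluster_length_um` is defined as the exponential decay length that
  `cluster_length_fit()` recovers; the internal mapping to the field's
  range parameter is affine (`0.74·ℓ/pitch − 5` px), with the offset
  absorbing the discreteness of the cell lattice (~10 um between
  centres), calibrated once by simulating the full
  generate–classify–rate–fit loop at 30 and 60 um. G2 intensities peak at
  2x G1 (CV 8%), S is uniform between the peaks, M-phase cells are drawn
  as split condensed lobes.
* Dual-channel movies: cells random-walk (reflected at the borders) with
  a per-frame step well under the 16.5 um linking limit; pulses dim green
  to 40% for 3 frames; cascades are planted by drawing each child within
  `step_frac`·√lag·D′ of its parent (default 0.8, leaving margin below
  the recovery reach); entotic inclusions are smaller particles with red
  elevated and green at 15%, living `ceiling(Exp(mean))` frames while
  random-walking, their paths steered clear of cell footprints so the
  noiseless detection chain is exact. Reaction–diffusion cAMP dynamics,
  cell division and deformation are out of scope.

Because the generator defines what "truth" means, passing recovery tests
shows the chain is self-consistent at realistic geometry, rarity and
noise — it does not certify performance on real movies with debris,
focus drift, or segmentation-confounding textures.

## Numerical choices and degenerate inputs

* Distances are Euclidean in um (pixel index × pitch); pixel indices are
  0-based with x = column, y = row; physical coordinates are documented
  per table.
* `ann_frame()` returns `NA` below two points; such frames are skipped
  and never flagged. `information_content()` uses `pnorm(log.p = TRUE)`
  for numerical stability in the deep tail.
* `intensity_histogram()` reports `status = "unimodal"` (no phase model)
  rather than guessing when fewer than two modes survive the 5%
  prominence rule; `cluster_length_fit()` reports `status = "failed"` on
  non-decaying input; `gaussian_fwhm()` errors with residual diagnostics
  on non-convergence.
* The exact-intensity tie at the midpoint goes to G2; equal-distance
  linking ties resolve by scan order; primary-parent ties resolve by
  (lag, distance, id). All are deterministic.
* Linking is greedy nearest-neighbour (closest pair first), not a global
  assignment; at the planted densities this is exact, and it mirrors
  what a per-frame particle tracker does.
* Test problem sizes: the pulse-recovery suite uses a 512×512×200 movie
  with 2000 cells at 10^−4^ pulses/cell/frame; CSR nulls use 500
  replicates at n ∈ {20, 100, 500}; cluster-length recovery pools three
  2500-cell scenes per condition. These sizes make every stochastic
  assertion a >3σ call while keeping the full suite a few minutes on one
  CPU.

## Known limitations

* The flat-field model is multiplicative only; stray light and sensor
  fixed-pattern noise are not modelled.
* The skewness screen assumes pulses are positive-going and sparse in
  time; a cell pulsing in a large fraction of frames would lower its
  skewness and could be missed.
* The ANN null treats events as points; at very high event density the
  finite cell size (excluded volume) would bias W upward relative to CSR.
* Greedy linking can swap identities when two particles approach within
  the displacement limit in the same frame pair.
* The quadrat estimator assumes uniform density; it inherits the full
  bias of any real spatial gradient.

## Reproducibility

Every generator takes a `seed` and is byte-deterministic given one; the
pipeline driver (`run_pipeline()`) threads a single seed through each
stage, echoes the configuration into a JSON manifest next to the result
tables, and `scripts/acceptance.R --seed N --out file.json` recomputes
the package's headline quantities from scratch.
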