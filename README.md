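# rarecell

Rare-cell analytics for wide-field ("trans-scale") time-lapse fluorescence
imaging: recordings that watch 10^5–10^6 cells at once at a few-micrometre
resolution, where events occurring in fewer than 0.01% of cells per frame
become statistically accessible. The package is aimed at imaging groups who
build or use such instruments and need a tested, reproducible analysis
chain rather than one-off scripts.

It implements:

* **Optical geometry & flat-field compensation** — µm/pixel conversions
  from sensor and lens parameters, Gaussian-FWHM resolution fitting, and
  shading correction by division with a mean-normalised uniform-plate
  image (`optical_config()`, `gaussian_fwhm()`, `flatfield_correct()`).
* **Nuclei cytometry** — classical segmentation (threshold, morphology,
  watershed, size band), the bimodal DNA-content histogram with G1/G2
  peaks, midpoint phase classification, and two in-phase spatial
  statistics (by neighbour order and by radius) with exponential
  cluster-length fitting (`segment_nuclei()`, `intensity_histogram()`,
  `classify_phase()`, `in_phase_rate_by_radius()`, `cluster_length_fit()`).
* **Rare calcium-pulse detection** — per-pixel baseline flattening,
  skewness screening, robust peak calling, and the average
  nearest-neighbour (ANN) spatial-randomness test with a normal null in a
  rectangular window, an information-content score, and a 3σ clustering
  flag (`detect_pulsing_cells()`, `ann_series()`,
  `flag_clustered_frames()`).
* **Pulse-relay tree networks** — dual-channel ratio imaging, particle
  detection/linking/screening, parent–child inference with a
  pseudo-diffusive reach `√F · D′` (D′ = 250 µm, F ≤ 3 by default), wave
  origins, and quadrat cell-count estimation (`build_tree()`,
  `find_wave_origins()`, `quadrat_estimate()`).
* **Entosis detection** — long-lived high-ratio inclusions: size-banded
  red-particle detection, 11 µm/frame linking, and the strict
  more-than-10-consecutive-frames persistence rule
  (`classify_entosis()`, `occurrence_series()`).
* **A synthetic-movie generator** — every scenario plants ground truth
  (cells, pulses, cascades, inclusions) and returns truth tables in the
  detectors' schema, so each stage is validated by precision/recall
  scoring (`generate_calcium_movie()`, `generate_dicty_movie()`,
  `generate_nuclei_scene()`, `score_events()`).

The core spatial statistic: in frame *i* with M_i pulsing cells, the ANN
is W = (1/M_i) Σ_j d_j, the mean distance of each pulsing cell to its
nearest co-pulsing neighbour; normalised by the complete-spatial-randomness
expectation E[W] ≈ 1/(2√(M_i/S)) for FOV area S, w = W/E[W] ≈ 1 indicates
randomness and w < 1 clustering. Under CSR, W is approximately normal with
mean 0.500√(S/n) + 0.051 L/n + 0.041 L/(n√n) (L the FOV perimeter); the
package provides both the printed variance form 0.070 S/n² + 0.037 √(S/n⁵)
and the Donnelly edge-corrected form 0.070 S/n² + 0.037 L√S/n^{5/2}, and
scores non-randomness as I(W) = −log p(W) nats.

## Worked example

Optical geometry of a 120-megapixel sensor behind a telecentric 2x lens,
then rare-pulse detection on a synthetic movie with planted truth:

```r
library(rarecell)

cfg <- optical_config(29.2, 20.2, 2.2, 2, numerical_aperture = 0.12,
                      wavelength_nm = 520)
fov_dimensions(cfg, display = TRUE)
#>    width_mm   height_mm diagonal_mm
#>        14.6        10.1        17.8

mv <- generate_calcium_movie(n_frames = 100, shape = c(256, 256),
                             n_cells = 500, pulse_prob = 5e-4,
                             n_clusters = 1, cluster_size = 13,
                             cluster_per_step = 6, seed = 11)
ev <- detect_pulsing_cells(mv$stack, pitch_um = 1.1)
head(ev, 3)
#>   event_id cell_id frame x_um  y_um amplitude
#> 1        1       1    75  5.5  39.6  19.97165
#> 2        2       2    68  8.8  70.4  20.15866
#> 3        3       3    23 12.1 257.4  20.24964

score_events(ev, mv$truth, dist_tol_um = 10, frame_tol = 1)[c("precision", "recall")]
#> $precision  [1] 1
#> $recall     [1] 1
```

49 planted events (36 isolated rare pulses plus a 13-cell propagation
cluster around frames 23–25) are all recovered with no false positives.
The ANN randomness test then localises the propagation cluster:

```r
geom <- field_geometry(256 * 1.1, 256 * 1.1)
pts <- lapply(1:100, function(f) {
  e <- ev[ev$frame == f, ]; cbind(e$x_um, e$y_um)
})
ann <- ann_series(pts, geom, form = "donnelly")
flag_clustered_frames(ann)
#> [1] 24
subset(ann, frame == 24, select = c(frame, m, w_obs, w_norm, info))
#>    frame m w_obs w_norm  info
#> 24    24 6 9.733  0.169 8.621
```

Frame 24 — six cluster cells pulsing together — has an observed ANN of
9.7 µm, 0.17x its random expectation, an information content of 8.6 nats,
and is the only frame flagged; the isolated rare pulses elsewhere are
correctly left as spatially random.

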