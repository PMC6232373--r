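# neuritescreen

Image-based screening of neurite alignment and neuronal differentiation on
nanogrooved substrates.

Nanogrooved surfaces (parallel grooves/ridges with periods of a few hundred
nanometres, named `DxxxLyyy`: period `xxx` nm, ridge width `yyy` nm) guide
neurite outgrowth. Screening many groove geometries against flat controls
requires an automated readout of neurite *alignment* and of the culture's
*differentiation state* from multi-channel fluorescence micrographs
(nuclei, F-actin, beta-tubulin III). This package implements that readout
for high-content screening work: cell and neurite detection, per-pixel
orientation analysis, and the nonparametric statistics used to compare
substrates. A seeded synthetic-image generator with full ground truth makes
the whole chain testable without microscope data.

## The core statistic

On a neurite-only image (somata and background removed), the multiscale
Frangi vesselness filter computes the σ²-normalized Hessian of the
Gaussian-smoothed image at each scale σ. With eigenvalues ordered
|λ₁| ≤ |λ₂|,

    V = exp(−R_B² / 2β²) · (1 − exp(−S² / 2c²)),
    R_B = λ₁/λ₂,  S = √(λ₁² + λ₂²),  V = 0 where λ₂ > 0,

maximized over scales; the local ridge orientation is the axial angle of
the λ₁ eigenvector. The **alignment percentage** is the share of
supra-threshold pixels whose orientation lies within 30° (axially) of the
groove direction. Under isotropy — e.g. on flat control substrates, which
carry a conventional reference angle of 0° — the expectation is
100 × 60/180 = **33.3%**. Two independent cross-checks are computed side by
side: a Fourier-spectrum directionality histogram and a per-neurite chord
measurement (straight line from soma attachment to tip).

Detection (HCA-style neuronal feature detection, re-implemented openly)
yields the per-image variables: cell count, differentiated fraction, number
of neurites, neurite lengths, polarity (unipolar/bipolar/multipolar = 1/2/>2
neurites), branching, and the B/U and M/U polarity ratios. The statistics
layer provides Lilliefors normality (Monte-Carlo null), Kruskal–Wallis with
Dunn's post hoc comparisons, Spearman correlation, and median/IQR
summaries.

## Worked example

```r
library(neuritescreen)

# a synthetic culture on a grooved substrate: 10 cells, 80% of neurite
# orientations drawn near the pattern angle of 15 degrees
spec <- scene_spec(n_cells = 10, aligned_fraction = 0.8,
                   pattern_angle_deg = 15, concentration_deg = 8)
gi <- generate_culture_image(spec, seed = 42)

sc <- screen_image(gi$stack, pattern_angle_deg = 15,
                   image_id = "demo", pattern_name = "D600L180")
t(sc$record[, c("n_cells", "n_cells_with_neurites", "n_neurites",
                "mean_neurite_length_um", "alignment_vesselness",
                "alignment_fft", "alignment_chord")])
#> n_cells                10.00000
#> n_cells_with_neurites   6.00000
#> n_neurites             12.00000
#> mean_neurite_length_um 40.65804
#> alignment_vesselness   82.55516
#> alignment_fft          79.85943
#> alignment_chord        83.33333
gi$truth$true_aligned_fraction
#> [1] 0.8461538
```

Ten cells were placed, six formed neurites (differentiated fraction 0.6),
and twelve neurites were traced with a mean length of 40.7 µm. All three
alignment methods agree that roughly 80–83% of the neurite signal lies
within 30° of the groove direction — matching the ground-truth chord-level
fraction of 0.846, and far above the 33.3% isotropic baseline.

Substrate metadata and reference-image angle estimation:

```r
pattern_spec("D600L180", pattern_angle_deg = 15)
#> pattern_spec: D600L180  period 600 nm, ridge 180 nm, groove 420 nm,
#>               L/D 0.3, angle 15.00 deg
estimate_pattern_angle(generate_reference_edge_image(7, seed = 1))
#> [1] 6.96
```

Batch processing is manifest-driven (`run_batch()` with a `run_config()`),
and a thin command-line wrapper with `simulate` / `angle` / `screen` /
`stats` subcommands lives at `inst/cli/neuritescreen.R`.

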