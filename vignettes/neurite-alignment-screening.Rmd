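---
title: "Quantifying neurite alignment on nanogrooved substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurite alignment on nanogrooved substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritescreen)
```

## The measurement problem

Nanogrooved substrates (parallel grooves and ridges with periods of a few
hundred nanometres, named `DxxxLyyy` for a period of `xxx` nm and a ridge
width of `yyy` nm) guide the outgrowth of neurites from differentiating
neuronal cells. Screening many groove geometries requires an automated,
unbiased readout of (i) how strongly neurites align to the groove direction
and (ii) how the culture differentiates: how many cells form neurites, how
long the neurites grow, how many neurites each cell bears (its polarity)
and how often they branch.

`neuritescreen` computes these readouts from three-channel epifluorescence
micrographs (nuclei, F-actin, beta-tubulin III) and screens them across
substrates with nonparametric statistics. Because no public micrograph set
accompanies this problem, the package ships a seeded synthetic-image
generator with complete ground truth; every stage of the pipeline is tested
against that ground truth.

## The alignment statistic

The core quantity is per-pixel. On a *neurite-only* image (cell bodies and
background removed), the multiscale Frangi vesselness filter computes, at
each scale $\sigma$, the $\sigma^2$-normalized Hessian of the
Gaussian-smoothed image. With eigenvalues ordered $|\lambda_1| \le
|\lambda_2|$, the vesselness is

$$V = \exp\!\left(-\frac{R_B^2}{2\beta^2}\right)
      \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
\qquad R_B = \frac{\lambda_1}{\lambda_2},
\quad S = \sqrt{\lambda_1^2 + \lambda_2^2},$$

with $V = 0$ wherever $\lambda_2 > 0$ (bright ridges on a dark background).
The per-pixel response is the maximum over scales, and the local ridge
orientation is the axial angle of the $\lambda_1$ eigenvector at the
maximizing scale. Pixels whose vesselness exceeds a threshold form the
support; the alignment percentage is the share of support pixels whose
orientation lies strictly within 30 degrees (axially) of the groove
direction. Under an isotropic orientation distribution the expectation is
$100 \times 60/180 = 33.3\%$ — the calibration value for flat control
substrates, which carry a conventional reference angle of 0 degrees.

Two independent methods cross-check this statistic:

* **Fourier directionality** — the power spectrum of the (Hann-windowed,
  mean-subtracted) image is binned by orientation. Spectral energy of a
  structure lies perpendicular to it, so the 90-degree rotation is applied
  inside the histogram; the alignment percentage is the band mass within
  the cutoff. Power weighting makes this method emphasize long straight
  structures quadratically, which is the main source of disagreement with
  the per-pixel statistic on sparse images.
* **Chord measurement** — the per-neurite analogue of a manual protocol:
  a neurite counts as aligned when the straight line from its soma
  attachment to its tip lies within the cutoff. It is per-neurite, not
  per-pixel, so long and short neurites weigh equally.

### Angle conventions

All orientations are axial angles in degrees in $[-90, 90)$, measured
counterclockwise from the +x (column) axis, with images stored row-major
and the origin at the top-left. Differences between orientations are taken
modulo 180 (`axial_difference()`), so the cutoff comparison is symmetric
and periodic. The cutoff is strict (`< 30`) — a measure-zero choice for
continuous orientations, made explicit and configurable.

## Feature detection

The per-image variables are produced by a four-stage pipeline
(`screen_image()`):

1. **Soma segmentation** — the smoothed nuclei channel is Otsu-thresholded
   into seed labels (specks below a minimum area or below a robust
   intensity floor of median + 5 MAD are dropped); soma extent grows from
   the seeds over a body mask from the heavily smoothed actin + tubulin
   channels by Voronoi propagation, which splits touching somata.
2. **Neurite skeleton** — the tubulin channel is high-passed (subtracting a
   blurred copy) so soma slopes do not defeat the ridge filter, enhanced
   with multiscale vesselness, hysteresis-thresholded (weak components
   survive only when they contain a strong pixel and rise 4 MAD above the
   residual noise), thinned to one pixel (Zhang-Suen), and pruned of short
   spurs.
3. **Tracing and linking** — skeleton pixels form a weighted graph
   (diagonal steps $\sqrt 2$). Crossings are resolved by angular
   continuity: four-armed junction clusters are cut and near-opposite arms
   reconnected, so crossing neurites do not merge. Each component attaches
   to the soma (or somata) it approaches within the attachment radius; a
   contact that never closely touches the soma and runs straight through
   its neighbourhood is classified as a passing neurite, not an
   attachment. Within the soma neighbourhood arms may still be merged by
   limited optical resolution, so each arm leaving that zone counts as one
   neurite; its length is the longest root-to-tip geodesic plus the
   straight gap back to the soma boundary, and junction clusters beyond
   the zone count as branch points. Polarity is none / unipolar / bipolar
   / multipolar for 0 / 1 / 2 / >2 neurites.
4. **Neurite-only image** — tubulin intensities (background-subtracted) on
   the dilated skeleton support, soma pixels zeroed, edges feathered
   inward so the hard mask edge does not inject perpendicular power into
   the Fourier pathway.

All tunable parameters live in `detection_params()` with documented
defaults; an otherwise wizard-tuned stage is thereby fully reproducible.

## The synthetic generator

`generate_culture_image()` emulates a sparse differentiated culture imaged
at 10x: Gaussian-blob somata with nuclei, neurites as constant-width
Gaussian-profile ridges (about 2–4 px wide) rendered by bilinear sub-pixel
deposition (no staircase bias), Poisson shot noise then additive Gaussian
read noise, over a constant background offset.

Key default choices, made once and documented here:

* **Pixel size 0.65 µm/px, 512 x 512 field** — plausible for a 10x
  objective on a standard camera; calibration is configurable because the
  imaging hardware is not part of the method.
* **10 cells per field** — derived from the protocol this emulates:
  seeding at 1500 cells/cm² puts ~1.7 cells in such a field; modest
  proliferation before differentiation is inhibited brings the fixed
  culture to roughly ten.
* **Neurites per cell with probabilities (0.5, 0.25, 0.15, 0.1)** for
  (0, 1, 2, 3) neurites — a differentiated fraction of one half, in the
  range reported for retinoic-acid/BDNF-differentiated cultures.
* **Neurite length ~ N(45, 12) µm** — matching the tens-of-micrometres
  scale of differentiated neuroblastoma neurites.
* **Orientation mixture** — each neurite's chord orientation is drawn,
  with probability `aligned_fraction`, from an axial wrapped normal around
  the pattern angle (sd `concentration_deg`), otherwise uniformly on
  $[-90, 90)$. The per-step heading wiggles around that chord orientation
  as a mean-reverting process with bounded innovations, so the chord angle
  stays close to the drawn orientation — without mean reversion a random
  heading walk would destroy the requested mixture.
* **Departure sides** — the ±180° departure side of each neurite is chosen
  to spread departure points around the soma. Two neurites leaving one
  boundary point are indistinguishable from a branching neurite, making
  polarity ground truth ill-defined; the axial orientation distribution is
  untouched by this choice.

What the generator does **not** emulate: optical PSF structure beyond
Gaussian profiles, uneven illumination, autofluorescence, touching or
overlapping somata, neurites that start on other neurites, and 3D
structure. Passing tests therefore demonstrate correctness of the
measurement chain under controlled geometry and noise, not performance on
every real-world artifact.

## Statistics layer

Screening variables per image: cell count, differentiated fraction (cells
with at least one neurite over all cells), neurite count, mean neurite
length, polarity counts and their ratios B/U and M/U (missing when no
unipolar cell exists — never infinite), branching fraction per polarity
class, and the three alignment percentages. Ratios that cannot be formed
propagate as missing values and are dropped pairwise, with counts logged.

The tests are nonparametric throughout:

* `lilliefors_test()` — Kolmogorov-Smirnov distance against a normal with
  estimated parameters; the p-value comes from a Monte-Carlo simulation of
  the null (fixed internal seed, 10⁴ replicates by default) rather than a
  critical-value table, removing table-dialect ambiguity.
* `kruskal_wallis()` — tie-corrected H with the chi-square approximation
  (delegated to the standard implementation; the test suite re-derives H
  from the rank-sum formula as an independent oracle).
* `dunns_posthoc()` — pairwise z from pooled tie-corrected mean ranks.
  The multiplicity family is a documented choice: Bonferroni over all
  pairs by default, configurable (`none`/`holm`/`bonferroni`), because
  common implementations of the test differ exactly here.
* `spearman_cor()` — average-rank correlation, two-tailed t-approximation
  p, optional Fisher-transform interval (99% by default, matching a
  screening threshold of P < 0.01).
* `summarize_median_iqr()` — quartiles by type-7 linear interpolation,
  stated explicitly because quantile conventions differ.

The batch runner supports two aggregation levels (per-image observations,
or per-substrate medians) because screening studies report both; the
choice is a config entry, not a hidden default.

## Numerical choices and degenerate inputs

* Gaussian derivative kernels are sampled on an integer grid truncated at
  4σ; the second-derivative kernel is zero-sum corrected so constant
  images produce an exactly null vesselness response.
* The structureness sensitivity `c` adapts per scale to half the maximal
  $S$, making the filter contrast-invariant; structureness below the
  floating-point noise of the convolutions is treated as zero.
* Degenerate Hessians ($\lambda_1 = \lambda_2$) carry no ridge direction;
  such pixels are excluded from the support rather than assigned an
  arbitrary orientation.
* An empty alignment support yields an explicitly undefined result, never
  0%.
* The directionality histogram centres its bins so that 0° (the common
  near-horizontal reference) is a bin centre; the first bin wraps across
  the axial seam. `estimate_pattern_angle()` refines the modal bin by
  parabolic interpolation of its circular neighbours on a 1° grid and
  requires the peak to reach twice the uniform level (an explicit
  dominance criterion), otherwise it asks for a manual angle. Accuracy is
  about ±0.5° for generic angles; angles within ~1–2° of the frequency
  lattice axes (e.g. 89°) can be off by up to ~1° — an intrinsic
  quantization limit of spectral orientation estimation at this image
  size.
* Ties in soma attachment resolve to the lower cell id; reruns with the
  same configuration and seed are bit-identical.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise every code path with
stable statistics: 50 fields x 100 neurites for the isotropy calibration
(mean within 2 percentage points of 33.3%), a 20-scene battery at the
generator defaults for detection recovery (cell counts within 10%, mean
neurite length within 15%, polarity class at least 80% correct), a
30-scene mixed battery for cross-method agreement (pairwise Spearman
r ≥ 0.8 between the vesselness, Fourier and chord statistics — the
cross-method batteries use denser, well-populated scenes, 12 cells with
neurite probabilities (0.1, 0.3, 0.3, 0.3), since comparing estimators on
nearly empty images measures only noise), and 2000 null simulations for
the Kruskal-Wallis type-I calibration (rejection rate in [3.5%, 6.5%] at
α = 0.05).

## Known limitations

* Neurites that merge and run together for long stretches (common in very
  strongly aligned, dense cultures) are resolved only where they cross at
  a clean four-armed junction; zipped parallel segments can still be
  counted as one.
* The chord statistic uses the traced skeleton's endpoint, so its
  agreement with ground truth degrades when tracing fragments a neurite.
* The Fourier alignment needs several structures per image to be stable;
  on nearly empty images it is reported but noisy.
* Lengths are measured on 8-connected geodesics; very tortuous paths are
  slightly underestimated relative to their continuous arc length.
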