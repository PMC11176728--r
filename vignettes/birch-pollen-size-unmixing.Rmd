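---
title: "Measuring birch pollen size and unmixing species proportions"
author: "betulaSize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring birch pollen size and unmixing species proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betulaSize)
```

## The problem

Dwarf birch and tree birch pollen are morphologically so similar that
fossil records cannot separate tundra from forest by identification
alone. Their size distributions differ, however, and within a species
pollen size is close to normally distributed. A mixed sample therefore
has a compound size distribution

$$f(x) = \sum_{k=1}^{K} p_k\, \mathcal{N}(x;\ \mu_k, \sigma_k), \qquad
K \le 4,$$

and the species proportions $p$ can be estimated from many per-grain
size measurements. `betulaSize` implements the measurement geometry,
the quality-control and pooling steps, and the proportion estimator,
together with a synthetic generator that supplies every input with
exact ground truth.

## Measurement model

Two size parameters are computed per grain from a binary outline mask
and a calibration $c$ (µm/px):

* **Area**: foreground pixel count $\times\ c^2$ — the area occupied in
  the polar-view image, not the curved surface area.
* **Rotational mean width**: the Feret diameter $F(\theta)$ (maximum
  horizontal extension after rotating by $\theta$) is evaluated at
  $\theta = 0^\circ, 1^\circ, \dots, 179^\circ$ and averaged.

$F(\theta)$ is computed by projecting the boundary-pixel centers onto
the axis at $\theta$ and taking the extent of the projection plus one
pixel. Projection is mathematically the same as rotating the raster and
measuring horizontally, but avoids resampling error; the test suite
asserts agreement with a brute-force rotate-and-measure oracle (4×
upsampled raster rotation) within one pixel at every angle. Two
conventions are fixed here and matter for very small objects:

* the **+1 px** term makes a one-pixel object one pixel wide rather
  than zero wide;
* concave indentations (e.g. near pores) do **not** reduce the width at
  an angle — the projection extent equals the convex-hull Feret, which
  matches "maximum horizontal extension".

For convex bodies, Cauchy's formula gives mean Feret width =
perimeter$/\pi$; the suite checks this identity on disks, squares,
rectangles and rotated ellipses to within 2%. With the default
1° stepping, 180 angles cover every distinct axis orientation; using
360 angles changes the result by well under 0.5% on smooth convex
masks.

The pixel-center geometry makes measured widths very slightly larger
than the continuous ground truth (≈ 0.5–1 px overall, i.e. ≈ 0.2 µm at
0.25 µm/px). This is visible downstream as a small bias of unmixed
proportions toward the larger-grained species, well inside the
recovery tolerances verified by the tests, but worth knowing when
absolute sizes are compared across instruments.

## Imaging and screening

The package is designed to ingest grain outlines produced elsewhere
(e.g. by a semantic segmentation model) via `importMasks()`. For
self-contained operation it also provides:

* `selectBestFocus()` — picks the sharpest layer of a focus stack by
  the variance of the 3×3 Laplacian response, a standard focus measure
  that decreases monotonically under defocus blur. No particular
  contrast metric is canonical for this step; Laplacian variance was
  chosen for its monotonicity and is configurable in spirit — the
  selection is deterministic with ties broken by the lowest index, and
  invariant under global affine intensity rescaling.
* `segmentGrains()` — a deliberately simple classical fallback (Otsu
  threshold, hole filling, 4-connected labelling, border and area
  gates). Its job is to make the pipeline runnable end to end on
  synthetic scenes, not to match a trained network's accuracy on real
  slides.

`screenGrain()` reproduces the contract of a suitable/unsuitable
classifier with explicit rules: border contact (a truncated grain has
no valid width), solidity below 0.90 (area over convex-hull area — a
proxy for fused, folded or fragmented grains), calibrated area outside
150–1500 µm², and multiple components. Each violated rule contributes
a reason code; the verdict is suitable exactly when no rule fires.
Because the real selection step in a production pipeline is a trained
classifier, `screenGrain()` and `runUnmix()` accept an external verdict
(`external`/`external_suitable`) that overrides the heuristic per
grain, so network outputs can be used verbatim.

Solidity is computed over pixel *corners* (centers ± 0.5) so numerator
and denominator use the same pixel footprint. Touching grain pairs have
solidity ≈ 0.88 — geometrically the minimum for a fused pair of disks,
since deeper overlaps are *more* convex — which is why the synthetic
fused class places pairs just touching: it is both the realistic
outline-merge condition and the hardest one the solidity rule still
catches.

## Per-sample statistics

* **Outlier removal**: values with |z| > 2.5 are removed, and the
  filter is applied twice *with re-estimation of mean and SD between
  passes* — otherwise a second pass could never remove anything. A pass
  removes nothing when the SD is zero or fewer than three values
  remain; the output is always a subsequence of the input. The filter
  is applied per pooled analysis unit (configurable), i.e. on the same
  values that are subsequently fitted.
* **Pooling**: consecutive, non-overlapping runs of five 1-cm samples
  are concatenated (trailing partial bins kept and flagged), because
  single centimetre samples often hold too few birch grains. The
  minimum-count gate of 25 grains is deliberately applied by consumers
  (`unmixRecord()`), not inside `poolSeries()`, keeping pooling a pure
  data operation.
* **Summaries and densities**: mean, sample SD (n−1 denominator,
  matching standard practice; a single value reports SD = 0 with a QC
  note), and Gaussian kernel densities with Silverman's rule-of-thumb
  bandwidth (the `nrd0` default of common plotting functions), so
  density shapes are comparable with conventional diagrams.

## Proportion estimation

The species components $(\mu_k, \sigma_k)$ are **fixed inputs** taken
from reference measurements of modern pollen
(`betulaReference()`; silicone-oil mounted material, both width and
area metrics). Only the proportions are free. Two similarity objectives
are provided:

* `"nll"` (default): mean negative log-likelihood of the observations
  under the mixture — smooth, statistically principled, and exactly
  checkable against an EM-for-weights oracle;
* `"histL2"`: squared L2 distance between empirical and model histogram
  probabilities on a fixed 50-bin grid — a more literal "distribution
  similarity", useful for robustness comparisons.

The optimiser is classic differential evolution (DE/rand/1/bin) over
$K$ raw weights in $[0,1]^K$, normalised by their sum onto the simplex
before evaluation (all-zero candidates are re-sampled). This keeps the
box constraints trivial while guaranteeing a simplex result.
Hyperparameters follow common DE defaults — population $10K$,
$F = 0.8$, $CR = 0.9$, 200 generations — and everything is driven by a
seed that is stored in the result, so fits are bit-reproducible.
Because the per-observation component densities are precomputed, each
DE evaluation is a single $K$-vector operation and a fit takes well
under a second.

Since the likelihood in the weights is concave up to reparameterisation
and the EM oracle converges to the same optimum, the suite requires DE
and EM to agree within 0.01 per coordinate; in practice they agree to
~1e-8. An optional shared location shift can be added to all component
means to absorb a known preparation-related size offset (mounting-medium
swelling); it defaults to off because estimating it from fossil data
alone is not identifiable with the species means also fixed.

Degenerate inputs are handled explicitly: a single-component fit is
$p = 1$ with no optimisation; an all-identical sample is fitted but
flagged `converged = FALSE`; samples under the minimum count are
reported with missing proportions and a reason code rather than
dropped.

The choice of size metric (area vs mean width) is the caller's; both
are supported identically and no conversion between them is attempted.

## The synthetic generator

`makeGrain()` rasterises the radial silhouette
$r(\varphi) = R + A\,\max(0, \cos 3\varphi)^3$ — a disk with three
smooth bumps at 120° spacing emulating the pore protrusions of a
triporate grain in polar view. No published shape model exists for this
silhouette; the cos³ form is the simplest analytic radial function that
produces realistic convex-ish outlines with mild protrusions, and it
admits closed-form ground truth (its polar area integral is elementary,
and its mean width follows from a dense-polygon Feret profile). Ground
truth is computed by a 10× supersampled rasterisation oracle and agrees
with the closed form within 0.5%. `grainSpecForWidth()` inverts the
model so scenes can be built whose grains realise sizes drawn from a
specified species mixture.

`makeScene()` places grains and irregular detritus blobs on one canvas
and labels each grain `clean`, `border_clipped` or `fused`, returning
exact canvas-registered masks for IoU scoring. Detritus is kept clear
of the grains (it emulates debris *near* targets; debris overlapping a
grain is a segmentation-failure mode that the fused class already
covers more controllably). `sampleSizes()` and
`makeStratigraphicRecord()` generate mixture size data with retained
labels and generating proportions.

What the generator does **not** emulate: pollen wall texture and
internal structure, focus blur gradients, illumination fields,
mounting-medium swelling kinetics, and the appearance variability that
motivates trained detectors on real slides. Passing tests therefore
demonstrate correctness of the geometry, statistics and optimisation on
known ground truth — not detector-grade performance on real
micrographs, which requires the upstream networks this package
deliberately treats as external mask providers.

Default study conditions used by the tests and the acceptance script:
grains of base radius ≈ 40 px at 0.25 µm/px (the *B. nana* size class),
scenes of up to ~45 grains, stratigraphic records of ten 1-cm samples
with ~40–60 grains each pooled in bins of five (~200+ grains per pooled
unit, comfortably above the 25-grain gate), mixture fits at n = 500,
and a dwarf-birch step of 0.1 → 0.6 for end-to-end recovery. These
sizes keep every property measurable with tight tolerances while a full
run of suite plus acceptance script completes in a few minutes.

## Numerical choices and edge cases

* 4-connectivity for components (the labelling convention of the
  underlying image library), consistently in validity checks, mask
  splitting and segmentation.
* Raster convention: row-major, pixel (0,0) top-left, pixel centers at
  integer coordinates; crops carry their offset and source dimensions
  so border contact is judged against the original field of view.
* Mixture densities are floored at 1e-300 inside the log so far
  outliers clamp rather than error.
* `which.max` tie-breaking (lowest index) makes focus selection
  deterministic on constant stacks.
* Uniform images yield an empty segmentation rather than an Otsu error.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; record-level operations derive per-sample
  seeds as `seed + i - 1`.

## Known limitations

* The screening heuristic encodes stated criteria (intact single grain,
  in-range size); it makes no claim of matching a trained classifier's
  error profile on real material. Use the external-verdict hook for
  production screening.
* The fallback segmenter assumes dark grains on a bright background and
  will merge touching objects; that is intended (the fused class) and
  caught by screening, but crowded real slides need a proper outline
  detector upstream.
* Reference parameters are preparation-specific (mounting medium,
  acetolysis); fossil material must share the preparation of the
  reference table, and the packaged table covers silicone-oil mounting
  only.
* The small positive width bias of pixel-grid measurement (≈ 0.2 µm at
  0.25 µm/px) slightly favours larger-grained species in unmixing; at
  the calibrations and component separations tested this stays well
  inside the verified recovery error.
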