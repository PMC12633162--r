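---
title: "Methods: models, parameters and numerical choices in voxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in voxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voxkit implements classical image processing for 2-D and 3-D fluorescence
microscopy behind a backend-dispatch layer, together with the quality
metrics, deconvolution and segmentation machinery such pipelines need. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the numerical decisions taken where the
literature leaves them open.

## Backend dispatch

Arrays carry a *residence* tag (`reference` = host, `accelerated` = a
pluggable device backend). `dispatch(op, ...)` routes each mirrored
operation to the backend of its **first array-typed argument** — the
primary-argument rule. This rule is a design choice: it is deterministic,
trivially documentable, and matches the single-array call patterns that
dominate imaging code. Secondary arrays on a different residence are
transferred automatically and the transfer is logged, because implicit
transfers are the classic performance trap of device programming and must be
observable (`dispatch_log()`).

Three degradation guarantees shape the implementation: probing for backends
never raises; `to_device()` on a machine without an accelerated runtime
returns the input unchanged (with a warning-level log record) rather than
erroring; and an accelerated backend that lacks a given operation triggers a
logged host round-trip instead of a failure. With reference residence the
dispatch layer is a strict pass-through: its output is bit-identical to
calling the reference implementation directly, which the test suite asserts.
No accelerated array runtime exists for R in this environment, so the
accelerated slot is exercised by a mock backend registered in the tests;
the contract (residence persistence, fallback round-trips, probe/transfer
semantics) is what the package promises, independent of any one runtime.

## Image quality metrics

**PSNR** is `10·log10(L²/MSE)` with `L` supplied by the caller; identical
inputs return `Inf` rather than erroring, so convergence monitors can
consume the value directly.

**Scale-invariant PSNR.** Restoration methods often recover structure up to
an unknown affine intensity transform. The reference is standardized to
zero mean and unit variance; the estimate is matched to it by the
closed-form least-squares fit `est' = α·est + β` (for a constant estimate,
`α = 0` and only `β` is fitted — a defined result, not an error); PSNR is
then computed with `L = max − min` of the standardized reference. The
standardization makes the value invariant to affine transforms of *either*
argument's scale, and the closed-form fit is checked in the tests against a
grid-search minimizer.

**SSIM** uses the standard luminance/contrast/structure product with
stabilizers `C1 = (0.01·L)²`, `C2 = (0.03·L)²`. Local statistics come from
an n-D sliding window — genuinely 3-D windows on volumes — with *valid*
cropping, so the window (default 7, odd) must fit in every dimension. The
default window is uniform because the test volumes are small and a box
window is the cheapest consistent choice; a Gaussian window (σ = 1.5) is
available by flag. Statistics are population moments, making
`ssim(a, b) == ssim(b, a)` exactly.

**FRC/FSC.** For two images, each FFT sample is assigned to a shell by
rounding its normalized frequency radius onto the grid of the smallest axis
(unit-width bins up to Nyquist, 0.5 cycles/px); per shell the normalized
cross-correlation is accumulated. Cauchy–Schwarz bounds the value in
[−1, 1]; the implementation clamps at the boundary against floating-point
spill. Empty shells are dropped. Resolution is the first crossing of the
correlation below a criterion threshold, linearly interpolated between
shells, reported as 1/f* in pixels; a curve that never crosses is
*unresolved* (`NA`). The default criterion is the fixed 1/7 threshold — the
field's customary choice — with the half-bit curve available.

**Single-image FRC** splits one image into the two diagonal classes of the
pixel checkerboard (`x[odd, odd]` vs `x[even, even]`), computes their FRC,
and multiplies the frequency axis by the 0.5 decimation factor so the curve
reads in original-pixel units. 3-D input uses the central Z-plane. This
split geometry is one of several in use; the diagonal pair was chosen
because both sub-images see the same 2× sub-sampled lattice and therefore
share a Nyquist limit. A caveat follows from the construction: an image
whose high frequencies are *deterministically* shared between the two
diagonal classes (e.g. pure smoothed noise with no detector noise on top)
never decorrelates and is reported unresolved; a noise floor is what makes
the estimator informative.

**Average precision.** IoU is computed on voxel sets; background (label 0)
never matches. Matching is greedy in descending IoU with ties broken by
ascending `(gt_id, pred_id)` — equal to optimal matching whenever IoUs are
distinct, and fully deterministic, which is what a reproducibility contract
needs. `AP = TP/(TP+FP+FN)`; the tests pin hand-computed contingencies,
relabelling/transposition invariance and monotonicity in the threshold.

## Richardson–Lucy deconvolution

The multiplicative update `e ← e · [(o / (e ⊛ p)) ⊛ p̂]` maximizes Poisson
likelihood; `p` is normalized to unit sum on entry, `p̂` is the
coordinate-reversed PSF, and the initial estimate is the observed image
(faster at desk scale than a flat field). Numerical choices:

- **Boundary handling.** The observed image is padded by half the PSF
  extent per axis with edge replication; convolutions are FFT-based (hence
  circular) on that padded canvas; the result is cropped back. This keeps
  circular-wrap artifacts out of the cropped interior for
  interior-supported structures and preserves total flux to within 1%
  (asserted in the tests). The test oracle is an independent direct
  spatial-domain implementation of the same padded-canvas model.
- **Stabilizer.** ε = 1e-12 on the ratio denominator.
- **PSF centring.** The centre voxel is `floor(n/2)` (0-based) per axis,
  which also fixes the convention for even-sized PSFs.
- **Non-negativity.** Negative observed values are clipped to zero with a
  warning; the estimate is clamped non-negative after each update.

**Automatic stopping.** After each iteration the rule's metric is evaluated
between the previous and current estimate (`psnr_vs_previous`,
`ssim_vs_previous`) or on the current estimate alone (`frc_resolution`,
via the single-image FRC of the central plane — documented as the expensive
option). The loop stops once the absolute per-iteration change of the
metric stays below `tolerance` for `patience` consecutive iterations. Two
conventions make the fixed-point case well defined: PSNR between estimates
is saturated to `Inf` beyond 140 dB (differences at that level are float
noise, not signal), and `Inf − Inf` counts as zero improvement — so a delta
PSF converges right after the patience window. The default rule
(`psnr_vs_previous`, tolerance 0.5 dB, patience 1) needs no ground truth;
0.5 dB is a conservative reading of "the estimate has stopped changing" on
data with a dynamic range of order 1. When a ground-truth reference is
supplied, PSNR/SSIM against it are recorded in the trace for inspection but
never used for stopping.

## Monolayer segmentation

The two stages follow the classic hierarchical recipe: nuclei first (they
are compact and high-contrast), then cells grown from nuclear seeds.
All parameters live in `monolayer_config()` with the reference defaults:
nuclei downscale 0.5, median ball radius 5 px, hole area threshold 20 px,
nuclei watershed ball radius 10 px, nuclei minimum size 50 px, 3 membrane
Otsu classes, closing disk radius 17 px at 0.25× mask resolution, seed
erosion ball radius 5 px, cell watershed ball radius 8 px, cell minimum
size 100 px. Radii are isotropic in voxel units, matching the pixel-unit
phrasing of the reference pipeline even on anisotropic stacks; `spacing`
lets the distance transform account for anisotropy when wanted.

Decisions taken where the recipe is underspecified:

- **Normalization** is a 0.1–99.9 percentile stretch to [0, 1], clipped —
  the robust standard for fluorescence, invariant to affine intensity
  changes; a constant channel yields zeros with a warning.
- **Otsu / multi-Otsu** maximize between-class variance over a 256-bin
  histogram; the 3-class search is exhaustive over all bin pairs and is
  verified against a brute-force oracle. Constant images raise a
  degenerate-histogram error.
- **Watershed construction**: Euclidean distance transform of the binary
  mask (separable exact algorithm); markers are plateaus of local maxima
  detected with the stated ball footprint, *labelled with that same
  footprint* so near-coincident discrete maxima of one object merge into a
  single marker; flooding runs on the negated distance map with face
  connectivity and FIFO tie-breaking (deterministic). In the cell stage the
  markers are given (eroded nuclei), so the stated ball radius
  parameterizes maxima detection only when no markers are supplied.
- **Cell-stage relief**: the watershed floods the normalized membrane
  intensity itself, so watershed lines form on the bright membrane ridges
  (equivalently: the inverted cell-interior signal). Flooding an image in
  which ridges were low would draw boundaries inside cells.
- **Monolayer mask**: voxelwise maximum of the three normalized channels
  (the least lossy combination), binarized by Otsu, OR-ed with the
  multi-Otsu membrane foreground, closed slicewise with the disk at reduced
  resolution, and upscaled order-0.
- **Hole filling** operates per Z-slice in 2-D, as small-area hole removal
  on stacks conventionally does; whether 2-D or 3-D is configurable in
  spirit by the area threshold (3-D holes at these scales do not survive
  the closing anyway).
- **Morphology at borders**: out-of-image samples take the operation's
  identity (erosion: foreground, dilation: background) so structures
  touching the volume border are not clipped — without this, closing a
  32×32 downscaled slice with a radius-17 disk would erode a 17-pixel rim.
- **Label canonicalization**: labels are renumbered by descending object
  size, ties by lexicographic centroid, making labelings comparable across
  runs and backends. Upscaling of label images is strictly order-0
  (labels are categorical).

## Rescaling

Orders 0–5 use separable B-spline interpolation: for order ≥ 2 the samples
are converted to spline coefficients by the classical recursive two-pass
pole filter with exact mirror-boundary initialization, then resampled with
the closed-form centred B-spline kernel. Output coordinates map by the
pixel-centre convention `x_in = (i_out + 0.5)/f − 0.5`; output shapes are
`round(shape · f)` with round-half-to-even. These two conventions make the
order-0 up-2×/down-0.5× round trip an exact identity, which the tests
assert, and they reproduce an independent reference interpolator to 1e-9 on
frozen fixtures. Anti-aliasing Gaussian pre-smoothing uses
`σ = √(max(0, f⁻² − 1))/2` per axis and activates only for factors < 1.
The benchmark harness synthesizes a seeded volume per configuration, runs
untimed warmup rounds, then times the up-2×/down-0.5× pair per repeat;
host/device transfers are excluded by placing the array on the backend
before the stopwatch starts, and medians are reported.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, and bit-reproducible; they restore
the caller's RNG state. `make_nuclei_phantom` places non-overlapping
spheres (rejection sampling, ≥2-voxel surface gaps, capacity error after
10,000 attempts) with exact labels. `make_monolayer_phantom` builds a
Voronoi partition of the XY plane from nucleus centres, extrudes it over a
central Z-slab, raises membrane ridges on the cell boundaries (blurred,
σ = 1), fills nuclei as Z-clipped ellipsoids restricted to their own cell
(so nucleus-in-cell containment holds exactly), and adds smooth interior
texture for the mitochondria channel. `degrade` applies the same
padded-boundary convolution as the deconvolution module plus seeded
Poisson/Gaussian noise; `make_band_limited` hard-truncates white noise in
frequency space so FRC ground truth is exact.

Defaults are fixed once as the study conditions: the deconvolution phantom
is 32×64×64 with 4 spheres of radius 5–9 px, PSF σ = (1, 2, 2) px and
Poisson noise at 200 peak counts — desk-scale but non-trivial; the
monolayer phantom is 32×128×128 with 6 cells and nuclear radii 10–12 px,
sized so that the pipeline's pixel-unit radii (median ball 5 at 0.5×
downscale, watershed footprint 10) relate to object sizes the way they do
on the real confocal data the parameters come from (nuclei of order 10 µm
at 65 nm pixels are far larger than the filter radii; phantom nuclei must
be too).

What the phantoms deliberately do not model: realistic optics (depth-variant
or aberrated PSFs), intensity inhomogeneity, touching/overlapping nuclei in
dense tissue, anisotropic resolution, or camera-specific noise. Passing
tests therefore demonstrate algorithmic correctness and pipeline
recoverability under controlled conditions, not segmentation accuracy on
real monolayers.

## Problem sizes and limitations

The test suite and the acceptance script run on deliberately small volumes
(16³–32×128×128; 5–20 seeded replicates per property), chosen as the
smallest sizes at which every pipeline stage still operates in its intended
regime. Known limitations:

- TIFF storage is 32-bit float (rescaled to [0, 1], scale recorded in the
  JSON sidecar) for intensities and 16-/32-bit unsigned for labels; round
  trips are exact at those precisions, not at float64.
- `multi_otsu` supports 2 or 3 classes (exhaustive search); more classes
  would need the recursive formulation.
- The accelerated backend is a registry slot; no GPU runtime ships with the
  package.
- The single-image FRC needs a noise floor to be informative (see above).
- Greedy AP matching can differ from optimal matching on exactly tied IoUs;
  ties are broken deterministically and documented.
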