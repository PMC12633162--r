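# voxkit

Device-agnostic 2-D/3-D bioimage computing for fluorescence microscopy, in R.

Quantitative microscopy pipelines — deblurring, segmentation, quality
control — chain the same classical operations (filtering, thresholding,
distance transforms, watershed, resampling) over increasingly large 3-D
volumes. voxkit packages those operations behind a *backend-dispatch* layer:
every mirrored operation runs on the compute backend on which its input array
resides, falling back transparently to the host (reference) backend when no
accelerated runtime is present, so the same script runs unchanged on any
machine. On top of that layer it implements the pieces such pipelines need
but general-purpose image libraries in R do not provide:

- **Image quality and agreement metrics.** PSNR
  (`10·log10(L²/MSE)`), scale-invariant PSNR (PSNR after the closed-form
  least-squares affine match `est' = α·est + β` to the standardized
  reference), SSIM in 2-D and 3-D with the standard stabilizers
  `C1 = (0.01·L)²`, `C2 = (0.03·L)²`, Fourier ring/shell correlation
  `FRC(s) = Re Σ F₁·F̄₂ / √(Σ|F₁|² · Σ|F₂|²)` per frequency shell with
  resolution read off the 1/7 (or half-bit) threshold crossing, a
  single-image FRC from checkerboard decimation, and instance-segmentation
  average precision `AP(τ) = TP/(TP+FP+FN)` under one-to-one IoU matching.
- **Richardson–Lucy deconvolution with automatic stopping.** The
  multiplicative update `e ← e · [(o / (e ⊛ p)) ⊛ p̂]` with FFT convolutions
  on an edge-replicated padded canvas, plus a stopping rule that monitors an
  image-quality metric between consecutive iterations and halts when its
  per-iteration improvement drops below a tolerance — the point of
  diminishing returns.
- **A two-stage 3-D monolayer segmentation pipeline.** Nuclei from the DNA
  channel (downscale 0.5×, median filter ball r=5, Otsu, hole filling <20 px,
  distance-transform watershed with ball-footprint maxima r=10, upscale, size
  filter ≥50 px), then whole cells by seeded watershed on the membrane
  channel (3-class multi-Otsu, monolayer mask from the combined channels
  closed with a disk r=17 at 0.25× resolution, seeds from ball-eroded nuclei
  r=5, watershed r=8, size filter ≥100 px).
- **Anti-aliased rescaling, orders 0–5.** Separable B-spline interpolation
  with recursive prefiltering, mirror boundaries, and Gaussian pre-smoothing
  (σ = √(max(0, f⁻² − 1))/2 per axis) before downscaling, plus a timing
  harness.
- **Seeded phantom generators** (sphere nuclei, Voronoi-cell monolayers,
  Gaussian PSFs, blur + Poisson/Gaussian degradation, band-limited fields)
  so every claim above is testable on synthetic data with exact ground
  truth.
- **Multi-page TIFF I/O** with axis normalization ((C)ZYX), JSON sidecars,
  YAML pipeline configs and provenance records, and a thin command-line
  front end (`inst/cli/voxkit.R`) with `metrics`, `deconvolve`, `segment`,
  `benchmark` and `simulate` subcommands.

## Worked example

```r
library(voxkit)

# a 32x64x64 sphere phantom, blurred with a Gaussian PSF (sigma 1,2,2 px)
# and degraded with Poisson noise at ~200 peak counts
truth    <- make_nuclei_phantom(phantom_spec(seed = 7, poisson = TRUE))
psf      <- make_gaussian_psf(c(9, 13, 13), sigmas = c(1, 2, 2))
observed <- degrade(truth$image, psf, seed = 7)

fit <- richardson_lucy_auto(observed, psf,
                            rule = stopping_rule("psnr_vs_previous",
                                                 tolerance = 0.5),
                            max_iterations = 40)
fit
#> <rl_deconvolution> 16 iterations (converged), metric psnr_vs_previous
#>   final psnr_vs_previous = 64.52

rng <- diff(range(truth$image))
psnr(truth$image, vol_data(observed), rng)      # 23.79 dB (blurred input)
psnr(truth$image, vol_data(fit$estimate), rng)  # 25.09 dB (deconvolved)
```

The stopping rule halted after 16 iterations because consecutive estimates
stopped changing by more than 0.5 dB; the deconvolved volume gains ~1.3 dB
of PSNR against the known ground truth over the blurred input.

```r
# three-channel monolayer phantom: 6 Voronoi cells with membrane ridges
mp  <- make_monolayer_phantom(phantom_spec(shape = c(32, 128, 128),
                                           n_objects = 6,
                                           radius_range = c(10, 12),
                                           noise_sigma = 0.02, seed = 7))
cfg    <- monolayer_config()       # all pipeline radii/thresholds, as above
nuclei <- segment_nuclei(mp$dna, cfg)
cells  <- segment_cells(mp$membrane, mp$mito, mp$dna, nuclei, cfg)
max(nuclei); max(cells)            # 6 nuclei, 6 cells
average_precision(mp$cells_gt, cells, c(0.5, 0.75))
#>   threshold  ap tp fp fn
#> 1      0.50 1.0  6  0  0
#> 2      0.75 0.5  4  2  2
```

All six cells are recovered with IoU ≥ 0.5 against the Voronoi ground truth
(AP@0.5 = 1.0); at the stricter IoU 0.75 four of six still match.

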