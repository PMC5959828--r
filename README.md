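# physgrid

Physically grounded image analysis in R: intensity-based registration,
segmentation evaluation and spherical-fiducial localization for 2-D/3-D
scalar images that carry their geometry with them.

Medical and biological images are not arrays: each voxel grid occupies a
physical region of space, described by an origin, per-axis spacing and a
direction cosine matrix. Ignoring that geometry silently corrupts every
downstream measurement. `physgrid` makes the geometry a first-class part
of the image type (`grid_image`) and builds on it:

* **Transforms** — centered matrix-offset transforms
  `T(x) = A(x − c) + t + c` (translation, rigid, similarity, affine),
  bounded displacement fields `x ↦ x + D(x)`, and composite transforms
  with stack semantics (*first added, last applied*), plus JSON
  serialization.
* **Resampling** — onto any reference grid through any transform, and
  isotropic resampling that preserves the physical extent.
* **Registration** — the virtual-domain three-transform model
  `ᵐp = T_opt(T_m(T_f⁻¹(ᶠp)))`, mean-squares and sampled
  mutual-information metrics, geometric-center initialization,
  parameter scales derived from physical shift (so radians and
  millimeters get comparable steps), multi-resolution smooth+shrink
  schedules, and a seeded, bit-reproducible sampling scheme.
* **Segmentation evaluation** — reference construction by majority vote
  and STAPLE (EM estimation of a consensus plus per-rater
  sensitivity/specificity), volumetric overlap measures (Dice, Jaccard,
  volume similarity, FN/FP fractions) and directed surface-distance
  statistics from an exact anisotropy-aware Euclidean distance map.
* **Fiducial localization** — a bright spherical marker is localized
  inside a box ROI either by Otsu threshold → largest component →
  centroid + equivalent-sphere radius, or by 3-D edge detection →
  least-squares sphere fit (algebraic seed + Gauss–Newton refinement).
* **I/O and data sharing** — MetaImage (`.mha`/`.mhd`) and NRRD
  read/write; resource control via the `PHYSGRID_SHRINK` environment
  variable (read-then-resample, no code changes); MD5-verified,
  cache-aware data fetching from a JSON manifest.
* **Synthetic fixtures** — deterministic generators for multi-modal
  registration pairs with known truth, multi-rater segmentations with
  known performance, and fiducial volumes, so the entire suite runs
  without downloading anything.

## Worked example

Multi-modal rigid registration on a synthetic pair with known ground
truth (the moving image is the fixed image resampled through a rigid
transform — 0.1 rad about the volume center plus a (3, −2, 1) mm shift —
and intensity-inverted to emulate a second modality):

```r
library(physgrid)

truth <- rigid_transform(angle = c(0.1, 0, 0), translation = c(3, -2, 1),
                         center = c(31.5, 31.5, 31.5))
pair <- make_registration_pair(truth, "invert", size = c(64, 64, 64), seed = 20)

prob <- registration_problem(
  pair$fixed, pair$moving,
  t_opt_init = initialize_geometric_center(pair$fixed, pair$moving, "rigid"),
  metric = "mutual_information", sampling_fraction = 0.01, mi_bins = 50,
  convergence_tol = 1e-8, max_iterations = 150,
  schedule = list(c(4, 2), c(2, 1), c(1, 0)), seed = 7)
res <- register(prob)
res
#> registration_result
#>   final metric: -0.7277901
#>   stop reason : converged
#>   iterations  : 107 over 3 levels
#> rigid transform (3-D)
#>   parameters: -0.0989446, 0.000243473, 0.00156964, -2.80191, 2.2953, -1.03454
#>   center    : 31.5, 31.5, 31.5
```

The pair was generated by resampling *through* `truth`, so registration
recovers its inverse: composing the estimate with `truth` gives a
rotation error of 0.0019 rad and a 0.042 mm displacement at the volume
center — about 1/25 voxel, from 1 % voxel sampling.

Consensus segmentation from five simulated raters (sensitivity 0.90,
specificity 0.95) on a 48³ sphere:

```r
truth_mask <- make_sphere_mask(c(48, 48, 48), 1, center = rep(23.5, 3), radius = 10)
raters <- make_rater_stack(truth_mask, 5, 0.90, 0.95, seed = 11)
st <- staple(raters)
st
#> staple_result: 5 raters, 16 iterations (converged)
#>   sensitivity p: 0.8839, 0.8792, 0.8885, 0.8870, 0.8827
#>   specificity q: 0.9495, 0.9505, 0.9498, 0.9500, 0.9508
overlap_measures(st$consensus, truth_mask)
#> overlap_report: dice 0.9813, jaccard 0.9633, volume similarity +0.0162, fnf 0.0107, fpf 0.0266
```

The estimated per-rater performance lands within ~0.02 of the simulated
rates, and the consensus Dice against the (normally unknown) truth is
0.98. The directed surface-distance report
(`surface_distance_measures()`) has median 0 mm here; its `max` — the
directed Hausdorff distance — is sensitive to single stray consensus
voxels by construction.

A command-line wrapper covering registration, resampling, evaluation,
STAPLE, fiducial localization, data fetching and fixture generation is
installed at `inst/cli/physgrid.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "physgrid.R", package = "physgrid"))')" \
    register --fixed fixed.mha --moving moving.mha --metric mi \
    --sampling 0.01 --seed 7 --out transform.json --trace trace.csv
```

## Scope

Scalar 2-D/3-D images only; no DICOM, no B-spline/diffeomorphic
registration, no GUI. The methods vignette
(`vignettes/physically-grounded-image-analysis.Rmd`) documents the
models, parameter defaults, numerical choices and known limitations.
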