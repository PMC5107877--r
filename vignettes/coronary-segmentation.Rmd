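---
title: "Statistical region growing for coronary CTA: models, parameters, design"
author: "coroSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical region growing for coronary CTA: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coroSeg implements a fully automated coronary-artery segmentation pipeline
for contrast cardiac CT angiography (CTA). This vignette explains the
science each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, and the numerical and design choices made where the underlying
method leaves room.

## The pipeline

Four stages run in fixed order, each a pure function of its inputs, the
configuration, and the seed:

1. **Heart extraction** — multi-atlas segmentation. Each labelled reference
   image is registered to the patient volume in two stages: an affine
   transform minimising the mean squared intensity difference over random
   samples, then a cubic B-spline free-form deformation maximising a
   localized mutual information. Atlas heart labels are propagated through
   the recovered transforms (nearest neighbour) and fused by strict-majority
   voting.
2. **Vessel enhancement** — a multiscale Hessian line filter applied inside
   the heart region. At each scale the image is convolved with analytic
   Gaussian second-derivative kernels, the 3×3 Hessian is eigendecomposed
   per voxel and the eigenvalues, magnitude-sorted |λ₁| ≤ |λ₂| ≤ |λ₃|, feed
   the bright-line measure
   |λ₃|·(λ₂/λ₃)^γ₂₃·w(λ₁;λ₂)^γ₁₂, which is maximal for tubes
   (λ₁ ≈ 0, λ₂ ≈ λ₃ < 0), zero for blobs and plates. Responses are
   σ²-normalised and the per-voxel maximum over scales is kept.
3. **Seed detection** — voxels at or above 120 HU whose enhancement response
   exceeds a floor form the candidate mask; a 3D box erosion (4 × 4
   in-plane × 3 across slices) removes thin or isolated responses so that
   every surviving voxel lies well inside an artery. Each survivor becomes a
   seed, in raster order.
4. **Region growing with a heuristic bounds decision** — for each unabsorbed
   seed, the mean m and population standard deviation d over its
   26-neighbourhood define the acceptance interval [m − v·d, m + v·d]; a
   26-connected flood fill from the seed through in-interval voxels joins
   the region, and seeds already absorbed are skipped. The interval is then
   re-estimated from the whole region and the region expanded to closure,
   repeated up to 5 times. Because the right v varies across patients, the
   pipeline sweeps v = 1.0, 1.1, … and watches the segmented-voxel count
   N(v): when the interval engulfs the myocardium, N jumps by a large
   fraction of the heart region (the "mutation"); the selected v is the last
   value before the jump.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| seed threshold | 120 | HU | conservative lumen/myocardium separator for contrast CTA |
| erosion kernel | (3, 4, 4) | voxels (z, y, x) | 4×4 in-plane, 3 across the thicker slice axis |
| vesselness floor | 0 | response (≈ HU) | minimal enhancement for seed eligibility; raise to ~10 in fields of view with strong blob edges (chambers) |
| scales σ | 0.5–3 | mm | should bracket the target lumen radii; defaults cover coronaries at sub-millimetre resolution |
| γ₂₃, γ₁₂, α | 1, 1, 0.25 | — | line-filter sharpness and asymmetry tolerance |
| v₀, step | 1.0, 0.1 | — | sweep start and grid |
| mutation threshold | 0.5 of heart-ROI voxels | — | relative mode; the absolute 1e8 count is available as `mode = "absolute"` |
| refinement iterations | 5 | — | statistics re-estimations after seed growth |
| variance floor | 1 | HU | lets uniform plateaus grow (degenerate zero-variance seeds) |
| affine iterations | 256 | — | fixed gradient-descent budget, split evenly over pyramid levels |
| MI neighbourhood | 50 | mm | cube side for the localized similarity samples |
| histogram bins | 32 | — | joint-histogram resolution over the 1st–99th intensity percentiles |
| B-spline control spacing | 16 | mm | free-form lattice pitch for heart-scale anatomy |

Two parameter groups deserve comment because they must be *matched to the
data*, not taken as universal constants. The enhancement scales must
bracket the lumen radii of the vessels of interest; on the 32 mm reference
phantom, whose tubes have 1.2–1.5 mm radii, the package's own studies use
σ ∈ {0.75, 1, 1.25} mm. Likewise the B-spline control spacing must be finer
than the deformation wavelength: the synthetic atlas deformations have
wavelengths of the order of the phantom extent (16–32 mm), so the phantom
registration studies use a 6 mm lattice, while 16 mm is appropriate for
heart-scale anatomy at clinical fields of view.

## The phantoms

`makeCardiacPhantom()` rasterises a lung background (−800 HU), a myocardium
ellipsoid (60 HU), a blood-pool ellipsoid (300 HU) and contrast tubes (peak
350 HU) along curved centerlines inside the myocardium. The tube radial
profile is the ideal Gaussian line scaled so the intensity is at least half
the peak inside the nominal lumen radius; the profile is truncated at the
lumen wall, and a 0.5-voxel Gaussian blur then produces a realistic
partial-volume edge (without it, region growing would be trivially exact).
Centerlines are sampled at arc steps of a quarter voxel and each voxel
takes the maximum profile over samples, so curved tubes have no
rasterisation gaps. The gold vessel mask marks voxels within the nominal
radius of any centerline; the gold heart mask is the ellipsoid union the
tubes. All noise flows through one explicit seed; identical specs give
bit-identical phantoms.

The phantom deliberately emulates only the *intensity ordering and
morphology* that the pipeline's contracts depend on: lung ≪ myocardium <
120 HU < lumen, tubes thin and curved, a bright blob (the pool) that the
vesselness gate must reject, soft partial-volume edges. It does not emulate
anatomy (no real coronary tree, no chamber geometry), acquisition physics
(no beam hardening, motion, or streak artifacts), nor patient variability.
Passing the phantom studies therefore demonstrates the *mechanics* of the
method — seed purity, interval nesting, mutation detection, sub-voxel
registration recovery — not clinical accuracy on real scans.

`makeTwoPopulationPhantom()` is the controlled scene for the sweep: a
straight tube whose intensities carry a deterministic two-level ±10 HU
texture with *exact* mean 300 and standard deviation 10 (the darker level
is made at least as frequent so the nominal bound is attained), embedded in
myocardium held exactly at 60 HU. With stochastic myocardium noise the
flooding point would be governed by noise tails and 26-connectivity
percolation (which sets in around 10% occupancy, i.e. more than a full
standard deviation before the interval reaches the myocardium mean), making
the jump location unpredictable on the 0.1 sweep grid and contaminating the
pre-jump region with tail voxels. The deterministic texture keeps the
vessel population's dispersion real while making the jump exactly
predictable from the measured region statistics: the first grid v with
m − v·d ≤ 60, which is where the sweep is observed to jump.

`makeAtlasSet()` warps the base phantom through known smooth maps (small
affine about the volume centre plus two low-frequency sinusoidal
displacement waves) and returns the maps, so registration accuracy can be
scored as a landmark error |φ(T(x)) − x| without inverting anything.

## Numerical choices

- **Axis conventions.** Arrays are (z, y, x), 1-based; world coordinates
  are (x, y, z) mm with `world = origin + (index − 1)·spacing`. Nothing in
  the method depends on the convention; it is fixed once and used
  everywhere, including the seed CSV (`k,j,i,x_mm,y_mm,z_mm`).
- **Anisotropic spacing** is honoured wherever millimetres are meant
  (Gaussian derivative kernels, MI neighbourhood, B-spline lattice, surface
  distances) and ignored where voxel counts are meant (N(v), erosion
  kernel, 26-neighbourhoods).
- **Derivative kernels** are sampled analytically per axis and
  moment-corrected (zero DC; unit first/second moment) so that responses
  match continuous derivatives on polynomials; boundaries replicate edges.
- **Eigenvalues** use the closed-form trigonometric solution for symmetric
  3×3 matrices, vectorised over voxels, with the acos argument clamped to
  [−1, 1]; the isotropic (p → 0) branch returns the triple eigenvalue
  exactly. Magnitude ordering (the line-filter convention) is used, not
  signed ordering.
- **Intervals are closed** ([low, high] inclusive); the growing's standard
  deviation is the population estimator, floored at 1 HU.
- **Erosion with even kernels** anchors at floor(d/2) per axis;
  out-of-bounds counts as background. The separable min-filter
  implementation is contractually identical to the structuring-element-fit
  definition and is tested against a brute-force oracle.
- **Tie votes** (even atlas counts) resolve to background: the heart ROI is
  deliberately conservative, since the growing stage re-expands within it.
- **SSD is averaged over retained samples** (those mapping inside the
  moving image), the consistent estimator when samples are random.
- **MI histograms** span the 1st–99th percentile of each image's sampled
  intensities with hard bins for the reported value; the B-spline optimiser
  uses a cubic-kernel Parzen window on the moving axis so the objective is
  differentiable, with the analytic gradient flowing through the Parzen
  window, the trilinear interpolation and the spline support weights. Fewer
  than two occupied bins on a marginal yields 0 with a warning.
- **Step control.** The affine stage takes normalised gradient steps in a
  scaled parameter space (translations in mm; linear part scaled by the
  image extent) with geometric decay within each pyramid level; the
  B-spline stage backtracks (halves the step up to five times) whenever the
  objective decreases on the iteration's own sample set.
- **The sweep selects v_{i−1}**, the last pre-jump value: selecting the
  jump value itself would return the oversegmented result the mutation is
  meant to reject. A jump at the very first increment selects v₀ with a
  warning; no jump by the safety cap selects the cap with a warning.
- **Jump magnitudes.** The conventional absolute thresholds (10⁷/10⁸ voxels)
  exceed the voxel count of a typical scan, so they cannot both be literal
  counts; the relative mode (default 0.5 of the heart-ROI voxel count) is
  the robust default and the absolute mode is kept as a documented option.
- **Refinement granularity.** Each of the 5 refinement passes expands to
  closure (BFS until no neighbour qualifies) before statistics are
  re-estimated; region statistics use all region voxels. Existing region
  voxels are never dropped, even if a re-estimated interval excludes them.
- **Growth is clipped to the heart mask**, which prevents leakage through
  the coronary ostia into the aorta from dominating N(v); a region touching
  the mask boundary is logged as possible leakage.
- **Threshold placement.** The 120 HU test applies to the original
  intensities (HU is only meaningful there), gated by a positive
  enhancement response; setting the floor to −Inf recovers a pure HU
  threshold.

## Known limitations

- The line filter responds at curved step edges (chamber and pool
  boundaries), not only at tubes. On the phantom the blood pool's interior
  picks up a residual response of up to ~20 units against a tube-axis
  response of ~60; the phantom studies therefore gate seeds at a floor
  of 10 with scales matched to the lumen. On real data the same gating
  logic applies at the ventricles.
- Sweep monotonicity of N(v) holds on all tested phantoms but is not a
  theorem: because absorbed seeds never contribute their own intervals, a
  pathological seed ordering could in principle shrink a region as v grows.
  The package checks monotonicity empirically rather than enforcing it as a
  class invariant.
- Majority voting needs registrations to fail independently; with few
  atlases a single bad registration dominates. Failed registrations are
  excluded with a warning rather than silently fused.
- The B-spline stage optimises a localized objective with stochastic
  sampling; it inherits the usual caveats (local maxima, sampling noise),
  mitigated by the affine initialisation, the pyramid, and backtracking.
- MetaImage support covers the common axis-aligned little-endian subset;
  oblique orientation matrices in NIfTI headers are not interpreted.

## Problem sizes

The package's own studies (tests and the acceptance script) run on 64³
phantoms at 0.5 mm isotropic spacing: large enough for three pyramid
levels, realistic tube curvature and a meaningful sweep, small enough that
the full suite runs in minutes on one CPU. Oracle-equivalence checks use
hundreds of random volumes up to 12³–16³, where brute-force BFS, erosion
and pairwise-distance oracles are exact and fast.
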