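# coroSeg

Fully automated coronary-artery segmentation from contrast cardiac CT
angiography (CTA), for image-analysis researchers and pipeline builders who
need a tested, scriptable implementation with synthetic ground truth.

Segmenting the coronaries is the first step of stenosis assessment, and it
has to run without interaction to be useful clinically. coroSeg chains four
automated stages:

1. **Heart extraction** by multi-atlas registration: affine (mean squared
   intensity difference over random samples, fixed gradient-descent budget)
   then cubic B-spline free-form deformation (localized mutual information
   from one random centre voxel plus samples in a 50 mm cube), both
   pyramid-accelerated; propagated atlas labels are fused by strict
   majority vote.
2. **Vessel enhancement** with a multiscale Hessian line filter. With
   eigenvalues magnitude-sorted |λ₁| ≤ |λ₂| ≤ |λ₃|, the bright-line
   response is |λ₃| (λ₂/λ₃)^γ₂₃ w(λ₁; λ₂)^γ₁₂ — maximal for tubes
   (λ₁ ≈ 0, λ₂ ≈ λ₃ < 0), zero for blobs and plates — σ²-normalised and
   maximised over scales.
3. **Seed detection**: voxels ≥ 120 HU with positive vesselness, eroded by
   a 4 × 4 × 3 box so every surviving voxel lies inside an artery.
4. **Statistical region growing with a heuristic bounds decision**: each
   seed's 26-neighbourhood statistics define an acceptance interval
   I = [m − v·d, m + v·d]; flood fills grow the region (absorbed seeds are
   skipped), then the interval is re-estimated from the whole region for up
   to 5 refinement passes. The bounds multiplier v is chosen automatically
   by sweeping v = 1.0, 1.1, … and detecting the abrupt jump ("mutation")
   in segmented-voxel count N(v) that signals the interval has engulfed the
   myocardium; the selected v is the last pre-jump value.

Everything is testable offline: a seeded phantom generator produces CTA-like
volumes (lung −800 HU, myocardium 60 HU, blood pool 300 HU, contrast tubes
with Gaussian radial profiles and optional stenosis) with gold-standard
heart and vessel masks, plus synthetic atlas sets with known deformations.
Quality is scored with Dice overlap and symmetric mean/maximum surface
distances (MSD/MAXSD, mm).

## Worked example

```r
library(coroSeg)

ph  <- makeCardiacPhantom(phantomSpec(noiseSdHU = 0))   # volume + gold masks
cfg <- pipelineConfig(
  vesselness = vesselnessParams(sigmasMM = c(0.75, 1, 1.25)),  # match lumen radii
  seeds      = seedDetectionParams(vesselnessFloor = 10))      # reject pool edges
res <- runPipeline(ph$volume, heartMask = ph$heartGold, config = cfg)
res
#> SegmentationResult
#>   heart ROI: 62280 voxels
#>   seeds:     167
#>   vessels:   2888 voxels at v = 2.4 (mutation)

segmentationMetrics(res@vesselMask, ph$vesselGold)[c("dice", "msd_mm", "maxsd_mm")]
#> $dice
#> [1] 1
#> $msd_mm
#> [1] 0
#> $maxsd_mm
#> [1] 0
```

The sweep trace (`sweepTrace(res@sweep)`) shows N(v) creeping from 1263 to
2888 voxels over v = 1.0…2.4, then exploding to 54594 at v = 2.5 — the
mutation; the selected segmentation at v = 2.4 matches the gold tubes
voxel-for-voxel on this noiseless phantom. The 167 seeds all lie inside the
gold vessels: the 120 HU threshold alone would also pass the 300 HU blood
pool, but the vesselness gate (scales matched to the 1.2–1.5 mm lumen
radii, floor 10) rejects it.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/coroseg.R phantom --out-dir phantom/ --noise-sd 0
Rscript inst/cli/coroseg.R run --input phantom/volume.nii.gz \
    --heart-mask phantom/heart_gold.nii.gz --out-dir out/
Rscript inst/cli/coroseg.R eval --seg out/vessel_mask.nii.gz \
    --gold phantom/vessel_gold.nii.gz --out report.json
```

Subcommands: `phantom | heart | enhance | seeds | grow | eval | run`.

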