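# Analysis configuration matched to the reference phantom: enhancement
# scales bracket the phantom lumen radii (1.2-1.5 mm), the vesselness floor
# sits well below a true axis response (~60 response units) but above the
# residual blob/edge response of the blood pool, and the B-spline lattice is
# finer than the synthetic deformation wavelength (which is of the order of
# the 32 mm phantom extent).
phantomVesselness <- function()
  vesselnessParams(sigmasMM = c(0.75, 1, 1.25))

phantomSeedParams <- function()
  seedDetectionParams(vesselnessFloor = 10)

phantomRegOptions <- function(seed = 11L)
  registrationOptions(rngSeed = seed, bsplineControlSpacingMM = 6,
                      nBsplineIterations = 400L)

phantomPipelineConfig <- function(seed = 17L)
  pipelineConfig(vesselness = phantomVesselness(),
                 seeds = phantomSeedParams(),
                 registration = phantomRegOptions(),
                 rngSeed = seed)

# Landmark error of a recovered patient-to-atlas transform against the known
# synthetic deformation: |phi(T(x)) - x| over heart voxels.
landmarkError <- function(base, atlas, transform, n = 300) {
  idx <- which(volData(base$heartGold))
  idx <- idx[seq(1, length(idx), length.out = n)]
  kji <- coroSeg:::.linToKJI(as.integer(idx), gridDim(base$volume))
  w <- voxelToWorld(base$volume, kji)
  mapped <- deformationApply(atlas$deformation, transformPoints(transform, w))
  sqrt(rowSums((mapped - w)^2))
}
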