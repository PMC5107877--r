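test_that("the SSD cost matches hand-computed values", {
  set.seed(2)
  a <- array(rnorm(10^3, 100, 20), c(10, 10, 10))
  fixed <- Volume3D(a)
  idt <- affineTransform3D()
  pts <- cbind(sample(2:9, 20, TRUE), sample(2:9, 20, TRUE),
               sample(2:9, 20, TRUE))
  expect_equal(ssdCost(fixed, fixed, idt, pts), 0)
  # moving = fixed + c everywhere: cost is exactly c^2
  expect_equal(ssdCost(fixed, Volume3D(a + 12), idt, pts), 144)
  # one sample, intensities 100 vs 90: cost 100
  f1 <- Volume3D(array(100, c(4, 4, 4)))
  m1 <- Volume3D(array(90, c(4, 4, 4)))
  expect_equal(ssdCost(f1, m1, idt, matrix(c(2, 2, 2), 1)), 100)
  # all samples outside the moving domain: undefined
  far <- affineTransform3D(translation = c(1000, 0, 0))
  expect_error(ssdCost(fixed, fixed, far, pts), "outside")
})

test_that("the Gaussian pyramid halves shape and doubles spacing per level", {
  vol <- Volume3D(array(rnorm(64^3), c(64, 64, 64)), spacing = c(0.5, 0.5, 0.5))
  pyr <- gaussianPyramid(vol, 3)
  expect_length(pyr, 3)
  expect_equal(gridDim(pyr[[2]]), c(32L, 32L, 32L))
  expect_equal(gridDim(pyr[[3]]), c(16L, 16L, 16L))
  expect_equal(voxelSpacing(pyr[[3]]), c(2, 2, 2))
  expect_length(gaussianPyramid(vol, 1), 1)
  # a constant volume stays constant at every level
  cpyr <- gaussianPyramid(Volume3D(array(5, c(32, 32, 32))), 3)
  for (p in cpyr) expect_equal(range(volData(p)), c(5, 5))
  # truncation below 8 voxels per axis
  expect_warning(p2 <- gaussianPyramid(Volume3D(array(0, c(16, 16, 16))), 4),
                 "truncated")
  expect_length(p2, 2)
})

test_that("label warping is exact for identity and integer translations", {
  m <- randomMask(c(8, 8, 8), 0.4, seed = 31)
  lab <- BinaryMask3D(m)
  grid <- Volume3D(array(0, c(8, 8, 8)))
  idw <- warpLabels(lab, affineTransform3D(), grid)
  expect_identical(volData(idw), m)
  # T(x) = x + 2 voxels along x: content shifts by -2 along i
  tr <- warpLabels(lab, affineTransform3D(translation = c(2, 0, 0)), grid)
  expect_identical(volData(tr)[, , 1:6], m[, , 3:8])
  expect_true(all(!volData(tr)[, , 7:8]))
  expect_setequal(unique(as.vector(volData(tr))), c(TRUE, FALSE))
})

test_that("majority voting implements the strict-majority rule", {
  d <- c(4, 4, 4)
  one <- BinaryMask3D(array(TRUE, d))
  zero <- BinaryMask3D(array(FALSE, d))
  expect_true(all(volData(majorityVote(list(one, one, zero)))))   # 2 of 3
  expect_false(any(volData(majorityVote(list(one, zero)))))       # tie -> 0
  expect_identical(volData(majorityVote(list(one, one, one))),
                   volData(one))
  # fused output is bounded by intersection and union
  m1 <- BinaryMask3D(randomMask(d, 0.5, 1)); m2 <- BinaryMask3D(randomMask(d, 0.5, 2))
  m3 <- BinaryMask3D(randomMask(d, 0.5, 3))
  fused <- volData(majorityVote(list(m1, m2, m3)))
  expect_false(any(fused & !(volData(m1) | volData(m2) | volData(m3))))
  expect_true(all(fused[volData(m1) & volData(m2) & volData(m3)]))
  expect_error(majorityVote(list()), "at least one")
})

test_that("affine self-registration stays near the identity and reduces the cost", {
  ph <- makeCardiacPhantom(phantomSpec(noiseSdHU = 0))
  opts <- registrationOptions(nAffineIterations = 60L,
                              nSamplesPerIteration = 1024L, rngSeed = 3L)
  aff <- affineRegister(ph$volume, ph$volume, opts)
  expect_lt(max(abs(aff@matrix - diag(3))), 0.02)
  expect_lt(max(abs(aff@translation)), 0.25)       # within half a voxel
  set.seed(1)
  pts <- cbind(sample(10:54, 400, TRUE), sample(10:54, 400, TRUE),
               sample(10:54, 400, TRUE))
  expect_lte(ssdCost(ph$volume, ph$volume, aff, pts),
             ssdCost(ph$volume, ph$volume, affineTransform3D(), pts) + 1e-9)
  # determinism under a fixed seed
  aff2 <- affineRegister(ph$volume, ph$volume, opts)
  expect_identical(aff@matrix, aff2@matrix)
  expect_identical(aff@translation, aff2@translation)
})

test_that("a known translation is recovered to sub-voxel accuracy", {
  spec <- phantomSpec(noiseSdHU = 0)
  base <- makeCardiacPhantom(spec)
  atl <- makeAtlasSet(spec, 1, translationsMM = list(c(1.5, -0.5, 1.0)))
  aff <- affineRegister(base$volume, atl[[1]]$volume,
                        registrationOptions(rngSeed = 11))
  idx <- which(volData(base$heartGold))
  idx <- idx[seq(1, length(idx), length.out = 200)]
  kji <- coroSeg:::.linToKJI(idx, gridDim(base$volume))
  w <- voxelToWorld(base$volume, kji)
  err <- sqrt(rowSums((deformationApply(atl[[1]]$deformation,
                                        transformPoints(aff, w)) - w)^2))
  expect_lt(median(err), 0.25)   # half a voxel at 0.5 mm spacing
})
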