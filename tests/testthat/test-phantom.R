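test_that("the ideal line phantom matches its closed form", {
  lp <- makeLinePhantom(c(16, 17, 17), sigmaVoxels = 2, peak = 350)
  a <- volData(lp)
  ctr <- 9L   # (17 + 1) %/% 2
  expect_equal(a[5, ctr, ctr], 350)                       # on-axis: peak
  expect_equal(a[5, ctr, ctr + 2L], 350 * exp(-1 / 2))    # r = sigma
  expect_equal(a[5, ctr + 6L, ctr], 350 * exp(-4.5))      # r = 3 sigma
  expect_error(makeLinePhantom(sigmaVoxels = 0), "sigmaVoxels")
})

test_that("phantom tissue levels are ordered and reproducible", {
  spec <- phantomSpec(noiseSdHU = 0)
  ph <- makeCardiacPhantom(spec)
  a <- volData(ph$volume)
  # every gold vessel voxel is above the 120 HU seed threshold
  expect_gt(min(a[volData(ph$vesselGold)]), 120)
  # lung voxels away from the partial-volume transition sit exactly at -800
  farLung <- !volData(erodeMask(BinaryMask3D(!volData(ph$heartGold),
                                             grid = ph$volume),
                                c(7, 7, 7)))
  expect_equal(max(abs(a[!farLung & !volData(ph$heartGold)] + 800)), 0,
               tolerance = 1e-6)
  # gold vessel mask is inside the gold heart mask
  expect_false(any(volData(ph$vesselGold) & !volData(ph$heartGold)))
  # determinism: same spec + seed, bit-identical including noise
  s2 <- phantomSpec(noiseSdHU = 10, seed = 99L)
  expect_identical(volData(makeCardiacPhantom(s2)$volume),
                   volData(makeCardiacPhantom(s2)$volume))
})

test_that("thresholding the noiseless phantom at 120 HU inside the heart recovers a vessel superset and no lung", {
  ph <- makeCardiacPhantom(phantomSpec(noiseSdHU = 0))
  a <- volData(ph$volume)
  thr <- a >= 120 & volData(ph$heartGold)
  expect_true(all(thr[volData(ph$vesselGold)]))
  lung <- !volData(ph$heartGold) & a <= -700
  expect_false(any(thr & lung))
})

test_that("a 0.5 radius stenosis over 5 mm quarters the minimal cross-section area", {
  n <- 81L
  sp <- c(0.5, 0.5, 0.5)
  z <- seq(4, 36, length.out = n)
  cl <- cbind(rep(16, n), rep(16, n), z)
  radii <- stenoseRadii(cl, rep(2, n), centerMM = 16, extentMM = 5,
                        factor = 0.5)
  spec <- phantomSpec(shape = c(80, 64, 64), spacing = sp,
                      centerlines = list(cl), radiiMM = list(radii),
                      heartSemiaxesMM = c(14, 14, 18),
                      poolSemiaxesMM = c(3, 3, 3), noiseSdHU = 0)
  ph <- makeCardiacPhantom(spec)
  perSlice <- apply(volData(ph$vesselGold), 1, sum)
  # compare inside the tube body (away from the rounded end caps): the
  # stenosis spans z = 17.5-22.5 mm, i.e. slices 36-46
  nominal <- max(perSlice[21:61])
  expect_equal(min(perSlice[36:46]) / nominal, 0.25, tolerance = 0.15)
})

test_that("centerlines escaping their bounds are rejected", {
  cl <- cbind(seq(0, 40, length.out = 20), rep(16, 20), rep(16, 20))
  expect_error(makeCardiacPhantom(
    phantomSpec(centerlines = list(cl), radiiMM = list(1.5))),
    "ellipsoid|escapes")
})

test_that("atlas generation honours known deformations", {
  spec <- phantomSpec(noiseSdHU = 0)
  base <- makeCardiacPhantom(spec)
  # zero deformation: atlases identical to the base phantom
  atl0 <- makeAtlasSet(spec, 2, deformMagnitudeVox = 0)
  expect_equal(volData(atl0[[1]]$volume), volData(base$volume))
  expect_identical(volData(atl0[[2]]$label), volData(base$heartGold))
  # pure translation by 5 voxels along x shifts the label centroid by 5
  atl <- makeAtlasSet(spec, 1, translationsMM = list(c(5 * 0.5, 0, 0)))
  cen <- function(m) colMeans(which(volData(m), arr.ind = TRUE))
  shift <- cen(atl[[1]]$label) - cen(base$heartGold)
  expect_equal(unname(shift[3]), -5, tolerance = 0.1)   # i (x) axis
  expect_equal(unname(shift[1:2]), c(0, 0), tolerance = 0.1)
  # labels remain consistent with images under the warp
  expect_setequal(unique(as.vector(volData(atl[[1]]$label))), c(TRUE, FALSE))
  # three atlases means three pairs
  expect_length(makeAtlasSet(spec, 3, deformMagnitudeVox = 2, seed = 4), 3)
})

test_that("the two-population phantom has exact first and second moments", {
  tp <- makeTwoPopulationPhantom()
  vals <- volData(tp$volume)[volData(tp$vesselGold)]
  expect_lte(abs(mean(vals) - 300), 0.2)
  expect_lte(abs(sqrt(mean((vals - mean(vals))^2)) - 10), 0.05)
  expect_setequal(unique(vals), c(290, 310))
  # darker level at least as frequent: the interval bound is attained
  expect_gte(sum(vals == 290), sum(vals == 310))
  expect_true(all(volData(tp$volume)[!volData(tp$vesselGold)] == 60))
})
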