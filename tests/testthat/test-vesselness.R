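test_that("the Hessian of a constant volume vanishes", {
  h <- hessianAtScale(Volume3D(array(7, c(16, 16, 16))), 1.5)
  for (comp in list(h@xx, h@yy, h@zz, h@xy, h@xz, h@yz))
    expect_lt(max(abs(comp)), 1e-10)
})

test_that("the Hessian of an axis-aligned ideal line has the bright-line signature", {
  lp <- makeLinePhantom(c(32, 33, 33), sigmaVoxels = 2, peak = 100)
  h <- hessianAtScale(lp, 2)
  ctr <- 17L
  expect_lt(abs(h@zz[16, ctr, ctr]), 0.02 * abs(h@xx[16, ctr, ctr]))
  expect_equal(h@xx[16, ctr, ctr], h@yy[16, ctr, ctr], tolerance = 1e-6)
  expect_lt(h@xx[16, ctr, ctr], 0)
  # closed form: the line convolved with a matched Gaussian has on-axis
  # second derivative -peak * s0^2 / (s0^2 + s^2)^2, gamma-normalised by s^2
  expect_equal(h@xx[16, ctr, ctr], -100 * 4 / (4 + 4)^2 * 4,
               tolerance = 0.01)
})

test_that("mixed derivatives agree with a central finite-difference oracle", {
  set.seed(3)
  base <- array(rnorm(20^3), c(20, 20, 20))
  sp <- c(0.8, 1, 1.2)
  vol <- Volume3D(base, spacing = sp)
  sig <- 2.5
  h <- hessianAtScale(vol, sig)
  smooth <- coroSeg:::.gaussSmooth3(base, sig, sp)
  core <- 6:15
  for (cmp in list(list(h@xy, 2, 3), list(h@xz, 1, 3), list(h@yz, 1, 2),
                   list(h@xx, 3, 3), list(h@zz, 1, 1))) {
    # Richardson-extrapolated central differences (4th-order oracle)
    fd <- (4 * fdSecondDeriv(smooth, sp, cmp[[2]], cmp[[3]], 1L) -
             fdSecondDeriv(smooth, sp, cmp[[2]], cmp[[3]], 2L)) / 3 * sig^2
    got <- cmp[[1]][core, core, core]
    want <- fd[core, core, core]
    # agreement is limited by the kernel sampling error, O((h/sigma)^2)
    expect_lt(max(abs(got - want)) / max(abs(want)), 0.05)
  }
})

test_that("closed-form eigenvalues match the general-purpose eigensolver", {
  set.seed(11)
  for (rep in 1:100) {
    m <- matrix(rnorm(9, sd = 5), 3, 3)
    m <- (m + t(m)) / 2
    ev <- coroSeg:::.symEig3(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3],
                             m[2, 3])
    got <- sort(c(ev$hi, ev$mid, ev$lo))
    want <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("eigen fields are magnitude-sorted and satisfy the trace identity", {
  set.seed(5)
  vol <- Volume3D(array(rnorm(12^3, sd = 100), c(12, 12, 12)))
  h <- hessianAtScale(vol, 1.2)
  e <- eigenvaluesSorted(h)
  expect_true(all(abs(e@l1) <= abs(e@l2) + 1e-9))
  expect_true(all(abs(e@l2) <= abs(e@l3) + 1e-9))
  tr <- h@xx + h@yy + h@zz
  su <- e@l1 + e@l2 + e@l3
  expect_lt(max(abs(tr - su) / pmax(abs(tr), 1e-6)), 1e-6)
  # a diagonal Hessian (0, -4, -4) sorts to lambda = (0, -4, -4)
  ev <- coroSeg:::.symEig3(0, -4, -4, 0, 0, 0)
  expect_equal(c(ev$hi, ev$mid, ev$lo), c(0, -4, -4))
})

test_that("an ideal line's eigenvalues obey lambda1 ~ 0, lambda2 ~ lambda3 << 0", {
  lp <- makeLinePhantom(c(32, 33, 33), sigmaVoxels = 2, peak = 100)
  e <- eigenvaluesSorted(hessianAtScale(lp, 2))
  ctr <- 17L
  l1 <- e@l1[16, ctr, ctr]; l2 <- e@l2[16, ctr, ctr]
  l3 <- e@l3[16, ctr, ctr]
  expect_lt(abs(l1), 0.02 * abs(l3))
  expect_lt(l2, 0)
  expect_lt(l3, 0)
  expect_equal(l2, l3, tolerance = 1e-6)
})

test_that("the line measure scores tubes, not blobs or plates", {
  ef <- function(l1, l2, l3)
    new("EigenField", l1 = array(l1, c(1, 1, 1)), l2 = array(l2, c(1, 1, 1)),
        l3 = array(l3, c(1, 1, 1)), spacing = c(1, 1, 1),
        origin = c(0, 0, 0))
  p <- vesselnessParams()
  expect_equal(volData(lineMeasure(ef(0, -5, -5), p))[1], 5)   # ideal line
  expect_equal(volData(lineMeasure(ef(-5, -5, -5), p))[1], 0)  # blob
  # bright plane: lambda2 -> 0- kills the response
  expect_lt(volData(lineMeasure(ef(0, -1e-4, -5), p))[1], 1e-3)
  # dark structures (positive eigenvalues) give exactly zero
  expect_equal(volData(lineMeasure(ef(0, 2, 5), p))[1], 0)
  # responses are never negative
  set.seed(8)
  e <- eigenvaluesSorted(hessianAtScale(
    Volume3D(array(rnorm(10^3), c(10, 10, 10))), 1))
  expect_gte(min(volData(lineMeasure(e, p))), 0)
})

test_that("multiscale vesselness selects the matched scale and respects the mask", {
  # two parallel tubes of different widths in one volume
  d <- c(40, 41, 81)
  a <- array(0, d)
  for (i in seq_len(d[3])) for (j in seq_len(d[2])) {
    r2a <- (j - 21)^2 + (i - 21)^2
    r2b <- (j - 21)^2 + (i - 61)^2
    a[, j, i] <- 100 * exp(-r2a / (2 * 1^2)) + 100 * exp(-r2b / (2 * 2.5^2))
  }
  vol <- Volume3D(a)
  mask <- BinaryMask3D(array(TRUE, d), grid = vol)
  p <- vesselnessParams(sigmasMM = c(1, 2.5))
  ms <- multiscaleVesselness(vol, mask, p, returnScales = TRUE)
  expect_equal(volData(ms$scaleMM)[20, 21, 21], 1)
  expect_equal(volData(ms$scaleMM)[20, 21, 61], 2.5)
  # zero outside the heart mask by construction
  m2 <- array(FALSE, d); m2[, , 1:40] <- TRUE
  out <- multiscaleVesselness(vol, BinaryMask3D(m2, grid = vol), p)
  expect_true(all(volData(out)[, , 41:81] == 0))
  expect_error(multiscaleVesselness(vol, BinaryMask3D(array(FALSE, d),
                                                      grid = vol), p),
               "empty")
})

test_that("the response is linear in image contrast", {
  lp1 <- makeLinePhantom(c(24, 25, 25), sigmaVoxels = 2, peak = 100)
  lp2 <- makeLinePhantom(c(24, 25, 25), sigmaVoxels = 2, peak = 200)
  mask <- BinaryMask3D(array(TRUE, c(24, 25, 25)), grid = lp1)
  p <- vesselnessParams(sigmasMM = c(1, 2, 3))
  r1 <- volData(multiscaleVesselness(lp1, mask, p))[12, 13, 13]
  r2 <- volData(multiscaleVesselness(lp2, mask, p))[12, 13, 13]
  expect_equal(r2 / r1, 2, tolerance = 1e-9)
})

test_that("tube response on the axis dominates the myocardium interior response", {
  ph <- makeCardiacPhantom(phantomSpec(noiseSdHU = 0))
  resp <- multiscaleVesselness(ph$volume, ph$heartGold, phantomVesselness())
  core <- volData(erodeMask(ph$vesselGold, c(3, 3, 3)))
  # myocardium proper: the ~60 HU tissue at least 2 mm away from the tubes,
  # the blood pool and the lung boundary (the curved organ boundary carries
  # a genuine edge response that is not "interior")
  myo <- volData(ph$heartGold) & !volData(ph$vesselGold) &
    volData(ph$volume) < 150
  myoInterior <- volData(erodeMask(BinaryMask3D(myo, grid = ph$volume),
                                   c(9, 9, 9)))
  r <- volData(resp)
  expect_gte(min(r[core]) / unname(quantile(r[myoInterior], 0.99)), 10)
  # strict separation: the seed floor can sit between the two populations
  expect_gt(min(r[core]), max(r[myoInterior]))
})
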