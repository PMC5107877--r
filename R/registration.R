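#' Registration options
#'
#' Settings of the two-stage (affine, then B-spline) atlas-to-patient
#' registration. The affine stage minimises the mean squared intensity
#' difference over randomly drawn samples with a fixed budget of gradient
#' descent iterations; the B-spline stage maximises a localized mutual
#' information computed from one random centre voxel plus samples in a
#' 50 mm cube around it. Both stages run coarse-to-fine on a Gaussian
#' pyramid with the iteration budget split evenly across levels.
#'
#' @param nAffineIterations total affine gradient-descent iterations.
#' @param nSamplesPerIteration random intensity samples per iteration.
#' @param pyramidLevels Gaussian pyramid levels (1 = no pyramid).
#' @param bsplineNeighborhoodMM side (mm) of the cubic sampling
#'   neighbourhood of the localized mutual information.
#' @param nHistogramBins intensity bins of the joint histogram.
#' @param stepSizes affine step length (mm) per pyramid level,
#'   coarse-to-fine; NULL derives them from the level spacing.
#' @param nBsplineIterations total B-spline ascent iterations.
#' @param bsplineControlSpacingMM control-point spacing of the free-form
#'   lattice, mm.
#' @param bsplineStepMM initial coefficient step (mm), halved by
#'   backtracking when the objective decreases.
#' @param rngSeed seed controlling all random sampling (registration is
#'   deterministic given the seed).
#' @return a classed parameter list.
#' @export
registrationOptions <- function(nAffineIterations = 256L,
                                nSamplesPerIteration = 2048L,
                                pyramidLevels = 3L,
                                bsplineNeighborhoodMM = 50,
                                nHistogramBins = 32L,
                                stepSizes = NULL,
                                nBsplineIterations = 240L,
                                bsplineControlSpacingMM = 16,
                                bsplineStepMM = 0.5,
                                rngSeed = 17L) {
  stopifnot(nAffineIterations >= 0, nSamplesPerIteration > 0,
            pyramidLevels >= 1, bsplineNeighborhoodMM > 0,
            nHistogramBins >= 2, nBsplineIterations >= 0,
            bsplineControlSpacingMM > 0, bsplineStepMM > 0)
  structure(list(nAffineIterations = as.integer(nAffineIterations),
                 nSamplesPerIteration = as.integer(nSamplesPerIteration),
                 pyramidLevels = as.integer(pyramidLevels),
                 bsplineNeighborhoodMM = bsplineNeighborhoodMM,
                 nHistogramBins = as.integer(nHistogramBins),
                 stepSizes = stepSizes,
                 nBsplineIterations = as.integer(nBsplineIterations),
                 bsplineControlSpacingMM = bsplineControlSpacingMM,
                 bsplineStepMM = bsplineStepMM,
                 rngSeed = as.integer(rngSeed)),
            class = "RegistrationOptions")
}

#' Construct an affine transform
#'
#' @param matrix 3x3 linear part.
#' @param translation numeric(3) mm.
#' @return an [AffineTransform3D-class].
#' @export
affineTransform3D <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  new("AffineTransform3D", matrix = matrix,
      translation = as.numeric(translation))
}

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "AffineTransform3D", function(transform,
                                                           points) {
  sweep(points %*% t(transform@matrix), 2, transform@translation, "+")
})

#' @rdname transformPoints
#' @export
setMethod("transformPoints", "BSplineTransform3D", function(transform,
                                                            points) {
  transformPoints(transform@bulk, points) +
    .bsplineDisplacement(transform, points)
})

setMethod("show", "AffineTransform3D", function(object) {
  cat("AffineTransform3D\n  matrix:\n")
  print(signif(object@matrix, 5))
  cat("  translation (mm):", signif(object@translation, 5), "\n")
})

setMethod("show", "BSplineTransform3D", function(object) {
  d <- dim(object@coefficients)
  mx <- max(abs(object@coefficients))
  cat(sprintf("BSplineTransform3D: %d x %d x %d control lattice, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@gridSpacing, 4), collapse = "/")))
  cat(sprintf("  max |displacement coefficient| = %.3g mm\n", mx))
})

# Trilinear interpolation of a volume at world points, with optional
# intensity gradient in world mm. Points outside the domain are flagged.
.interpTrilinear <- function(vol, ptsWorld, gradient = FALSE) {
  d <- gridDim(vol)
  if (any(d < 2L))
    stop("trilinear interpolation needs at least 2 voxels per axis")
  cc <- worldToVoxel(vol, ptsWorld)
  if (!is.matrix(cc)) cc <- matrix(cc, nrow = 1)
  rr <- round(cc)
  snap <- abs(cc - rr) < 1e-7
  cc[snap] <- rr[snap]
  inside <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
    cc[, 3] >= 1 & cc[, 3] <= d[3]
  n <- nrow(cc)
  value <- rep(NA_real_, n)
  grad <- if (gradient) matrix(NA_real_, n, 3) else NULL
  if (any(inside)) {
    ci <- cc[inside, , drop = FALSE]
    f <- floor(ci)
    for (ax in 1:3) f[, ax] <- pmin(pmax(f[, ax], 1), max(d[ax] - 1L, 1L))
    t1 <- ci[, 1] - f[, 1]; t2 <- ci[, 2] - f[, 2]; t3 <- ci[, 3] - f[, 3]
    a <- vol@data
    g <- function(dk, dj, di)
      a[.kjiToLin(cbind(f[, 1] + dk, f[, 2] + dj, f[, 3] + di), d)]
    v000 <- g(0, 0, 0); v100 <- g(1, 0, 0); v010 <- g(0, 1, 0)
    v110 <- g(1, 1, 0); v001 <- g(0, 0, 1); v101 <- g(1, 0, 1)
    v011 <- g(0, 1, 1); v111 <- g(1, 1, 1)
    c00 <- v000 * (1 - t1) + v100 * t1
    c10 <- v010 * (1 - t1) + v110 * t1
    c01 <- v001 * (1 - t1) + v101 * t1
    c11 <- v011 * (1 - t1) + v111 * t1
    c0 <- c00 * (1 - t2) + c10 * t2
    c1 <- c01 * (1 - t2) + c11 * t2
    value[inside] <- c0 * (1 - t3) + c1 * t3
    if (gradient) {
      sp <- voxelSpacing(vol)
      # d/dt3 (x axis), d/dt2 (y), d/dt1 (z); convert to per-mm
      dk <- ((v100 - v000) * (1 - t2) + (v110 - v010) * t2) * (1 - t3) +
        ((v101 - v001) * (1 - t2) + (v111 - v011) * t2) * t3
      dj <- ((c10 - c00) * (1 - t3) + (c11 - c01) * t3)
      di <- (c1 - c0)
      grad[inside, ] <- cbind(di / sp[3], dj / sp[2], dk / sp[1])
    }
  }
  list(value = value, grad = grad, inside = inside)
}

#' Mean-squared-difference registration cost
#'
#' The affine dissimilarity: the average of squared intensity differences
#' between the fixed image at the sample voxels and the moving image at the
#' transformed sample positions (trilinear interpolation). Samples mapping
#' outside the moving domain are dropped from the average.
#'
#' @param fixed,moving [Volume3D-class] images.
#' @param t an [AffineTransform3D-class] (or any transform with a
#'   [transformPoints()] method).
#' @param samplePoints n x 3 integer matrix of fixed-voxel indices (k, j, i).
#' @return non-negative scalar.
#' @export
ssdCost <- function(fixed, moving, t, samplePoints) {
  sp <- if (is.matrix(samplePoints)) samplePoints
    else matrix(samplePoints, nrow = 1)
  fv <- fixed@data[.kjiToLin(sp, gridDim(fixed))]
  w <- voxelToWorld(fixed, sp)
  if (!is.matrix(w)) w <- matrix(w, nrow = 1)
  iv <- .interpTrilinear(moving, transformPoints(t, w))
  if (!any(iv$inside))
    stop("SSD cost undefined: all samples map outside the moving domain",
         call. = FALSE)
  mean((fv[iv$inside] - iv$value[iv$inside])^2)
}

# Split an iteration budget evenly over pyramid levels (remainder to the
# coarsest level so the total is exact).
.splitIterations <- function(total, levels) {
  base <- total %/% levels
  out <- rep(base, levels)
  out[1] <- out[1] + total - base * levels
  out
}

#' Gaussian pyramid of a volume
#'
#' Level 1 is the original; each further level smooths with a one-voxel
#' Gaussian and subsamples every second voxel, doubling the spacing. Levels
#' that would fall below 8 voxels on any axis are dropped with a warning.
#'
#' @param vol a [Volume3D-class].
#' @param levels requested number of levels (>= 1).
#' @return list of [Volume3D-class], finest first.
#' @export
gaussianPyramid <- function(vol, levels) {
  if (levels < 1) stop("levels must be >= 1")
  out <- list(vol)
  cur <- vol
  while (length(out) < levels) {
    d <- gridDim(cur)
    if (any(ceiling(d / 2) < 8)) {
      warning(sprintf("pyramid truncated at %d level(s): next level below 8 voxels per axis",
                      length(out)), call. = FALSE)
      break
    }
    a <- cur@data
    sp <- voxelSpacing(cur)
    for (ax in 1:3)
      a <- .convAxis(a, .gaussKernel1D(sp[ax], sp[ax], 0L), ax)
    a <- a[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
    cur <- Volume3D(a, spacing = sp * 2, origin = voxelOrigin(cur))
    out <- c(out, list(cur))
  }
  out
}

#' Affine registration by stochastic gradient descent on the SSD cost
#'
#' Runs exactly \code{nAffineIterations} gradient-descent steps (split
#' evenly over the pyramid levels, coarse to fine) on the mean squared
#' intensity difference, with fresh random samples each iteration and an
#' analytic gradient through the trilinear interpolation. Parameters are
#' scaled so a step moves the translation by about the scheduled length in
#' mm; steps decay geometrically within each level. Deterministic given
#' \code{opts$rngSeed}.
#'
#' @param fixed patient image (registration target).
#' @param moving atlas image.
#' @param opts a [registrationOptions()] list.
#' @return an [AffineTransform3D-class] mapping fixed world coordinates to
#'   moving world coordinates.
#' @export
affineRegister <- function(fixed, moving, opts = registrationOptions()) {
  withSeed(opts$rngSeed, {
    pf <- gaussianPyramid(fixed, opts$pyramidLevels)
    pm <- suppressWarnings(gaussianPyramid(moving, opts$pyramidLevels))
    nl <- min(length(pf), length(pm))
    pf <- pf[seq_len(nl)]; pm <- pm[seq_len(nl)]
    iters <- .splitIterations(opts$nAffineIterations, nl)
    extent <- max((gridDim(fixed) - 1) * voxelSpacing(fixed))
    scales <- c(rep(extent, 9), rep(1, 3))
    p <- c(as.vector(diag(3)), 0, 0, 0)
    it_global <- 0L
    for (lev in rev(seq_len(nl))) {   # coarse -> fine
      f <- pf[[lev]]; m <- pm[[lev]]
      d <- gridDim(f)
      nIter <- iters[lev]
      if (nIter == 0L) next
      step0 <- if (!is.null(opts$stepSizes)) {
        ss <- rep_len(opts$stepSizes, nl)
        ss[lev]
      } else 2 * max(voxelSpacing(m))
      decay <- 0.05^(1 / nIter)
      fvAll <- f@data
      for (k in seq_len(nIter)) {
        it_global <- it_global + 1L
        lin <- sample.int(prod(d), min(opts$nSamplesPerIteration, prod(d)),
                          replace = TRUE)
        kji <- .linToKJI(lin, d)
        fv <- fvAll[lin]
        w <- voxelToWorld(f, kji)
        M <- matrix(p[1:9], 3, 3)
        tr <- p[10:12]
        mw <- sweep(w %*% t(M), 2, tr, "+")
        iv <- .interpTrilinear(m, mw, gradient = TRUE)
        keep <- iv$inside
        if (!any(keep))
          stop(sprintf("affine registration diverged at iteration %d: no overlap",
                       it_global), call. = FALSE)
        r <- iv$value[keep] - fv[keep]
        g <- iv$grad[keep, , drop = FALSE]
        wk <- w[keep, , drop = FALSE]
        n <- length(r)
        GM <- (2 / n) * crossprod(g, r * wk)   # d cost / d M (3x3)
        Gt <- (2 / n) * colSums(r * g)
        G <- c(as.vector(GM), Gt)
        if (!all(is.finite(G)))
          stop(sprintf("affine registration diverged at iteration %d: non-finite gradient",
                       it_global), call. = FALSE)
        gs <- G / scales
        nrm <- sqrt(sum(gs^2))
        if (nrm > 0) {
          eta <- step0 * decay^(k - 1)
          p <- p - eta * gs / (nrm * scales)
        }
      }
    }
    affineTransform3D(matrix = matrix(p[1:9], 3, 3), translation = p[10:12])
  })
}

#' Propagate a label through a transform (nearest neighbour)
#'
#' Resamples a binary label onto the target grid: each target voxel maps
#' through the (fixed-to-moving) transform and takes the label of the
#' nearest moving voxel; positions outside the label's domain are
#' background. Values remain exactly {0, 1}.
#'
#' @param label a [BinaryMask3D-class] on the moving grid.
#' @param t an [AffineTransform3D-class] or [BSplineTransform3D-class].
#' @param targetGrid a Volume3D/BinaryMask3D supplying the output grid.
#' @return a [BinaryMask3D-class] on the target grid.
#' @export
warpLabels <- function(label, t, targetGrid) {
  d <- gridDim(targetGrid)
  idx <- .linToKJI(seq_len(prod(d)), d)
  w <- voxelToWorld(targetGrid, idx)
  mw <- transformPoints(t, w)
  kji <- round(worldToVoxel(label, mw))
  dl <- gridDim(label)
  inb <- kji[, 1] >= 1 & kji[, 1] <= dl[1] & kji[, 2] >= 1 &
    kji[, 2] <= dl[2] & kji[, 3] >= 1 & kji[, 3] <= dl[3]
  out <- logical(nrow(kji))
  out[inb] <- label@data[.kjiToLin(kji[inb, , drop = FALSE], dl)]
  BinaryMask3D(array(out, d), spacing = voxelSpacing(targetGrid),
               origin = voxelOrigin(targetGrid))
}

#' Majority-vote label fusion
#'
#' A voxel is foreground iff strictly more than half of the propagated
#' labels mark it (ties with an even atlas count resolve to background).
#'
#' @param labels nonempty list of [BinaryMask3D-class] on one grid.
#' @return the fused [BinaryMask3D-class].
#' @export
majorityVote <- function(labels) {
  if (length(labels) == 0) stop("majority vote needs at least one label")
  for (l in labels[-1]) .stopIfGridMismatch(labels[[1]], l, "vote labels")
  acc <- Reduce(`+`, lapply(labels, function(l) l@data * 1L))
  BinaryMask3D(acc > length(labels) / 2, spacing = labels[[1]]@spacing,
               origin = labels[[1]]@origin)
}

#' Multi-atlas heart segmentation
#'
#' For each atlas, registers the atlas image to the patient image (affine,
#' then B-spline initialised from the affine), propagates the atlas heart
#' label through the recovered transform, and fuses the propagated labels
#' by majority vote. An atlas whose registration fails is excluded with a
#' warning; if all fail, the stage errors.
#'
#' @param patient the patient [Volume3D-class] (fixed image).
#' @param atlases list of atlases, each \code{list(volume, label)} (as
#'   produced by [makeAtlasSet()]).
#' @param opts a [registrationOptions()] list.
#' @return the fused heart [BinaryMask3D-class] on the patient grid.
#' @export
segmentHeart <- function(patient, atlases, opts = registrationOptions()) {
  if (length(atlases) < 1) stop("need at least one atlas")
  warped <- vector("list", length(atlases))
  for (a in seq_along(atlases)) {
    o <- opts
    o$rngSeed <- opts$rngSeed + 7919L * a
    warped[[a]] <- tryCatch({
      aff <- affineRegister(patient, atlases[[a]]$volume, o)
      bsp <- bsplineRegister(patient, atlases[[a]]$volume, aff, o)
      warpLabels(atlases[[a]]$label, bsp, patient)
    }, error = function(e) {
      warning(sprintf("atlas %d excluded: %s", a, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  warped <- Filter(Negate(is.null), warped)
  if (length(warped) == 0)
    stop("heart segmentation failed: every atlas registration failed",
         call. = FALSE)
  majorityVote(warped)
}
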