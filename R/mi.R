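# Localized mutual information and the cubic B-spline deformable stage.

# Uniform cubic B-spline basis weights at fractional position u in [0, 1),
# for the four control points floor-1 .. floor+2; and their derivatives.
.bspl3 <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}
.bspl3d <- function(u) {
  cbind(-(1 - u)^2 / 2,
        (3 * u^2 - 4 * u) / 2,
        (-3 * u^2 + 2 * u + 1) / 2,
        u^2 / 2)
}

# Build an identity BSplineTransform3D whose lattice covers the fixed-image
# world domain plus the cubic support margin.
.bsplineLattice <- function(fixed, bulk, controlSpacingMM) {
  d <- gridDim(fixed)
  sp <- voxelSpacing(fixed)
  or <- voxelOrigin(fixed)                       # (x, y, z)
  extent <- c((d[3] - 1) * sp[3], (d[2] - 1) * sp[2], (d[1] - 1) * sp[1])
  delta <- rep_len(controlSpacingMM, 3L)
  g0 <- or - 2 * delta
  nc <- ceiling(extent / delta) + 6L
  new("BSplineTransform3D", bulk = bulk, gridOrigin = g0,
      gridSpacing = delta,
      coefficients = array(0, c(nc[1], nc[2], nc[3], 3L)))
}

# Per-point support indices (n x 64, linear into the flattened lattice) and
# tensor-product weights (n x 64) of the cubic lattice at world points.
.bsplineSupport <- function(bsp, pts) {
  nc <- dim(bsp@coefficients)[1:3]
  cidx <- sweep(sweep(pts, 2, bsp@gridOrigin), 2, bsp@gridSpacing, "/") + 1
  fl <- floor(cidx)
  for (ax in 1:3) fl[, ax] <- pmin(pmax(fl[, ax], 2L), nc[ax] - 2L)
  u <- cidx - fl
  wx <- .bspl3(u[, 1]); wy <- .bspl3(u[, 2]); wz <- .bspl3(u[, 3])
  n <- nrow(pts)
  idx <- matrix(0L, n, 64)
  wt <- matrix(0, n, 64)
  colnum <- 0L
  for (c3 in 0:3) for (c2 in 0:3) for (c1 in 0:3) {
    colnum <- colnum + 1L
    ii <- fl[, 1] - 1L + c1           # x control index
    jj <- fl[, 2] - 1L + c2           # y
    kk <- fl[, 3] - 1L + c3           # z
    idx[, colnum] <- (kk - 1L) * nc[1] * nc[2] + (jj - 1L) * nc[1] + ii
    wt[, colnum] <- wx[, c1 + 1L] * wy[, c2 + 1L] * wz[, c3 + 1L]
  }
  list(idx = idx, wt = wt)
}

# Displacement field D(points) of a B-spline transform, n x 3 mm.
.bsplineDisplacement <- function(bsp, pts) {
  if (all(bsp@coefficients == 0)) return(matrix(0, nrow(pts), 3))
  sup <- .bsplineSupport(bsp, pts)
  ncTot <- prod(dim(bsp@coefficients)[1:3])
  out <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    cf <- bsp@coefficients[, , , ax]
    out[, ax] <- rowSums(sup$wt * matrix(cf[sup$idx], nrow(pts), 64))
  }
  out
}

#' Localized mutual information (bits)
#'
#' Mutual information of the joint intensity histogram built from the
#' fixed-image voxels in a cube of side \code{bsplineNeighborhoodMM}
#' centred on \code{center} (the centre voxel always included) and the
#' moving image at the transformed sample positions. Bins are regularly
#' spaced over the 1st-99th percentile of each image's sampled intensities.
#' Returns 0 with a warning when either marginal occupies fewer than two
#' bins.
#'
#' @param fixed,moving [Volume3D-class] images.
#' @param t transform mapping fixed world to moving world.
#' @param center integer(3) fixed voxel (k, j, i) at the neighbourhood
#'   centre.
#' @param opts a [registrationOptions()] list (neighbourhood size and bin
#'   count are taken from it).
#' @param maxSamples deterministic stride-subsampling cap on the number of
#'   cube voxels used.
#' @return scalar MI in bits (>= 0).
#' @export
localizedMI <- function(fixed, moving, t, center,
                        opts = registrationOptions(), maxSamples = 20000L) {
  d <- gridDim(fixed)
  sp <- voxelSpacing(fixed)
  half <- opts$bsplineNeighborhoodMM / 2
  rad <- pmax(0L, floor(half / sp))             # (z, y, x) index radii
  kR <- seq.int(max(1L, center[1] - rad[1]), min(d[1], center[1] + rad[1]))
  jR <- seq.int(max(1L, center[2] - rad[2]), min(d[2], center[2] + rad[2]))
  iR <- seq.int(max(1L, center[3] - rad[3]), min(d[3], center[3] + rad[3]))
  kji <- as.matrix(expand.grid(k = kR, j = jR, i = iR))
  if (nrow(kji) > maxSamples) {
    stride <- ceiling(nrow(kji) / maxSamples)
    kji <- kji[seq(1, nrow(kji), by = stride), , drop = FALSE]
  }
  fv <- fixed@data[.kjiToLin(kji, d)]
  iv <- .interpTrilinear(moving, transformPoints(t, voxelToWorld(fixed, kji)))
  keep <- iv$inside
  fv <- fv[keep]
  mv <- iv$value[keep]
  .histMI(fv, mv, opts$nHistogramBins)
}

# Hard-binned joint-histogram MI in bits over paired intensity samples.
.histMI <- function(fv, mv, nb) {
  if (length(fv) < 4) {
    warning("localized MI: too few in-domain samples; returning 0",
            call. = FALSE)
    return(0)
  }
  fe <- quantile(fv, c(0.01, 0.99), names = FALSE)
  me <- quantile(mv, c(0.01, 0.99), names = FALSE)
  if (diff(fe) <= 0 || diff(me) <= 0) {
    warning("localized MI: degenerate intensity range; returning 0",
            call. = FALSE)
    return(0)
  }
  fb <- pmin(pmax(floor((fv - fe[1]) / diff(fe) * nb) + 1L, 1L), nb)
  mb <- pmin(pmax(floor((mv - me[1]) / diff(me) * nb) + 1L, 1L), nb)
  if (length(unique(fb)) < 2L || length(unique(mb)) < 2L) {
    warning("localized MI: fewer than 2 occupied bins on a marginal; returning 0",
            call. = FALSE)
    return(0)
  }
  P <- tabulate((mb - 1L) * nb + fb, nbins = nb * nb) / length(fb)
  dim(P) <- c(nb, nb)
  pf <- rowSums(P)
  pm <- colSums(P)
  nzi <- which(P > 0, arr.ind = TRUE)
  p <- P[nzi]
  sum(p * log2(p / (pf[nzi[, 1]] * pm[nzi[, 2]])))
}

# Parzen-smoothed MI (cubic window on the moving axis) and its gradient with
# respect to the moving intensities; shared sample set. Used by the B-spline
# optimizer, whose objective must be differentiable.
.parzenMI <- function(fv, mv, nb, fe, me, gradient = TRUE) {
  n <- length(fv)
  fb <- pmin(pmax(floor((fv - fe[1]) / diff(fe) * nb) + 1L, 1L), nb)
  mu <- pmin(pmax((mv - me[1]) / diff(me) * nb + 0.5, 2), nb - 1)
  l <- floor(mu)
  l <- pmin(pmax(l, 2L), nb - 2L)
  u <- mu - l
  wt <- .bspl3(u)
  P <- matrix(0, nb, nb)
  for (c in 0:3) {
    mbin <- l - 1L + c
    inc <- rowsum(wt[, c + 1L], group = (mbin - 1L) * nb + fb)
    at <- as.integer(rownames(inc))
    P[at] <- P[at] + inc
  }
  P <- P / n
  pf <- rowSums(P)
  pm <- colSums(P)
  nzi <- which(P > 0, arr.ind = TRUE)
  p <- P[nzi]
  value <- sum(p * log2(p / (pf[nzi[, 1]] * pm[nzi[, 2]])))
  if (!gradient) return(list(value = value))
  dwt <- .bspl3d(u)
  dmu <- numeric(n)
  eps <- 1e-12
  for (c in 0:3) {
    mbin <- l - 1L + c
    Pv <- P[(mbin - 1L) * nb + fb]
    term <- log((Pv + eps) / (pf[fb] * pm[mbin] + eps)) / log(2)
    dmu <- dmu + dwt[, c + 1L] * term / n
  }
  # d mu / d (moving intensity)
  list(value = value, dMI_dm = dmu * nb / diff(me))
}

#' B-spline deformable registration by localized mutual information
#'
#' Second registration stage: starting from the affine initialisation, the
#' displacement coefficients of a cubic B-spline lattice are optimised by
#' stochastic gradient ascent on a Parzen-smoothed mutual information. Each
#' iteration selects one random voxel in the fixed domain and draws the
#' remaining samples from the cube of side \code{bsplineNeighborhoodMM}
#' around it; the analytic gradient flows through the Parzen window, the
#' trilinear moving-image gradient and the spline support weights. Steps
#' backtrack (halve) when the objective decreases on the iteration's sample
#' set. With \code{nBsplineIterations = 0} the affine initialisation is
#' returned embedded in an identity lattice. Deterministic given
#' \code{opts$rngSeed}.
#'
#' @param fixed,moving [Volume3D-class] images.
#' @param init [AffineTransform3D-class] initialisation (bulk transform).
#' @param opts a [registrationOptions()] list.
#' @return a [BSplineTransform3D-class].
#' @export
bsplineRegister <- function(fixed, moving, init,
                            opts = registrationOptions()) {
  bsp <- .bsplineLattice(fixed, init, opts$bsplineControlSpacingMM)
  if (opts$nBsplineIterations == 0L) return(bsp)
  withSeed(opts$rngSeed + 104729L, {
    pf <- suppressWarnings(gaussianPyramid(fixed, opts$pyramidLevels))
    pm <- suppressWarnings(gaussianPyramid(moving, opts$pyramidLevels))
    nl <- min(length(pf), length(pm))
    iters <- .splitIterations(opts$nBsplineIterations, nl)
    nb <- opts$nHistogramBins
    nc <- dim(bsp@coefficients)[1:3]
    ncTot <- prod(nc)
    coef <- bsp@coefficients
    for (lev in rev(seq_len(nl))) {
      f <- pf[[lev]]; m <- pm[[lev]]
      d <- gridDim(f)
      sp <- voxelSpacing(f)
      fe <- quantile(f@data, c(0.01, 0.99), names = FALSE)
      me <- quantile(m@data, c(0.01, 0.99), names = FALSE)
      if (diff(fe) <= 0 || diff(me) <= 0) next
      rad <- pmax(1L, floor((opts$bsplineNeighborhoodMM / 2) / sp))
      for (k in seq_len(iters[lev])) {
        ctr <- c(sample.int(d[1], 1), sample.int(d[2], 1),
                 sample.int(d[3], 1))
        kR <- seq.int(max(1L, ctr[1] - rad[1]), min(d[1], ctr[1] + rad[1]))
        jR <- seq.int(max(1L, ctr[2] - rad[2]), min(d[2], ctr[2] + rad[2]))
        iR <- seq.int(max(1L, ctr[3] - rad[3]), min(d[3], ctr[3] + rad[3]))
        nBox <- length(kR) * length(jR) * length(iR)
        ns <- min(opts$nSamplesPerIteration, nBox)
        pick <- sample.int(nBox, ns)
        kji <- cbind(kR[((pick - 1L) %% length(kR)) + 1L],
                     jR[(((pick - 1L) %/% length(kR)) %% length(jR)) + 1L],
                     iR[((pick - 1L) %/% (length(kR) * length(jR))) + 1L])
        kji[1, ] <- ctr                     # centre voxel always included
        fv <- f@data[.kjiToLin(kji, d)]
        w <- voxelToWorld(f, kji)
        bulkPts <- transformPoints(bsp@bulk, w)
        sup <- .bsplineSupport(bsp, w)
        evalObj <- function(cf, gradient = FALSE) {
          disp <- matrix(0, nrow(w), 3)
          for (ax in 1:3) {
            cfa <- cf[, , , ax]
            disp[, ax] <- rowSums(sup$wt * matrix(cfa[sup$idx], nrow(w), 64))
          }
          iv <- .interpTrilinear(m, bulkPts + disp, gradient = gradient)
          keep <- iv$inside
          if (sum(keep) < 8) return(NULL)
          pm_ <- .parzenMI(fv[keep], iv$value[keep], nb, fe, me,
                           gradient = gradient)
          list(keep = keep, iv = iv, mi = pm_)
        }
        cur <- evalObj(coef, gradient = TRUE)
        if (is.null(cur)) next
        dMdm <- numeric(nrow(w))
        dMdm[cur$keep] <- cur$mi$dMI_dm
        G <- array(0, dim(coef))
        for (ax in 1:3) {
          s <- dMdm
          s[cur$keep] <- s[cur$keep] * cur$iv$grad[cur$keep, ax]
          s[!cur$keep] <- 0
          gflat <- numeric(ncTot)
          for (c in seq_len(64)) {
            inc <- rowsum(s * sup$wt[, c], group = sup$idx[, c])
            at <- as.integer(rownames(inc))
            gflat[at] <- gflat[at] + inc
          }
          G[, , , ax] <- gflat
        }
        gmax <- max(abs(G))
        if (!is.finite(gmax)) stop("B-spline registration: non-finite objective gradient")
        if (gmax == 0) next
        dir <- G / gmax
        step <- opts$bsplineStepMM
        for (bt in 1:5) {
          prop <- coef + step * dir
          pr <- evalObj(prop, gradient = FALSE)
          if (!is.null(pr) && is.finite(pr$mi$value) &&
              pr$mi$value >= cur$mi$value) {
            coef <- prop
            break
          }
          step <- step / 2
        }
      }
    }
    bsp@coefficients <- coef
    bsp
  })
}
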