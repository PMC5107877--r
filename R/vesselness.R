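#' Vesselness filter parameters
#'
#' Parameters of the multiscale Hessian line filter. Scales are the standard
#' deviations (mm) of the Gaussian used for the derivative computation; the
#' defaults span typical coronary lumen radii at sub-millimetre CTA
#' resolution. \code{gamma23} sharpens the cross-section symmetry term
#' (lambda2/lambda3), \code{gamma12} the tube-versus-blob term, and
#' \code{alpha} tolerates mild asymmetry (lambda1 slightly positive).
#'
#' @param sigmasMM strictly increasing positive scales, mm.
#' @param gamma23,gamma12 sharpness exponents (>= 0).
#' @param alpha asymmetry tolerance in (0, 1].
#' @return a classed parameter list.
#' @export
vesselnessParams <- function(sigmasMM = c(0.5, 1, 1.5, 2, 3),
                             gamma23 = 1, gamma12 = 1, alpha = 0.25) {
  if (any(sigmasMM <= 0) || is.unsorted(sigmasMM, strictly = TRUE))
    stop("sigmasMM must be strictly positive and increasing")
  if (gamma23 < 0 || gamma12 < 0) stop("gamma exponents must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(sigmasMM = sigmasMM, gamma23 = gamma23, gamma12 = gamma12,
                 alpha = alpha), class = "VesselnessParams")
}

#' Hessian of a volume at one scale
#'
#' The six unique second derivatives of the Gaussian-smoothed image at scale
#' \code{sigmaMM}, computed by analytic Gaussian-derivative convolution in
#' millimetres (anisotropic voxel spacing honoured per axis) and multiplied
#' by sigma^2 (gamma-normalisation, so responses are comparable across
#' scales).
#'
#' @param vol a [Volume3D-class].
#' @param sigmaMM scale, mm; a warning is issued if the scale undersamples
#'   the grid (sigma below half the largest voxel spacing).
#' @return a [HessianField-class].
#' @export
hessianAtScale <- function(vol, sigmaMM) {
  if (sigmaMM <= 0) stop("sigmaMM must be > 0")
  sp <- voxelSpacing(vol)
  if (sigmaMM < max(sp) / 2)
    warning(sprintf("scale %.3g mm undersampled (largest spacing %.3g mm)",
                    sigmaMM, max(sp)), call. = FALSE)
  a <- volData(vol)
  s2 <- sigmaMM^2
  # axis order of `ord` is (z, y, x)
  new("HessianField",
      zz = s2 * .gaussDeriv3(a, sigmaMM, sp, c(2L, 0L, 0L)),
      yy = s2 * .gaussDeriv3(a, sigmaMM, sp, c(0L, 2L, 0L)),
      xx = s2 * .gaussDeriv3(a, sigmaMM, sp, c(0L, 0L, 2L)),
      yz = s2 * .gaussDeriv3(a, sigmaMM, sp, c(1L, 1L, 0L)),
      xz = s2 * .gaussDeriv3(a, sigmaMM, sp, c(1L, 0L, 1L)),
      xy = s2 * .gaussDeriv3(a, sigmaMM, sp, c(0L, 1L, 1L)),
      sigmaMM = sigmaMM, spacing = sp, origin = voxelOrigin(vol))
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorised over voxels
# (trigonometric method); returns three vectors sorted descending by value.
.symEig3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  e1 <- e2 <- e3 <- q  # degenerate (isotropic) voxels: all eigenvalues = q
  nz <- p > 0
  if (any(nz)) {
    pn <- p[nz]
    b11 <- (a11[nz] - q[nz]) / pn; b22 <- (a22[nz] - q[nz]) / pn
    b33 <- (a33[nz] - q[nz]) / pn
    b12 <- a12[nz] / pn; b13 <- a13[nz] / pn; b23 <- a23[nz] / pn
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    x1 <- q[nz] + 2 * pn * cos(phi)
    x3 <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    e1[nz] <- x1
    e3[nz] <- x3
    e2[nz] <- 3 * q[nz] - x1 - x3
  }
  list(hi = e1, mid = e2, lo = e3)  # hi >= mid >= lo (by value)
}

#' Per-voxel eigenvalues of a Hessian field, magnitude-sorted
#'
#' Eigendecomposition of the symmetric 3x3 Hessian at every voxel, with the
#' line-filter ordering |lambda1| <= |lambda2| <= |lambda3|. The sum of the
#' three equals the Hessian trace to numerical precision.
#'
#' @param h a [HessianField-class].
#' @return an [EigenField-class].
#' @export
eigenvaluesSorted <- function(h) {
  comps <- list(h@xx, h@yy, h@zz, h@xy, h@xz, h@yz)
  bad <- !vapply(comps, function(x) all(is.finite(x)), TRUE)
  if (any(bad)) {
    nf <- which(!is.finite(h@xx + h@yy + h@zz + h@xy + h@xz + h@yz))
    kji <- .linToKJI(nf[1], dim(h@xx))
    stop(sprintf("non-finite Hessian at voxel (k=%d, j=%d, i=%d)",
                 kji[1], kji[2], kji[3]), call. = FALSE)
  }
  d <- dim(h@xx)
  ev <- .symEig3(as.vector(h@xx), as.vector(h@yy), as.vector(h@zz),
                 as.vector(h@xy), as.vector(h@xz), as.vector(h@yz))
  m <- cbind(ev$hi, ev$mid, ev$lo)
  am <- abs(m)
  o1 <- max.col(-am, ties.method = "first")   # smallest magnitude
  o3 <- max.col(am, ties.method = "last")     # largest magnitude
  clash <- o1 == o3                           # all three equal in magnitude
  o1[clash] <- 1L; o3[clash] <- 3L
  o2 <- 6L - o1 - o3
  n <- nrow(m)
  l1 <- m[cbind(seq_len(n), o1)]
  l2 <- m[cbind(seq_len(n), o2)]
  l3 <- m[cbind(seq_len(n), o3)]
  new("EigenField", l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d),
      spacing = h@spacing, origin = h@origin)
}

#' Line (tube-likeness) measure from Hessian eigenvalues
#'
#' The bright-line response: zero unless lambda2 and lambda3 are both
#' negative (bright tube cross-section), then
#' \deqn{|\lambda_3| (\lambda_2/\lambda_3)^{\gamma_{23}}
#'       w(\lambda_1; \lambda_2)^{\gamma_{12}}}
#' where the tube-versus-blob weight is \eqn{1 + \lambda_1/|\lambda_2|} for
#' \eqn{\lambda_1 \le 0}, \eqn{1 - \alpha \lambda_1/|\lambda_2|} for
#' \eqn{0 < \lambda_1 \le |\lambda_2|/\alpha}, and 0 beyond. An ideal bright
#' line (0, -c, -c) scores c; a blob (-c, -c, -c) and a bright plane score 0.
#'
#' @param e an [EigenField-class].
#' @param p a [vesselnessParams()] list.
#' @return a [Volume3D-class] of non-negative responses.
#' @export
lineMeasure <- function(e, p = vesselnessParams()) {
  l1 <- as.vector(e@l1); l2 <- as.vector(e@l2); l3 <- as.vector(e@l3)
  resp <- numeric(length(l1))
  act <- l2 < 0 & l3 < 0
  if (any(act)) {
    a1 <- l1[act]; a2 <- l2[act]; a3 <- l3[act]
    base <- abs(a3) * (a2 / a3)^p$gamma23
    w <- numeric(length(a1))
    neg <- a1 <= 0
    w[neg] <- pmax(1 + a1[neg] / abs(a2[neg]), 0)^p$gamma12
    pos <- !neg & (a1 <= abs(a2) / p$alpha)
    w[pos] <- pmax(1 - p$alpha * a1[pos] / abs(a2[pos]), 0)^p$gamma12
    resp[act] <- base * w
  }
  v <- new("Volume3D", data = array(resp, dim(e@l1)), spacing = e@spacing,
           origin = e@origin)
  v
}

#' Multiscale vessel enhancement inside the heart region
#'
#' Per-voxel maximum of the sigma^2-normalised line measure over the scale
#' list, restricted to (zeroed outside) the heart mask.
#'
#' @param vol a [Volume3D-class] of HU intensities.
#' @param heartMask a [BinaryMask3D-class] on the same grid.
#' @param p a [vesselnessParams()] list.
#' @param returnScales if TRUE, also return the per-voxel argmax scale.
#' @return a [Volume3D-class] response, or (with \code{returnScales}) a list
#'   \code{list(response, scaleMM)}.
#' @export
multiscaleVesselness <- function(vol, heartMask, p = vesselnessParams(),
                                 returnScales = FALSE) {
  .stopIfGridMismatch(vol, heartMask, "volume and heart mask")
  if (!any(heartMask@data))
    stop("empty heart mask: nothing to enhance", call. = FALSE)
  best <- array(0, gridDim(vol))
  bestScale <- array(NA_real_, gridDim(vol))
  for (s in p$sigmasMM) {
    r <- volData(lineMeasure(eigenvaluesSorted(hessianAtScale(vol, s)), p))
    take <- r > best
    best[take] <- r[take]
    bestScale[take] <- s
  }
  best[!heartMask@data] <- 0
  bestScale[!heartMask@data] <- NA_real_
  out <- new("Volume3D", data = best, spacing = voxelSpacing(vol),
             origin = voxelOrigin(vol))
  if (returnScales)
    list(response = out,
         scaleMM = new("Volume3D",
                       data = ifelse(is.na(bestScale), 0, bestScale),
                       spacing = voxelSpacing(vol),
                       origin = voxelOrigin(vol)))
  else out
}
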