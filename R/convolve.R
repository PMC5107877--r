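# Separable Gaussian / Gaussian-derivative filtering on 3D arrays.
# Kernels are sampled analytically in millimetres (anisotropic spacing is
# honoured per axis) and moment-corrected so that on polynomial inputs the
# discrete response matches the continuous derivative:
#   order 0: sum(k) == 1
#   order 1: sum(k) == 0, sum(k * t) == 1   (t in mm)
#   order 2: sum(k) == 0, sum(k * t^2)/2 == 1
# Boundary handling is nearest-neighbour (edge replication).

.gaussKernel1D <- function(sigmaMM, stepMM, order = 0L) {
  sv <- sigmaMM / stepMM
  r <- max(1L, as.integer(ceiling(4 * sv)))
  t <- (-r:r) * stepMM
  g <- exp(-t^2 / (2 * sigmaMM^2))
  if (order == 0L) {
    k <- g / sum(g)
  } else if (order == 1L) {
    # correlation kernel for d/dx of the Gaussian-smoothed signal
    k <- t / sigmaMM^2 * g
    k <- k - mean(k)           # exact zero DC (symmetry makes this a no-op)
    k <- k / sum(k * t)
  } else if (order == 2L) {
    k <- (t^2 / sigmaMM^4 - 1 / sigmaMM^2) * g
    k <- k - mean(k)
    k <- k / (sum(k * t^2) / 2)
  } else stop("derivative order must be 0, 1 or 2")
  k
}

# Correlate a 3D array with a 1D kernel along one axis (1 = z, 2 = y, 3 = x)
# using a banded-matrix multiply; edges replicate.
.convAxis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  pd <- dim(ap)
  n <- pd[1]
  dim(ap) <- c(n, prod(pd[-1]))
  r <- (length(k) - 1L) %/% 2L
  idx <- pmin(pmax(seq.int(1L - r, n + r), 1L), n)
  P <- ap[idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * r)
  for (t in seq_along(k))
    K[cbind(seq_len(n), seq_len(n) + (t - 1L))] <- k[t]
  out <- K %*% P
  dim(out) <- pd
  aperm(out, order(perm))
}

# Smooth with an isotropic-in-mm Gaussian (sigma per axis derived from
# spacing); sigma of 0 is a no-op.
.gaussSmooth3 <- function(a, sigmaMM, spacing) {
  if (sigmaMM <= 0) return(a)
  for (ax in 1:3)
    a <- .convAxis(a, .gaussKernel1D(sigmaMM, spacing[ax], 0L), ax)
  a
}

# Gaussian-derivative filter with per-axis derivative orders
# ord = (oz, oy, ox); result is d^(oz+oy+ox) (G_sigma * I) in mm units.
.gaussDeriv3 <- function(a, sigmaMM, spacing, ord) {
  for (ax in 1:3)
    a <- .convAxis(a, .gaussKernel1D(sigmaMM, spacing[ax], ord[ax]), ax)
  a
}
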