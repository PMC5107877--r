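#' Dice similarity coefficient
#'
#' \code{2 |A & B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param a,b [BinaryMask3D-class] masks on the same grid.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  .stopIfGridMismatch(a, b, "masks")
  na <- sum(a@data); nb <- sum(b@data)
  if (na + nb == 0) return(1)
  2 * sum(a@data & b@data) / (na + nb)
}

#' Surface voxels of a mask
#'
#' Voxels of the mask with at least one face-adjacent (6-connected)
#' background or out-of-bounds neighbour.
#'
#' @param mask a [BinaryMask3D-class].
#' @return integer n x 3 matrix of (k, j, i) surface voxel indices.
#' @export
surfaceVoxels <- function(mask) {
  m <- mask@data
  interior <- .shift3(m, c(1, 0, 0)) & .shift3(m, c(-1, 0, 0)) &
    .shift3(m, c(0, 1, 0)) & .shift3(m, c(0, -1, 0)) &
    .shift3(m, c(0, 0, 1)) & .shift3(m, c(0, 0, -1))
  lin <- which(m & !interior)
  co <- .linToKJI(lin, dim(m))
  storage.mode(co) <- "integer"
  co
}

#' Symmetric mean and maximum surface distance
#'
#' Distances between the surface voxel sets of two masks, measured between
#' voxel centres in world millimetres (anisotropic spacing applied).
#' Per-point nearest-surface distances are collected in both directions and
#' pooled; the mean of the pool is MSD and the maximum is MAXSD (the
#' symmetric Hausdorff distance).
#'
#' @param a,b non-empty [BinaryMask3D-class] masks on the same grid.
#' @return named numeric: \code{msd_mm}, \code{maxsd_mm}.
#' @export
surfaceDistances <- function(a, b) {
  .stopIfGridMismatch(a, b, "masks")
  if (!any(a@data) || !any(b@data))
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  sa <- voxelToWorld(a, surfaceVoxels(a))
  sb <- voxelToWorld(b, surfaceVoxels(b))
  dAB <- cpp_nn_dist(sa, sb)
  dBA <- cpp_nn_dist(sb, sa)
  pooled <- c(dAB, dBA)
  c(msd_mm = mean(pooled), maxsd_mm = max(pooled))
}

#' Segmentation quality report
#'
#' Dice overlap plus symmetric mean/maximum surface distance between a
#' segmentation and a gold mask, the validation metrics of the pipeline.
#'
#' @param a,b [BinaryMask3D-class] masks on the same grid (segmentation and
#'   gold standard).
#' @return list with \code{dice}, \code{msd_mm}, \code{maxsd_mm},
#'   \code{n_voxels_a}, \code{n_voxels_b}.
#' @export
segmentationMetrics <- function(a, b) {
  dc <- diceCoefficient(a, b)
  if (any(a@data) && any(b@data)) {
    sdist <- surfaceDistances(a, b)
  } else if (dc == 1) {
    sdist <- c(msd_mm = 0, maxsd_mm = 0)
  } else {
    sdist <- c(msd_mm = NA_real_, maxsd_mm = NA_real_)
  }
  list(dice = dc, msd_mm = unname(sdist["msd_mm"]),
       maxsd_mm = unname(sdist["maxsd_mm"]),
       n_voxels_a = sum(a@data), n_voxels_b = sum(b@data))
}
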