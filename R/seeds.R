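#' Seed detection parameters
#'
#' Conservative thresholding plus 3D erosion. The 120 HU threshold keeps
#' contrast-filled lumen and discards myocardium; the erosion kernel
#' suppresses isolated noise points so that surviving voxels lie well inside
#' the arteries. The conventional 4 x 4 x 3 kernel is mapped to (dz, dy, dx) =
#' (3, 4, 4): 4 x 4 in-plane, 3 across slices (the thicker axis); the axis
#' assignment is exposed because the in-plane/through-plane attribution is a
#' convention.
#'
#' @param thresholdHU HU threshold applied to the original intensities.
#' @param erosionKernel integer(3) box (dz, dy, dx), all >= 1.
#' @param vesselnessFloor minimal enhancement response for eligibility;
#'   \code{-Inf} disables the vesselness gate.
#' @return a classed parameter list.
#' @export
seedDetectionParams <- function(thresholdHU = 120,
                                erosionKernel = c(3L, 4L, 4L),
                                vesselnessFloor = 0) {
  erosionKernel <- as.integer(erosionKernel)
  if (length(erosionKernel) != 3L || any(erosionKernel < 1L))
    stop("erosionKernel must be 3 integers >= 1")
  structure(list(thresholdHU = thresholdHU, erosionKernel = erosionKernel,
                 vesselnessFloor = vesselnessFloor),
            class = "SeedDetectionParams")
}

#' Candidate seed mask by HU threshold gated by vesselness
#'
#' A voxel is a candidate iff its original intensity is at least
#' \code{thresholdHU} and its enhancement response exceeds
#' \code{vesselnessFloor}. HU is only meaningful on the original volume, so
#' the threshold applies there; the response gate removes bright but
#' non-tubular structures (e.g. the blood pool).
#'
#' @param vol original HU volume.
#' @param response enhancement response on the same grid (zero outside the
#'   heart region).
#' @param p a [seedDetectionParams()] list.
#' @return a [BinaryMask3D-class].
#' @export
thresholdMask <- function(vol, response, p = seedDetectionParams()) {
  .stopIfGridMismatch(vol, response, "volume and response")
  BinaryMask3D(volData(vol) >= p$thresholdHU &
                 volData(response) > p$vesselnessFloor,
               spacing = voxelSpacing(vol), origin = voxelOrigin(vol))
}

#' 3D binary erosion with a box structuring element
#'
#' A voxel survives iff the box kernel, anchored at floor(d/2) per axis,
#' fits entirely inside the mask (out-of-bounds counts as background). The
#' box erosion is computed separably (three 1D erosions), which is exactly
#' equivalent to the structuring-element-fit definition.
#'
#' @param mask a [BinaryMask3D-class].
#' @param kernel integer(3) box (dz, dy, dx).
#' @return an eroded [BinaryMask3D-class] (always a subset of the input).
#' @export
erodeMask <- function(mask, kernel = c(3L, 4L, 4L)) {
  kernel <- as.integer(kernel)
  if (any(kernel < 1L)) stop("kernel dimensions must be >= 1")
  m <- mask@data
  for (ax in 1:3) {
    d <- kernel[ax]
    if (d == 1L) next
    offs <- seq_len(d) - 1L - (d %/% 2L)   # anchor floor(d/2)
    acc <- NULL
    for (o in offs) {
      s <- integer(3); s[ax] <- -o         # out[x] = m[x + o]
      sh <- .shift3(m, s, fill = FALSE)
      acc <- if (is.null(acc)) sh else (acc & sh)
    }
    m <- acc
  }
  BinaryMask3D(m, spacing = mask@spacing, origin = mask@origin)
}

#' Extract the ordered seed set from a mask
#'
#' Every surviving voxel becomes a seed, in deterministic raster order
#' (k fastest, then j, then i — ascending linear index of the (z, y, x)
#' array). An empty mask is an error: the growing stage cannot proceed
#' without seeds.
#'
#' @param mask a [BinaryMask3D-class].
#' @return a [SeedSet-class].
#' @export
extractSeeds <- function(mask) {
  lin <- which(mask@data)
  if (length(lin) == 0L)
    stop("no seeds detected: threshold/erosion removed every candidate",
         call. = FALSE)
  co <- .linToKJI(lin, dim(mask@data))
  storage.mode(co) <- "integer"
  new("SeedSet", coords = co, gridDim = as.integer(dim(mask@data)),
      spacing = mask@spacing, origin = mask@origin)
}

#' Run the full seed-detection stage
#'
#' threshold -> erode -> extract, as a convenience wrapper.
#'
#' @inheritParams thresholdMask
#' @return a [SeedSet-class].
#' @export
detectSeeds <- function(vol, response, p = seedDetectionParams()) {
  extractSeeds(erodeMask(thresholdMask(vol, response, p), p$erosionKernel))
}
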