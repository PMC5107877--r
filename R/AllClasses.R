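#' @useDynLib coroSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif quantile sd approx median
#' @importFrom utils head read.csv write.csv
NULL

#' Volume3D: a scalar 3D image on a regular anisotropic grid
#'
#' The carrier of every image in the pipeline: Hounsfield-calibrated CTA
#' intensities on input, arbitrary response units after filtering. The array
#' is stored in (z, y, x) order, i.e. \code{dim(data) == c(nz, ny, nx)} and
#' \code{data[k, j, i]} addresses slice k, row j, column i (1-based). Voxel
#' spacing is stored in the same (z, y, x) order in millimetres; the origin
#' is the world-space (x, y, z) position in mm of voxel (1, 1, 1).
#'
#' @slot data 3D numeric (or logical, for masks) array, dim (nz, ny, nx).
#' @slot spacing numeric(3), mm per voxel along (z, y, x); all > 0.
#' @slot origin numeric(3), world (x, y, z) mm of voxel (1, 1, 1).
#'
#' @seealso [Volume3D()], [BinaryMask3D-class], [voxelToWorld()]
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("Volume3D", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all shape components must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  TRUE
})

#' BinaryMask3D: a boolean label map sharing a Volume3D grid
#'
#' Used for the heart region of interest, the seed mask, and segmentations.
#' Stored as a logical array; the grid (shape, spacing, origin) must match
#' its companion volume exactly.
#'
#' @seealso [BinaryMask3D()], [sameGrid()]
#' @export
setClass("BinaryMask3D", contains = "Volume3D")

setValidity("BinaryMask3D", function(object) {
  if (!is.logical(object@data))
    return("mask data must be a logical array (values exactly {0,1})")
  if (anyNA(object@data)) return("mask data must not contain NA")
  TRUE
})

#' SeedSet: an ordered collection of seed voxel indices
#'
#' Seeds are produced by thresholding + erosion and consumed (and depleted,
#' via the absorption rule) by the statistical region growing. Rows are
#' (k, j, i) 1-based voxel indices in deterministic raster order; the grid of
#' the source volume is carried along so seeds can be exported with world
#' coordinates.
#'
#' @slot coords integer matrix, n x 3, columns (k, j, i), 1-based.
#' @slot gridDim integer(3) shape (nz, ny, nx) of the owning grid.
#' @slot spacing numeric(3) mm, (z, y, x).
#' @slot origin numeric(3) mm, world (x, y, z) of voxel (1, 1, 1).
#'
#' @seealso [extractSeeds()], [writeSeedsCSV()]
#' @export
setClass("SeedSet",
  representation(coords = "matrix", gridDim = "integer",
                 spacing = "numeric", origin = "numeric"))

setValidity("SeedSet", function(object) {
  co <- object@coords
  if (ncol(co) != 3L) return("coords must have 3 columns (k, j, i)")
  if (nrow(co) > 0) {
    if (any(co < 1L) || any(t(co) > object@gridDim))
      return("every seed must be in bounds of the source grid")
    if (anyDuplicated(co)) return("duplicate seed indices are not allowed")
  }
  TRUE
})

#' AffineTransform3D: world-space affine map
#'
#' Maps fixed-image world coordinates (x, y, z) mm to moving-image world
#' coordinates: \code{T(x) = matrix \%*\% x + translation}. This is the
#' transform estimated in the first registration stage.
#'
#' @slot matrix 3x3 linear part (invertible).
#' @slot translation numeric(3), mm.
#' @export
setClass("AffineTransform3D",
  representation(matrix = "matrix", translation = "numeric"),
  prototype(matrix = diag(3), translation = c(0, 0, 0)))

setValidity("AffineTransform3D", function(object) {
  if (!all(dim(object@matrix) == c(3, 3))) return("matrix must be 3x3")
  if (abs(det(object@matrix)) <= 1e-12)
    return("matrix must be invertible (|det| > 1e-12)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' BSplineTransform3D: free-form deformation on a cubic B-spline lattice
#'
#' Second-stage transform: an affine bulk initialisation plus a displacement
#' field parameterised by control-point coefficients on a regular lattice.
#' \code{T(x) = bulk(x) + D(x)} with \code{D(x)} the cubic B-spline tensor
#' interpolation of the coefficients (mm). The lattice covers the fixed-image
#' domain plus the spline support margin.
#'
#' @slot bulk AffineTransform3D initialisation.
#' @slot gridOrigin numeric(3), world (x, y, z) mm of control point (1,1,1).
#' @slot gridSpacing numeric(3), mm between control points, (x, y, z).
#' @slot coefficients 4D array (ncx, ncy, ncz, 3) of displacements, mm.
#' @export
setClass("BSplineTransform3D",
  representation(bulk = "AffineTransform3D", gridOrigin = "numeric",
                 gridSpacing = "numeric", coefficients = "array"))

setValidity("BSplineTransform3D", function(object) {
  d <- dim(object@coefficients)
  if (length(d) != 4L || d[4] != 3L)
    return("coefficients must be an (ncx, ncy, ncz, 3) array")
  if (any(d[1:3] < 4L))
    return("control lattice needs >= 4 points per axis (cubic support)")
  if (any(object@gridSpacing <= 0)) return("gridSpacing must be positive")
  TRUE
})

#' HessianField: the six unique second-derivative images at one scale
#'
#' Components of the (symmetric) Hessian of the image after Gaussian
#' smoothing at scale \code{sigmaMM}, gamma-normalised by sigma^2 so that
#' responses are comparable across scales. Derivatives are with respect to
#' world millimetres (anisotropic spacing honoured).
#'
#' @slot xx,yy,zz,xy,xz,yz numeric arrays, dim (nz, ny, nx).
#' @slot sigmaMM scale in mm.
#' @slot spacing,origin grid geometry of the source volume.
#' @export
setClass("HessianField",
  representation(xx = "array", yy = "array", zz = "array",
                 xy = "array", xz = "array", yz = "array",
                 sigmaMM = "numeric", spacing = "numeric", origin = "numeric"))

#' EigenField: magnitude-sorted Hessian eigenvalues per voxel
#'
#' lambda1..lambda3 with |lambda1| <= |lambda2| <= |lambda3| at every voxel
#' (the line-filter convention). For a bright tube the characteristic
#' pattern is lambda1 ~ 0 and lambda2 ~ lambda3 << 0.
#'
#' @slot l1,l2,l3 numeric arrays, dim (nz, ny, nx).
#' @slot spacing,origin grid geometry of the source volume.
#' @export
setClass("EigenField",
  representation(l1 = "array", l2 = "array", l3 = "array",
                 spacing = "numeric", origin = "numeric"))

#' PhantomSpec: parameters of the synthetic cardiac CTA phantom
#'
#' Describes a contrast-CTA-like scene: air/lung background, a myocardium
#' ellipsoid, a blood-pool ellipsoid, and contrast-filled tubes with a
#' Gaussian radial intensity profile (half peak at the nominal lumen radius)
#' rasterised along arbitrary centerline polylines. Local radius reduction
#' along a centerline models stenosis. All randomness flows through the
#' single \code{seed}.
#'
#' @slot shape integer(3) voxel counts (nz, ny, nx).
#' @slot spacing numeric(3) mm (z, y, x).
#' @slot origin numeric(3) world mm of voxel (1,1,1), (x, y, z).
#' @slot centerlines list of n x 3 matrices of world (x, y, z) mm polylines.
#' @slot radiiMM list of per-vertex lumen radii (mm), one vector per curve.
#' @slot heartCenter,heartSemiaxesMM,poolSemiaxesMM ellipsoid geometry (mm).
#' @slot vesselPeakHU,myocardiumHU,bloodPoolHU,lungHU tissue plateaus (HU).
#' @slot noiseSdHU additive Gaussian noise sigma (HU).
#' @slot partialVolumeSigmaVox pre-noise Gaussian blur, voxels.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [makeCardiacPhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric",
                 centerlines = "list", radiiMM = "list",
                 heartCenter = "numeric", heartSemiaxesMM = "numeric",
                 poolSemiaxesMM = "numeric",
                 vesselPeakHU = "numeric", myocardiumHU = "numeric",
                 bloodPoolHU = "numeric", lungHU = "numeric",
                 noiseSdHU = "numeric", partialVolumeSigmaVox = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!(object@vesselPeakHU > 120 && 120 > object@myocardiumHU))
    return("need vesselPeakHU > 120 > myocardiumHU (seed threshold must separate them)")
  if (length(object@centerlines) != length(object@radiiMM))
    return("one radius profile per centerline required")
  for (r in object@radiiMM)
    if (any(r <= 0)) return("radius profiles must be strictly positive")
  if (object@noiseSdHU < 0) return("noiseSdHU must be >= 0")
  TRUE
})

#' VSweepResult: trace and outcome of the heuristic bounds sweep
#'
#' Records the (v_i, N_i) pairs of the sweep over the bounds multiplier v,
#' the selected v (last value before the mutation jump), how the sweep
#' terminated, and the segmentation at the selected v.
#'
#' @slot trace data.frame with columns \code{v} and \code{n_voxels}.
#' @slot selectedV the chosen bounds multiplier.
#' @slot terminatedBy "mutation" or "max_v".
#' @slot mask BinaryMask3D at \code{selectedV}.
#' @seealso [vSweep()]
#' @export
setClass("VSweepResult",
  representation(trace = "data.frame", selectedV = "numeric",
                 terminatedBy = "character", mask = "BinaryMask3D"))

setValidity("VSweepResult", function(object) {
  tr <- object@trace
  if (!all(c("v", "n_voxels") %in% names(tr)))
    return("trace needs columns v and n_voxels")
  if (nrow(tr) > 1 && any(diff(tr$v) <= 0))
    return("trace v values must be strictly increasing")
  if (!object@terminatedBy %in% c("mutation", "max_v"))
    return("terminatedBy must be 'mutation' or 'max_v'")
  TRUE
})

#' SegmentationResult: everything the end-to-end pipeline produced
#'
#' @slot vesselMask final coronary segmentation (subset of heartMask).
#' @slot heartMask heart region of interest.
#' @slot seeds SeedSet used by the growing stage.
#' @slot sweep VSweepResult of the bounds selection.
#' @slot timings data.frame (stage, seconds).
#' @slot log character vector of stage-boundary log lines.
#' @seealso [runPipeline()]
#' @export
setClass("SegmentationResult",
  representation(vesselMask = "BinaryMask3D", heartMask = "BinaryMask3D",
                 seeds = "SeedSet", sweep = "VSweepResult",
                 timings = "data.frame", log = "character"))

setValidity("SegmentationResult", function(object) {
  if (any(object@vesselMask@data & !object@heartMask@data))
    return("vesselMask must be a subset of heartMask")
  TRUE
})
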