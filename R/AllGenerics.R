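#' @rdname Volume3D
#' @param x,object a Volume3D (or subclass)
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname Volume3D
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname Volume3D
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname Volume3D
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Map points through a spatial transform
#'
#' Applies an [AffineTransform3D-class] or [BSplineTransform3D-class] to world
#' coordinates: rows of \code{points} are (x, y, z) in mm.
#'
#' @param transform the transform.
#' @param points n x 3 numeric matrix of world mm coordinates.
#' @return n x 3 matrix of mapped world coordinates.
#' @export
setGeneric("transformPoints",
           function(transform, points) standardGeneric("transformPoints"))

#' @rdname SeedSet
#' @param x a SeedSet
#' @export
setGeneric("seedCoords", function(x) standardGeneric("seedCoords"))

#' @rdname VSweepResult
#' @param x a VSweepResult
#' @export
setGeneric("sweepTrace", function(x) standardGeneric("sweepTrace"))

#' @rdname VSweepResult
#' @export
setGeneric("selectedV", function(x) standardGeneric("selectedV"))
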