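#' Construct a Volume3D
#'
#' @param data 3D numeric array in (z, y, x) order.
#' @param spacing numeric(3), mm per voxel along (z, y, x).
#' @param origin numeric(3), world (x, y, z) mm of voxel (1, 1, 1).
#' @return a [Volume3D-class].
#' @examples
#' v <- Volume3D(array(0, c(4, 5, 6)), spacing = c(0.4, 0.33, 0.33))
#' gridDim(v)
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(data)) storage.mode(data) <- "double"
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask3D
#'
#' @param data 3D logical array (numeric 0/1 accepted and coerced).
#' @param spacing,origin grid geometry, as for [Volume3D()].
#' @param grid optional Volume3D whose geometry the mask shares (overrides
#'   \code{spacing}/\code{origin}).
#' @return a [BinaryMask3D-class].
#' @export
BinaryMask3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         grid = NULL) {
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask values must be exactly {0, 1}")
    data <- array(as.logical(data), dim(data))
  }
  if (!is.null(grid)) {
    spacing <- voxelSpacing(grid)
    origin <- voxelOrigin(grid)
    if (!all(dim(data) == gridDim(grid)))
      stop("mask shape does not match its companion grid")
  }
  new("BinaryMask3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname Volume3D
#' @export
setMethod("volData", "Volume3D", function(x) x@data)

#' @rdname Volume3D
#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)

#' @rdname Volume3D
#' @export
setMethod("voxelOrigin", "Volume3D", function(x) x@origin)

#' @rdname Volume3D
#' @export
setMethod("gridDim", "Volume3D", function(x) dim(x@data))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels (z,y,x)\n", class(object),
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x): %s mm\n",
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  origin  (x,y,z): %s mm\n",
              paste(signif(object@origin, 4), collapse = ", ")))
  if (is.logical(object@data)) {
    cat(sprintf("  foreground voxels: %d\n", sum(object@data)))
  } else {
    rng <- range(object@data)
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
  }
})

#' Do two volumes/masks share the same grid?
#'
#' Shape must match exactly; spacing and origin within 1e-6 mm.
#'
#' @param a,b Volume3D or BinaryMask3D.
#' @return logical scalar.
#' @export
sameGrid <- function(a, b) {
  all(dim(a@data) == dim(b@data)) &&
    all(abs(a@spacing - b@spacing) < 1e-6) &&
    all(abs(a@origin - b@origin) < 1e-6)
}

.stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(sprintf("grid mismatch: %s must share shape, spacing and origin",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Voxel index to world coordinates
#'
#' \code{world = origin + (index - 1) * spacing}, mapping the (k, j, i) =
#' (z, y, x) index order to (x, y, z) world order. Accepts a single index or
#' an n x 3 matrix of (k, j, i) rows; fractional (continuous) indices are
#' allowed except that integer indices are bounds-checked.
#'
#' @param grid a Volume3D/BinaryMask3D (or anything with the grid accessors).
#' @param index integer(3) (k, j, i), 1-based, or an n x 3 matrix.
#' @return numeric(3) world (x, y, z) mm, or an n x 3 matrix.
#' @examples
#' v <- Volume3D(array(0, c(8, 8, 8)))
#' voxelToWorld(v, c(3, 4, 5))  # -> c(4, 3, 2)
#' @export
voxelToWorld <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  d <- gridDim(grid)
  if (any(idx < 1) || any(t(t(idx) > d)))
    stop("voxel index out of bounds", call. = FALSE)
  sp <- voxelSpacing(grid); or <- voxelOrigin(grid)
  w <- cbind(or[1] + (idx[, 3] - 1) * sp[3],
             or[2] + (idx[, 2] - 1) * sp[2],
             or[3] + (idx[, 1] - 1) * sp[1])
  if (is.matrix(index)) w else drop(w)
}

#' World coordinates to (continuous) voxel index
#'
#' Inverse of [voxelToWorld()]; returns fractional (k, j, i) indices, not
#' rounded and not bounds-checked (out-of-domain queries are the caller's
#' concern, e.g. during resampling).
#'
#' @param grid a Volume3D/BinaryMask3D.
#' @param world numeric(3) (x, y, z) mm or an n x 3 matrix.
#' @return numeric(3) (k, j, i) or an n x 3 matrix.
#' @export
worldToVoxel <- function(grid, world) {
  w <- if (is.matrix(world)) world else matrix(world, nrow = 1)
  sp <- voxelSpacing(grid); or <- voxelOrigin(grid)
  idx <- cbind((w[, 3] - or[3]) / sp[1] + 1,
               (w[, 2] - or[2]) / sp[2] + 1,
               (w[, 1] - or[1]) / sp[3] + 1)
  if (is.matrix(world)) idx else drop(idx)
}

# Evaluate RNG-dependent code under a local, restorable seed so no global
# state leaks between pipeline stages.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

# Shift a 3D array by integer offsets s = (dz, dy, dx); out[x] = a[x - s],
# vacated voxels take `fill`.
.shift3 <- function(a, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  if (any(abs(s) >= d)) return(out)
  dst <- src <- vector("list", 3)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      dst[[ax]] <- seq.int(1 + s[ax], d[ax])
      src[[ax]] <- seq.int(1, d[ax] - s[ax])
    } else {
      dst[[ax]] <- seq.int(1, d[ax] + s[ax])
      src[[ax]] <- seq.int(1 - s[ax], d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Linear index <-> (k, j, i) for dim d = (nz, ny, nx); R column-major order.
.linToKJI <- function(lin, d) {
  lin0 <- lin - 1L
  k <- lin0 %% d[1]
  rest <- lin0 %/% d[1]
  j <- rest %% d[2]
  i <- rest %/% d[2]
  cbind(k = k + 1L, j = j + 1L, i = i + 1L)
}

.kjiToLin <- function(kji, d) {
  (kji[, 3] - 1L) * (d[1] * d[2]) + (kji[, 2] - 1L) * d[1] + kji[, 1]
}
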