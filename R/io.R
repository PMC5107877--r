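#' Read a 3D volume from NIfTI-1 or MetaImage
#'
#' Supported formats: NIfTI-1 (\code{.nii}, \code{.nii.gz}) via RNifti, and
#' MetaImage (\code{.mha} single-file, or \code{.mhd} header + \code{.raw}).
#' Spacing and origin are taken from the file header; intensities are not
#' modified (HU calibration is assumed already applied by the source).
#' Oblique orientation matrices are not interpreted: the voxel lattice is
#' read as axis-aligned, with spacing magnitudes and the header translation
#' as origin.
#'
#' @param path file path.
#' @return a [Volume3D-class]; the file's (x, y, z) raster is stored in the
#'   package's (z, y, x) array order.
#' @export
loadVolume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- tryCatch(RNifti::readNifti(path), error = function(e)
      stop(sprintf("not a readable NIfTI-1 file: '%s' (%s)", path,
                   conditionMessage(e)), call. = FALSE))
    if (length(dim(img)) != 3L)
      stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
    sp_xyz <- abs(RNifti::pixdim(img))[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    or_xyz <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
    arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    return(Volume3D(arr, spacing = rev(sp_xyz), origin = or_xyz))
  }
  if (grepl("\\.mhd?a?$", low) && grepl("\\.(mha|mhd)$", low))
    return(.readMetaImage(path))
  stop(sprintf(paste0("unsupported volume format: '%s' ",
                      "(expected .nii, .nii.gz, .mha or .mhd)"), path),
       call. = FALSE)
}

#' Write a 3D volume to NIfTI-1 or MetaImage
#'
#' The output format follows the file extension. The header records voxel
#' spacing and origin, so [loadVolume()] round-trips grid geometry; integer
#' element types round-trip bit-for-bit.
#'
#' @param vol a [Volume3D-class] or [BinaryMask3D-class].
#' @param path output path (\code{.nii}, \code{.nii.gz}, \code{.mha},
#'   \code{.mhd}).
#' @param elementType storage type: \code{"auto"} picks 8-bit unsigned for
#'   masks, 16-bit signed for integer-valued data in range, 32-bit float
#'   otherwise; or force one of \code{"uchar"}, \code{"short"},
#'   \code{"float"}, \code{"double"}.
#' @return invisibly, \code{path}.
#' @export
saveVolume <- function(vol, path,
                       elementType = c("auto", "uchar", "short", "float",
                                       "double")) {
  elementType <- match.arg(elementType)
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': parent directory does not exist", path),
         call. = FALSE)
  dat <- vol@data
  if (is.logical(dat)) storage.mode(dat) <- "double"
  if (elementType == "auto") {
    v <- range(dat)
    isInt <- all(dat == round(dat))
    elementType <- if (isInt && v[1] >= 0 && v[2] <= 255) "uchar"
      else if (isInt && v[1] >= -32768 && v[2] <= 32767) "short"
      else "float"
  }
  arr <- aperm(dat, c(3, 2, 1))  # (x, y, z) raster for on-disk formats
  sp_xyz <- rev(vol@spacing)
  or_xyz <- vol@origin
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    dt <- switch(elementType, uchar = "uint8", short = "int16",
                 float = "float", double = "double")
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp_xyz
    m <- diag(c(sp_xyz, 1)); m[1:3, 4] <- or_xyz
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path, datatype = dt)
  } else if (grepl("\\.(mha|mhd)$", low)) {
    .writeMetaImage(arr, sp_xyz, or_xyz, path, elementType)
  } else {
    stop(sprintf("unsupported output format: '%s'", path), call. = FALSE)
  }
  invisible(path)
}

# ---- MetaImage (hand-rolled: header text + raw little-endian block) -------

.metaTypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

.readMetaImage <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  headerLines <- character()
  dataStart <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line <- rawToChar(raw[seq.int(prev + 1L, p - 1L)])
    line <- sub("\r$", "", line)
    headerLines <- c(headerLines, line)
    prev <- p
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { dataStart <- p; break }
  }
  if (is.na(dataStart))
    stop(sprintf("not a MetaImage file: '%s' (no ElementDataFile key)", path),
         call. = FALSE)
  kv <- strsplit(headerLines, "\\s*=\\s*")
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  names(vals) <- keys
  need <- function(k) {
    if (!k %in% keys)
      stop(sprintf("MetaImage '%s' lacks required key %s", path, k),
           call. = FALSE)
    vals[[k]]
  }
  if (!identical(need("NDims"), "3"))
    stop(sprintf("'%s': only 3D MetaImages are supported", path),
         call. = FALSE)
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])      # nx ny nz
  sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])  # sx sy sz
  or <- if ("Offset" %in% keys)
    as.numeric(strsplit(vals[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  et <- need("ElementType")
  tp <- .metaTypes[[et]]
  if (is.null(tp))
    stop(sprintf("'%s': unsupported ElementType %s", path, et), call. = FALSE)
  if (isTRUE(toupper(vals["BinaryDataByteOrderMSB"]) == "TRUE") ||
      isTRUE(toupper(vals["ElementByteOrderMSB"]) == "TRUE"))
    stop(sprintf("'%s': big-endian MetaImage not supported", path),
         call. = FALSE)
  dataFile <- vals[["ElementDataFile"]]
  n <- prod(dims)
  if (identical(dataFile, "LOCAL")) {
    payload <- raw[seq.int(dataStart + 1L, length(raw))]
  } else {
    rawPath <- file.path(dirname(path), dataFile)
    if (!file.exists(rawPath))
      stop(sprintf("'%s': raw data file '%s' missing", path, dataFile),
           call. = FALSE)
    payload <- readBin(rawPath, "raw", n = file.size(rawPath))
  }
  if (length(payload) < n * tp$size)
    stop(sprintf("'%s': truncated MetaImage (need %d bytes, found %d)",
                 path, n * tp$size, length(payload)), call. = FALSE)
  vec <- readBin(payload, tp$what, n = n, size = tp$size,
                 signed = tp$signed, endian = "little")
  arr <- array(as.numeric(vec), dims)              # (x, y, z)
  Volume3D(aperm(arr, c(3, 2, 1)), spacing = rev(sp), origin = or)
}

.writeMetaImage <- function(arrXYZ, sp_xyz, or_xyz, path, elementType) {
  et <- switch(elementType, uchar = "MET_UCHAR", short = "MET_SHORT",
               float = "MET_FLOAT", double = "MET_DOUBLE")
  tp <- .metaTypes[[et]]
  mhd <- grepl("\\.mhd$", tolower(path))
  dataFile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path),
                                  ignore.case = TRUE), ".raw") else "LOCAL"
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.10g %.10g %.10g", or_xyz[1], or_xyz[2], or_xyz[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g", sp_xyz[1], sp_xyz[2],
            sp_xyz[3]),
    sprintf("DimSize = %d %d %d", dim(arrXYZ)[1], dim(arrXYZ)[2],
            dim(arrXYZ)[3]),
    sprintf("ElementType = %s", et),
    sprintf("ElementDataFile = %s", dataFile))
  vec <- as.vector(arrXYZ)
  if (tp$what == "integer") vec <- as.integer(round(vec))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  if (mhd) {
    rawCon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rawCon), add = TRUE)
    writeBin(vec, rawCon, size = tp$size, endian = "little")
  } else {
    writeBin(vec, con, size = tp$size, endian = "little")
  }
  invisible(path)
}

# ---- Seed CSV -------------------------------------------------------------

#' Export / import a SeedSet as CSV
#'
#' The CSV has the header \code{k,j,i,x_mm,y_mm,z_mm}: 1-based voxel indices
#' in (z, y, x) order plus the corresponding world coordinates, one row per
#' seed, in the seed set's order.
#'
#' @param seeds a [SeedSet-class].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeSeedsCSV <- function(seeds, path) {
  df <- as.data.frame(seeds)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSeedsCSV
#' @param grid a Volume3D/BinaryMask3D supplying the grid the seeds index.
#' @return for \code{readSeedsCSV}, a [SeedSet-class].
#' @export
readSeedsCSV <- function(path, grid) {
  df <- read.csv(path)
  if (!all(c("k", "j", "i") %in% names(df)))
    stop(sprintf("'%s' is not a seed CSV (needs columns k,j,i)", path),
         call. = FALSE)
  new("SeedSet",
      coords = cbind(k = as.integer(df$k), j = as.integer(df$j),
                     i = as.integer(df$i)),
      gridDim = as.integer(gridDim(grid)), spacing = voxelSpacing(grid),
      origin = voxelOrigin(grid))
}

#' @describeIn SeedSet-class number of seeds
#' @export
setMethod("length", "SeedSet", function(x) nrow(x@coords))

#' @rdname SeedSet-class
#' @export
setMethod("seedCoords", "SeedSet", function(x) x@coords)

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d seeds on a %s grid\n", nrow(object@coords),
              paste(object@gridDim, collapse = " x ")))
  if (nrow(object@coords) > 0)
    print(head(as.data.frame(object), 5))
})

#' @rdname SeedSet-class
#' @param x a SeedSet
#' @param row.names,optional,... passed for S3 compatibility (unused)
#' @method as.data.frame SeedSet
#' @export
as.data.frame.SeedSet <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  co <- x@coords
  fake <- new("Volume3D", data = array(0, pmax(x@gridDim, 1L)),
              spacing = x@spacing, origin = x@origin)
  if (nrow(co) == 0)
    return(data.frame(k = integer(), j = integer(), i = integer(),
                      x_mm = numeric(), y_mm = numeric(), z_mm = numeric()))
  w <- voxelToWorld(fake, co)
  data.frame(k = co[, 1], j = co[, 2], i = co[, 3],
             x_mm = w[, 1], y_mm = w[, 2], z_mm = w[, 3])
}
setMethod("as.data.frame", "SeedSet", as.data.frame.SeedSet)
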