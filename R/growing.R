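#' Region-growing parameters
#'
#' @param v bounds multiplier of the intensity interval (dimensionless, > 0).
#' @param nRefinementIterations number of statistics re-estimation passes
#'   after the initial seed growth (each pass expands to closure).
#' @param connectivity 6, 18 or 26 (neighbourhood used throughout).
#' @param minStdHU floor on the standard deviation so uniform plateaus still
#'   grow (HU).
#' @return a classed parameter list.
#' @export
growthParams <- function(v, nRefinementIterations = 5L, connectivity = 26L,
                         minStdHU = 1) {
  if (v <= 0) stop("v must be > 0")
  if (nRefinementIterations < 0) stop("iterations must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (minStdHU < 0) stop("minStdHU must be >= 0")
  structure(list(v = v,
                 nRefinementIterations = as.integer(nRefinementIterations),
                 connectivity = as.integer(connectivity),
                 minStdHU = minStdHU), class = "GrowthParams")
}

#' Bounds-sweep parameters
#'
#' The sweep grows the region at v = v0, v0 + step, ... and stops at the
#' "mutation": an abrupt jump in the segmented-voxel count signalling that
#' the interval has engulfed the myocardium. In absolute mode the jump
#' threshold is a fixed voxel count (1e8 by convention); since that exceeds
#' the voxel count of typical scans, the relative mode (fraction of
#' heart-ROI voxels) is the default.
#'
#' @param v0 starting multiplier.
#' @param step grid increment.
#' @param mode "relative" or "absolute".
#' @param mutationFrac relative-mode threshold, fraction of heart-ROI voxels.
#' @param mutationAbs absolute-mode threshold, voxels.
#' @param maxV safety cap on the sweep.
#' @return a classed parameter list.
#' @export
vSweepParams <- function(v0 = 1.0, step = 0.1,
                         mode = c("relative", "absolute"),
                         mutationFrac = 0.5, mutationAbs = 1e8, maxV = 5.0) {
  mode <- match.arg(mode)
  if (step <= 0) stop("step must be > 0")
  if (mutationFrac <= 0 || mutationAbs <= 0)
    stop("mutation thresholds must be > 0")
  if (maxV < v0) stop("maxV must be >= v0")
  structure(list(v0 = v0, step = step, mode = mode,
                 mutationFrac = mutationFrac, mutationAbs = mutationAbs,
                 maxV = maxV), class = "VSweepParams")
}

#' Seed-neighbourhood intensity statistics
#'
#' Mean and population standard deviation over the seed voxel plus its
#' 26-neighbourhood (or 6/18), clipped at the volume border; the standard
#' deviation is floored at \code{minStdHU}.
#'
#' @param vol a [Volume3D-class].
#' @param seed integer(3) voxel index (k, j, i), 1-based.
#' @param connectivity 6, 18 or 26.
#' @param minStdHU variance floor (HU).
#' @return named numeric: \code{mean}, \code{sd}.
#' @export
seedStatistics <- function(vol, seed, connectivity = 26L, minStdHU = 1) {
  d <- gridDim(vol)
  if (any(seed < 1L) || any(seed > d))
    stop("seed index out of bounds", call. = FALSE)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = m <= 1, "18" = m <= 2, "26" = rep(TRUE, nrow(off)))
  off <- off[keep, , drop = FALSE]
  nb <- sweep(off, 2, as.integer(seed), "+")
  inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  vals <- vol@data[.kjiToLin(nb[inb, , drop = FALSE], d)]
  mu <- mean(vals)
  sdv <- sqrt(mean((vals - mu)^2))   # population sd
  c(mean = mu, sd = max(sdv, minStdHU))
}

#' Consistent intensity interval
#'
#' \code{[mean - v * sd, mean + v * sd]}: the acceptance interval of the
#' statistical region growing.
#'
#' @param mean,sd interval centre and spread (HU); \code{sd >= 0}.
#' @param v bounds multiplier (> 0).
#' @return named numeric: \code{low}, \code{high}.
#' @export
confidenceInterval <- function(mean, sd, v) {
  if (v <= 0) stop("v must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  c(low = unname(mean - v * sd), high = unname(mean + v * sd))
}

#' Statistical region growing from a seed set
#'
#' Phase 1 processes seeds in order: a seed already absorbed by the running
#' region is skipped (the depletion rule); otherwise its neighbourhood
#' statistics define an interval and a connected flood fill from the seed
#' through in-interval voxels (within the heart mask) is unioned into the
#' region. Phase 2 re-estimates mean and standard deviation over the entire
#' current region, rebuilds the interval, and expands the region to closure
#' through in-interval neighbours; this is repeated
#' \code{nRefinementIterations} times or until a pass adds nothing.
#'
#' @param vol HU volume.
#' @param heartMask growth is confined to this mask.
#' @param seeds a [SeedSet-class] (or n x 3 index matrix).
#' @param p a [growthParams()] list.
#' @param warnLeak warn when the region touches the heart-mask boundary
#'   (possible leakage).
#' @return a [BinaryMask3D-class].
#' @export
growFromSeeds <- function(vol, heartMask, seeds, p, warnLeak = TRUE) {
  .stopIfGridMismatch(vol, heartMask, "volume and heart mask")
  co <- if (is(seeds, "SeedSet")) seeds@coords else as.matrix(seeds)
  if (nrow(co) == 0L) stop("empty seed set", call. = FALSE)
  d <- gridDim(vol)
  dat <- vol@data
  mask <- heartMask@data
  region <- array(FALSE, d)
  lins <- .kjiToLin(co, d)
  for (s in seq_len(nrow(co))) {
    if (region[lins[s]]) next                      # absorbed: depleted
    st <- seedStatistics(vol, co[s, ], p$connectivity, p$minStdHU)
    iv <- confidenceInterval(st["mean"], st["sd"], p$v)
    adm <- mask & dat >= iv["low"] & dat <= iv["high"]
    grown <- cpp_flood(adm, d, as.integer(lins[s]), p$connectivity)
    region <- region | array(grown, d)
  }
  if (p$nRefinementIterations > 0 && any(region)) {
    for (it in seq_len(p$nRefinementIterations)) {
      vals <- dat[region]
      mu <- mean(vals)
      sdv <- max(sqrt(mean((vals - mu)^2)), p$minStdHU)
      iv <- confidenceInterval(mu, sdv, p$v)
      adm <- region | (mask & dat >= iv["low"] & dat <= iv["high"])
      grown <- array(cpp_flood(adm, d, which(region), p$connectivity), d)
      if (sum(grown) == sum(region)) break
      region <- grown
    }
  }
  if (warnLeak) {
    interior <- .shift3(mask, c(1, 0, 0)) & .shift3(mask, c(-1, 0, 0)) &
      .shift3(mask, c(0, 1, 0)) & .shift3(mask, c(0, -1, 0)) &
      .shift3(mask, c(0, 0, 1)) & .shift3(mask, c(0, 0, -1))
    if (any(region & mask & !interior))
      warning("grown region touches the heart-mask boundary (possible leakage)",
              call. = FALSE)
  }
  BinaryMask3D(region, spacing = vol@spacing, origin = vol@origin)
}

#' Number of segmented voxels
#'
#' @param mask a [BinaryMask3D-class].
#' @return integer count of 1-voxels.
#' @export
countSegmented <- function(mask) sum(mask@data)

#' Heuristic bounds sweep with mutation detection
#'
#' Runs [growFromSeeds()] at v = v0, v0 + step, ... recording the
#' segmented-voxel count N_i. The sweep stops when N_i - N_{i-1} exceeds
#' the mutation threshold (the segmented count jumping by a large fraction
#' of the heart region means the interval has engulfed the myocardium), and
#' the selected v is the last value before the jump; or when v passes
#' \code{maxV}, with a warning.
#'
#' @param vol,heartMask,seeds as in [growFromSeeds()].
#' @param sweep a [vSweepParams()] list.
#' @param growth a [growthParams()] list whose \code{v} is overridden by the
#'   sweep; pass \code{growthParams(v = 1)} defaults otherwise.
#' @return a [VSweepResult-class].
#' @export
vSweep <- function(vol, heartMask, seeds, sweep = vSweepParams(),
                   growth = growthParams(v = 1)) {
  thr <- if (sweep$mode == "absolute") sweep$mutationAbs
    else sweep$mutationFrac * sum(heartMask@data)
  vs <- numeric(); ns <- numeric()
  masks <- list()   # keep last two masks only
  v <- sweep$v0
  i <- 0L
  selected <- NA_real_
  terminated <- NA_character_
  repeat {
    i <- i + 1L
    g <- growth; g$v <- v
    m <- growFromSeeds(vol, heartMask, seeds, g, warnLeak = FALSE)
    vs[i] <- v
    ns[i] <- countSegmented(m)
    masks <- c(masks[length(masks)], list(m))
    if (i > 1L && (ns[i] - ns[i - 1L]) > thr) {
      selected <- vs[i - 1L]
      terminated <- "mutation"
      sel <- masks[[1]]
      if (i == 2L)
        warning("mutation at the very first increment; selected v = v0",
                call. = FALSE)
      break
    }
    vNext <- sweep$v0 + i * sweep$step
    if (vNext > sweep$maxV + 1e-9) {
      selected <- v
      terminated <- "max_v"
      sel <- masks[[length(masks)]]
      warning(sprintf(
        "no mutation detected by maxV = %.3g; selected v = %.3g", sweep$maxV,
        selected), call. = FALSE)
      break
    }
    v <- vNext
  }
  new("VSweepResult",
      trace = data.frame(v = vs, n_voxels = ns),
      selectedV = selected, terminatedBy = terminated, mask = sel)
}

#' @rdname VSweepResult-class
#' @export
setMethod("sweepTrace", "VSweepResult", function(x) x@trace)

#' @rdname VSweepResult-class
#' @export
setMethod("selectedV", "VSweepResult", function(x) x@selectedV)

#' @rdname VSweepResult-class
#' @param object a VSweepResult
#' @export
setMethod("show", "VSweepResult", function(object) {
  cat(sprintf("VSweepResult: %d sweep points, terminated by %s\n",
              nrow(object@trace), object@terminatedBy))
  cat(sprintf("  selected v = %.3g (%d voxels)\n", object@selectedV,
              countSegmented(object@mask)))
})
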