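#' Ideal bright-line phantom
#'
#' A straight tube along the z-axis through the (x, y) in-plane centre voxel
#' with the ideal Gaussian cross-section
#' \eqn{I(x, y, z) = peak \cdot \exp(-(x^2+y^2)/(2\sigma^2))}, distances in
#' voxels from the line axis. The on-axis value equals \code{peak} exactly.
#' This is the analytic fixture for the Hessian/eigenvalue oracle tests.
#'
#' @param shape integer(3) (nz, ny, nx).
#' @param spacing numeric(3) mm (z, y, x).
#' @param sigmaVoxels Gaussian width of the line cross-section, voxels (> 0).
#' @param peak plateau intensity on the axis.
#' @return a [Volume3D-class].
#' @export
makeLinePhantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                            sigmaVoxels, peak = 350) {
  if (sigmaVoxels <= 0) stop("sigmaVoxels must be > 0")
  shape <- as.integer(shape)
  cy <- (shape[2] + 1L) %/% 2L
  cx <- (shape[3] + 1L) %/% 2L
  y2 <- (seq_len(shape[2]) - cy)^2
  x2 <- (seq_len(shape[3]) - cx)^2
  r2 <- outer(y2, x2, "+")                       # (ny, nx)
  sl <- peak * exp(-r2 / (2 * sigmaVoxels^2))
  dat <- aperm(array(sl, c(shape[2], shape[3], shape[1])), c(3, 1, 2))
  Volume3D(dat, spacing = spacing)
}

#' Build a PhantomSpec
#'
#' Defaults describe the package's reference cardiac phantom: a 64^3 grid at
#' 0.5 mm isotropic spacing holding a myocardium ellipsoid (60 HU) with a
#' blood-pool ellipsoid (300 HU) inside it and two disjoint curved coronary
#' tubes (peak 350 HU, lumen radii 1.5 and 1.2 mm) running inside the
#' myocardium, on a lung background (-800 HU). Intensities are ordered as in
#' contrast CTA: lung << myocardium < 120 HU seed threshold < vessel.
#'
#' @param shape,spacing,origin grid geometry; see [Volume3D()].
#' @param centerlines list of n x 3 world-mm polylines; NULL for the default
#'   two-vessel geometry.
#' @param radiiMM list of per-vertex lumen radii matching
#'   \code{centerlines}; recycled from scalars.
#' @param heartSemiaxesMM,poolSemiaxesMM ellipsoid semi-axes (x, y, z) mm.
#' @param vesselPeakHU,myocardiumHU,bloodPoolHU,lungHU tissue levels.
#' @param noiseSdHU additive Gaussian noise sigma (HU).
#' @param partialVolumeSigmaVox pre-noise blur in voxels (0 disables).
#' @param seed RNG seed for the noise.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(0.5, 0.5, 0.5),
                        origin = c(0, 0, 0), centerlines = NULL,
                        radiiMM = NULL,
                        heartSemiaxesMM = c(13, 13, 11),
                        poolSemiaxesMM = c(6, 6, 5),
                        vesselPeakHU = 350, myocardiumHU = 60,
                        bloodPoolHU = 300, lungHU = -800,
                        noiseSdHU = 10, partialVolumeSigmaVox = 0.5,
                        seed = 1L) {
  shape <- as.integer(shape)
  centre <- c(origin[1] + (shape[3] - 1) * spacing[3] / 2,
              origin[2] + (shape[2] - 1) * spacing[2] / 2,
              origin[3] + (shape[1] - 1) * spacing[1] / 2)
  if (is.null(centerlines)) {
    arc <- function(thetas, a, zAmp, zFreq, zOff = 0) {
      cbind(centre[1] + a * cos(thetas),
            centre[2] + a * sin(thetas),
            centre[3] + zOff + zAmp * sin(zFreq * thetas))
    }
    centerlines <- list(arc(seq(-2, 2, length.out = 121), 9.5, 4, 1.3),
                        arc(seq(2.6, 3.8, length.out = 49), 9.5, 2, 1, -2))
    if (is.null(radiiMM)) radiiMM <- list(1.5, 1.2)
  }
  if (is.null(radiiMM)) radiiMM <- rep(list(1.5), length(centerlines))
  radiiMM <- mapply(function(r, cl) rep_len(r, nrow(cl)), radiiMM,
                    centerlines, SIMPLIFY = FALSE)
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      origin = as.numeric(origin), centerlines = centerlines,
      radiiMM = radiiMM, heartCenter = centre,
      heartSemiaxesMM = heartSemiaxesMM, poolSemiaxesMM = poolSemiaxesMM,
      vesselPeakHU = vesselPeakHU, myocardiumHU = myocardiumHU,
      bloodPoolHU = bloodPoolHU, lungHU = lungHU, noiseSdHU = noiseSdHU,
      partialVolumeSigmaVox = partialVolumeSigmaVox, seed = as.integer(seed))
}

#' Apply a stenosis (local radius reduction) to a radius profile
#'
#' Multiplies the lumen radius by \code{1 - factor} over a window of
#' centerline arc length, modelling a focal narrowing.
#'
#' @param centerline n x 3 polyline (world mm).
#' @param radii length-n radius profile (mm).
#' @param centerMM arc-length position of the stenosis centre (mm).
#' @param extentMM length of the narrowed span (mm).
#' @param factor radius reduction factor in [0, 1).
#' @return modified radius vector.
#' @export
stenoseRadii <- function(centerline, radii, centerMM, extentMM, factor) {
  if (factor < 0 || factor >= 1) stop("stenosis factor must be in [0, 1)")
  s <- c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
  inWin <- abs(s - centerMM) <= extentMM / 2
  radii[inWin] <- radii[inWin] * (1 - factor)
  radii
}

# Resample a polyline (+ radius profile) to a fixed arc-length step.
.resampleCurve <- function(cl, radii, stepMM) {
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  if (max(s) == 0) return(list(pts = cl[1, , drop = FALSE], r = radii[1]))
  ss <- seq(0, max(s), by = stepMM)
  pts <- cbind(approx(s, cl[, 1], ss)$y, approx(s, cl[, 2], ss)$y,
               approx(s, cl[, 3], ss)$y)
  list(pts = pts, r = approx(s, radii, ss)$y)
}

#' Generate the synthetic cardiac CTA phantom
#'
#' Rasterises the [phantomSpec()] scene: lung background, myocardium and
#' blood-pool ellipsoids, and contrast tubes whose radial profile is the
#' ideal Gaussian line scaled so the intensity is at least half the peak
#' inside the nominal lumen radius (the profile is truncated at the lumen
#' wall; the partial-volume blur then produces the soft edge). Centerlines
#' are sampled at arc steps of a quarter of the smallest voxel spacing and
#' each voxel takes the maximum profile over samples, so curved tubes have
#' no rasterisation gaps. Identical spec (including seed) gives bit-identical
#' output.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{volume} ([Volume3D-class]),
#'   \code{heartGold} and \code{vesselGold} ([BinaryMask3D-class]): the gold
#'   vessel mask marks voxels within the nominal radius of any centerline,
#'   the gold heart mask the ellipsoid union the tubes.
#' @export
makeCardiacPhantom <- function(spec) {
  validObject(spec)
  d <- spec@shape; sp <- spec@spacing; or <- spec@origin
  wx <- or[1] + (seq_len(d[3]) - 1) * sp[3]
  wy <- or[2] + (seq_len(d[2]) - 1) * sp[2]
  wz <- or[3] + (seq_len(d[1]) - 1) * sp[1]
  C <- spec@heartCenter
  ell <- function(semi) {
    zs <- ((wz - C[3]) / semi[3])^2
    ys <- ((wy - C[2]) / semi[2])^2
    xs <- ((wx - C[1]) / semi[1])^2
    outer(outer(zs, ys, "+"), xs, "+") <= 1
  }
  heartEll <- ell(spec@heartSemiaxesMM)
  pool <- ell(spec@poolSemiaxesMM)
  vol <- array(spec@lungHU, d)
  vol[heartEll] <- spec@myocardiumHU
  vol[pool] <- spec@bloodPoolHU
  tube <- array(-Inf, d)
  gold <- array(FALSE, d)
  domainLo <- c(or[1], or[2], or[3])
  domainHi <- c(wx[d[3]], wy[d[2]], wz[d[1]])
  step <- 0.25 * min(sp)
  for (ci in seq_along(spec@centerlines)) {
    rs <- .resampleCurve(spec@centerlines[[ci]], spec@radiiMM[[ci]], step)
    # pre-flight containment checks over the resampled curve
    pe <- ((rs$pts[, 1] - C[1]) / spec@heartSemiaxesMM[1])^2 +
      ((rs$pts[, 2] - C[2]) / spec@heartSemiaxesMM[2])^2 +
      ((rs$pts[, 3] - C[3]) / spec@heartSemiaxesMM[3])^2
    if (any(pe > 1))
      stop(sprintf("centerline %d leaves the myocardium ellipsoid", ci),
           call. = FALSE)
    escapes <- FALSE
    for (ax in 1:3)
      escapes <- escapes || any(rs$pts[, ax] - rs$r < domainLo[ax]) ||
        any(rs$pts[, ax] + rs$r > domainHi[ax])
    if (escapes)
      stop(sprintf("centerline %d (plus its radius) escapes the volume", ci),
           call. = FALSE)
    for (s in seq_len(nrow(rs$pts))) {
      p <- rs$pts[s, ]; R <- rs$r[s]
      sig2 <- (R / sqrt(2 * log(2)))^2
      iR <- seq.int(max(1L, floor((p[1] - R - or[1]) / sp[3]) + 1L),
                    min(d[3], ceiling((p[1] + R - or[1]) / sp[3]) + 1L))
      jR <- seq.int(max(1L, floor((p[2] - R - or[2]) / sp[2]) + 1L),
                    min(d[2], ceiling((p[2] + R - or[2]) / sp[2]) + 1L))
      kR <- seq.int(max(1L, floor((p[3] - R - or[3]) / sp[1]) + 1L),
                    min(d[1], ceiling((p[3] + R - or[3]) / sp[1]) + 1L))
      dz2 <- (wz[kR] - p[3])^2
      dy2 <- (wy[jR] - p[2])^2
      dx2 <- (wx[iR] - p[1])^2
      d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
      hit <- d2 <= R^2
      if (!any(hit)) next
      prof <- spec@vesselPeakHU * exp(-d2 / (2 * sig2))
      prof[!hit] <- -Inf
      cur <- tube[kR, jR, iR]
      tube[kR, jR, iR] <- pmax(cur, prof)
      g <- gold[kR, jR, iR]
      gold[kR, jR, iR] <- g | hit
    }
  }
  vol <- pmax(vol, tube)
  heartGold <- heartEll | gold
  if (spec@partialVolumeSigmaVox > 0) {
    for (ax in 1:3)
      vol <- .convAxis(vol, .gaussKernel1D(spec@partialVolumeSigmaVox *
                                             sp[ax], sp[ax], 0L), ax)
  }
  if (spec@noiseSdHU > 0) {
    vol <- withSeed(spec@seed,
                    vol + array(rnorm(prod(d), 0, spec@noiseSdHU), d))
  }
  list(volume = Volume3D(vol, spacing = sp, origin = or),
       heartGold = BinaryMask3D(heartGold, spacing = sp, origin = or),
       vesselGold = BinaryMask3D(gold, spacing = sp, origin = or))
}

# ---- synthetic atlases ----------------------------------------------------

# A smooth spatial map phi(x) = M (x - C) + C + t + sum_w a_w sin(2 pi f_w.x
# + p_w) used both to synthesise atlases and as registration ground truth.
.applyDeformation <- function(def, pts) {
  out <- sweep(pts, 2, def$center) %*% t(def$matrix)
  out <- sweep(out, 2, def$center + def$translation, "+")
  if (length(def$waves) > 0) {
    for (w in def$waves) {
      ph <- 2 * pi * (pts %*% w$freq) + w$phase
      out <- out + sin(as.vector(ph)) %o% w$amp
    }
  }
  out
}

#' Evaluate a synthetic atlas deformation at world points
#'
#' Returns phi(points) for a deformation produced by [makeAtlasSet()]; used
#' to form registration ground truth (for a recovered patient-to-atlas
#' transform T, phi(T(x)) should be close to x).
#'
#' @param def a deformation entry (\code{$deformation} of an atlas).
#' @param points n x 3 world-mm matrix.
#' @return n x 3 matrix of mapped points.
#' @export
deformationApply <- function(def, points) .applyDeformation(def, points)

#' Generate a synthetic atlas set from a phantom spec
#'
#' Each atlas is the base phantom resampled through a known random smooth
#' deformation (small affine about the volume centre plus low-frequency
#' sinusoidal displacement), with its heart label warped identically
#' (nearest neighbour). The applied deformations are returned as
#' registration ground truth. \code{deformMagnitudeVox} controls the
#' approximate peak displacement in voxels; 0 yields atlases identical to
#' the base phantom.
#'
#' @param spec a [PhantomSpec-class].
#' @param nAtlases number of atlases (>= 1).
#' @param deformMagnitudeVox approximate peak deformation, voxels.
#' @param seed RNG seed for the deformation draws.
#' @param translationsMM optional list of fixed (x, y, z) mm translations,
#'   one per atlas, used instead of random deformations.
#' @return list of atlases, each \code{list(volume, label, deformation)}.
#' @export
makeAtlasSet <- function(spec, nAtlases, deformMagnitudeVox = 0, seed = 1L,
                         translationsMM = NULL) {
  if (nAtlases < 1) stop("nAtlases must be >= 1")
  base <- makeCardiacPhantom(spec)
  vol <- base$volume
  lbl <- base$heartGold
  d <- gridDim(vol)
  C <- spec@heartCenter
  extent <- max((d - 1) * voxelSpacing(vol))
  meanSp <- mean(voxelSpacing(vol))
  defs <- withSeed(seed, lapply(seq_len(nAtlases), function(a) {
    if (!is.null(translationsMM)) {
      tr <- if (is.list(translationsMM)) translationsMM[[a]]
        else translationsMM
      return(list(matrix = diag(3), center = C, translation = as.numeric(tr),
                  waves = list()))
    }
    mag <- deformMagnitudeVox * meanSp
    if (mag == 0)
      return(list(matrix = diag(3), center = C, translation = c(0, 0, 0),
                  waves = list()))
    thetaMax <- 0.3 * mag / (extent / 2)
    th <- runif(3, -thetaMax, thetaMax)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    sc <- diag(1 + runif(3, -0.15, 0.15) * mag / (extent / 2))
    tr <- runif(3, -1, 1) * 0.4 * mag
    waves <- lapply(1:2, function(w) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      wavelength <- extent / runif(1, 1, 2)
      list(amp = rnorm(3, 0, 1) / sqrt(3) * 0.3 * mag,
           freq = dir / wavelength, phase = runif(1, 0, 2 * pi))
    })
    list(matrix = Rz %*% Ry %*% Rx %*% sc, center = C, translation = tr,
         waves = waves)
  }))
  allIdx <- .linToKJI(seq_len(prod(d)), d)
  allW <- voxelToWorld(vol, allIdx)
  lapply(defs, function(def) {
    mapped <- .applyDeformation(def, allW)
    iv <- .interpTrilinear(vol, mapped)
    av <- ifelse(iv$inside, iv$value, spec@lungHU)
    kji <- round(worldToVoxel(vol, mapped))
    inb <- kji[, 1] >= 1 & kji[, 1] <= d[1] & kji[, 2] >= 1 &
      kji[, 2] <= d[2] & kji[, 3] >= 1 & kji[, 3] <= d[3]
    lv <- logical(nrow(kji))
    lv[inb] <- lbl@data[.kjiToLin(kji[inb, , drop = FALSE], d)]
    list(volume = Volume3D(array(av, d), voxelSpacing(vol),
                           voxelOrigin(vol)),
         label = BinaryMask3D(array(lv, d), voxelSpacing(vol),
                              voxelOrigin(vol)),
         deformation = def)
  })
}

#' Two-population sweep phantom
#'
#' A deliberately simple scene for studying the mutation sweep: a straight
#' contrast tube along z through the volume centre embedded in uniform
#' myocardium. The tube carries a deterministic two-level +/- texture whose
#' sample mean and standard deviation equal \code{vesselHU} and
#' \code{textureHU} exactly (the darker level is made at least as frequent),
#' so the sweep's flooding point is exactly predictable from the Eq.-style
#' interval bound: the first grid v with \code{mean - v * sd <=
#' myocardiumHU}. The myocardium sits exactly at its nominal level so no
#' myocardium voxel can enter the region before that bound is reached.
#'
#' @param shape,spacing grid geometry.
#' @param vesselHU,textureHU tube mean and texture half-amplitude (HU).
#' @param myocardiumHU background level (HU).
#' @param radiusMM tube lumen radius, mm.
#' @return list with \code{volume}, \code{vesselGold}, \code{heartMask}
#'   (whole volume) and \code{seed} (the centre-axis voxel, integer(3)).
#' @export
makeTwoPopulationPhantom <- function(shape = c(64, 64, 64),
                                     spacing = c(0.5, 0.5, 0.5),
                                     vesselHU = 300, textureHU = 10,
                                     myocardiumHU = 60, radiusMM = 2) {
  d <- as.integer(shape)
  cy <- (d[2] + 1L) %/% 2L; cx <- (d[3] + 1L) %/% 2L
  y2 <- ((seq_len(d[2]) - cy) * spacing[2])^2
  x2 <- ((seq_len(d[3]) - cx) * spacing[3])^2
  inTube2D <- outer(y2, x2, "+") <= radiusMM^2
  tube <- aperm(array(inTube2D, c(d[2], d[3], d[1])), c(3, 1, 2))
  k <- slice.index(tube, 1); j <- slice.index(tube, 2)
  i <- slice.index(tube, 3)
  par <- (k + j + i) %% 2 == 0
  # choose the texture phase so the darker level is >= as frequent
  if (sum(tube & par) > sum(tube & !par)) par <- !par
  vol <- array(myocardiumHU, d)
  vol[tube] <- vesselHU + ifelse(par[tube], textureHU, -textureHU)
  list(volume = Volume3D(vol, spacing = spacing),
       vesselGold = BinaryMask3D(tube, spacing = spacing),
       heartMask = BinaryMask3D(array(TRUE, d), spacing = spacing),
       seed = c((d[1] + 1L) %/% 2L, cy, cx))
}
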