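#' Pipeline configuration
#'
#' Bundles every stage's parameter block plus the global RNG seed. Defaults
#' are the method's standard operating point: 120 HU seed threshold, 4 x 4 x 3
#' erosion kernel, v0 = 1.0 with step 0.1 and 5 refinement iterations for
#' the growing, 256 affine iterations and a 50 mm mutual-information
#' neighbourhood for the registration.
#'
#' @param registration a [registrationOptions()] list.
#' @param vesselness a [vesselnessParams()] list.
#' @param seeds a [seedDetectionParams()] list.
#' @param growth a [growthParams()] list (its \code{v} is overridden by the
#'   sweep unless \code{fixedV} is set).
#' @param sweep a [vSweepParams()] list.
#' @param fixedV optional fixed bounds multiplier; skips the sweep.
#' @param rngSeed global seed; stage seeds are derived from it.
#' @return a classed configuration list.
#' @export
pipelineConfig <- function(registration = registrationOptions(),
                           vesselness = vesselnessParams(),
                           seeds = seedDetectionParams(),
                           growth = growthParams(v = 1),
                           sweep = vSweepParams(),
                           fixedV = NULL,
                           rngSeed = 17L) {
  stopifnot(inherits(registration, "RegistrationOptions"),
            inherits(vesselness, "VesselnessParams"),
            inherits(seeds, "SeedDetectionParams"),
            inherits(growth, "GrowthParams"),
            inherits(sweep, "VSweepParams"))
  if (!is.null(fixedV) && fixedV <= 0) stop("fixedV must be > 0")
  structure(list(registration = registration, vesselness = vesselness,
                 seeds = seeds, growth = growth, sweep = sweep,
                 fixedV = fixedV, rngSeed = as.integer(rngSeed)),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the constructor arguments as one flat document of
#' parameter blocks; unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return a [pipelineConfig()] list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("registration", "vesselness", "seeds", "growth", "sweep",
             "fixedV", "rngSeed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  build <- function(ctor, args) do.call(ctor, as.list(args))
  pipelineConfig(
    registration = if (is.null(y$registration)) registrationOptions()
      else build(registrationOptions, y$registration),
    vesselness = if (is.null(y$vesselness)) vesselnessParams()
      else build(vesselnessParams, y$vesselness),
    seeds = if (is.null(y$seeds)) seedDetectionParams()
      else build(seedDetectionParams, y$seeds),
    growth = if (is.null(y$growth)) growthParams(v = 1)
      else build(growthParams, c(list(v = 1), y$growth)),
    sweep = if (is.null(y$sweep)) vSweepParams()
      else build(vSweepParams, y$sweep),
    fixedV = y$fixedV,
    rngSeed = if (is.null(y$rngSeed)) 17L else y$rngSeed)
}

#' @rdname readPipelineConfig
#' @param config a [pipelineConfig()] list.
#' @export
writePipelineConfig <- function(config, path) {
  y <- lapply(config[c("registration", "vesselness", "seeds", "growth",
                       "sweep")], function(b) lapply(unclass(b), identity))
  y$growth$v <- NULL
  y$fixedV <- config$fixedV
  y$rngSeed <- config$rngSeed
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full segmentation pipeline
#'
#' Executes the four stages in order — (1) multi-atlas heart segmentation
#' (skipped when a heart mask is supplied), (2) multiscale vessel
#' enhancement inside the heart region, (3) automatic seed detection, (4)
#' statistical region growing with the heuristic bounds sweep (or at
#' \code{fixedV}). No stage ever prompts; a missing required input is a
#' startup error. When \code{outDir} is given, each completed stage's
#' output is persisted (NIfTI masks/volumes, seed CSV, sweep trace JSON)
#' even if a later stage fails.
#'
#' @param volume patient [Volume3D-class].
#' @param atlases list of \code{list(volume, label)} atlases (required
#'   unless \code{heartMask} is given).
#' @param heartMask optional precomputed heart [BinaryMask3D-class].
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory for stage artefacts.
#' @return a [SegmentationResult-class].
#' @export
runPipeline <- function(volume, atlases = NULL, heartMask = NULL,
                        config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(heartMask) && (is.null(atlases) || length(atlases) == 0))
    stop("need either an atlas set or a precomputed heart mask",
         call. = FALSE)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  logLines <- character()
  timings <- data.frame(stage = character(), seconds = numeric())
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    timings <<- rbind(timings, data.frame(stage = stage, seconds = el))
    logLines <<- c(logLines, sprintf("[%s] done in %.2f s", stage, el))
    out
  }
  persist <- function(obj, name) {
    if (is.null(outDir)) return(invisible(NULL))
    if (is(obj, "BinaryMask3D") || is(obj, "Volume3D"))
      saveVolume(obj, file.path(outDir, paste0(name, ".nii.gz")))
    else if (is(obj, "SeedSet"))
      writeSeedsCSV(obj, file.path(outDir, paste0(name, ".csv")))
  }

  if (is.null(heartMask)) {
    reg <- config$registration
    reg$rngSeed <- config$rngSeed
    heartMask <- clock("heart", segmentHeart(volume, atlases, reg))
  } else {
    .stopIfGridMismatch(volume, heartMask, "volume and heart mask")
    logLines <- c(logLines, "[heart] using supplied heart mask")
  }
  persist(heartMask, "heart_mask")

  response <- clock("enhance",
                    multiscaleVesselness(volume, heartMask,
                                         config$vesselness))
  persist(response, "vesselness")

  seeds <- clock("seeds", detectSeeds(volume, response, config$seeds))
  persist(seeds, "seeds")
  logLines <- c(logLines, sprintf("[seeds] %d seed points", length(seeds)))

  if (is.null(config$fixedV)) {
    sweep <- clock("grow", vSweep(volume, heartMask, seeds, config$sweep,
                                  config$growth))
  } else {
    g <- config$growth
    g$v <- config$fixedV
    mk <- clock("grow", growFromSeeds(volume, heartMask, seeds, g))
    sweep <- new("VSweepResult",
                 trace = data.frame(v = config$fixedV,
                                    n_voxels = countSegmented(mk)),
                 selectedV = config$fixedV, terminatedBy = "max_v",
                 mask = mk)
  }
  vessels <- sweep@mask
  persist(vessels, "vessel_mask")
  tr <- sweep@trace
  logLines <- c(logLines,
                sprintf("[grow] sweep N trace: %s",
                        paste(sprintf("(%.2f, %d)", tr$v, tr$n_voxels),
                              collapse = " ")),
                sprintf("[grow] selected v = %.3g (%s)", sweep@selectedV,
                        sweep@terminatedBy))
  if (!is.null(outDir)) {
    jsonlite::write_json(
      list(trace = tr, selected_v = sweep@selectedV,
           terminated_by = sweep@terminatedBy),
      file.path(outDir, "sweep_trace.json"), auto_unbox = TRUE,
      digits = NA)
    writeLines(logLines, file.path(outDir, "pipeline_log.txt"))
  }
  new("SegmentationResult", vesselMask = vessels, heartMask = heartMask,
      seeds = seeds, sweep = sweep, timings = timings, log = logLines)
}

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  cat(sprintf("  heart ROI: %d voxels\n", countSegmented(object@heartMask)))
  cat(sprintf("  seeds:     %d\n", length(object@seeds)))
  cat(sprintf("  vessels:   %d voxels at v = %.3g (%s)\n",
              countSegmented(object@vesselMask), object@sweep@selectedV,
              object@sweep@terminatedBy))
})
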