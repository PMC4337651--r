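#' Parameters of the silencing-loss / recombination process
#'
#' Generative parameters for the branching-process colony simulator. Each
#' cell division of an unswitched cell independently experiences a
#' loss-of-silencing event with probability `pDiv`; a successful event
#' recombines the fluorescent reporter cassette permanently, so the switched
#' state is heritable and irreversible. The founder cell may already be
#' switched at plating with probability `qPre` (escape from drug
#' pre-selection).
#'
#' Two timing models are supported. In `"simple"` mode each event switches
#' exactly one progeny of the division, mother or daughter with equal
#' probability. In `"cell_cycle"` mode the event time is drawn within the
#' cycle: with probability `fPreReplication` recombination acts before DNA
#' replication and both progeny inherit a recombined cassette; otherwise it
#' acts after replication on one of the two cassette copies and exactly one
#' progeny (mother or daughter, equiprobable) is switched.
#'
#' @slot pDiv probability per division of a permanent switch (0-1).
#' @slot qPre probability the founder is already switched at plating (0-1).
#' @slot generations number of division generations simulated per colony.
#' @slot timingModel `"simple"` or `"cell_cycle"`.
#' @slot fPreReplication in `"cell_cycle"` mode, probability the event acts
#'   before DNA replication (unused in `"simple"` mode).
#' @slot gfpDelay lag between recombination and detectable reporter signal,
#'   in fractions of a cell cycle (used only by [classifySwitchPattern()]).
#' @slot horizon visible horizon in generations: events after this
#'   generation are too small to score and do not affect the colony class.
#'
#' @seealso [SwitchParams()], [simulateColony()], [simulatePopulation()]
#' @export
setClass("SwitchParams",
  representation(
    pDiv = "numeric",
    qPre = "numeric",
    generations = "integer",
    timingModel = "character",
    fPreReplication = "numeric",
    gfpDelay = "numeric",
    horizon = "integer"
  )
)

setValidity("SwitchParams", function(object) {
  msg <- character()
  probs <- c(pDiv = object@pDiv, qPre = object@qPre,
             fPreReplication = object@fPreReplication)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste0("probabilities must lie in [0, 1]: ",
                         paste(bad, collapse = ", ")))
  if (length(object@generations) != 1L || is.na(object@generations) ||
      object@generations < 1L)
    msg <- c(msg, "'generations' must be a single integer >= 1")
  if (!object@timingModel %in% c("simple", "cell_cycle"))
    msg <- c(msg, "'timingModel' must be \"simple\" or \"cell_cycle\"")
  if (length(object@horizon) != 1L || is.na(object@horizon) ||
      object@horizon < 1L)
    msg <- c(msg, "'horizon' must be a single integer >= 1")
  if (length(object@gfpDelay) != 1L || !is.finite(object@gfpDelay) ||
      object@gfpDelay < 0)
    msg <- c(msg, "'gfpDelay' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct switching-process parameters
#'
#' @param pDiv per-division probability of a permanent reporter switch.
#' @param qPre probability the founder cell is already switched at plating.
#' @param generations number of division generations per colony.
#' @param timingModel `"simple"` (each event switches exactly one progeny)
#'   or `"cell_cycle"` (event time within the cycle decides whether one or
#'   both progeny inherit a recombined cassette).
#' @param fPreReplication probability, in `"cell_cycle"` mode, that
#'   recombination acts before DNA replication.
#' @param gfpDelay lag between recombination and detectable reporter signal,
#'   in fractions of a cell cycle.
#' @param horizon generation after which switch events are invisible at the
#'   plate scale (sectors too small to score).
#' @return A [SwitchParams-class] object.
#' @examples
#' SwitchParams(pDiv = 1.6e-3)
#' @export
SwitchParams <- function(pDiv, qPre = 0, generations = 14L,
                         timingModel = c("simple", "cell_cycle"),
                         fPreReplication = 0.25, gfpDelay = 0.5,
                         horizon = 6L) {
  timingModel <- match.arg(timingModel)
  new("SwitchParams", pDiv = as.numeric(pDiv), qPre = as.numeric(qPre),
      generations = as.integer(generations), timingModel = timingModel,
      fPreReplication = as.numeric(fPreReplication),
      gfpDelay = as.numeric(gfpDelay), horizon = as.integer(horizon))
}

setMethod("show", "SwitchParams", function(object) {
  cat("SwitchParams\n")
  cat("  pDiv:", object@pDiv, " qPre:", object@qPre, "\n")
  cat("  generations:", object@generations,
      " horizon:", object@horizon, "\n")
  cat("  timingModel:", object@timingModel)
  if (object@timingModel == "cell_cycle")
    cat("  (fPreReplication:", object@fPreReplication,
        ", gfpDelay:", object@gfpDelay, ")")
  cat("\n")
})

#' Outcome of one simulated colony
#'
#' Per-colony record produced by [simulateColony()]: the list of switch
#' events, whether the founder was pre-switched, the fraction of
#' final-generation cells descending from switched lineages, and the
#' resulting fluorescence class. A half-sectored colony arises when exactly
#' one progeny of the first division heads a fully switched subtree; later
#' events add smaller sectors within the red half without destroying the
#' half-sector morphology, so they do not change the class.
#'
#' @slot events data frame of switch events (`generation`, `lineage`,
#'   `progeny`, `phase`, `tCycle`).
#' @slot founderPreSwitched logical; founder already switched at plating.
#' @slot greenFraction fraction of final-generation cells switched.
#' @slot colonyClass `"red"`, `"half_sector"`, `"partial_sector"` or
#'   `"full_green"`.
#' @export
setClass("ColonyOutcome",
  representation(
    events = "data.frame",
    founderPreSwitched = "logical",
    greenFraction = "numeric",
    colonyClass = "character"
  )
)

setValidity("ColonyOutcome", function(object) {
  msg <- character()
  if (!object@colonyClass %in%
      c("red", "half_sector", "partial_sector", "full_green"))
    msg <- c(msg, "unknown colony class")
  if (object@greenFraction < 0 || object@greenFraction > 1)
    msg <- c(msg, "greenFraction must lie in [0, 1]")
  if (object@founderPreSwitched &&
      (object@colonyClass != "full_green" || object@greenFraction != 1))
    msg <- c(msg, "pre-switched founder implies a fully green colony")
  if (!object@founderPreSwitched && nrow(object@events) == 0L &&
      (object@colonyClass != "red" || object@greenFraction != 0))
    msg <- c(msg, "no events and unswitched founder imply a red colony")
  ev <- object@events
  if (nrow(ev) && any(ev$progeny == "both" & ev$phase != "pre_replication"))
    msg <- c(msg, "'both' progeny can only arise pre-replication")
  if (length(msg)) msg else TRUE
})

#' @describeIn ColonyOutcome colony fluorescence class.
#' @param x a `ColonyOutcome` object.
#' @export
setMethod("colonyClass", "ColonyOutcome", function(x) x@colonyClass)

#' @describeIn ColonyOutcome fraction of final-generation cells switched.
#' @export
setMethod("greenFraction", "ColonyOutcome", function(x) x@greenFraction)

#' @describeIn ColonyOutcome data frame of switch events.
#' @export
setMethod("switchEvents", "ColonyOutcome", function(x) x@events)

setMethod("show", "ColonyOutcome", function(object) {
  cat("ColonyOutcome:", object@colonyClass,
      sprintf("(green fraction %.3g)", object@greenFraction), "\n")
  cat("  events:", nrow(object@events),
      if (object@founderPreSwitched) " founder pre-switched" else "", "\n")
})

#' Plate-level colony tallies
#'
#' Counts of colonies by fluorescence class for one plating replicate.
#' These are the three terms of the half-sector frequency estimator
#' (partially sectored and red colonies are tallied but never enter the
#' estimator).
#'
#' @slot replicateId replicate label.
#' @slot totalColonies total colonies counted.
#' @slot halfSectored number of half red / half green colonies.
#' @slot fullyGreen number of entirely green colonies.
#' @slot partialSectored number of colonies with smaller green sectors
#'   (`NA` when not tallied).
#' @slot red number of entirely red colonies (`NA` when not tallied).
#' @seealso [halfSectorFrequency()], [simulatePopulation()]
#' @export
setClass("SectorCounts",
  representation(
    replicateId = "character",
    totalColonies = "integer",
    halfSectored = "integer",
    fullyGreen = "integer",
    partialSectored = "integer",
    red = "integer"
  )
)

setValidity("SectorCounts", function(object) {
  msg <- character()
  if (object@totalColonies < 0L || object@halfSectored < 0L ||
      object@fullyGreen < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (object@halfSectored + object@fullyGreen > object@totalColonies)
    msg <- c(msg,
      "half-sectored plus fully green colonies exceed the total")
  if (length(msg)) msg else TRUE
})

#' Construct plate-level colony tallies
#'
#' @param totalColonies total number of colonies on the plate(s).
#' @param halfSectored number of half-sectored colonies.
#' @param fullyGreen number of fully green colonies.
#' @param partialSectored,red optional tallies of the remaining classes.
#' @param replicateId replicate label.
#' @return A [SectorCounts-class] object.
#' @examples
#' SectorCounts(1267, halfSectored = 2, fullyGreen = 3)
#' @export
SectorCounts <- function(totalColonies, halfSectored, fullyGreen,
                         partialSectored = NA_integer_, red = NA_integer_,
                         replicateId = "rep1") {
  new("SectorCounts", replicateId = as.character(replicateId),
      totalColonies = as.integer(totalColonies),
      halfSectored = as.integer(halfSectored),
      fullyGreen = as.integer(fullyGreen),
      partialSectored = as.integer(partialSectored),
      red = as.integer(red))
}

#' @describeIn SectorCounts named vector of the tallies.
#' @param x a `SectorCounts` object.
#' @export
setMethod("sectorTallies", "SectorCounts", function(x) {
  c(total = x@totalColonies, half_sectored = x@halfSectored,
    fully_green = x@fullyGreen, partial_sectored = x@partialSectored,
    red = x@red)
})

setMethod("show", "SectorCounts", function(object) {
  cat("SectorCounts [", object@replicateId, "]\n", sep = "")
  print(sectorTallies(object))
})

#' Replicate summary of a per-division rate
#'
#' Summary of half-sector frequency estimates across independent plating
#' replicates: the arithmetic mean, the sample (n-1) standard deviation and,
#' optionally, a percentile bootstrap confidence interval.
#'
#' @slot replicateEstimates per-replicate frequencies.
#' @slot mean arithmetic mean of the replicate estimates.
#' @slot sd sample standard deviation (`NA` for a single replicate).
#' @slot nReplicates number of replicates.
#' @slot ci numeric vector `c(level, lower, upper)`; length 0 when no
#'   bootstrap interval was computed.
#' @seealso [summarizeReplicates()], [recoverRate()], [bootstrapRateCI()]
#' @export
setClass("RateEstimate",
  representation(
    replicateEstimates = "numeric",
    mean = "numeric",
    sd = "numeric",
    nReplicates = "integer",
    ci = "numeric"
  )
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (length(object@replicateEstimates) != object@nReplicates)
    msg <- c(msg, "replicate estimates and nReplicates disagree")
  if (object@nReplicates >= 1L &&
      !isTRUE(all.equal(object@mean, mean(object@replicateEstimates))))
    msg <- c(msg, "mean must equal the mean of the replicate estimates")
  if (object@nReplicates >= 2L &&
      !isTRUE(all.equal(object@sd, stats::sd(object@replicateEstimates))))
    msg <- c(msg, "sd must be the sample standard deviation")
  if (length(object@ci) && length(object@ci) != 3L)
    msg <- c(msg, "ci must be c(level, lower, upper)")
  if (length(msg)) msg else TRUE
})

#' @describeIn RateEstimate per-replicate frequencies.
#' @param x a `RateEstimate` object.
#' @export
setMethod("rateReplicates", "RateEstimate",
          function(x) x@replicateEstimates)

#' @describeIn RateEstimate mean over replicates.
#' @export
setMethod("rateMean", "RateEstimate", function(x) x@mean)

#' @describeIn RateEstimate sample standard deviation over replicates.
#' @export
setMethod("rateSD", "RateEstimate", function(x) x@sd)

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: %.4g +/- %.2g (n = %d)\n",
              object@mean, object@sd, object@nReplicates))
  if (length(object@ci) == 3L)
    cat(sprintf("  %g%% bootstrap CI: [%.4g, %.4g]\n",
                100 * object@ci[1L], object@ci[2L], object@ci[3L]))
})

#' Per-cell transcript-count distribution
#'
#' Specification of the distribution of transcripts per cell used by the
#' synthetic FISH generator. Three families are supported: `"poisson"`
#' (constitutive transcription; variance equals the mean), `"negbin"`
#' (overdispersed transcription parameterized by mean and variance; the
#' minimal two-moment overdispersed choice) and `"mixture"` (a zero-heavy
#' two-state mixture in which a fraction `piExpressed` of cells draws counts
#' from a nested expressed-component model and the rest have exactly zero
#' transcripts, emulating bistable silencing).
#'
#' @slot family `"poisson"`, `"negbin"` or `"mixture"`.
#' @slot mean mean transcripts per cell (of the expressed component for
#'   mixtures, see [CountModel()]).
#' @slot variance variance of transcripts per cell (negbin only).
#' @slot piExpressed mixture weight of the expressing component.
#' @slot expressedComponent nested `CountModel` (mixture only), else `NULL`.
#' @export
setClass("CountModel",
  representation(
    family = "character",
    mean = "numeric",
    variance = "numeric",
    piExpressed = "numeric",
    expressedComponent = "ANY"
  )
)

setValidity("CountModel", function(object) {
  msg <- character()
  if (!object@family %in% c("poisson", "negbin", "mixture"))
    msg <- c(msg, "family must be poisson, negbin or mixture")
  if (object@family != "mixture" &&
      (!is.finite(object@mean) || object@mean < 0))
    msg <- c(msg, "mean must be a non-negative number")
  if (object@family == "mixture") {
    if (!is.finite(object@piExpressed) || object@piExpressed < 0 ||
        object@piExpressed > 1)
      msg <- c(msg, "piExpressed must lie in [0, 1]")
    if (!is(object@expressedComponent, "CountModel"))
      msg <- c(msg, "mixture requires a nested expressed-component model")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a per-cell transcript-count model
#'
#' @param family `"poisson"`, `"negbin"` or `"mixture"`.
#' @param mean mean transcripts per cell. For `"mixture"` this is the
#'   overall mean; the expressed-component mean defaults to
#'   `mean / piExpressed` so that the overall moments match.
#' @param variance variance of transcripts per cell (`"negbin"` only; must
#'   exceed the mean, otherwise sampling falls back to Poisson with a
#'   warning).
#' @param piExpressed fraction of cells in the expressing state
#'   (`"mixture"` only).
#' @param expressedComponent nested `CountModel` for the expressing state;
#'   defaults to `Poisson(mean / piExpressed)`.
#' @return A [CountModel-class] object.
#' @examples
#' CountModel("negbin", mean = 12, variance = 53)
#' CountModel("mixture", mean = 5, piExpressed = 0.46)
#' @export
CountModel <- function(family = c("poisson", "negbin", "mixture"),
                       mean, variance = NA_real_, piExpressed = NA_real_,
                       expressedComponent = NULL) {
  family <- match.arg(family)
  if (family == "mixture" && is.null(expressedComponent)) {
    if (!is.finite(piExpressed) || piExpressed < 0 || piExpressed > 1)
      stop("mixture requires piExpressed in [0, 1]")
    expressedComponent <- CountModel("poisson",
      mean = if (piExpressed > 0) mean / piExpressed else 0)
  }
  new("CountModel", family = family, mean = as.numeric(mean),
      variance = as.numeric(variance),
      piExpressed = as.numeric(piExpressed),
      expressedComponent = expressedComponent)
}

setMethod("show", "CountModel", function(object) {
  cat("CountModel:", object@family, "\n")
  if (object@family == "mixture") {
    cat("  piExpressed:", object@piExpressed, "\n  expressed component:\n")
    show(object@expressedComponent)
  } else {
    cat("  mean:", object@mean)
    if (object@family == "negbin") cat("  variance:", object@variance)
    cat("\n")
  }
})

#' Geometry and optics of a synthetic FISH stack
#'
#' Describes the voxel grid, point-spread function, noise model and cell
#' geometry used by [generateStack()]. Dimensions follow the (z, y, x)
#' array convention; physical sizes are in micrometres. The default axial
#' PSF width is about twice the lateral width, the typical anisotropy of a
#' widefield microscope, and the default z step of 0.2 um matches standard
#' smFISH acquisition.
#'
#' @slot dim integer vector (z, y, x) of voxel counts.
#' @slot voxelXY lateral voxel size (um).
#' @slot voxelZ z step (um).
#' @slot amplitude peak intensity added by one transcript.
#' @slot sigmaLateral,sigmaAxial Gaussian PSF sigmas (um).
#' @slot background constant background level.
#' @slot noiseModel `"gaussian"` or `"poisson"`.
#' @slot noiseSd standard deviation of Gaussian read noise (ignored for
#'   Poisson noise, where the rendered intensity is the Poisson mean).
#' @slot nCells number of cells placed in the field.
#' @slot cellAxes mean semi-axes (um) of the elliptical cell footprints.
#' @slot minSeparation minimum Euclidean distance between true spot
#'   centres, in voxels (0 disables the constraint).
#' @slot falseSpotRate expected number of autofluorescence false spots per
#'   cell (rendered but excluded from the ground-truth counts).
#' @export
setClass("StackSpec",
  representation(
    dim = "integer",
    voxelXY = "numeric",
    voxelZ = "numeric",
    amplitude = "numeric",
    sigmaLateral = "numeric",
    sigmaAxial = "numeric",
    background = "numeric",
    noiseModel = "character",
    noiseSd = "numeric",
    nCells = "integer",
    cellAxes = "numeric",
    minSeparation = "numeric",
    falseSpotRate = "numeric"
  )
)

setValidity("StackSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive voxel counts (z, y, x)")
  if (object@voxelZ <= 0 || object@voxelXY <= 0)
    msg <- c(msg, "voxel sizes must be positive")
  if (object@sigmaLateral <= 0 || object@sigmaAxial <= 0)
    msg <- c(msg, "PSF sigmas must be positive")
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be gaussian or poisson")
  if (object@nCells < 0L)
    msg <- c(msg, "nCells must be non-negative")
  if (length(object@cellAxes) != 2L || any(object@cellAxes <= 0))
    msg <- c(msg, "cellAxes must be two positive semi-axes")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic stack specification
#'
#' Defaults emulate a 60x widefield acquisition of budding yeast: 0.13 um
#' lateral voxels, 0.2 um z steps, a diffraction-limited PSF
#' (sigma 0.12 um lateral, 0.24 um axial) and a peak-signal to
#' read-noise ratio of 10.
#'
#' @param dim voxel counts (z, y, x).
#' @param voxelXY,voxelZ voxel sizes in um.
#' @param amplitude peak intensity of one transcript.
#' @param sigmaLateral,sigmaAxial PSF sigmas in um.
#' @param background constant background level.
#' @param noiseModel `"gaussian"` or `"poisson"`.
#' @param noiseSd Gaussian read-noise standard deviation.
#' @param nCells number of cells in the field.
#' @param cellAxes mean semi-axes of the cell footprint ellipses (um).
#' @param minSeparation minimum distance between true spots (voxels).
#' @param falseSpotRate expected autofluorescence false spots per cell.
#' @return A [StackSpec-class] object.
#' @examples
#' StackSpec(dim = c(16, 128, 128), nCells = 5)
#' @export
StackSpec <- function(dim = c(24L, 320L, 320L), voxelXY = 0.13,
                      voxelZ = 0.2, amplitude = 200, sigmaLateral = 0.12,
                      sigmaAxial = 0.24, background = 100,
                      noiseModel = c("gaussian", "poisson"), noiseSd = 20,
                      nCells = 20L, cellAxes = c(1.9, 1.4),
                      minSeparation = 0, falseSpotRate = 0) {
  noiseModel <- match.arg(noiseModel)
  new("StackSpec", dim = as.integer(dim), voxelXY = as.numeric(voxelXY),
      voxelZ = as.numeric(voxelZ), amplitude = as.numeric(amplitude),
      sigmaLateral = as.numeric(sigmaLateral),
      sigmaAxial = as.numeric(sigmaAxial),
      background = as.numeric(background), noiseModel = noiseModel,
      noiseSd = as.numeric(noiseSd), nCells = as.integer(nCells),
      cellAxes = as.numeric(cellAxes),
      minSeparation = as.numeric(minSeparation),
      falseSpotRate = as.numeric(falseSpotRate))
}

setMethod("show", "StackSpec", function(object) {
  cat("StackSpec:", paste(object@dim, collapse = " x "),
      "(z, y, x) voxels;", object@nCells, "cells\n")
  cat(sprintf("  voxel %.3g um (xy) x %.3g um (z); PSF sigma %.3g/%.3g um\n",
              object@voxelXY, object@voxelZ, object@sigmaLateral,
              object@sigmaAxial))
  cat(sprintf("  amplitude %g over background %g; %s noise (sd %g)\n",
              object@amplitude, object@background, object@noiseModel,
              object@noiseSd))
})

#' A 3D fluorescence image stack with anisotropic voxel spacing
#'
#' @slot data numeric array with dimensions (z, y, x).
#' @slot voxelXY lateral voxel size (um).
#' @slot voxelZ z step (um).
#' @seealso [ImageStack()], [logFilter3d()], [readStackTIFF()]
#' @export
setClass("ImageStack",
  representation(data = "array", voxelXY = "numeric", voxelZ = "numeric")
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (z, y, x)")
  if (object@voxelXY <= 0 || object@voxelZ <= 0)
    msg <- c(msg, "voxel sizes must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an image stack
#'
#' @param data numeric array with dimensions (z, y, x).
#' @param voxelXY lateral voxel size in um.
#' @param voxelZ z step in um.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(data, voxelXY = 0.13, voxelZ = 0.2) {
  new("ImageStack", data = data, voxelXY = as.numeric(voxelXY),
      voxelZ = as.numeric(voxelZ))
}

#' @describeIn ImageStack the voxel intensity array.
#' @param x an `ImageStack` object.
#' @export
setMethod("stackData", "ImageStack", function(x) x@data)

#' @describeIn ImageStack physical voxel spacing in um.
#' @export
setMethod("voxelSize", "ImageStack",
          function(x) c(z = x@voxelZ, xy = x@voxelXY))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d x %d (z, y, x); %.3g/%.3g um voxels\n",
              d[1L], d[2L], d[3L], object@voxelXY, object@voxelZ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' Summary statistics of per-cell transcript counts
#'
#' The per-cell count summary reported for each strain and RNA species:
#' mean spots per cell, sample variance, percentage of cells with at least
#' one spot, percentage with more than one spot, and the dispersion index
#' (variance over mean; 1 under Poisson, larger under overdispersed or
#' bimodal expression).
#'
#' @slot meanSpots mean spots per cell.
#' @slot varianceSpots sample (n-1) variance of spots per cell.
#' @slot pctPositive percentage of cells with > 0 spots.
#' @slot pctMultiple percentage of cells with > 1 spot.
#' @slot nCells number of cells summarized.
#' @slot dispersionIndex variance / mean (`NA` when the mean is 0).
#' @seealso [summarizeCounts()]
#' @export
setClass("FISHSummary",
  representation(
    meanSpots = "numeric",
    varianceSpots = "numeric",
    pctPositive = "numeric",
    pctMultiple = "numeric",
    nCells = "integer",
    dispersionIndex = "numeric"
  )
)

setValidity("FISHSummary", function(object) {
  msg <- character()
  if (object@pctPositive < 0 || object@pctPositive > 100 ||
      object@pctMultiple < 0 || object@pctMultiple > 100)
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (object@pctMultiple > object@pctPositive + 1e-12)
    msg <- c(msg, "% cells > 1 spot cannot exceed % cells > 0 spots")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FISHSummary", function(object) {
  cat(sprintf(
    "FISHSummary over %d cells\n  mean %.3g, variance %.3g (dispersion %.3g)\n",
    object@nCells, object@meanSpots, object@varianceSpots,
    object@dispersionIndex))
  cat(sprintf("  %%>0 spots: %.3g  %%>1 spot: %.3g\n",
              object@pctPositive, object@pctMultiple))
})

#' Idealized rendering of a scanned plate
#'
#' A 2D grayscale rendering of sectored colonies as seen in the GFP channel
#' of a fluorescence plate scan, plus a composite channel in which every
#' colony is bright (used when counting total colonies). Sectors are drawn
#' as ideal wedges; a half sector is a 180-degree wedge.
#'
#' @slot gfp GFP-channel image matrix (y, x).
#' @slot composite composite image in which all colonies exceed background.
#' @slot colonies data frame of colony records (`x`, `y`, `radius`,
#'   `class`, `wedgeAngle` in radians, `wedgeStart`).
#' @seealso [renderPlate()], [countColonies()]
#' @export
setClass("PlateRender",
  representation(gfp = "matrix", composite = "matrix",
                 colonies = "data.frame")
)

setMethod("show", "PlateRender", function(object) {
  cat(sprintf("PlateRender: %d x %d px, %d colonies\n",
              nrow(object@gfp), ncol(object@gfp), nrow(object@colonies)))
  if (nrow(object@colonies))
    print(table(object@colonies$class))
})
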