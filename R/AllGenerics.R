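#' @import methods
NULL

#' Colony fluorescence class of a simulated colony
#'
#' @param x a [ColonyOutcome-class] object.
#' @return Character scalar: one of `"red"`, `"half_sector"`,
#'   `"partial_sector"`, `"full_green"`.
#' @export
setGeneric("colonyClass", function(x) standardGeneric("colonyClass"))

#' Fraction of final-generation cells descending from switched lineages
#'
#' @param x a [ColonyOutcome-class] object.
#' @return Numeric scalar in `[0, 1]`.
#' @export
setGeneric("greenFraction", function(x) standardGeneric("greenFraction"))

#' Switch events recorded for a simulated colony
#'
#' @param x a [ColonyOutcome-class] object.
#' @return A data frame with one row per switch event (columns `generation`,
#'   `lineage`, `progeny`, `phase`, `tCycle`).
#' @export
setGeneric("switchEvents", function(x) standardGeneric("switchEvents"))

#' Plate-level colony tallies
#'
#' @param x a [SectorCounts-class] object.
#' @return Named integer vector with elements `total`, `half_sectored`,
#'   `fully_green`, `partial_sectored`, `red`.
#' @export
setGeneric("sectorTallies", function(x) standardGeneric("sectorTallies"))

#' Replicate-level estimates of a rate
#'
#' @param x a [RateEstimate-class] object.
#' @return Numeric vector of per-replicate frequencies.
#' @export
setGeneric("rateReplicates", function(x) standardGeneric("rateReplicates"))

#' Mean of replicate rate estimates
#'
#' @param x a [RateEstimate-class] object.
#' @return Numeric scalar.
#' @export
setGeneric("rateMean", function(x) standardGeneric("rateMean"))

#' Sample standard deviation of replicate rate estimates
#'
#' @param x a [RateEstimate-class] object.
#' @return Numeric scalar (`NA` when fewer than two replicates).
#' @export
setGeneric("rateSD", function(x) standardGeneric("rateSD"))

#' Voxel intensity array of an image stack
#'
#' @param x an [ImageStack-class] object.
#' @return Numeric array with dimensions (z, y, x).
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' Physical voxel spacing of an image stack
#'
#' @param x an [ImageStack-class] object.
#' @return Named numeric vector `c(z = <z step>, xy = <lateral size>)` in
#'   micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
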