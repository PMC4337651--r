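# File interchange: multi-page TIFF stacks (one page per z slice),
# 16-bit label masks, and the CSV tables used by the plate and FISH
# workflows.

.TIFF_MAX <- 65535

#' Write an image stack as a multi-page TIFF
#'
#' One 16-bit page per z slice. Intensities are stored as rounded
#' integer grey levels; values outside `[0, 65535]` are clipped.
#'
#' @param stack an [ImageStack-class] object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeStackTIFF <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  arr <- stack@data
  pages <- lapply(seq_len(dim(arr)[1L]), function(z)
    pmin(pmax(round(arr[z, , ]), 0), .TIFF_MAX) / .TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file with one page per z slice.
#' @param voxelXY,voxelZ physical voxel sizes (um) to attach.
#' @return An [ImageStack-class] object with integer grey levels.
#' @export
readStackTIFF <- function(path, voxelXY = 0.13, voxelZ = 0.2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) arr[z, , ] <- round(pages[[z]] * .TIFF_MAX)
  ImageStack(arr, voxelXY = voxelXY, voxelZ = voxelZ)
}

#' Write a cell-label mask as a 16-bit TIFF
#'
#' @param mask integer label matrix (0 = background).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMaskTIFF <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= .TIFF_MAX)
  tiff::writeTIFF(mask / .TIFF_MAX, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label mask TIFF
#'
#' @param path TIFF file written by [writeMaskTIFF()] (or equivalent).
#' @return Integer label matrix.
#' @export
readMaskTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  mode(m) <- "numeric"
  matrix(as.integer(round(m * .TIFF_MAX)), nrow = nrow(m))
}

#' Read plate-level sector counts from CSV
#'
#' Expected columns: `replicate_id`, `total_colonies`, `half_sectored`,
#' `fully_green` (extra columns are ignored).
#'
#' @param path CSV file path.
#' @return A list of [SectorCounts-class] objects, one per row.
#' @export
readSectorCounts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "total_colonies", "half_sectored",
            "fully_green")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sector-count CSV lacks columns: ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    SectorCounts(df$total_colonies[i], df$half_sectored[i],
                 df$fully_green[i], replicateId = df$replicate_id[i]))
}

#' Estimate a rate from a list of replicate sector counts
#'
#' @param countsList list of [SectorCounts-class] objects.
#' @return A [RateEstimate-class] object.
#' @export
estimateRate <- function(countsList) {
  est <- vapply(countsList, halfSectorFrequency, numeric(1))
  summarizeReplicates(est)
}

#' Write a per-colony outcome table as CSV
#'
#' Columns: `colony_id`, `class`, `green_fraction`, `n_events`,
#' `first_event_generation`.
#'
#' @param colonyTable data frame from [simulateColonyTable()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeColonyTable <- function(colonyTable, path) {
  out <- data.frame(colony_id = colonyTable$colonyId,
                    class = colonyTable$class,
                    green_fraction = colonyTable$greenFraction,
                    n_events = colonyTable$nEvents,
                    first_event_generation =
                      colonyTable$firstEventGeneration)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a spot-call table as CSV
#'
#' @param spots spot-call data frame (see [detectSpots()]).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  utils::write.csv(spots[, c("z", "y", "x", "size", "response", "cell")],
                   path, row.names = FALSE)
  invisible(path)
}

fishSummaryRow <- function(summary) {
  data.frame(n_cells = summary@nCells,
             mean_spots_per_cell = summary@meanSpots,
             variance = summary@varianceSpots,
             pct_cells_gt0 = summary@pctPositive,
             pct_cells_gt1 = summary@pctMultiple,
             dispersion_index = summary@dispersionIndex)
}
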