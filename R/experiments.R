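# Orchestration: reproducible, seeded experiment runs tying together
# simulation, estimation, FISH synthesis and spot calling. Outputs are
# CSV tables whose header comment records the configuration hash, so
# identical configurations give byte-identical outputs.

writeCsvWithHeader <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by the experiment runners
#'
#' @param path CSV path (first line is a `# config_md5` comment).
#' @return A data frame.
#' @export
readResultsCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run a colony-sector rate experiment
#'
#' For each named strain (parameter set) in the configuration, simulates
#' `n_replicates` plated populations of `n_colonies` colonies, estimates
#' the per-division switch rate with the half-sector formula, and writes
#' a rates table plus all pairwise comparisons (fold-change of means and
#' an equal-variance Student's t test on the replicate estimates).
#'
#' @param cfg run configuration (see [readRunConfig()]); requires
#'   `seed`, `n_colonies`, `n_replicates` and a named `strains` list with
#'   per-strain `switch` blocks.
#' @param outDir output directory for `rates.csv` and
#'   `comparisons.csv`; `NULL` skips writing.
#' @return A list with data frames `rates` and `comparisons`.
#' @examples
#' cfg <- list(experiment = "demo", seed = 1, n_colonies = 5000,
#'             n_replicates = 3,
#'             strains = list(
#'               wt = list(switch = list(p_div = 0.0016)),
#'               sir1 = list(switch = list(p_div = 0.055))))
#' res <- runSectorExperiment(cfg)
#' res$comparisons
#' @export
runSectorExperiment <- function(cfg, outDir = NULL) {
  cfg <- validateRunConfig(cfg)
  if (is.null(cfg$strains)) stop("config: 'strains' block is required")
  if (is.null(cfg$n_colonies) || is.null(cfg$n_replicates))
    stop("config: 'n_colonies' and 'n_replicates' are required")
  hash <- configHash(cfg)
  message("sector experiment '", cfg$experiment, "': seed ", cfg$seed,
          ", config ", hash)
  t0 <- proc.time()[["elapsed"]]
  strains <- names(cfg$strains)
  nRep <- as.integer(cfg$n_replicates)
  estimates <- list()
  rates <- do.call(rbind, lapply(seq_along(strains), function(i) {
    params <- switchParamsFromConfig(cfg$strains[[i]]$switch)
    est <- recoverRate(params, as.integer(cfg$n_colonies), nRep,
                       seed = cfg$seed + (i - 1L) * nRep)
    estimates[[strains[i]]] <<- est
    data.frame(strain = strains[i], mean = rateMean(est),
               sd = rateSD(est), n_replicates = nRep,
               stringsAsFactors = FALSE)
  }))
  comparisons <- NULL
  if (length(strains) >= 2L) {
    pairs <- utils::combn(seq_along(strains), 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)),
                                         function(p) {
      i <- pairs[1L, p]
      j <- pairs[2L, p]
      a <- estimates[[strains[i]]]
      b <- estimates[[strains[j]]]
      fc <- foldChange(a, b)
      tt <- twoSampleT(rateReplicates(a), rateReplicates(b))
      data.frame(numerator = strains[i], denominator = strains[j],
                 fold = fc$fold, fold_se = fc$se,
                 t_statistic = tt$statistic, p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  } else {
    comparisons <- data.frame(numerator = character(),
                              denominator = character(),
                              fold = numeric(), fold_se = numeric(),
                              t_statistic = numeric(),
                              p_value = numeric())
  }
  message(sprintf("  simulated %d strains x %d x %g colonies in %.1f s",
                  length(strains), nRep, cfg$n_colonies,
                  proc.time()[["elapsed"]] - t0))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCsvWithHeader(rates, file.path(outDir, "rates.csv"), hash)
    writeCsvWithHeader(comparisons, file.path(outDir, "comparisons.csv"),
                       hash)
  }
  list(rates = rates, comparisons = comparisons)
}

countModelFromConfig <- function(block) {
  family <- if (is.null(block$family)) "poisson" else block$family
  expressed <- if (!is.null(block$expressed_component))
    countModelFromConfig(block$expressed_component) else NULL
  CountModel(family = family,
             mean = if (is.null(block$mean)) NA_real_ else block$mean,
             variance = if (is.null(block$variance)) NA_real_
                        else block$variance,
             piExpressed = if (is.null(block$pi_expressed)) NA_real_
                           else block$pi_expressed,
             expressedComponent = expressed)
}

stackSpecFromConfig <- function(block) {
  if (is.null(block)) block <- list()
  args <- list()
  map <- c(dim = "dim", voxel_xy = "voxelXY", voxel_z = "voxelZ",
           amplitude = "amplitude", sigma_lateral = "sigmaLateral",
           sigma_axial = "sigmaAxial", background = "background",
           noise_model = "noiseModel", noise_sd = "noiseSd",
           n_cells = "nCells", cell_axes = "cellAxes",
           min_separation = "minSeparation",
           false_spot_rate = "falseSpotRate")
  for (nm in names(map))
    if (!is.null(block[[nm]])) args[[map[[nm]]]] <- unlist(block[[nm]])
  do.call(StackSpec, args)
}

#' Run a two-channel FISH synthesis + spot-calling experiment
#'
#' For each named strain, generates `n_stacks` two-channel fixtures
#' (channel A: the silenced reporter model; channel B: the constitutive
#' control model) over shared cell masks, runs the 3D LoG caller on
#' every stack, and emits a per-strain, per-channel count summary plus
#' detection scores against the synthetic ground truth. One detection
#' threshold per channel is fixed on the first generated stack of the
#' experiment (or taken from the config) and reused across all samples.
#'
#' @param cfg run configuration; requires `seed` and a `fish` block with
#'   `strains` (each naming `model_a` and `model_b` count-model blocks),
#'   `stack` (a [StackSpec()] block, snake_case) and `n_stacks`.
#'   An optional `caller` block supplies `sigma_lateral`, `sigma_axial`,
#'   `threshold_a`, `threshold_b` (numbers, or `"auto"` for the MAD
#'   helper), `size_range` and `match_radius`.
#' @param outDir output directory for `fish_summary.csv`; `NULL` skips
#'   writing.
#' @return A data frame with one row per strain x channel: the count
#'   summary (mean, variance, % cells with >0 and >1 spots, dispersion)
#'   and detection precision / recall / F1.
#' @export
runFishExperiment <- function(cfg, outDir = NULL) {
  cfg <- validateRunConfig(cfg)
  if (is.null(cfg$fish) || is.null(cfg$fish$strains))
    stop("config: 'fish$strains' block is required")
  spec <- stackSpecFromConfig(cfg$fish$stack)
  if (spec@nCells < 1L) stop("config: fish stack needs n_cells >= 1")
  nStacks <- if (is.null(cfg$fish$n_stacks)) 1L
             else as.integer(cfg$fish$n_stacks)
  caller <- if (is.null(cfg$caller)) list() else cfg$caller
  sigmaL <- if (is.null(caller$sigma_lateral)) spec@sigmaLateral
            else caller$sigma_lateral
  sigmaA <- if (is.null(caller$sigma_axial)) spec@sigmaAxial
            else caller$sigma_axial
  sizeRange <- if (is.null(caller$size_range)) c(4, 200)
               else unlist(caller$size_range)
  matchRadius <- if (is.null(caller$match_radius)) 3
                 else caller$match_radius
  thresholds <- list(
    A = if (is.null(caller$threshold_a)) "auto" else caller$threshold_a,
    B = if (is.null(caller$threshold_b)) "auto" else caller$threshold_b)
  hash <- configHash(cfg)
  message("FISH experiment '", cfg$experiment, "': seed ", cfg$seed,
          ", config ", hash)
  strains <- names(cfg$fish$strains)
  rows <- list()
  for (i in seq_along(strains)) {
    t0 <- proc.time()[["elapsed"]]
    blk <- cfg$fish$strains[[i]]
    modelA <- countModelFromConfig(blk$model_a)
    modelB <- countModelFromConfig(blk$model_b)
    acc <- list(A = list(counts = integer(), tp = 0L, fp = 0L, fn = 0L),
                B = list(counts = integer(), tp = 0L, fp = 0L, fn = 0L))
    for (s in seq_len(nStacks)) {
      fx <- makeTwoChannelFixture(modelA, modelB, spec,
              seed = cfg$seed + (i - 1L) * nStacks + (s - 1L))
      for (ch in c("A", "B")) {
        chan <- fx[[paste0("channel", ch)]]
        filt <- logFilter3d(chan$stack, sigmaL, sigmaA)
        if (identical(thresholds[[ch]], "auto"))
          thresholds[[ch]] <- proposeThreshold(filt)
        spots <- detectSpots(filt, thresholds[[ch]],
                             sizeRange = sizeRange)
        assigned <- assignSpotsToCells(spots, fx$mask)
        sc <- scoreDetection(spots, chan$truth$spots, matchRadius)
        acc[[ch]]$counts <- c(acc[[ch]]$counts, assigned$counts$count)
        acc[[ch]]$tp <- acc[[ch]]$tp + sc$tp
        acc[[ch]]$fp <- acc[[ch]]$fp + sc$fp
        acc[[ch]]$fn <- acc[[ch]]$fn + sc$fn
      }
    }
    for (ch in c("A", "B")) {
      a <- acc[[ch]]
      summ <- summarizeCounts(a$counts)
      precision <- if (a$tp + a$fp > 0L) a$tp / (a$tp + a$fp) else NA_real_
      recall <- if (a$tp + a$fn > 0L) a$tp / (a$tp + a$fn) else NA_real_
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(strain = strains[i], channel = ch,
                   threshold = thresholds[[ch]],
                   stringsAsFactors = FALSE),
        fishSummaryRow(summ),
        data.frame(precision = precision, recall = recall,
                   f1 = if (is.na(precision) || is.na(recall) ||
                            precision + recall == 0) NA_real_
                        else 2 * precision * recall /
                             (precision + recall)))
    }
    message(sprintf("  strain %s: %d stacks in %.1f s", strains[i],
                    nStacks, proc.time()[["elapsed"]] - t0))
  }
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCsvWithHeader(out, file.path(outDir, "fish_summary.csv"), hash)
  }
  out
}
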