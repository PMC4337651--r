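# Branching-process simulator of colony growth with rare, irreversible
# epigenetic switching. Two implementations share one generative model:
# an explicit lineage tree (simulateColony) and a generation-wise binomial
# thinning of the unswitched-cell count (simulatePopulation, O(generations)
# per colony). The reduction is exact, not approximate: events occur iid
# across unswitched dividing cells, and the colony class depends only on
# the per-generation event counts (a switched subtree can never host a
# further event, so "no events in the sister subtree" is equivalent to
# "no events among any unswitched cell").

# Cell-cycle landmarks, as fractions of one cycle. The bud emerges at the
# start of S phase; a large bud marks G2/M. Recombination before the
# replication boundary acts on the single cassette copy and switches both
# progeny; after it, on one of the two copies.
.CYCLE_BUD_EMERGENCE <- 0.25
.CYCLE_LARGE_BUD <- 0.6

emptyEventTable <- function() {
  data.frame(generation = integer(), lineage = integer(),
             progeny = character(), phase = character(),
             tCycle = numeric(), stringsAsFactors = FALSE)
}

# Draw progeny/phase/time for one event under the given timing model.
drawEventDetail <- function(params) {
  if (params@timingModel == "simple") {
    list(progeny = if (stats::runif(1) < 0.5) "mother" else "daughter",
         phase = "not_applicable", tCycle = NA_real_)
  } else {
    pre <- stats::runif(1) < params@fPreReplication
    if (pre) {
      list(progeny = "both", phase = "pre_replication",
           tCycle = stats::runif(1, 0, .CYCLE_BUD_EMERGENCE))
    } else {
      list(progeny = if (stats::runif(1) < 0.5) "mother" else "daughter",
           phase = "post_replication",
           tCycle = stats::runif(1, .CYCLE_BUD_EMERGENCE, 1))
    }
  }
}

# Colony class from the event record. Half-sector scoring keys on the
# first division only: a first-division event that switches exactly one
# progeny fixes the half-green / half-red morphology of the colony, and
# later events merely add smaller sectors within the red half, so the
# expected half-sector frequency equals pDiv exactly and the printed
# frequency-equals-rate relationship holds at any rate.
classFromEvents <- function(events, founderPre, params) {
  H <- min(params@horizon, params@generations)
  visible <- events[events$generation <= H, , drop = FALSE]
  if (founderPre) return("full_green")
  if (nrow(visible) == 0L) return("red")
  gen1 <- visible[visible$generation == 1L, , drop = FALSE]
  if (nrow(gen1)) {
    if (gen1$progeny[1L] == "both") return("full_green")
    return("half_sector")
  }
  "partial_sector"
}

#' Simulate one colony as an explicit lineage tree
#'
#' Grows a colony from a single founder for `generations` synchronous
#' division generations. At every division of an unswitched cell, a
#' loss-of-silencing event occurs independently with probability `pDiv`
#' and permanently switches one or both progeny according to the timing
#' model; the switched state is heritable and irreversible. The colony
#' class is scored from the events visible within the horizon: a single
#' first-division event with no later visible events gives a half sector,
#' a pre-switched founder (or a first-division pre-replication event that
#' switches both progeny) gives a fully green colony.
#'
#' @param params a [SwitchParams-class] object.
#' @param seed explicit RNG seed (required).
#' @return A [ColonyOutcome-class] object.
#' @examples
#' simulateColony(SwitchParams(pDiv = 0.05, generations = 8L), seed = 1)
#' @export
simulateColony <- function(params, seed) {
  stopifnot(is(params, "SwitchParams"))
  validObject(params)
  withSeed(seed, {
    founderPre <- stats::runif(1) < params@qPre
    switched <- founderPre
    rows <- list()
    for (g in seq_len(params@generations)) {
      n <- length(switched)
      hit <- !switched & (stats::runif(n) < params@pDiv)
      child <- logical(2L * n)
      child[2L * seq_len(n) - 1L] <- switched
      child[2L * seq_len(n)] <- switched
      for (i in which(hit)) {
        d <- drawEventDetail(params)
        rows[[length(rows) + 1L]] <- data.frame(
          generation = g, lineage = i, progeny = d$progeny,
          phase = d$phase, tCycle = d$tCycle, stringsAsFactors = FALSE)
        if (d$progeny == "both") {
          child[2L * i - 1L] <- TRUE
          child[2L * i] <- TRUE
        } else if (d$progeny == "mother") {
          child[2L * i - 1L] <- TRUE
        } else {
          child[2L * i] <- TRUE
        }
      }
      switched <- child
    }
    events <- if (length(rows)) do.call(rbind, rows) else emptyEventTable()
    new("ColonyOutcome", events = events, founderPreSwitched = founderPre,
        greenFraction = mean(switched),
        colonyClass = classFromEvents(events, founderPre, params))
  })
}

# Vectorized thinned simulation of n colonies; returns per-colony detail.
simulateThinned <- function(params, n) {
  G <- params@generations
  H <- min(params@horizon, G)
  cellCycle <- params@timingModel == "cell_cycle"
  founderPre <- stats::runif(n) < params@qPre
  u <- as.numeric(!founderPre)       # unswitched cells this generation
  e1 <- integer(n)                   # events at the first division
  b1 <- integer(n)                   # of those, pre-replication (both)
  later <- logical(n)                # visible events after generation 1
  nEvents <- integer(n)
  firstGen <- rep(NA_integer_, n)
  for (g in seq_len(G)) {
    e <- stats::rbinom(n, u, params@pDiv)
    b <- if (cellCycle) stats::rbinom(n, e, params@fPreReplication)
         else integer(n)
    u <- 2 * u - e - b
    if (g == 1L) {
      e1 <- e
      b1 <- b
    } else if (g <= H) {
      later <- later | e > 0L
    }
    nEvents <- nEvents + e
    firstGen[is.na(firstGen) & e > 0L] <- g
  }
  cls <- rep("partial_sector", n)
  cls[e1 == 0L & !later] <- "red"
  cls[e1 == 1L & b1 == 0L] <- "half_sector"
  cls[founderPre | b1 == 1L] <- "full_green"
  data.frame(
    class = cls,
    greenFraction = ifelse(founderPre, 1, (2^G - u) / 2^G),
    nEvents = nEvents,
    firstEventGeneration = firstGen)
}

#' Simulate a per-colony outcome table for a plated population
#'
#' @param params a [SwitchParams-class] object.
#' @param nColonies number of colonies to simulate.
#' @param seed explicit RNG seed.
#' @param method `"thinned"` uses generation-wise binomial thinning of the
#'   unswitched-cell count (O(generations) per colony; the default);
#'   `"tree"` simulates explicit lineage trees (exact same distribution,
#'   for small populations and cross-checks).
#' @return A data frame with one row per colony and columns `colonyId`,
#'   `class`, `greenFraction`, `nEvents`, `firstEventGeneration`.
#' @seealso [simulatePopulation()] for class tallies,
#'   [writeColonyTable()] for the CSV export.
#' @export
simulateColonyTable <- function(params, nColonies, seed,
                                method = c("thinned", "tree")) {
  stopifnot(is(params, "SwitchParams"))
  validObject(params)
  method <- match.arg(method)
  if (nColonies < 1L) stop("'nColonies' must be >= 1")
  seed <- checkSeed(seed)
  if (method == "thinned") {
    det <- withSeed(seed, simulateThinned(params, nColonies))
  } else {
    det <- do.call(rbind, lapply(seq_len(nColonies), function(i) {
      out <- simulateColony(params, seed = seed + i - 1L)
      ev <- switchEvents(out)
      data.frame(
        class = colonyClass(out), greenFraction = greenFraction(out),
        nEvents = nrow(ev),
        firstEventGeneration = if (nrow(ev)) min(ev$generation)
                               else NA_integer_)
    }))
  }
  cbind(colonyId = seq_len(nColonies), det)
}

#' Simulate a plated population and tally colony classes
#'
#' @inheritParams simulateColonyTable
#' @param replicateId replicate label stored in the result.
#' @return A [SectorCounts-class] object with `total = nColonies`.
#' @examples
#' simulatePopulation(SwitchParams(pDiv = 0.01), nColonies = 1000, seed = 1)
#' @export
simulatePopulation <- function(params, nColonies, seed,
                               method = c("thinned", "tree"),
                               replicateId = "rep1") {
  det <- simulateColonyTable(params, nColonies, seed, method)
  tab <- table(factor(det$class, levels = c("red", "half_sector",
                                            "partial_sector", "full_green")))
  SectorCounts(totalColonies = nColonies,
               halfSectored = tab[["half_sector"]],
               fullyGreen = tab[["full_green"]],
               partialSectored = tab[["partial_sector"]],
               red = tab[["red"]], replicateId = replicateId)
}

#' Classify colonies by their green fraction
#'
#' Fraction-based counterpart of the event-based colony classification,
#' for use on rendered or measured images where only the green area
#' fraction is available: a colony is half-sectored when its green
#' fraction lies within `tol` of one half.
#'
#' @param greenFraction numeric vector of green area fractions in
#'   `[0, 1]`.
#' @param tol half-sector tolerance on the fraction.
#' @return Character vector of colony classes.
#' @examples
#' classifyByFraction(c(0, 0.48, 0.2, 1))
#' @export
classifyByFraction <- function(greenFraction, tol = 0.05) {
  stopifnot(all(greenFraction >= 0 & greenFraction <= 1))
  ifelse(greenFraction == 0, "red",
  ifelse(greenFraction == 1, "full_green",
  ifelse(abs(greenFraction - 0.5) <= tol, "half_sector",
         "partial_sector")))
}

#' Classify switch events into the live-imaging pattern taxonomy
#'
#' Live imaging categorizes reporter switches by the bud morphology of the
#' cell when fluorescent signal is first detected (unbudded, small-budded
#' or large-budded) crossed with which progeny of the division remain
#' green (mother, daughter or both). The detection stage is derived from
#' the in-cycle event time plus the reporter maturation delay, modulo one
#' cycle; the progeny label comes from the event itself. Numbered patterns:
#' unbudded mother/daughter/both = 1/2/3, small-budded = 4/5/6,
#' large-budded mother/daughter = 7/8. A large-budded division in which
#' both progeny remain green has no number in the printed taxonomy and is
#' returned with `pattern = NA`. Pattern 3 is labelled but deliberately
#' assigned no mechanism.
#'
#' @param events one or more switch events as a data frame with columns
#'   `progeny`, `phase` and `tCycle` (e.g. from [switchEvents()] on a
#'   `"cell_cycle"`-mode colony).
#' @param params the [SwitchParams-class] used for the simulation
#'   (`timingModel` must be `"cell_cycle"`; `gfpDelay` supplies the lag).
#' @return A data frame with columns `budStage` (`"unbudded"`,
#'   `"small_budded"`, `"large_budded"`), `progeny` and `pattern`
#'   (integer 1-8 or `NA`). Zero events give zero rows: cells without an
#'   event stay red and have no pattern.
#' @export
classifySwitchPattern <- function(events, params) {
  stopifnot(is(params, "SwitchParams"))
  if (params@timingModel != "cell_cycle")
    stop("pattern classification requires events from a ",
         "\"cell_cycle\"-mode simulation")
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(budStage = character(), progeny = character(),
                      pattern = integer(), stringsAsFactors = FALSE))
  if (any(events$phase == "not_applicable" | is.na(events$tCycle)))
    stop("events lack cell-cycle timing; re-simulate in \"cell_cycle\" mode")
  detect <- (events$tCycle + params@gfpDelay) %% 1
  stage <- ifelse(detect < .CYCLE_BUD_EMERGENCE, "unbudded",
           ifelse(detect < .CYCLE_LARGE_BUD, "small_budded", "large_budded"))
  lookup <- matrix(c(1L, 2L, 3L,        # unbudded: m, d, both
                     4L, 5L, 6L,        # small-budded
                     7L, 8L, NA),       # large-budded (both: unnumbered)
                   nrow = 3L, byrow = TRUE,
                   dimnames = list(
                     c("unbudded", "small_budded", "large_budded"),
                     c("mother", "daughter", "both")))
  pattern <- lookup[cbind(stage, events$progeny)]
  data.frame(budStage = stage, progeny = events$progeny,
             pattern = as.integer(pattern), stringsAsFactors = FALSE)
}
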