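# Half-sector frequency estimator and replicate-level comparisons.
# The estimator is the printed formula
#   half-sectored / (total - fully green):
# fully green colonies were founded by a cell that switched before its
# first division on the plate, so they are excluded from the denominator
# of per-division opportunities.

#' Half-sector frequency of a plate
#'
#' Computes `half_sectored / (total - fully_green)`, the per-division
#' frequency of reporter switches. Partially sectored colonies never enter
#' the estimator.
#'
#' @param counts a [SectorCounts-class] object.
#' @return Frequency of half-sectored colonies per countable colony
#'   (dimensionless; equals the per-division switch rate).
#' @examples
#' halfSectorFrequency(SectorCounts(1267, halfSectored = 2, fullyGreen = 3))
#' @export
halfSectorFrequency <- function(counts) {
  stopifnot(is(counts, "SectorCounts"))
  validObject(counts)
  denom <- counts@totalColonies - counts@fullyGreen
  if (denom <= 0L)
    stop("degenerate plate: no countable colonies ",
         "(total - fully green must be positive)")
  counts@halfSectored / denom
}

#' Summarize replicate frequency estimates
#'
#' @param estimates numeric vector of per-replicate frequencies.
#' @return A [RateEstimate-class] object with the arithmetic mean and the
#'   sample (n-1) standard deviation. With a single replicate the SD is
#'   `NA` and a warning is issued.
#' @examples
#' summarizeReplicates(c(0.0015, 0.0016, 0.00164))
#' @export
summarizeReplicates <- function(estimates) {
  if (!is.numeric(estimates) || length(estimates) == 0L ||
      anyNA(estimates))
    stop("'estimates' must be a non-empty numeric vector without NAs")
  n <- length(estimates)
  if (n < 2L)
    warning("single replicate: standard deviation undefined")
  new("RateEstimate", replicateEstimates = as.numeric(estimates),
      mean = mean(estimates),
      sd = if (n >= 2L) stats::sd(estimates) else NA_real_,
      nReplicates = n, ci = numeric())
}

#' Fold-change between two rate estimates
#'
#' Ratio of replicate means, with a delta-method standard error propagated
#' from the replicate SDs (reported as supporting plumbing; printed
#' comparisons in the field quote the ratio of means alone).
#'
#' @param numerator,denominator [RateEstimate-class] objects (or bare
#'   numeric means, in which case no SE is propagated).
#' @return A list with elements `fold` and `se` (`NA` when SEs are
#'   unavailable).
#' @examples
#' a <- summarizeReplicates(c(0.054, 0.052, 0.059))
#' b <- summarizeReplicates(c(0.0015, 0.0016, 0.00164))
#' foldChange(a, b)
#' @export
foldChange <- function(numerator, denominator) {
  asPair <- function(x) {
    if (is(x, "RateEstimate"))
      c(mean = x@mean,
        se = if (x@nReplicates >= 2L && !is.na(x@sd))
               x@sd / sqrt(x@nReplicates) else NA_real_)
    else c(mean = as.numeric(x), se = NA_real_)
  }
  a <- asPair(numerator)
  b <- asPair(denominator)
  if (!is.finite(b[["mean"]]) || b[["mean"]] <= 0)
    stop("denominator mean must be positive")
  fold <- a[["mean"]] / b[["mean"]]
  se <- if (anyNA(c(a[["se"]], b[["se"]]))) NA_real_
        else fold * sqrt((a[["se"]] / a[["mean"]])^2 +
                         (b[["se"]] / b[["mean"]])^2)
  list(fold = fold, se = se)
}

#' Equal-variance two-sided Student's t test on replicate frequencies
#'
#' @param groupA,groupB numeric vectors of replicate estimates (at least
#'   two per group).
#' @return A list with `statistic`, `p.value`, `df` and `degenerate`.
#'   When both groups have zero variance the test is degenerate: equal
#'   means give `t = 0, p = 1`; different means are reported as an
#'   infinite statistic with `p = 0` and `degenerate = TRUE`.
#' @export
twoSampleT <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("at least two replicates per group are required")
  df <- length(groupA) + length(groupB) - 2L
  pooled <- (sum((groupA - mean(groupA))^2) +
             sum((groupB - mean(groupB))^2)) / df
  if (pooled == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, p.value = 1, df = df, degenerate = TRUE))
    return(list(statistic = sign(mean(groupA) - mean(groupB)) * Inf,
                p.value = 0, df = df, degenerate = TRUE))
  }
  fit <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p.value = fit$p.value,
       df = unname(fit$parameter), degenerate = FALSE)
}

#' Simulation / estimation round trip
#'
#' Simulates `nReplicates` independent plated populations under `params`
#' and feeds the class tallies through [halfSectorFrequency()] and
#' [summarizeReplicates()], recovering the generative per-division rate.
#'
#' @param params a [SwitchParams-class] object.
#' @param nColonies colonies per replicate.
#' @param nReplicates number of independent replicates.
#' @param seed explicit RNG seed; replicate r uses `seed + r - 1`.
#' @param method simulation method, see [simulateColonyTable()].
#' @return A [RateEstimate-class] object.
#' @examples
#' recoverRate(SwitchParams(pDiv = 0.01), nColonies = 2e4,
#'             nReplicates = 3, seed = 1)
#' @export
recoverRate <- function(params, nColonies, nReplicates, seed,
                        method = c("thinned", "tree")) {
  method <- match.arg(method)
  seed <- checkSeed(seed)
  est <- vapply(seq_len(nReplicates), function(r) {
    counts <- simulatePopulation(params, nColonies,
                                 seed = seed + r - 1L, method = method,
                                 replicateId = paste0("rep", r))
    halfSectorFrequency(counts)
  }, numeric(1))
  suppressWarnings(summarizeReplicates(est))
}

#' Percentile bootstrap confidence interval for a rate estimate
#'
#' Resamples colonies with replacement within each replicate (multinomial
#' resampling of the class tallies), re-applies the half-sector formula,
#' averages across replicates, and takes percentile limits over the
#' bootstrap distribution of that mean.
#'
#' @param countsList list of [SectorCounts-class] objects, one per
#'   replicate.
#' @param nBoot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed explicit RNG seed.
#' @return A [RateEstimate-class] object whose `ci` slot holds
#'   `c(level, lower, upper)`.
#' @export
bootstrapRateCI <- function(countsList, nBoot = 2000L, level = 0.95,
                            seed) {
  stopifnot(length(countsList) >= 1L,
            all(vapply(countsList, is, logical(1), "SectorCounts")))
  est <- vapply(countsList, halfSectorFrequency, numeric(1))
  out <- suppressWarnings(summarizeReplicates(est))
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      mean(vapply(countsList, function(cc) {
        n <- cc@totalColonies
        other <- n - cc@halfSectored - cc@fullyGreen
        draw <- stats::rmultinom(1L, n,
                  prob = c(cc@halfSectored, cc@fullyGreen, other) / n)
        denom <- n - draw[2L]
        if (denom <= 0L) return(NA_real_)
        draw[1L] / denom
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                       names = FALSE)
  initialize(out, ci = c(level, q[1L], q[2L]))
}
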