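# Sampling of per-cell transcript counts from the supported distribution
# families. The negative binomial is parameterized by (mean, variance):
# size = mean^2 / (variance - mean), so the first two moments match the
# printed summary statistics exactly.

#' Draw per-cell transcript counts from a count model
#'
#' @param model a [CountModel-class] object.
#' @param nCells number of cells.
#' @param seed explicit RNG seed.
#' @return Integer vector of length `nCells` with non-negative counts.
#'   A `"negbin"` model whose variance does not exceed its mean falls back
#'   to Poisson sampling with a warning.
#' @examples
#' sampleCounts(CountModel("negbin", mean = 12, variance = 53),
#'              nCells = 10, seed = 1)
#' @export
sampleCounts <- function(model, nCells, seed) {
  stopifnot(is(model, "CountModel"))
  validObject(model)
  if (nCells < 0L) stop("'nCells' must be non-negative")
  seed <- checkSeed(seed)
  withSeed(seed, sampleCountsImpl(model, nCells))
}

sampleCountsImpl <- function(model, nCells) {
  n <- as.integer(nCells)
  switch(model@family,
    poisson = stats::rpois(n, lambda = model@mean),
    negbin = {
      if (!is.finite(model@variance) || model@variance <= model@mean) {
        warning("negative binomial requires variance > mean; ",
                "falling back to Poisson(", model@mean, ")")
        stats::rpois(n, lambda = model@mean)
      } else {
        size <- model@mean^2 / (model@variance - model@mean)
        stats::rnbinom(n, size = size, mu = model@mean)
      }
    },
    mixture = {
      counts <- integer(n)
      expressed <- stats::runif(n) < model@piExpressed
      if (any(expressed))
        counts[expressed] <- sampleCountsImpl(model@expressedComponent,
                                              sum(expressed))
      counts
    })
}
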