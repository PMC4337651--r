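# Seed discipline: every stochastic operation takes an explicit seed and
# restores the caller's RNG state on exit, so no function touches global
# RNG state as a side effect.

checkSeed <- function(seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L ||
      !is.numeric(seed) || is.na(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  as.integer(seed)
}

withSeed <- function(seed, expr) {
  seed <- checkSeed(seed)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}
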