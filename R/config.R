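# Run configuration: a YAML file with an experiment name, a seed, and
# module-specific parameter blocks. Field names in the [switch] block
# mirror the SwitchParams slots (snake_case in the file).

#' Read and validate a run configuration
#'
#' The file is YAML with top-level fields `experiment`, `seed` and module
#' blocks (`strains` with per-strain `switch` blocks for sector
#' experiments; `fish` and `caller` blocks for FISH experiments). Every
#' stochastic run takes its seed from the config; a missing or
#' non-numeric seed is a validation error.
#'
#' @param path YAML config path.
#' @return A validated named list (the run configuration).
#' @seealso [runSectorExperiment()], [runFishExperiment()],
#'   [writeRunConfig()]
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$experiment) || !nzchar(cfg$experiment))
    stop("config: 'experiment' name is required")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || is.na(cfg$seed))
    stop("config: a numeric 'seed' is required")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$strains)) {
    if (!length(cfg$strains)) stop("config: 'strains' is empty")
    for (nm in names(cfg$strains)) {
      blk <- cfg$strains[[nm]]$switch
      if (is.null(blk))
        stop("config: strains.", nm, ".switch block is required")
      tryCatch(switchParamsFromConfig(blk),
               error = function(e)
                 stop("config: strains.", nm, ".switch: ",
                      conditionMessage(e), call. = FALSE))
    }
  }
  cfg
}

#' Build switching parameters from a config block
#'
#' @param block named list with fields mirroring [SwitchParams()]
#'   arguments in snake_case: `p_div`, `q_pre`, `generations`,
#'   `timing_model`, `f_pre_replication`, `gfp_delay`, `horizon`.
#' @return A [SwitchParams-class] object.
#' @export
switchParamsFromConfig <- function(block) {
  if (is.null(block$p_div)) stop("'p_div' is required")
  known <- c("p_div", "q_pre", "generations", "timing_model",
             "f_pre_replication", "gfp_delay", "horizon")
  extra <- setdiff(names(block), known)
  if (length(extra))
    stop("unknown switch field(s): ", paste(extra, collapse = ", "))
  SwitchParams(
    pDiv = block$p_div,
    qPre = if (is.null(block$q_pre)) 0 else block$q_pre,
    generations = if (is.null(block$generations)) 14L
                  else block$generations,
    timingModel = if (is.null(block$timing_model)) "simple"
                  else block$timing_model,
    fPreReplication = if (is.null(block$f_pre_replication)) 0.25
                      else block$f_pre_replication,
    gfpDelay = if (is.null(block$gfp_delay)) 0.5 else block$gfp_delay,
    horizon = if (is.null(block$horizon)) 6L else block$horizon)
}

#' Write a run configuration to YAML
#'
#' Round-trips losslessly with [readRunConfig()] for configurations made
#' of scalars and nested lists.
#'
#' @param cfg run configuration list.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Stable content hash of a configuration, recorded in output headers so
# a results file can be traced to the exact configuration that made it.
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
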