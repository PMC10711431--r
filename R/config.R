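# Pipeline configuration: defaults, YAML round-trip, validation.

#' Default pipeline configuration
#'
#' Defaults equal the published screen design where a printed value
#' exists: 15 search rounds, 0.7 clustering identity, 60-mer oligos,
#' -16 kcal/mol folding floor, an 11-sample schedule and persistence
#' through barcode 9.
#'
#' @return named list of class `pipeline_config`
#' @export
default_config <- function() {
  structure(list(
    # homolog mining
    rounds = 15L, identity_threshold = 0.7, e_threshold = 1e-3,
    genus = "Pseudomonas", n_planted = 50L, n_decoys = 200L,
    pseudocount_weight = 2,
    # oligo design
    oligo_length = 60L, dg_min = -16, fold_temperature = 30,
    # screen simulation
    n_variants = 52L, n_active = 4L, gene_length = 750L,
    n_pre_samples = 2L, cycles_per_round = 4L, n_rounds = 2L,
    retransform_sample = TRUE, recovery_hours = 4,
    bottleneck_N = 1e5, spontaneous_resistance_p = 1e-8,
    growth_generations = 12L,
    depth = 4000L, error_rate = 0.08,
    # analysis
    persistence_barcode = 9L, min_fraction = 0.001, min_margin = 0.1,
    # stats fixtures
    arf_true = 0.005, n_replicates = 3L, total_cfu = 1e5
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$rounds >= 1, "rounds must be >= 1")
  chk(cfg$identity_threshold > 0 && cfg$identity_threshold <= 1,
      "identity_threshold must lie in (0, 1]")
  chk(cfg$e_threshold > 0, "e_threshold must be positive")
  chk(cfg$oligo_length >= 20, "oligo_length must be >= 20")
  chk(is.numeric(cfg$dg_min), "dg_min must be numeric")
  chk(cfg$n_variants >= 2, "n_variants must be >= 2")
  chk(cfg$n_active >= 0 && cfg$n_active <= cfg$n_variants,
      "n_active must lie in [0, n_variants]")
  chk(cfg$error_rate >= 0 && cfg$error_rate <= 0.3,
      "error_rate must lie in [0, 0.3]")
  chk(cfg$depth >= 1, "depth must be >= 1")
  chk(cfg$min_fraction >= 0 && cfg$min_fraction < 1,
      "min_fraction must lie in [0, 1)")
  chk(cfg$min_margin >= 0 && cfg$min_margin < 1,
      "min_margin must lie in [0, 1)")
  chk(cfg$persistence_barcode >= 1, "persistence_barcode must be >= 1")
  chk(cfg$arf_true >= 0 && cfg$arf_true <= 1,
      "arf_true must lie in [0, 1]")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected; all
#' constraints are checked and violations listed exhaustively.  An empty
#' file yields the full default configuration.
#'
#' @param path YAML file
#' @return validated `pipeline_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(unclass(defaults), user)
  # preserve the defaults' types for integer-valued keys
  int_keys <- names(defaults)[vapply(defaults, is.integer, logical(1))]
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  cfg <- structure(cfg, class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `pipeline_config`
#' @param path output path
#' @return invisibly, the path
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Screen schedule implied by a configuration
#'
#' @param cfg a `pipeline_config`
#' @return a [screen_schedule()]
#' @export
config_schedule <- function(cfg) {
  screen_schedule(n_pre_samples = cfg$n_pre_samples,
                  cycles_per_round = cfg$cycles_per_round,
                  n_rounds = cfg$n_rounds,
                  retransform_sample = cfg$retransform_sample,
                  recovery_hours = cfg$recovery_hours,
                  bottleneck_N = cfg$bottleneck_N,
                  spontaneous_resistance_p = cfg$spontaneous_resistance_p,
                  growth_generations = cfg$growth_generations)
}
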