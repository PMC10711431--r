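# Synthetic CFU plating counts and per-colony mutation tables for the
# efficiency-statistics module.

#' Generate synthetic CFU plating counts
#'
#' Resistant counts are Binomial(total, arf_true) per induced replicate;
#' non-induced controls use the spontaneous rate.
#'
#' @param arf_true true per-cell edit probability in \[0, 1\]
#' @param n_replicates biological replicates per condition
#' @param total_cfu total (dilution-corrected) CFU plated per replicate
#' @param spontaneous_p per-cell spontaneous resistance rate for the
#'   non-induced controls
#' @param seed RNG seed
#' @return data.frame with `replicate`, `induced`, `resistant_cfu`,
#'   `total_cfu`
#' @export
generate_assay_fixtures <- function(arf_true, n_replicates = 3,
                                    total_cfu = 1e5, spontaneous_p = 0,
                                    seed = 1) {
  stopifnot(arf_true >= 0, arf_true <= 1, n_replicates >= 1, total_cfu > 0)
  set.seed(seed)
  induced <- rbinom(n_replicates, total_cfu, arf_true)
  control <- rbinom(n_replicates, total_cfu, spontaneous_p)
  data.frame(replicate = rep(seq_len(n_replicates), 2),
             induced = rep(c(TRUE, FALSE), each = n_replicates),
             resistant_cfu = c(induced, control),
             total_cfu = total_cfu,
             stringsAsFactors = FALSE)
}

#' Generate synthetic per-colony mutation tables
#'
#' Every colony carries the shared parental background plus a
#' Poisson-distributed number of extra mutations at positions drawn
#' without replacement, plus (optionally) the intended on-target edit.
#'
#' @param background data.frame of parental mutations (`position`, `ref`,
#'   `alt`)
#' @param n_colonies number of colonies
#' @param lambda_extra Poisson mean of extra (off-target) mutations per
#'   colony
#' @param genome_length coordinate space for the extra positions
#' @param ontarget optional one-row data.frame (`position`, `ref`, `alt`)
#'   added to every colony
#' @param seed RNG seed
#' @return list with `colonies` (data.frame: colony_id, position, ref,
#'   alt) and `parental` (the background data.frame)
#' @export
generate_mutation_fixtures <- function(background, n_colonies = 2,
                                       lambda_extra = 5,
                                       genome_length = 20000,
                                       ontarget = NULL, seed = 1) {
  set.seed(seed)
  taken <- c(background$position,
             if (!is.null(ontarget)) ontarget$position)
  colonies <- lapply(seq_len(n_colonies), function(ci) {
    n_extra <- rpois(1, lambda_extra)
    pos <- sample(setdiff(seq_len(genome_length), taken), n_extra)
    extra <- data.frame(position = pos,
                        ref = sample(DNA4, n_extra, replace = TRUE),
                        alt = NA_character_, stringsAsFactors = FALSE)
    if (n_extra > 0)
      extra$alt <- vapply(extra$ref, function(b) sample(setdiff(DNA4, b), 1),
                          character(1))
    muts <- rbind(background[, c("position", "ref", "alt")],
                  if (!is.null(ontarget))
                    ontarget[, c("position", "ref", "alt")],
                  extra)
    cbind(colony_id = sprintf("colony%02d", ci), muts,
          stringsAsFactors = FALSE)
  })
  list(colonies = do.call(rbind, colonies), parental = background)
}
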