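# Stochastic simulation of the pooled two-round serial-enrichment screen.

#' Per-variant simulation parameters
#'
#' Validates a parameter table for the screen simulator.
#'
#' @param variant_id unique variant ids
#' @param arf per-cycle edit-acquisition probability at saturation
#'   (allelic replacement frequency), in \[0, 1\]
#' @param tau action-rate time constant in hours (> 0): the edited
#'   fraction reached after recovery time T is `arf * (1 - exp(-T/tau))`
#' @param fitness relative per-generation growth multiplier (toxicity < 1)
#' @param dropout_p per-generation plasmid-loss probability in \[0, 1)
#' @return data.frame of class `variant_params`
#' @export
variant_params <- function(variant_id, arf, tau = 1, fitness = 1,
                           dropout_p = 0) {
  n <- length(variant_id)
  df <- data.frame(variant_id = as.character(variant_id),
                   arf = rep_len(arf, n), tau = rep_len(tau, n),
                   fitness = rep_len(fitness, n),
                   dropout_p = rep_len(dropout_p, n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$variant_id)) stop("duplicate variant ids")
  stopifnot(all(df$arf >= 0 & df$arf <= 1), all(df$tau > 0),
            all(df$fitness > 0), all(df$dropout_p >= 0 & df$dropout_p < 1))
  class(df) <- c("variant_params", "data.frame")
  df
}

#' Screen schedule
#'
#' Defaults mirror the study design: 2 pre-selection samples (pool and
#' growth), 4 recombineering cycles per round, 2 rounds with a
#' retransformation sample in between, 4 h recovery before selection —
#' 11 sample points in total.
#'
#' @param n_pre_samples pre-selection samples
#' @param cycles_per_round recombineering cycles per enrichment round
#' @param n_rounds enrichment rounds
#' @param retransform_sample sample the pool at each retransformation into
#'   a naive host between rounds
#' @param recovery_hours recovery time between recombineering and
#'   selection
#' @param bottleneck_N cells kept at each sampling bottleneck (`Inf` for
#'   deterministic expectation propagation)
#' @param spontaneous_resistance_p per-cell spontaneous resistance
#'   probability
#' @param growth_generations doublings per growth phase; fitness and
#'   plasmid dropout act once per generation
#' @return list of class `screen_schedule`
#' @export
screen_schedule <- function(n_pre_samples = 2, cycles_per_round = 4,
                            n_rounds = 2, retransform_sample = TRUE,
                            recovery_hours = 4, bottleneck_N = 1e5,
                            spontaneous_resistance_p = 1e-8,
                            growth_generations = 12) {
  stopifnot(n_pre_samples >= 0, cycles_per_round >= 1, n_rounds >= 1,
            recovery_hours > 0, bottleneck_N > 0,
            spontaneous_resistance_p >= 0, spontaneous_resistance_p < 1,
            growth_generations >= 1)
  structure(as.list(environment()), class = "screen_schedule")
}

#' Number of sample-collection points implied by a schedule
#'
#' @param schedule a [screen_schedule()]
#' @return integer sample count (11 under the defaults)
#' @export
n_sample_points <- function(schedule) {
  stopifnot(inherits(schedule, "screen_schedule"))
  schedule$n_pre_samples + schedule$n_rounds * schedule$cycles_per_round +
    if (schedule$retransform_sample) schedule$n_rounds - 1L else 0L
}

#' Initialize an equimolar pool
#'
#' @param params a [variant_params()] table (>= 2 variants)
#' @param seed RNG seed, recorded in the state
#' @return object of class `screen_state` with uniform frequencies, zero
#'   edited fractions and an empty sample log
#' @export
init_pool <- function(params, seed = 1) {
  stopifnot(inherits(params, "variant_params"))
  if (nrow(params) < 2) stop("a pool needs at least two variants")
  set.seed(seed)
  n <- nrow(params)
  structure(list(variant_ids = params$variant_id,
                 frequencies = rep(1 / n, n),
                 edited_fraction = rep(0, n),
                 sample_log = list(), seed = seed),
            class = "screen_state")
}

#' @export
print.screen_state <- function(x, ...) {
  cat(sprintf("screen_state: %d variants, %d samples logged\n",
              length(x$variant_ids), length(x$sample_log)))
  invisible(x)
}

check_state <- function(state) {
  stopifnot(all(state$frequencies >= 0),
            abs(sum(state$frequencies) - 1) < 1e-9,
            all(state$edited_fraction >= 0 & state$edited_fraction <= 1))
  invisible(state)
}

resample <- function(freq, N) {
  if (!is.finite(N)) return(freq / sum(freq)) # expectation mode
  counts <- as.numeric(rmultinom(1, size = N, prob = freq))
  counts / sum(counts)
}

snapshot <- function(state) {
  state$sample_log[[length(state$sample_log) + 1]] <-
    list(barcode_index = length(state$sample_log) + 1L,
         frequencies = setNames(state$frequencies, state$variant_ids))
  state
}

# growth phase: fitness and plasmid dropout compound per generation, then a
# sampling bottleneck
growth_step <- function(state, params, schedule) {
  g <- schedule$growth_generations
  w <- (params$fitness * (1 - params$dropout_p))^g
  f <- state$frequencies * w
  if (sum(f) <= 0) stop("pool extinct during growth")
  state$frequencies <- resample(f / sum(f), schedule$bottleneck_N)
  state
}

#' Run one recombineering cycle
#'
#' One cycle is: (i) growth with fitness and dropout reweighting; (ii)
#' editing, where each variant's edited fraction rises to
#' `arf * (1 - exp(-recovery_hours / tau))` (saturating action-rate
#' model); (iii) antibiotic selection, keeping edited cells plus the
#' spontaneous-resistance fraction of unedited cells; (iv) a multinomial
#' bottleneck; (v) the edited fraction resets for the next locus.  The
#' post-selection state is appended to the sample log.
#'
#' @param state a [screen_state][init_pool()]
#' @param params a [variant_params()] table
#' @param schedule a [screen_schedule()]
#' @param cycle_label cycle number used in error messages
#' @return updated state
#' @export
run_cycle <- function(state, params, schedule, cycle_label = NA) {
  check_state(state)
  state <- growth_step(state, params, schedule)
  gain <- params$arf * (1 - exp(-schedule$recovery_hours / params$tau))
  edited <- pmin(1, state$edited_fraction + gain)
  surv <- state$frequencies *
    (edited + schedule$spontaneous_resistance_p * (1 - edited))
  if (sum(surv) <= 0)
    stop("pool extinct at cycle ", cycle_label, ": no survivors of selection")
  state$frequencies <- resample(surv / sum(surv), schedule$bottleneck_N)
  state$edited_fraction <- rep(0, length(edited))
  snapshot(state)
}

#' Run the full pooled enrichment screen
#'
#' Emits `n_pre_samples` growth snapshots, then `cycles_per_round`
#' post-selection snapshots per round, with a retransformation snapshot
#' between rounds (plasmids moved into a naive host: frequencies pass a
#' bottleneck, edited fractions reset).  The default schedule yields 11
#' sample points.
#'
#' @param params a [variant_params()] table
#' @param schedule a [screen_schedule()]
#' @param seed RNG seed
#' @return final `screen_state` with the full `sample_log`
#' @export
run_screen <- function(params, schedule = screen_schedule(), seed = 1) {
  state <- init_pool(params, seed)
  for (p in seq_len(schedule$n_pre_samples)) {
    state <- growth_step(state, params, schedule)
    state <- snapshot(state)
  }
  cycle <- 0L
  for (round in seq_len(schedule$n_rounds)) {
    if (round > 1) {
      # retransformation into a naive host
      state$frequencies <- resample(state$frequencies, schedule$bottleneck_N)
      state$edited_fraction <- rep(0, length(state$frequencies))
      if (schedule$retransform_sample) state <- snapshot(state)
    }
    for (cc in seq_len(schedule$cycles_per_round)) {
      cycle <- cycle + 1L
      state <- run_cycle(state, params, schedule, cycle_label = cycle)
    }
  }
  check_state(state)
  state
}

#' Sample-point frequencies as a matrix
#'
#' @param state a [run_screen()] result
#' @return numeric matrix, variants x barcodes
#' @export
screen_frequencies <- function(state) {
  stopifnot(inherits(state, "screen_state"))
  do.call(cbind, lapply(state$sample_log, `[[`, "frequencies"))
}
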