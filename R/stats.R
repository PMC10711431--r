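# Allelic replacement frequency statistics, replicate t-tests, action-rate
# time-course fits and off-target summaries.

#' Allelic replacement frequency from CFU counts
#'
#' `100 * resistant / total` minus the non-induced control ARF, clamped at
#' zero (a message flags the clamp).  Scale-invariant in a common dilution
#' factor.
#'
#' @param resistant_cfu,total_cfu dilution-corrected plate counts
#' @param control_arf non-induced control ARF in percent, subtracted
#' @return ARF in percent
#' @export
compute_arf <- function(resistant_cfu, total_cfu, control_arf = 0) {
  if (any(total_cfu <= 0)) stop("total_cfu must be positive")
  raw <- 100 * resistant_cfu / total_cfu
  out <- raw - control_arf
  if (any(out < 0)) {
    message("control ARF exceeds induced ARF; clamped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' Replicate summary: mean, sample sd, n
#'
#' @param values numeric ARF values (percent)
#' @return list with `mean`, `sd` (`NA` when n = 1) and `n`
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values")
  list(mean = mean(values),
       sd = if (length(values) >= 2) sd(values) else NA_real_,
       n = length(values))
}

#' Format a replicate summary as "mean ± sd"
#'
#' @param values numeric values
#' @param digits digits after the decimal point
#' @return character scalar, e.g. `"14 ± 5.66"`
#' @export
format_mean_sd <- function(values, digits = 2) {
  s <- summarize_replicates(values)
  fmt <- function(x) {
    out <- sprintf(paste0("%.", digits, "f"), x)
    sub("\\.$", "", sub("(\\.[0-9]*?)0+$", "\\1", out))
  }
  if (is.na(s$sd)) fmt(s$mean)
  else paste0(fmt(s$mean), " ± ", fmt(s$sd))
}

#' Two-tailed two-sample t-test with significance stars
#'
#' Student's pooled-variance t-test by default (Welch with
#' `welch = TRUE`).  Stars follow the usual figure-legend map:
#' p <= 0.05 `*`, p < 0.01 `**`, p < 0.001 `***`, p < 0.0001 `****`.
#' Two zero-variance groups with equal means return t = 0, p = 1 by
#' convention.
#'
#' @param groupA,groupB numeric vectors, each n >= 2
#' @param welch use the Welch (unequal-variance) test
#' @return list with `t`, `p`, `stars`
#' @export
two_tailed_t <- function(groupA, groupB, welch = FALSE) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      message("both groups constant and equal; p = 1 by convention")
      return(list(t = 0, p = 1, stars = ""))
    }
    return(list(t = Inf * sign(mean(groupA) - mean(groupB)), p = 0,
                stars = "****"))
  }
  fit <- t.test(groupA, groupB, var.equal = !welch)
  p <- fit$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 1e-2) "**" else if (p <= 0.05) "*" else ""
  list(t = unname(fit$statistic), p = p, stars = stars)
}

#' Time-course fraction of final ARF and action-rate fit
#'
#' Normalizes an ARF time course by its final value and fits the
#' saturating action-rate model `A * (1 - exp(-t / tau))` by bounded
#' Levenberg-Marquardt least squares (tau bounded below at 0.01 h).
#'
#' @param hours sampling times in hours
#' @param arf_percent ARF at each time (percent); the final value must be
#'   positive
#' @return list with `fractions` (data.frame hours, fraction_of_final),
#'   `tau` (hours) and `A`
#' @export
time_course_fraction <- function(hours, arf_percent) {
  stopifnot(length(hours) == length(arf_percent), length(hours) >= 2)
  ord <- order(hours)
  hours <- hours[ord]; arf_percent <- arf_percent[ord]
  final <- arf_percent[length(arf_percent)]
  if (final <= 0) stop("final ARF is zero; fractions undefined")
  fractions <- arf_percent / final
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ A * (1 - exp(-t / tau)),
    data = data.frame(t = hours, y = arf_percent),
    start = list(A = max(arf_percent), tau = max(hours[1], 0.5)),
    lower = c(A = 0, tau = 0.01),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # saturation already complete at the first sample: tau hits its floor
    est <- c(A = final, tau = 0.01)
  } else {
    est <- coef(fit)
  }
  list(fractions = data.frame(hours = hours, fraction_of_final = fractions),
       tau = unname(est["tau"]), A = unname(est["A"]))
}

#' Off-target mutation summary with parental subtraction
#'
#' Counts, per colony, mutations absent from the parental background and
#' distinct from the intended on-target edit, then summarizes across
#' colonies.  Mutations are keyed on (position, ref, alt).
#'
#' @param colonies data.frame with `colony_id`, `position`, `ref`, `alt`
#' @param parental data.frame with `position`, `ref`, `alt`
#' @param ontarget optional one-row data.frame (`position`, `ref`, `alt`)
#'   naming the intended edit so it is not counted as off-target
#' @return list with `per_colony` (data.frame colony_id, off_target) and
#'   `mean`, `sd`, `n`, `label` (Table-style "mean ± sd")
#' @export
offtarget_summary <- function(colonies, parental, ontarget = NULL) {
  stopifnot(nrow(colonies) >= 1)
  key <- function(df) paste(df$position, df$ref, df$alt, sep = ":")
  excluded <- c(key(parental), if (!is.null(ontarget)) key(ontarget))
  per <- lapply(split(colonies, colonies$colony_id), function(cc) {
    if (anyDuplicated(cc$position)) stop("duplicate positions in a colony")
    sum(!key(cc) %in% excluded)
  })
  counts <- unlist(per)
  s <- summarize_replicates(counts)
  list(per_colony = data.frame(colony_id = names(counts),
                               off_target = unname(counts),
                               stringsAsFactors = FALSE),
       mean = s$mean, sd = s$sd, n = s$n,
       label = format_mean_sd(counts))
}

#' ARF summary table from a CFU table
#'
#' Computes per-replicate ARFs with non-induced control subtraction (the
#' mean control ARF per strain/locus), then summarizes replicates and
#' tests each strain against a named baseline with [two_tailed_t()].
#'
#' @param cfu data.frame with columns `strain_id`, `locus`, `replicate`,
#'   `induced`, `resistant_cfu`, `total_cfu`
#' @param baseline strain id used as the comparison group (optional)
#' @param welch passed to [two_tailed_t()]
#' @return data.frame with strain_id, locus, mean, sd, n, stars (vs the
#'   baseline; empty when no baseline)
#' @export
arf_summary <- function(cfu, baseline = NULL, welch = FALSE) {
  needed <- c("strain_id", "locus", "replicate", "induced", "resistant_cfu",
              "total_cfu")
  stopifnot(all(needed %in% names(cfu)))
  groups <- split(cfu, list(cfu$strain_id, cfu$locus), drop = TRUE)
  per_group <- lapply(groups, function(g) {
    ctrl <- g[!g$induced, , drop = FALSE]
    ind <- g[g$induced, , drop = FALSE]
    control_arf <- if (nrow(ctrl))
      mean(100 * ctrl$resistant_cfu / ctrl$total_cfu) else 0
    arfs <- compute_arf(ind$resistant_cfu, ind$total_cfu, control_arf)
    list(strain_id = ind$strain_id[1], locus = ind$locus[1], arfs = arfs)
  })
  out <- lapply(per_group, function(g) {
    s <- summarize_replicates(g$arfs)
    stars <- ""
    if (!is.null(baseline) && g$strain_id != baseline) {
      base <- Filter(function(h) h$strain_id == baseline &&
                       h$locus == g$locus, per_group)
      if (length(base) == 1 && length(base[[1]]$arfs) >= 2 &&
          length(g$arfs) >= 2)
        stars <- two_tailed_t(g$arfs, base[[1]]$arfs, welch = welch)$stars
    }
    data.frame(strain_id = g$strain_id, locus = g$locus, mean = s$mean,
               sd = s$sd, n = s$n, stars = stars, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
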