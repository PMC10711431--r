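# Position-specific scoring profiles and E-value calibration.

#' Background amino-acid frequencies
#'
#' Robinson & Robinson database frequencies over the 20 amino acids,
#' normalized to sum to one.  Used as the default log-odds background and
#' for shuffle decoys.
#' @return named numeric vector of length 20 summing to 1
#' @export
aa_background <- function() {
  f <- c(A = 0.0781, C = 0.0157, D = 0.0536, E = 0.0629, F = 0.0401,
         G = 0.0737, H = 0.0219, I = 0.0593, K = 0.0595, L = 0.0935,
         M = 0.0224, N = 0.0449, P = 0.0520, Q = 0.0426, R = 0.0512,
         S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0132, Y = 0.0321)
  f / sum(f)
}

#' Build a log-odds profile (PSSM) from a multiple alignment
#'
#' Column scores are `log2(p_a / bg_a)` in bits, where
#' `p_a = (W f_a + alpha bg_a) / (W + alpha)` mixes the weighted observed
#' column frequency `f_a` (uniform, position-independent sequence weights;
#' `W` is the summed weight of rows with a residue in the column) with the
#' background under pseudocount weight `alpha`.  Columns gapped in more
#' than half the rows are dropped.  X residues are ignored in counts and
#' score 0 everywhere.
#'
#' @param msa an [build_msa()] result, or a character matrix of aligned
#'   residues (rows = sequences)
#' @param pseudocount_weight positive pseudocount mass `alpha`
#' @param background amino-acid background frequencies (sum to 1)
#' @param gap_open,gap_extend profile gap penalties in bits
#' @param max_gap_frac columns with gap fraction strictly above this are
#'   dropped
#' @return object of class `ssap_profile` with fields `length`, `scores`
#'   (L x 21 matrix in bits, X column zero), `background`, `gap_open`,
#'   `gap_extend`, `pseudocount_weight`, `kept_columns`, and the source
#'   alignment matrix in `aln_matrix`
#' @export
build_profile <- function(msa, pseudocount_weight = 2,
                          background = aa_background(),
                          gap_open = -5.5, gap_extend = -0.5,
                          max_gap_frac = 0.5) {
  stopifnot(pseudocount_weight > 0)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  m <- if (inherits(msa, "ssap_msa")) msa_matrix(msa) else msa
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("empty alignment")

  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0) stop("all alignment columns exceed the gap cutoff")

  nseq <- nrow(m)
  w <- rep(1, nseq) # uniform position-independent sequence weights
  scores <- matrix(0, length(keep), length(AA_ALPHABET),
                   dimnames = list(NULL, AA_ALPHABET))
  for (ci in seq_along(keep)) {
    col <- m[, keep[ci]]
    obs <- col %in% AA20
    W <- sum(w[obs])
    f <- vapply(AA20, function(a) sum(w[obs & col == a]), numeric(1))
    f <- if (W > 0) f / W else f
    p <- (W * f + pseudocount_weight * background[AA20]) /
         (W + pseudocount_weight)
    scores[ci, AA20] <- log2(p / background[AA20])
  }
  if (any(!is.finite(scores))) stop("non-finite profile scores")

  structure(list(length = length(keep), scores = scores,
                 background = background, gap_open = gap_open,
                 gap_extend = gap_extend,
                 pseudocount_weight = pseudocount_weight,
                 kept_columns = keep, aln_matrix = m,
                 calibration = NULL),
            class = "ssap_profile")
}

#' @export
print.ssap_profile <- function(x, ...) {
  cat(sprintf("ssap_profile: %d columns (%d sequences)%s\n", x$length,
              nrow(x$aln_matrix),
              if (is.null(x$calibration)) ", uncalibrated" else ", calibrated"))
  invisible(x)
}

# Maximum-likelihood Gumbel fit (location mu, scale beta) to a numeric
# sample; falls back to the method of moments on a degenerate sample.
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  beta0 <- sd(x) * sqrt(6) / pi
  if (!is.finite(beta0) || beta0 < 1e-6)
    return(list(mu = mean(x), beta = 1e-6))
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(par) {
    beta <- exp(par[2])
    z <- (x - par[1]) / beta
    v <- sum(log(beta) + z + exp(-z))
    if (!is.finite(v)) 1e12 else v
  }
  fit <- tryCatch(optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit)) return(list(mu = mu0, beta = beta0))
  list(mu = fit$par[1], beta = exp(fit$par[2]))
}

# Residue-shuffled decoy of one sequence.
shuffle_seq <- function(x) {
  paste(sample(strsplit(x, "")[[1]]), collapse = "")
}

#' Calibrate a profile's E-value model on shuffled decoys
#'
#' Scores `n_decoys` residue-shuffled copies of database sequences against
#' the profile and fits a Gumbel (extreme-value) distribution to the local
#' alignment scores by maximum likelihood.  E-values are then
#' `db_size * P(S >= s)` under the fit, capped at `db_size`.
#'
#' @param profile an [build_profile()] object
#' @param database named character vector of protein sequences (decoy
#'   source and database size)
#' @param n_decoys number of shuffled decoys
#' @param seed RNG seed for the shuffles (recorded in the calibration)
#' @return the profile with a `calibration` list (mu, beta, db_size,
#'   n_decoys, seed)
#' @export
calibrate_profile <- function(profile, database, n_decoys = 200, seed = 1) {
  stopifnot(inherits(profile, "ssap_profile"), length(database) > 0)
  set.seed(seed)
  src <- sample(database, n_decoys, replace = TRUE)
  decoys <- vapply(src, shuffle_seq, character(1))
  sc <- vapply(decoys, function(s) {
    cpp_sw_profile(profile$scores, encode_aa(s), profile$gap_open,
                   profile$gap_extend, FALSE)$score
  }, numeric(1))
  fit <- fit_gumbel(sc)
  profile$calibration <- list(mu = fit$mu, beta = fit$beta,
                              db_size = length(database),
                              n_decoys = n_decoys, seed = seed)
  profile
}

#' Score a sequence against a calibrated profile
#'
#' Best local (Smith-Waterman) alignment of the sequence against the
#' profile with affine gaps.  The E-value is the expected number of
#' database sequences scoring at least as well under the calibrated Gumbel
#' model; it is strictly decreasing in the bit score and capped at the
#' database size.  A sequence with no known residues scores 0 with E-value
#' equal to the database size.
#'
#' @param profile a calibrated [ssap_profile][build_profile()]
#' @param sequence protein string (may contain X)
#' @return list with `bit_score` and `e_value`
#' @export
score_sequence <- function(profile, sequence) {
  stopifnot(inherits(profile, "ssap_profile"))
  if (!nzchar(sequence)) stop("empty sequence")
  if (is.null(profile$calibration))
    stop("profile is not calibrated; run calibrate_profile() first")
  cal <- profile$calibration
  codes <- encode_aa(sequence)
  if (all(AA_ALPHABET[codes] == "X"))
    return(list(bit_score = 0, e_value = cal$db_size))
  s <- cpp_sw_profile(profile$scores, codes, profile$gap_open,
                      profile$gap_extend, FALSE)$score
  p_tail <- -expm1(-exp(-(s - cal$mu) / cal$beta)) # 1 - exp(-exp(-z))
  list(bit_score = s, e_value = min(cal$db_size, cal$db_size * p_tail))
}

# Align a sequence to the profile and return the residue observed at each
# profile column ("-" where uncovered); used to absorb hits during search.
profile_align_row <- function(profile, sequence) {
  res <- cpp_sw_profile(profile$scores, encode_aa(sequence),
                        profile$gap_open, profile$gap_extend, TRUE)
  chars <- rep("-", profile$length)
  cov <- res$cols > 0
  chars[cov] <- AA_ALPHABET[res$cols[cov]]
  chars
}
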