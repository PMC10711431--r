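# Independent oracles used across the suite: exhaustive alignment
# enumeration, brute-force hairpin structures, Biostrings-based identity,
# closed-form statistics.  These never share code paths with the package
# implementations they check.

# --- exhaustive global affine alignment -----------------------------------
# Enumerates every global alignment of a and b (affine gap cost
# go + L * ge, penalties negative) and returns the best score plus the
# range of match counts among score-optimal alignments.
oracle_global_enum <- function(a, b, submat, go = -11, ge = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best <- -Inf
  match_set <- integer(0)
  rec <- function(i, j, prev, sc, mt) {
    if (i == m && j == n) {
      if (sc > best) { best <<- sc; match_set <<- mt }
      else if (sc == best) match_set <<- union(match_set, mt)
      return(invisible())
    }
    if (i < m && j < n)
      rec(i + 1, j + 1, "M", sc + submat[A[i + 1], B[j + 1]],
          mt + (A[i + 1] == B[j + 1]))
    if (i < m)
      rec(i + 1, j, "X", sc + if (prev == "X") ge else go + ge, mt)
    if (j < n)
      rec(i, j + 1, "Y", sc + if (prev == "Y") ge else go + ge, mt)
  }
  rec(0, 0, "start", 0, 0L)
  list(score = best, matches_min = min(match_set),
       matches_max = max(match_set))
}

# --- exhaustive local profile alignment -----------------------------------
# Best local alignment score of integer-coded sequence against a profile
# score matrix by explicit enumeration of every sub-alignment path.
oracle_local_profile_enum <- function(scores, codes, go, ge) {
  L <- nrow(scores); n <- length(codes)
  best <- 0
  rec <- function(i, j, prev, sc) {
    # path currently ends having consumed column i and residue j
    if (sc > best) best <<- sc
    if (i < L && j < n)
      rec(i + 1, j + 1, "M", sc + scores[i + 1, codes[j + 1]])
    if (i < L && prev != "start")
      rec(i + 1, j, "X", sc + if (prev == "X") ge else go + ge)
    if (j < n && prev != "start")
      rec(i, j + 1, "Y", sc + if (prev == "Y") ge else go + ge)
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(n))
    rec(i0, j0, "M", scores[i0, codes[j0]])
  best
}

# --- brute-force hairpin enumeration --------------------------------------
# Enumerates every contiguous-stem hairpin (outer pair (i, j), stem depth
# k, terminal loop >= 3) and sums nearest-neighbor stacks + loop penalty.
oracle_hairpin_enum <- function(sequence, temperature = 30) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  TK <- temperature + 273.15
  par <- ssapkit:::nn_dna_params()
  dg <- par$dH - TK * par$dS / 1000
  loop_pen <- function(len) {
    scale <- TK / 310.15
    if (len <= 30) par$loop_dG37[findInterval(len, par$loop_sizes)] * scale
    else (par$loop_dG37[length(par$loop_dG37)] +
            1.75 * 0.0019872 * 310.15 * log(len / 30)) * scale
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- function(x, y) x %in% names(comp) && identical(comp[[x]], y)
  best <- 0
  for (i in seq_len(n - 1)) {
    if (i + 4 > n) break
    for (j in (i + 4):n) {
      kmax <- (j - i - 3 + 1) %/% 2
      for (k in seq_len(max(kmax, 0))) {
        ok <- all(vapply(seq_len(k) - 1L,
                         function(mm) wc(s[i + mm], s[j - mm]), logical(1)))
        if (!ok) break
        loop <- j - i - 2 * k + 1
        if (loop < 3) break
        stack_e <- if (k >= 2)
          sum(vapply(seq_len(k - 1) - 1L, function(mm)
            dg[[paste0(s[i + mm], s[i + mm + 1])]], numeric(1)))
        else 0
        e <- stack_e + loop_pen(loop)
        if (e < best) best <- e
      }
    }
  }
  best
}

# --- Biostrings-based identity (CD-HIT convention) ------------------------
oracle_identity_bs <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

# --- closed-form pooled two-sample t --------------------------------------
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tt), df = na + nb - 2)
  list(t = tt, p = p)
}

# --- permutation test for a mean difference -------------------------------
oracle_permutation_p <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), length(a))
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# --- shared small fixtures -------------------------------------------------
fixture_seeds <- function() {
  read_fasta(system.file("extdata", "seed_ssaps_synthetic.faa",
                         package = "ssapkit"), "AA")
}
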