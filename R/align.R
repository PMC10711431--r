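# Pairwise and multiple protein alignment used by homolog mining.

#' BLOSUM62 substitution scores over the package's amino-acid alphabet
#'
#' Subsets the BLOSUM62 matrix shipped with Biostrings (half-bit scores) to
#' the 20 amino acids plus X.
#' @return numeric 21 x 21 matrix ordered like the internal alphabet
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "double"
  m
}

#' Global alignment of two protein sequences (affine gaps)
#'
#' Needleman-Wunsch with affine gap penalties; a gap of length L costs
#' `gap_open + L * gap_extend` (penalties are negative).
#'
#' @param a,b protein strings
#' @param submat substitution matrix over the package alphabet
#'   (default [blosum62_matrix()])
#' @param gap_open,gap_extend gap penalties in half-bits
#' @return list with `score`, `matches` (identical aligned positions) and
#'   `alignment` (two gapped strings)
#' @export
align_global <- function(a, b, submat = NULL, gap_open = -11, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in align_global()")
  if (is.null(submat)) submat <- blosum62_matrix()
  res <- cpp_nw_affine(encode_aa(a), encode_aa(b), submat, gap_open, gap_extend)
  list(score = res$score, matches = res$matches,
       alignment = c(decode_aa(res$aligned_a), decode_aa(res$aligned_b)))
}

#' Pairwise percent identity between two protein sequences
#'
#' Global alignment identity counted as exact matches divided by the length
#' of the shorter sequence (the CD-HIT convention), so a perfect substring
#' scores 1.
#'
#' @inheritParams align_global
#' @return scalar in \[0, 1\]
#' @export
pairwise_identity <- function(a, b, submat = NULL, gap_open = -11,
                              gap_extend = -1) {
  res <- align_global(a, b, submat, gap_open, gap_extend)
  res$matches / min(nchar(a), nchar(b))
}

#' Center-star multiple sequence alignment
#'
#' Progressive alignment around the center sequence (the one maximizing the
#' summed pairwise global-alignment score to all others), merging pairwise
#' alignments under the once-a-gap-always-a-gap rule.  Deterministic: ties
#' for the center are broken by input order, and sequences are merged in
#' input order.
#'
#' @param seeds named character vector of >= 2 protein sequences
#' @inheritParams align_global
#' @return an object of class `ssap_msa`: list with `ids`, `aln` (named
#'   gapped strings, equal width) and `width`
#' @export
build_msa <- function(seeds, submat = NULL, gap_open = -11, gap_extend = -1) {
  if (length(seeds) < 2)
    stop("build_msa() needs at least two sequences")
  if (is.null(names(seeds)) || anyDuplicated(names(seeds)))
    stop("seeds must carry unique names")
  if (any(!nzchar(seeds))) stop("empty sequence in seed set")
  if (is.null(submat)) submat <- blosum62_matrix()

  n <- length(seeds)
  enc <- lapply(seeds, encode_aa)
  scores <- matrix(0, n, n)
  pair_aln <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- cpp_nw_affine(enc[[i]], enc[[j]], submat, gap_open, gap_extend)
      scores[i, j] <- scores[j, i] <- r$score
      pair_aln[[(i - 1) * n + j]] <- r
    }
  }
  center <- which.max(rowSums(scores))

  # master alignment: rows as character vectors, first the center
  master_center <- strsplit(seeds[[center]], "")[[1]]
  rows <- list()
  rows[[names(seeds)[center]]] <- master_center

  for (j in seq_len(n)) {
    if (j == center) next
    r <- if (center < j) pair_aln[[(center - 1) * n + j]] else {
      rr <- pair_aln[[(j - 1) * n + center]]
      list(aligned_a = rr$aligned_b, aligned_b = rr$aligned_a)
    }
    ca <- r$aligned_a  # center, gapped codes (0 = gap)
    oa <- r$aligned_b  # new sequence
    new_row <- character(0)
    p <- 1L; q <- 1L
    width <- length(master_center)
    while (p <= width || q <= length(ca)) {
      if (p <= width && master_center[p] == "-") {
        # insertion column from an earlier merge: new row is gapped there,
        # unless the pairwise alignment also inserts here (consume together)
        if (q <= length(ca) && ca[q] == 0L) {
          new_row <- c(new_row, AA_ALPHABET[oa[q]])
          q <- q + 1L
        } else {
          new_row <- c(new_row, "-")
        }
        p <- p + 1L
      } else if (q <= length(ca) && ca[q] == 0L) {
        # new insertion relative to the center: open a column in the master
        master_center <- append(master_center, "-", after = p - 1L)
        rows <- lapply(rows, function(rw) append(rw, "-", after = p - 1L))
        new_row <- c(new_row, AA_ALPHABET[oa[q]])
        width <- width + 1L
        p <- p + 1L; q <- q + 1L
      } else if (p <= width && q <= length(ca)) {
        # center residue column
        new_row <- c(new_row,
                     if (oa[q] == 0L) "-" else AA_ALPHABET[oa[q]])
        p <- p + 1L; q <- q + 1L
      } else {
        stop("internal error: center-star merge out of sync")
      }
    }
    rows[[names(seeds)[j]]] <- new_row
  }

  aln <- vapply(rows, paste, character(1), collapse = "")
  aln <- aln[names(seeds)] # restore input order
  structure(list(ids = names(seeds), aln = aln,
                 width = nchar(aln[[1]])),
            class = "ssap_msa")
}

#' @export
print.ssap_msa <- function(x, ...) {
  cat(sprintf("ssap_msa: %d sequences, %d columns\n",
              length(x$aln), x$width))
  invisible(x)
}

# gapped strings -> character matrix (rows x columns)
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$aln), ""))
}
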