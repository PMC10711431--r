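# Recombineering oligonucleotide design: lagging-strand 60-mers with a
# nearest-neighbor hairpin free-energy filter.

#' Replichore map of a circular genome
#'
#' Coordinates of the replication origin and terminus; determines which
#' replichore (and hence which strand is lagging) a locus falls on.
#'
#' @param oriC,ter 1-based coordinates, distinct
#' @param genome_length genome length in bp
#' @return object of class `replichore_map`
#' @export
replichore_map <- function(oriC, ter, genome_length) {
  stopifnot(oriC >= 1, ter >= 1, oriC <= genome_length,
            ter <= genome_length, oriC != ter)
  structure(list(oriC = as.integer(oriC), ter = as.integer(ter),
                 genome_length = as.integer(genome_length)),
            class = "replichore_map")
}

#' Edit specification: a small genomic substitution
#'
#' @param genome_id genome/replicon id
#' @param position 1-based coordinate of the first edited base (plus
#'   strand)
#' @param ref_bases,alt_bases equal-length strings of 1-3 bases
#' @param label unique human-readable label (e.g. `"rpsL K43T"`)
#' @return object of class `edit_spec`
#' @export
edit_spec <- function(genome_id, position, ref_bases, alt_bases, label) {
  ref_bases <- toupper(ref_bases); alt_bases <- toupper(alt_bases)
  if (nchar(ref_bases) != nchar(alt_bases))
    stop("ref and alt must have equal length")
  if (nchar(ref_bases) < 1 || nchar(ref_bases) > 3)
    stop("edits are limited to 1-3 nucleotides")
  if (identical(ref_bases, alt_bases))
    stop("ref and alt are identical; not an edit")
  structure(list(genome_id = genome_id, position = as.integer(position),
                 ref_bases = ref_bases, alt_bases = alt_bases, label = label),
            class = "edit_spec")
}

#' Strand an oligo must carry to target the lagging strand
#'
#' The replication fork travels in increasing coordinates from oriC to ter
#' on one replichore (direction +1, with wrap-around) and decreasing on the
#' other (-1).  A recombineering oligo anneals to the lagging-strand
#' template, so it carries the sequence of the strand opposite to the
#' fork's continuously synthesized one: direction +1 returns `"minus"`,
#' direction -1 returns `"plus"`.  A locus exactly at oriC or ter has no
#' defined replichore and raises an error demanding an explicit override.
#'
#' @param edit an [edit_spec()]
#' @param map a [replichore_map()]
#' @return `"plus"` or `"minus"`
#' @export
determine_targeting_strand <- function(edit, map) {
  stopifnot(inherits(edit, "edit_spec"), inherits(map, "replichore_map"))
  pos <- edit$position
  if (pos < 1 || pos > map$genome_length) stop("locus outside the genome")
  if (pos == map$oriC || pos == map$ter)
    stop("locus falls exactly at oriC/ter; strand undefined - ",
         "override the strand explicitly")
  on_forward_arc <- if (map$oriC < map$ter) {
    pos > map$oriC && pos < map$ter
  } else {
    pos > map$oriC || pos < map$ter # wrap-around
  }
  if (on_forward_arc) "minus" else "plus"
}

#' Design a recombineering oligo for one edit
#'
#' Takes the `length`-nt plus-strand window centered on the edit (the edit
#' starts at plus-window offset `floor((length - k)/2) + 1`, so a 1-nt edit
#' in a 60-mer sits at position 30), substitutes the alternate bases,
#' reverse-complements when the targeting strand is minus, and scores the
#' hairpin minimum free energy.  The genome is treated as linear: windows
#' must fit inside it.
#'
#' @param genome named character vector of genome sequences
#' @param edit an [edit_spec()]
#' @param map a [replichore_map()], or `NULL` with `strand` given
#' @param length oligo length (default 60)
#' @param strand optional explicit strand override (`"plus"`/`"minus"`)
#' @param temperature folding temperature in Celsius
#' @return object of class `oligo_design`: list with `label`, `sequence`,
#'   `strand`, `edit_offset` (on the emitted strand), `fold_energy`
#'   (kcal/mol) and `passes_filter` (`NA` until [filter_oligos()])
#' @export
design_oligo <- function(genome, edit, map = NULL, length = 60,
                         strand = NULL, temperature = 30) {
  stopifnot(inherits(edit, "edit_spec"))
  g <- genome[[edit$genome_id]]
  if (is.null(g)) stop("genome id not found: ", edit$genome_id)
  k <- nchar(edit$ref_bases)
  if (k >= length) stop("edit wider than the oligo")
  off <- (length - k) %/% 2 + 1L  # 1-based edit start within the plus window
  start <- edit$position - off + 1L
  end <- start + length - 1L
  if (start < 1 || end > nchar(g))
    stop("oligo window [", start, ", ", end, "] out of genome range")
  window <- substr(g, start, end)
  observed <- substr(window, off, off + k - 1L)
  if (observed != edit$ref_bases)
    stop("ref mismatch at ", edit$label, " position ", edit$position,
         ": genome has ", observed, ", edit expects ", edit$ref_bases)
  edited <- window
  substr(edited, off, off + k - 1L) <- edit$alt_bases
  if (is.null(strand)) {
    if (is.null(map)) stop("provide a replichore map or an explicit strand")
    strand <- determine_targeting_strand(edit, map)
  }
  strand <- match.arg(strand, c("plus", "minus"))
  if (strand == "minus") {
    sequence <- revcomp(edited)
    edit_offset <- as.integer(length - (off + k - 1L) + 1L)
  } else {
    sequence <- edited
    edit_offset <- as.integer(off)
  }
  fe <- hairpin_min_energy(sequence, temperature = temperature)
  structure(list(label = edit$label, sequence = sequence, strand = strand,
                 edit_offset = edit_offset, fold_energy = fe,
                 passes_filter = NA),
            class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat(sprintf("oligo %s [%s strand, edit at %d, dG %.2f kcal/mol]\n%s\n",
              x$label, x$strand, x$edit_offset, x$fold_energy, x$sequence))
  invisible(x)
}

# SantaLucia unified nearest-neighbor DNA parameters: dH (kcal/mol) and
# dS (cal/mol/K) for the 16 stacks 5'-XY-3' over their Watson-Crick
# complement.  The table is reverse-complement symmetric.
nn_dna_params <- function() {
  dH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
          TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
          CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
          GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
          TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
          CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
          GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
  list(dH = dH, dS = dS,
       # hairpin loop initiation dG at 37 C by loop size (DNA)
       loop_sizes = c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
       loop_dG37 = c(3.5, 3.5, 3.3, 4.0, 4.1, 4.1, 4.2, 4.3, 4.5, 4.6,
                     4.7, 4.8, 4.9, 5.2, 5.4))
}

#' Minimum hairpin folding free energy of a DNA oligo
#'
#' Minimum free energy over single stem-loop (hairpin) structures with a
#' terminal loop of at least 3 nt: contiguous Watson-Crick stems scored by
#' nearest-neighbor stack energies at the given temperature plus an
#' entropic loop-initiation penalty.  Returns 0 when no structure has
#' negative energy; the value is always <= 0.  Ambiguous bases never pair.
#'
#' @param sequence DNA string, length >= 8
#' @param temperature Celsius (default 30, the screen growth temperature)
#' @return minimum free energy in kcal/mol (<= 0)
#' @export
hairpin_min_energy <- function(sequence, temperature = 30) {
  n <- nchar(sequence)
  stopifnot(n >= 8)
  s <- strsplit(toupper(sequence), "")[[1]]
  if (any(!s %in% DNA4))
    message("ambiguous bases treated as non-pairing")
  TK <- temperature + 273.15
  par <- nn_dna_params()
  dg_stack <- par$dH - TK * par$dS / 1000

  loop_pen <- function(len) {
    scale <- TK / 310.15 # loop initiation treated as purely entropic
    if (len <= 30) {
      i <- findInterval(len, par$loop_sizes)
      g <- par$loop_dG37[i]
    } else {
      g <- par$loop_dG37[length(par$loop_dG37)] +
        1.75 * 0.0019872 * 310.15 * log(len / 30)
    }
    g * scale
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_ok <- function(i, j) {
    s[i] %in% DNA4 && s[j] %in% DNA4 && comp[[s[i]]] == s[j]
  }

  H <- matrix(NA_real_, n, n)
  best <- 0
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      if (!pairs_ok(i, j)) next
      loop_len <- j - i - 1
      e <- loop_pen(loop_len) # close the loop directly
      if (!is.na(H[i + 1, j - 1])) {
        stacked <- dg_stack[[paste0(s[i], s[i + 1])]] + H[i + 1, j - 1]
        e <- min(e, stacked)
      }
      H[i, j] <- e
      if (e < best) best <- e
    }
  }
  best
}

#' Flag oligo designs by folding-energy threshold
#'
#' Sets `passes_filter = fold_energy >= threshold`.  The default threshold
#' of -16 kcal/mol reads the published magnitude as a floor on the
#' (non-positive) predicted folding energy: structures more stable than
#' -16 kcal/mol fail.  No design is removed, only flagged; order is
#' preserved.
#'
#' @param designs list of [design_oligo()] results
#' @param threshold kcal/mol
#' @return the list with `passes_filter` set on every design
#' @export
filter_oligos <- function(designs, threshold = -16) {
  stopifnot(is.finite(threshold) || threshold == -Inf)
  lapply(designs, function(d) {
    d$passes_filter <- d$fold_energy >= threshold
    d
  })
}

#' Design oligos for a table of edits
#'
#' @param genome named character vector of genome sequences
#' @param edits data.frame with columns `genome_id`, `position`, `ref`,
#'   `alt`, `label`
#' @param map a [replichore_map()]
#' @param length oligo length
#' @param threshold folding-energy threshold passed to [filter_oligos()]
#' @param temperature Celsius
#' @return data.frame with one row per edit: label, sequence, strand,
#'   edit_offset, fold_energy, passes_filter
#' @export
design_oligos <- function(genome, edits, map, length = 60, threshold = -16,
                          temperature = 30) {
  if (anyDuplicated(edits$label)) stop("edit labels must be unique")
  designs <- lapply(seq_len(nrow(edits)), function(i) {
    e <- edit_spec(edits$genome_id[i], edits$position[i], edits$ref[i],
                   edits$alt[i], edits$label[i])
    design_oligo(genome, e, map, length = length, temperature = temperature)
  })
  designs <- filter_oligos(designs, threshold)
  data.frame(label = vapply(designs, `[[`, character(1), "label"),
             sequence = vapply(designs, `[[`, character(1), "sequence"),
             strand = vapply(designs, `[[`, character(1), "strand"),
             edit_offset = vapply(designs, `[[`, integer(1), "edit_offset"),
             fold_energy = vapply(designs, `[[`, numeric(1), "fold_energy"),
             passes_filter = vapply(designs, `[[`, logical(1), "passes_filter"),
             stringsAsFactors = FALSE)
}
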