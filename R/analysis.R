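# Demultiplexing, read-to-gene assignment, abundance tables and
# active-variant calling.

#' Partition reads by barcode
#'
#' Reads labelled with a `barcode_index` (the simulator's output) are
#' split directly.  When a barcode table with reference sequences is
#' supplied (`barcode_id`, `barcode_seq`) together with observed barcode
#' sequences in `reads$barcode_seq`, reads are matched to the closest
#' barcode by edit distance with at most `max_edits` edits; ties and
#' distant barcodes go to the `"unclassified"` bin.
#'
#' @param reads data.frame of reads
#' @param barcode_table optional data.frame (`barcode_id`, `barcode_seq`)
#' @param max_edits maximum edit distance for a sequence-barcode match
#' @return named list of read data.frames, one per barcode (plus
#'   `unclassified` when sequence matching is used)
#' @export
demultiplex <- function(reads, barcode_table = NULL, max_edits = 3) {
  if (is.null(barcode_table)) {
    if (!"barcode_index" %in% names(reads))
      stop("reads carry no barcode_index and no barcode table was given")
    return(split(reads, reads$barcode_index))
  }
  if (anyDuplicated(barcode_table$barcode_id))
    stop("duplicate barcode ids")
  if (nrow(barcode_table) < 1) stop("empty barcode table")
  d <- utils::adist(reads$barcode_seq, barcode_table$barcode_seq)
  best <- apply(d, 1, which.min)
  bestd <- d[cbind(seq_len(nrow(d)), best)]
  tied <- rowSums(d == bestd) > 1
  bin <- ifelse(bestd <= max_edits & !tied,
                barcode_table$barcode_id[best], "unclassified")
  split(reads, bin)
}

#' Assign reads to reference genes
#'
#' Each read is screened against every reference by shared
#' (k, w)-minimizer count; the top two references are rescored by banded
#' local alignment around the minimizer diagonal whenever the runner-up
#' shares any minimizer, and the read is assigned to the best reference
#' unless the relative score margin `(best - second)/best` falls below
#' `min_margin` (unassigned).  Reads sharing no minimizer with any
#' reference are unassigned.  Deterministic.
#'
#' @param sequences character vector of read sequences
#' @param references named character vector of reference genes
#' @param min_margin relative margin below which a read is unassigned
#' @param k,w minimizer k-mer and window sizes
#' @param band banded-alignment half-width
#' @param match,mismatch,gap banded-alignment scores
#' @return list with `assigned` (character vector, `NA` = unassigned),
#'   `counts` (named per-reference counts) and `unassigned` (count)
#' @export
assign_reads <- function(sequences, references, min_margin = 0.1, k = 15,
                         w = 10, band = 40, match = 2, mismatch = -3,
                         gap = -3) {
  if (length(references) == 0) stop("empty reference set")
  if (is.null(names(references))) stop("references must be named")
  res <- cpp_assign_reads(as.character(sequences),
                          as.character(references), as.integer(k),
                          as.integer(w), min_margin, as.integer(band),
                          match, mismatch, gap)
  assigned <- ifelse(res$assignment == 0, NA_character_,
                     names(references)[res$assignment])
  counts <- table(factor(assigned, levels = names(references)))
  list(assigned = assigned,
       counts = setNames(as.integer(counts), names(references)),
       unassigned = sum(is.na(assigned)))
}

#' Build a variant-by-barcode abundance table
#'
#' Counts reads per reference per barcode and column-normalizes to
#' percentages over assigned reads (unassigned reads are tallied but
#' excluded from the denominator).  Columns with no assigned reads stay
#' all-zero and are flagged.
#'
#' @param reads data.frame with `barcode_index` and `sequence`
#' @param references named character vector of reference genes
#' @param n_barcodes table width (defaults to the largest barcode seen)
#' @param ... passed to [assign_reads()]
#' @return object of class `abundance_table`: list with `counts` and
#'   `percentages` (variants x barcodes matrices), `unassigned`
#'   (per-barcode), `empty_barcodes`
#' @export
abundance_table <- function(reads, references, n_barcodes = NULL, ...) {
  if (is.null(n_barcodes)) n_barcodes <- max(reads$barcode_index)
  counts <- matrix(0L, length(references), n_barcodes,
                   dimnames = list(names(references),
                                   paste0("barcode", seq_len(n_barcodes))))
  unassigned <- integer(n_barcodes)
  for (b in seq_len(n_barcodes)) {
    sub <- reads[reads$barcode_index == b, , drop = FALSE]
    if (nrow(sub) == 0) next
    a <- assign_reads(sub$sequence, references, ...)
    counts[, b] <- a$counts
    unassigned[b] <- a$unassigned
  }
  totals <- colSums(counts)
  percentages <- counts
  for (b in seq_len(n_barcodes)) {
    percentages[, b] <- if (totals[b] > 0) 100 * counts[, b] / totals[b] else 0
  }
  structure(list(counts = counts, percentages = percentages,
                 unassigned = unassigned,
                 empty_barcodes = which(totals == 0)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d variants x %d barcodes (%d unassigned reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$unassigned)))
  invisible(x)
}

#' Call active variants from an abundance table
#'
#' A variant is active when it persists through the screen: its read
#' percentage reaches `min_fraction * 100` in every selective barcode
#' from the first selection through `persistence_barcode`, and it is
#' present (any reads) in the pre-selection and retransformation barcodes
#' up to that point.  Otherwise the first barcode whose gate fails is
#' recorded as the dropout point.
#'
#' @param table an [abundance_table()]
#' @param persistence_barcode last barcode a variant must persist through
#' @param min_fraction minimum read fraction in selective barcodes
#' @param pre_barcodes indices of pre-selection samples (presence-gated)
#' @param retransform_barcodes indices of retransformation samples
#'   (presence-gated)
#' @return data.frame with `variant_id`, `active`,
#'   `first_dropout_barcode` (`NA` when active),
#'   `min_fraction_observed` (over the thresholded barcodes)
#' @export
call_active <- function(table, persistence_barcode = 9,
                        min_fraction = 0.001, pre_barcodes = 1:2,
                        retransform_barcodes = 7) {
  stopifnot(inherits(table, "abundance_table"))
  nb <- ncol(table$percentages)
  if (persistence_barcode > nb)
    stop("persistence barcode ", persistence_barcode,
         " beyond table width ", nb)
  gated <- seq_len(persistence_barcode)
  presence_only <- intersect(gated, c(pre_barcodes, retransform_barcodes))
  thresholded <- setdiff(gated, presence_only)
  out <- lapply(rownames(table$percentages), function(v) {
    pct <- table$percentages[v, ]
    ok <- vapply(gated, function(b) {
      if (b %in% presence_only) pct[b] > 0
      else pct[b] >= min_fraction * 100
    }, logical(1))
    first_fail <- if (all(ok)) NA_integer_ else gated[which.min(ok)]
    mfo <- if (length(thresholded)) min(pct[thresholded]) / 100 else NA_real_
    data.frame(variant_id = v, active = all(ok),
               first_dropout_barcode = first_fail,
               min_fraction_observed = mfo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative abundance change between consecutive barcodes
#'
#' Ratio of read percentages between each pair of consecutive barcodes
#' (covering the round-boundary comparisons); 0/0 yields `NA` (undefined),
#' never a division error.
#'
#' @param table an [abundance_table()]
#' @return matrix, variants x (barcode transitions), columns named
#'   `"b2/b1"` etc.
#' @export
enrichment_change <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  p <- table$percentages
  if (ncol(p) < 2) stop("need at least two barcodes")
  out <- matrix(NA_real_, nrow(p), ncol(p) - 1,
                dimnames = list(rownames(p),
                                paste0("b", 2:ncol(p), "/b", 1:(ncol(p) - 1))))
  for (b in seq_len(ncol(p) - 1)) {
    num <- p[, b + 1]; den <- p[, b]
    r <- ifelse(den == 0 & num == 0, NA_real_,
                ifelse(den == 0, Inf, num / den))
    out[, b] <- r
  }
  out
}

#' Write idxstats-style per-barcode count tables
#'
#' One 4-column TSV per barcode in samtools-idxstats layout: reference
#' name, reference length, assigned reads, 0; a final `*` row carries the
#' unassigned count.
#'
#' @param table an [abundance_table()]
#' @param references named character vector (for reference lengths)
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_idxstats <- function(table, references, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (b in seq_len(ncol(table$counts))) {
    df <- data.frame(ref_name = rownames(table$counts),
                     ref_length = nchar(references[rownames(table$counts)]),
                     assigned = table$counts[, b], other = 0L)
    df <- rbind(df, data.frame(ref_name = "*", ref_length = 0,
                               assigned = 0L,
                               other = table$unassigned[b]))
    path <- file.path(dir, sprintf("barcode%02d.idxstats.tsv", b))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
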