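# Barcoded noisy long-read emission and FASTQ round-trip.

#' Generate barcoded noisy reads for every sample point
#'
#' For each logged sample point, read counts per variant are multinomial
#' in the sample frequencies; each read is a uniformly placed fragment
#' (at least `min_fragment` nt, or the full gene when shorter) of its
#' variant's gene copied with i.i.d. errors split
#' substitution/insertion/deletion = 40/30/30 of `error_rate`.  Reads are
#' emitted on the forward strand.  The true variant is kept as a hidden
#' evaluation label (FASTQ header comment on write).
#'
#' @param state a [run_screen()] result with a populated sample log
#' @param genes named character vector of variant gene sequences (names
#'   match the state's variant ids)
#' @param depth reads per sample point
#' @param error_rate total per-base error rate in \[0, 0.3\]
#' @param seed RNG seed
#' @param min_fragment minimum fragment length in nt
#' @return data.frame with `read_id`, `barcode_index`, `sequence`,
#'   `true_variant`
#' @export
generate_reads <- function(state, genes, depth = 4000, error_rate = 0.08,
                           seed = 1, min_fragment = 200) {
  stopifnot(inherits(state, "screen_state"), error_rate >= 0,
            error_rate <= 0.3)
  if (depth < 1) {
    warning("depth 0: emitting no reads")
    return(data.frame(read_id = character(0), barcode_index = integer(0),
                      sequence = character(0), true_variant = character(0),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(state$variant_ids, names(genes))
  if (length(missing))
    stop("no gene sequence for variant(s): ", paste(missing, collapse = ", "))
  genes <- unname(genes[state$variant_ids])
  set.seed(seed)
  out <- vector("list", length(state$sample_log))
  for (b in seq_along(state$sample_log)) {
    freq <- state$sample_log[[b]]$frequencies
    counts <- as.integer(rmultinom(1, depth, freq))
    idx <- rep(seq_along(freq), counts)
    if (length(idx) == 0) next
    idx <- sample(idx) # interleave variants within the file
    seqs <- cpp_mutate_fragments(genes, idx, as.integer(min_fragment),
                                 error_rate, 0.4, 0.3, 0.3)
    out[[b]] <- data.frame(
      read_id = sprintf("bc%02d_read%06d", b, seq_along(idx)),
      barcode_index = b, sequence = seqs,
      true_variant = state$variant_ids[idx],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write reads to per-barcode FASTQ files
#'
#' One `barcodeNN.fastq` per barcode; the header comment field carries
#' `barcode=` and `true_variant=` tags.  Constant Q10 qualities.
#'
#' @param reads a [generate_reads()] data.frame
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (b in sort(unique(reads$barcode_index))) {
    sub <- reads[reads$barcode_index == b, , drop = FALSE]
    path <- file.path(dir, sprintf("barcode%02d.fastq", b))
    qual <- vapply(nchar(sub$sequence),
                   function(n) strrep("+", n), character(1))
    recs <- rbind(sprintf("@%s barcode=%d true_variant=%s", sub$read_id, b,
                          sub$true_variant),
                  sub$sequence, "+", qual)
    writeLines(as.vector(recs), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-barcode FASTQ files written by [write_fastq()]
#'
#' Strict 4-line-record parser; recovers the barcode and hidden truth
#' label from the header comment.
#'
#' @param dir directory of `barcodeNN.fastq` files
#' @return data.frame as produced by [generate_reads()]
#' @export
read_fastq_dir <- function(dir) {
  files <- list.files(dir, pattern = "^barcode[0-9]+\\.fastq$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no barcode FASTQ files in ", dir)
  out <- lapply(files, function(f) {
    lines <- readLines(f)
    if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", f)
    heads <- lines[seq(1, length(lines), by = 4)]
    seqs <- lines[seq(2, length(lines), by = 4)]
    read_id <- sub("^@(\\S+).*$", "\\1", heads)
    bc <- as.integer(sub(".*barcode=([0-9]+).*", "\\1", heads))
    tv <- sub(".*true_variant=(\\S+).*", "\\1", heads)
    tv[!grepl("true_variant=", heads)] <- NA_character_
    data.frame(read_id = read_id, barcode_index = bc, sequence = seqs,
               true_variant = tv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
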