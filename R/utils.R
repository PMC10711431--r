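# Shared small utilities: alphabets, encoders, FASTA/FASTQ/TSV I/O.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# profile alphabet: 20 amino acids + X (unknown, scores 0)
AA_ALPHABET <- c(AA20, "X")
DNA4 <- c("A", "C", "G", "T")

encode_aa <- function(x) {
  codes <- match(strsplit(toupper(x), "")[[1]], AA_ALPHABET)
  if (anyNA(codes)) {
    bad <- unique(strsplit(toupper(x), "")[[1]][is.na(codes)])
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  codes
}

decode_aa <- function(codes) {
  out <- rep("-", length(codes))
  out[codes > 0] <- AA_ALPHABET[codes[codes > 0]]
  paste(out, collapse = "")
}

encode_dna <- function(x) {
  codes <- match(strsplit(toupper(x), "")[[1]], DNA4)
  codes[is.na(codes)] <- 0L
  codes
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T (ambiguous bases are complemented
#'   to N).
#' @return character scalar
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file into a named character vector
#' @param path file path
#' @param type `"AA"` or `"DNA"`
#' @return named character vector of sequences
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  # keep only the first whitespace-delimited token as the id
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @param type `"AA"` or `"DNA"`
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# TSV with "# key=value" metadata comment headers
write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ssapkit %s",
                     as.character(utils::packageVersion("ssapkit"))), con)
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE)
}

# Derive a bounded per-stage seed from a global seed; keeps values < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(mine = 101L, design = 211L, simulate = 307L, reads = 401L,
               analyze = 503L, stats = 601L, calib = 701L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 2654435L + offsets[[stage]]) %% 2147483647L
}
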