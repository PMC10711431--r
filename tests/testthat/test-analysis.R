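# Demultiplexing, read assignment, abundance tables, active calling.

test_that("demultiplexing splits labelled reads and matches sequence barcodes", {
  reads <- data.frame(read_id = sprintf("r%d", 1:100),
                      barcode_index = rep(3L, 100),
                      sequence = strrep("ACGT", 10),
                      stringsAsFactors = FALSE)
  bins <- demultiplex(reads)
  expect_named(bins, "3")
  expect_equal(nrow(bins[["3"]]), 100)

  tab <- data.frame(barcode_id = c("bc1", "bc2"),
                    barcode_seq = c("AAAACCCC", "GGGGTTTT"),
                    stringsAsFactors = FALSE)
  reads2 <- data.frame(
    read_id = c("a", "b", "c"),
    barcode_seq = c("AAAACCCC",   # exact
                    "AAATCCCC",   # one substitution -> still bc1
                    "AAAATTTT"),  # equidistant to both -> unclassified
    sequence = "ACGT", stringsAsFactors = FALSE)
  bins2 <- demultiplex(reads2, tab)
  expect_setequal(bins2[["bc1"]]$read_id, c("a", "b"))
  expect_equal(bins2[["unclassified"]]$read_id, "c")
  expect_error(demultiplex(reads2, rbind(tab, tab)), "duplicate")
})

test_that("read assignment is exact on clean reads and conserves counts", {
  set.seed(61)
  genes <- synth_variant_genes(n = 3, length = 500, identity = 0.7,
                               seed = 61)
  p <- variant_params(names(genes), arf = 0.01)
  st <- ssapkit:::snapshot(init_pool(p, seed = 62))
  reads <- generate_reads(st, genes, depth = 300, error_rate = 0, seed = 63)
  a <- assign_reads(reads$sequence, genes)
  expect_equal(a$unassigned, 0)
  expect_true(all(a$assigned == reads$true_variant))
  # conservation: assigned + unassigned = input reads
  expect_equal(sum(a$counts) + a$unassigned, nrow(reads))

  # an unrelated random read is unassigned
  r <- assign_reads(ssapkit:::random_dna(400), genes)
  expect_true(is.na(r$assigned))
  expect_equal(r$unassigned, 1)
})

test_that("assignment stays >= 99% correct at 5% read error", {
  genes <- synth_variant_genes(n = 20, seed = 64)
  p <- synth_variant_params(names(genes), seed = 65)
  st <- run_screen(p, screen_schedule(), seed = 66)
  reads <- generate_reads(st, genes, depth = 1000, error_rate = 0.05,
                          seed = 67)
  a <- assign_reads(reads$sequence, genes)
  acc <- mean(a$assigned == reads$true_variant, na.rm = TRUE)
  expect_gte(acc, 0.99)
  expect_lte(a$unassigned / nrow(reads), 0.01)
})

test_that("assignment argmax agrees with a full Smith-Waterman oracle", {
  set.seed(68)
  genes <- synth_variant_genes(n = 5, length = 500, identity = 0.7,
                               seed = 68)
  p <- variant_params(names(genes), arf = 0.01)
  st <- ssapkit:::snapshot(init_pool(p, seed = 69))
  reads <- generate_reads(st, genes, depth = 200, error_rate = 0.08,
                          seed = 70)
  a <- assign_reads(reads$sequence, genes)

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  refs <- Biostrings::DNAStringSet(genes)
  scores <- vapply(seq_along(genes), function(g) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads$sequence), refs[[g]],
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 3,
      type = "local", scoreOnly = TRUE)
  }, numeric(nrow(reads)))
  oracle_best <- names(genes)[apply(scores, 1, which.max)]
  agree <- mean(a$assigned == oracle_best, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("abundance tables normalize per barcode and flag empty columns", {
  genes <- synth_variant_genes(n = 2, length = 400, identity = 0.7,
                               seed = 71)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:100),
    barcode_index = rep(1L, 100),
    sequence = c(rep(substr(genes[[1]], 1, 300), 50),
                 rep(substr(genes[[2]], 1, 300), 50)),
    stringsAsFactors = FALSE)
  tab <- abundance_table(reads, genes, n_barcodes = 2)
  expect_equal(unname(tab$percentages[, 1]), c(50, 50))
  expect_equal(sum(tab$percentages[, 1]), 100, tolerance = 1e-6)
  # barcode 2 has no reads: all-zero column, flagged
  expect_true(all(tab$percentages[, 2] == 0))
  expect_equal(unname(tab$empty_barcodes), 2L)
  expect_equal(sum(tab$counts[, 1]) + tab$unassigned[1], 100)
})

test_that("active calling gates presence and persistence", {
  mk_table <- function(pct) {
    counts <- round(pct * 10)
    structure(list(counts = counts, percentages = pct,
                   unassigned = integer(ncol(pct)),
                   empty_barcodes = integer(0)),
              class = "abundance_table")
  }
  pct <- matrix(0, 2, 11,
                dimnames = list(c("steady", "early_out"),
                                paste0("barcode", 1:11)))
  pct["steady", ] <- c(5, 5, 5, 5, 5, 5, 5, 5, 5, 0, 0) # gone after 9: fine
  pct["early_out", ] <- c(5, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  calls <- call_active(mk_table(pct))
  expect_true(calls$active[calls$variant_id == "steady"])
  expect_false(calls$active[calls$variant_id == "early_out"])
  expect_equal(calls$first_dropout_barcode[calls$variant_id == "early_out"],
               3L)
  expect_error(call_active(mk_table(pct), persistence_barcode = 12),
               "beyond table width")
})

test_that("simulated screens recover the truly active set", {
  genes <- synth_variant_genes(n = 52, seed = 72)
  p <- synth_variant_params(names(genes), n_active = 5, seed = 73)
  st <- run_screen(p, screen_schedule(), seed = 74)
  reads <- generate_reads(st, genes, depth = 2000, error_rate = 0.08,
                          seed = 75)
  calls <- call_active(abundance_table(reads, genes))
  expect_setequal(calls$variant_id[calls$active],
                  p$variant_id[p$arf > 0])
})

test_that("enrichment changes are ratios with safe degenerate handling", {
  pct <- matrix(c(10, 10, 10,   # constant
                  1, 2, 4,      # doubling
                  0, 0, 0),     # absent
                nrow = 3, byrow = TRUE,
                dimnames = list(c("flat", "up", "gone"), paste0("b", 1:3)))
  tab <- structure(list(counts = pct, percentages = pct,
                        unassigned = integer(3),
                        empty_barcodes = integer(0)),
                   class = "abundance_table")
  ch <- enrichment_change(tab)
  expect_equal(unname(ch["flat", ]), c(1, 1))
  expect_equal(unname(ch["up", ]), c(2, 2))
  expect_true(all(is.na(ch["gone", ])))
})

test_that("idxstats files carry four columns and the unassigned row", {
  genes <- synth_variant_genes(n = 2, length = 300, seed = 76)
  reads <- data.frame(read_id = "r1", barcode_index = 1L,
                      sequence = substr(genes[[1]], 1, 250),
                      stringsAsFactors = FALSE)
  tab <- abundance_table(reads, genes)
  dir <- withr::local_tempdir()
  write_idxstats(tab, genes, dir)
  lines <- read.delim(file.path(dir, "barcode01.idxstats.tsv"),
                      header = FALSE)
  expect_equal(ncol(lines), 4)
  expect_equal(as.character(lines[nrow(lines), 1]), "*")
  expect_equal(sum(lines$V3), 1)
})
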