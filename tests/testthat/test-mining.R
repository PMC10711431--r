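# Iterative search, taxonomy filtering, clustering, prioritization.

test_that("iterative search recovers the seeds and respects the schedule", {
  seeds <- fixture_seeds()
  prof <- build_profile(build_msa(seeds))
  hits <- iterate_search(prof, seeds, seed = 31)
  expect_setequal(hits$seq_id, names(seeds))
  expect_true(all(hits$round_found == 1))

  # max_rounds = 1 equals a single thresholded scoring pass
  fam <- synth_homolog_db(seeds, n_planted = 15, n_decoys = 40, seed = 32)
  one <- iterate_search(prof, fam$db, e_threshold = 1e-3, max_rounds = 1,
                        seed = 33)
  cal <- calibrate_profile(
    build_profile(prof$aln_matrix[, prof$kept_columns, drop = FALSE],
                  pseudocount_weight = prof$pseudocount_weight),
    fam$db, seed = 33 + 1)
  ev <- vapply(fam$db, function(s) score_sequence(cal, s)$e_value,
               numeric(1))
  expect_setequal(one$seq_id, names(ev)[ev <= 1e-3])

  # the hit set grows monotonically: round-1 hits are a subset of the
  # full run's hits, at the same e-values
  full <- iterate_search(prof, fam$db, e_threshold = 1e-3, seed = 33)
  expect_true(all(one$seq_id %in% full$seq_id))
  r1 <- full[full$round_found == 1, ]
  expect_setequal(r1$seq_id, one$seq_id)
})

test_that("planted homologs are fully recovered with zero decoys", {
  seeds <- synth_seed_set(seed = 7)
  fam <- synth_homolog_db(seeds, seed = 8)
  prof <- build_profile(build_msa(seeds))
  hits <- iterate_search(prof, fam$db, taxonomy = fam$taxonomy,
                         e_threshold = 1e-3, max_rounds = 15, seed = 9)
  expect_setequal(intersect(hits$seq_id, fam$planted_ids), fam$planted_ids)
  expect_equal(sum(!hits$seq_id %in% fam$planted_ids), 0)
})

test_that("taxonomy filtering keeps genus species and phages", {
  hits <- data.frame(
    seq_id = c("h1", "h2", "h3", "h4"),
    bit_score = 1, e_value = 1e-5, round_found = 1L,
    taxonomy = c("Pseudomonas putida", "Escherichia coli",
                 "Pseudomonas phage X", NA),
    source = c("bacterium", "bacterium", "phage", "bacterium"),
    stringsAsFactors = FALSE)
  expect_warning(kept <- filter_taxonomy(hits, "Pseudomonas"),
                 "without taxonomy")
  expect_equal(kept$seq_id, c("h1", "h3"))
  empty <- hits[0, ]
  expect_equal(nrow(filter_taxonomy(empty, "Pseudomonas")), 0)
})

test_that("greedy clustering partitions and matches a brute-force oracle", {
  expect_equal(length(cluster_greedy(c(a = "MKVLAW", b = "MKVLAW"))$clusters),
               1)

  set.seed(41)
  seeds <- synth_seed_set(n = 4, seed = 41)
  fam <- synth_homolog_db(seeds, n_planted = 12, n_decoys = 0, seed = 42)
  seqs <- c(seeds, fam$db[fam$planted_ids])[1:16]
  cs <- cluster_greedy(seqs, identity_threshold = 0.7)

  # partition: members disjoint and exhaustive; representatives belong to
  # their own cluster; members reach the threshold to their representative
  all_members <- unlist(lapply(cs$clusters, `[[`, "member_ids"))
  expect_setequal(all_members, names(seqs))
  expect_equal(anyDuplicated(all_members), 0)
  for (cl in cs$clusters) {
    expect_true(cl$representative_id %in% cl$member_ids)
    for (mid in cl$member_ids)
      expect_gte(pairwise_identity(seqs[[cl$representative_id]],
                                   seqs[[mid]]), 0.7)
  }

  # brute-force greedy oracle using an independent identity computation
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0); assign <- character(length(seqs))
  names(assign) <- names(seqs)
  for (id in names(seqs)[ord]) {
    hit <- NA_character_
    for (r in reps)
      if (oracle_identity_bs(seqs[[r]], seqs[[id]]) >= 0.7) { hit <- r; break }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    assign[id] <- hit
  }
  got <- setNames(cs$table$representative_id, cs$table$member_id)
  expect_identical(as.list(got[names(assign)]), as.list(assign))
})

test_that("mutually dissimilar sequences stay singletons and near-identical pairs merge", {
  set.seed(43)
  randoms <- setNames(vapply(1:10, function(i)
    ssapkit:::random_protein(60), character(1)), sprintf("r%02d", 1:10))
  # verify the premise with the independent oracle, then the claim
  idents <- utils::combn(names(randoms), 2, function(p)
    oracle_identity_bs(randoms[[p[1]]], randoms[[p[2]]]))
  expect_true(all(idents < 0.7))
  expect_equal(length(cluster_greedy(randoms)$clusters), 10)

  base <- ssapkit:::random_protein(100)
  variant <- ssapkit:::mutate_protein(base, 0.8)
  decoy <- ssapkit:::random_protein(90)
  cs <- cluster_greedy(c(long = base, var = variant, decoy = decoy))
  expect_equal(length(cs$clusters), 2)
  expect_true("long" %in% vapply(cs$clusters, `[[`, character(1),
                                 "representative_id"))
})

test_that("prioritization keys on e-value then phage source", {
  clusters <- structure(list(
    clusters = list(list(representative_id = "A", member_ids = c("A", "B")),
                    list(representative_id = "C", member_ids = c("C", "D"))),
    identity_threshold = 0.7,
    table = NULL), class = "cluster_set")
  hits <- data.frame(
    seq_id = c("A", "B", "C", "D"),
    e_value = c(1e-30, 1e-10, 1e-20, 1e-20),
    source = c("bacterium", "phage", "bacterium", "phage"),
    stringsAsFactors = FALSE)
  out <- prioritize_candidates(clusters, hits)
  expect_equal(out$candidate_id, c("A", "D")) # e-value first, then phage
  expect_equal(out$cluster_id, 1:2)

  # one candidate per cluster, 48 clusters in, 48 candidates out
  many <- structure(list(
    clusters = lapply(1:48, function(i)
      list(representative_id = paste0("s", i),
           member_ids = paste0("s", i))),
    identity_threshold = 0.7, table = NULL), class = "cluster_set")
  mh <- data.frame(seq_id = paste0("s", 1:48), e_value = 1e-6,
                   source = "bacterium", stringsAsFactors = FALSE)
  expect_equal(nrow(prioritize_candidates(many, mh)), 48)

  # unscored cluster is an explicit error naming the cluster
  bad <- structure(list(
    clusters = list(list(representative_id = "Z", member_ids = "Z")),
    identity_threshold = 0.7, table = NULL), class = "cluster_set")
  expect_error(prioritize_candidates(bad, hits), "cluster 1")
})
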