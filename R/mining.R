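# Iterative profile search, taxonomy filtering, clustering, prioritization.

#' Iterative profile search of a protein database
#'
#' jackhmmer-style search-refine-repeat loop around a PSSM: each round the
#' current profile is calibrated on shuffled decoys, every database
#' sequence is scored, sequences at or below the E-value threshold become
#' hits, and new hits are aligned back onto the profile columns and
#' absorbed into a rebuilt profile.  Stops when a round adds no hits or
#' after `max_rounds`.  The hit set is non-decreasing across rounds and
#' every hit records the round in which it was first found.
#'
#' @param profile profile built from the seed alignment
#'   ([build_profile()]); its source alignment seeds the refinement
#' @param database named character vector of protein sequences
#' @param taxonomy optional data.frame with columns `seq_id`, `taxonomy`,
#'   `source` (one of bacterium/phage/other) merged onto the hits
#' @param e_threshold E-value inclusion threshold
#' @param max_rounds maximum number of search rounds
#' @param n_decoys decoys per calibration round
#' @param seed RNG seed for decoy shuffles
#' @return data.frame with columns `seq_id`, `bit_score`, `e_value`,
#'   `round_found`, `taxonomy`, `source`
#' @export
iterate_search <- function(profile, database, taxonomy = NULL,
                           e_threshold = 1e-3, max_rounds = 15,
                           n_decoys = 200, seed = 1) {
  stopifnot(inherits(profile, "ssap_profile"))
  if (length(database) == 0) stop("empty database")
  if (is.null(names(database)) || anyDuplicated(names(database)))
    stop("database sequences must carry unique names")
  stopifnot(e_threshold > 0, max_rounds >= 1)

  # fix the column coordinate system to the seed profile's kept columns
  m_work <- profile$aln_matrix[, profile$kept_columns, drop = FALSE]
  hits <- data.frame(seq_id = character(0), bit_score = numeric(0),
                     e_value = numeric(0), round_found = integer(0),
                     stringsAsFactors = FALSE)

  for (round in seq_len(max_rounds)) {
    prof <- build_profile(m_work,
                          pseudocount_weight = profile$pseudocount_weight,
                          background = profile$background,
                          gap_open = profile$gap_open,
                          gap_extend = profile$gap_extend)
    prof <- calibrate_profile(prof, database, n_decoys = n_decoys,
                              seed = seed + round)
    todo <- setdiff(names(database), hits$seq_id)
    if (length(todo) == 0) break
    res <- lapply(database[todo], function(s) score_sequence(prof, s))
    ev <- vapply(res, `[[`, numeric(1), "e_value")
    bs <- vapply(res, `[[`, numeric(1), "bit_score")
    new_ids <- todo[ev <= e_threshold]
    if (length(new_ids) == 0) break
    hits <- rbind(hits, data.frame(seq_id = new_ids,
                                   bit_score = unname(bs[new_ids]),
                                   e_value = unname(ev[new_ids]),
                                   round_found = round,
                                   stringsAsFactors = FALSE))
    if (round == max_rounds) break
    # absorb new hits into the working alignment
    for (id in new_ids) {
      row_full <- rep("-", ncol(m_work))
      row_full[prof$kept_columns] <- profile_align_row(prof, database[[id]])
      m_work <- rbind(m_work, row_full)
    }
  }
  rownames(hits) <- NULL
  if (!is.null(taxonomy)) {
    idx <- match(hits$seq_id, taxonomy$seq_id)
    hits$taxonomy <- taxonomy$taxonomy[idx]
    hits$source <- taxonomy$source[idx]
  } else {
    hits$taxonomy <- NA_character_
    hits$source <- NA_character_
  }
  hits
}

#' Filter homolog hits to a genus
#'
#' Keeps hits whose taxonomy string contains the genus (covers both genus
#' species and phages named after the genus, e.g. "Pseudomonas phage X").
#' Hits lacking a taxonomy label are dropped with a warning.  Input order
#' is preserved.
#'
#' @param hits data.frame from [iterate_search()]
#' @param genus genus name, e.g. `"Pseudomonas"`
#' @return filtered data.frame
#' @export
filter_taxonomy <- function(hits, genus) {
  if (nrow(hits) == 0) return(hits)
  missing_tax <- is.na(hits$taxonomy) | !nzchar(hits$taxonomy)
  if (any(missing_tax))
    warning(sum(missing_tax), " hit(s) without taxonomy excluded")
  # genus species and phages of the genus both carry the genus in their
  # taxonomy string ("Pseudomonas putida", "Pseudomonas phage X")
  keep <- !missing_tax & grepl(genus, hits$taxonomy, fixed = TRUE)
  hits[keep, , drop = FALSE]
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted longest-first (ties
#' broken by id) and each joins the first existing cluster whose
#' representative it matches at or above the identity threshold
#' ([pairwise_identity()]); otherwise it founds a new cluster.
#'
#' @param sequences named character vector of protein sequences
#' @param identity_threshold scalar in (0, 1]
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   `representative_id`, `member_ids`), `identity_threshold` and a long
#'   `table` (cluster_id, representative_id, member_id, identity_to_rep)
#' @export
cluster_greedy <- function(sequences, identity_threshold = 0.7) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  ord <- order(-nchar(sequences), names(sequences))
  submat <- blosum62_matrix()

  reps <- character(0)
  members <- list()
  idents <- list()
  for (id in names(sequences)[ord]) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      idt <- pairwise_identity(sequences[[reps[ci]]], sequences[[id]],
                               submat = submat)
      if (idt >= identity_threshold) {
        members[[ci]] <- c(members[[ci]], id)
        idents[[ci]] <- c(idents[[ci]], idt)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
      idents[[length(reps)]] <- 1.0
    }
  }
  tab <- do.call(rbind, lapply(seq_along(reps), function(ci) {
    data.frame(cluster_id = ci, representative_id = reps[ci],
               member_id = members[[ci]],
               identity_to_rep = idents[[ci]],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(clusters = lapply(seq_along(reps), function(ci)
                   list(representative_id = reps[ci],
                        member_ids = members[[ci]])),
                 identity_threshold = identity_threshold,
                 table = tab),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d sequences (identity >= %g)\n",
              length(x$clusters), nrow(x$table), x$identity_threshold))
  invisible(x)
}

#' Pick one candidate per cluster
#'
#' Within each cluster, selects the member with the smallest E-value; ties
#' favour a phage source, then the lexicographically smallest id.  Output
#' is ordered by cluster index.
#'
#' @param clusters a [cluster_greedy()] result
#' @param hits hit table carrying `seq_id`, `e_value`, `source`
#' @return data.frame with `cluster_id`, `candidate_id`, `e_value`,
#'   `source`
#' @export
prioritize_candidates <- function(clusters, hits) {
  stopifnot(inherits(clusters, "cluster_set"))
  out <- lapply(seq_along(clusters$clusters), function(ci) {
    ids <- clusters$clusters[[ci]]$member_ids
    sub <- hits[hits$seq_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("cluster ", ci, " has no scored member")
    phage_rank <- ifelse(!is.na(sub$source) & sub$source == "phage", 0L, 1L)
    best <- sub[order(sub$e_value, phage_rank, sub$seq_id), , drop = FALSE][1, ]
    data.frame(cluster_id = ci, candidate_id = best$seq_id,
               e_value = best$e_value, source = best$source,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Shared C-terminal suffix length between sequence pairs
#'
#' For every pair of sequences, the length of the longest common
#' C-terminal suffix and whether it reaches `k` (SSB C-terminus
#' conservation check; e.g. the nine-residue DSFDDDIPF tail shared by
#' Pseudomonas SSBs).  Sequences shorter than `k` are compared over their
#' full length with a warning.
#'
#' @param sequences named character vector of protein sequences
#' @param k minimum shared suffix length of interest
#' @return data.frame with `id_a`, `id_b`, `shared_suffix`, `meets_k`
#' @export
cterm_motif_share <- function(sequences, k) {
  stopifnot(k >= 1, length(sequences) >= 2)
  if (any(nchar(sequences) < k))
    warning("sequence(s) shorter than k compared over their full length")
  ids <- names(sequences)
  pairs <- utils::combn(seq_along(ids), 2)
  shared <- apply(pairs, 2, function(p) {
    a <- rev(strsplit(sequences[[p[1]]], "")[[1]])
    b <- rev(strsplit(sequences[[p[2]]], "")[[1]])
    n <- min(length(a), length(b))
    same <- a[seq_len(n)] == b[seq_len(n)]
    if (all(same)) n else which.min(same) - 1L
  })
  # short sequences are judged over their full length
  thr <- pmin(k, pmin(nchar(sequences[ids[pairs[1, ]]]),
                      nchar(sequences[ids[pairs[2, ]]])))
  data.frame(id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
             shared_suffix = as.integer(shared),
             meets_k = shared >= thr,
             stringsAsFactors = FALSE)
}
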