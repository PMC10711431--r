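# End-to-end driver: mine -> design -> simulate -> analyze -> stats on
# synthetic inputs, with a run manifest.

#' Run the full synthetic screen pipeline
#'
#' Executes the whole discovery arc on synthetic data: profile-based
#' homolog mining with clustering and prioritization; recombineering
#' oligo design; stochastic simulation of the pooled enrichment screen
#' with barcoded noisy reads; abundance analysis with active-variant
#' calls; and ARF/off-target statistics.  Every output TSV carries a
#' metadata header (seed, parameters) and a manifest lists all artifacts
#' with MD5 hashes.  One global seed fans out to per-stage seeds so
#' stages are independently re-runnable.
#'
#' @param config a `pipeline_config` (default [default_config()])
#' @param outdir output directory
#' @param seed global seed
#' @return invisibly, a list with the stage results and the manifest path
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = 1) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  meta <- function(extra = list())
    c(list(seed = seed), extra)

  ## 1. mine ---------------------------------------------------------------
  mine <- stage("mine", {
    s_seed <- derive_seed(seed, "mine")
    seeds <- synth_seed_set(seed = s_seed)
    fam <- synth_homolog_db(seeds, n_planted = config$n_planted,
                            n_decoys = config$n_decoys,
                            genus = config$genus, seed = s_seed + 1L)
    msa <- build_msa(seeds)
    prof <- build_profile(msa, pseudocount_weight = config$pseudocount_weight)
    hits <- iterate_search(prof, fam$db, taxonomy = fam$taxonomy,
                           e_threshold = config$e_threshold,
                           max_rounds = config$rounds, seed = s_seed + 2L)
    genus_hits <- filter_taxonomy(hits, config$genus)
    clusters <- cluster_greedy(fam$db[genus_hits$seq_id],
                               identity_threshold = config$identity_threshold)
    candidates <- prioritize_candidates(clusters, genus_hits)
    write_tsv_meta(hits, file.path(outdir, "hits.tsv"),
                   meta(list(e_threshold = config$e_threshold,
                             rounds = config$rounds)))
    write_tsv_meta(clusters$table, file.path(outdir, "clusters.tsv"),
                   meta(list(identity_threshold = config$identity_threshold)))
    write_tsv_meta(candidates, file.path(outdir, "candidates.tsv"), meta())
    list(seeds = seeds, family = fam, hits = hits, clusters = clusters,
         candidates = candidates)
  })

  ## 2. design -------------------------------------------------------------
  design <- stage("design", {
    d_seed <- derive_seed(seed, "design")
    ge <- synth_genome_edits(seed = d_seed)
    oligos <- design_oligos(ge$genome, ge$edits, ge$map,
                            length = config$oligo_length,
                            threshold = config$dg_min,
                            temperature = config$fold_temperature)
    write_tsv_meta(oligos, file.path(outdir, "oligos.tsv"),
                   meta(list(length = config$oligo_length,
                             dg_min = config$dg_min,
                             dg_note = "printed magnitude 16 kcal/mol read as a floor on non-positive folding energies")))
    list(genome = ge, oligos = oligos)
  })

  ## 3. simulate -----------------------------------------------------------
  sim <- stage("simulate", {
    m_seed <- derive_seed(seed, "simulate")
    genes <- synth_variant_genes(n = config$n_variants,
                                 length = config$gene_length, seed = m_seed)
    params <- synth_variant_params(names(genes), n_active = config$n_active,
                                   seed = m_seed + 1L)
    schedule <- config_schedule(config)
    state <- run_screen(params, schedule, seed = m_seed + 2L)
    reads <- generate_reads(state, genes, depth = config$depth,
                            error_rate = config$error_rate,
                            seed = derive_seed(seed, "reads"))
    fastq_dir <- file.path(outdir, "reads")
    write_fastq(reads, fastq_dir)
    truth <- do.call(rbind, lapply(state$sample_log, function(s)
      data.frame(barcode = s$barcode_index,
                 variant = names(s$frequencies),
                 true_frequency = unname(s$frequencies),
                 stringsAsFactors = FALSE)))
    write_tsv_meta(truth, file.path(outdir, "truth.tsv"), meta())
    write_tsv_meta(params, file.path(outdir, "variant_params.tsv"), meta())
    write_fasta(genes, file.path(outdir, "variant_genes.fasta"), "DNA")
    cfu <- generate_assay_fixtures(config$arf_true,
                                   n_replicates = config$n_replicates,
                                   total_cfu = config$total_cfu,
                                   seed = m_seed + 3L)
    write_tsv_meta(cfu, file.path(outdir, "cfu.tsv"),
                   meta(list(arf_true = config$arf_true)))
    parental <- data.frame(position = c(1201L, 5410L, 9902L),
                           ref = c("A", "G", "C"), alt = c("G", "A", "T"),
                           stringsAsFactors = FALSE)
    muts <- generate_mutation_fixtures(parental, n_colonies = 2,
                                       seed = m_seed + 4L)
    write_tsv_meta(muts$colonies, file.path(outdir, "mutations.tsv"), meta())
    write_tsv_meta(parental, file.path(outdir, "parental_mutations.tsv"),
                   meta())
    list(genes = genes, params = params, schedule = schedule, state = state,
         reads = reads, cfu = cfu, mutations = muts)
  })

  ## 4. analyze ------------------------------------------------------------
  analysis <- stage("analyze", {
    tab <- abundance_table(sim$reads, sim$genes,
                           min_margin = config$min_margin)
    calls <- call_active(tab,
                         persistence_barcode = config$persistence_barcode,
                         min_fraction = config$min_fraction)
    counts_df <- data.frame(variant_id = rownames(tab$counts), tab$counts,
                            stringsAsFactors = FALSE, check.names = FALSE)
    pct_df <- data.frame(variant_id = rownames(tab$percentages),
                         round(tab$percentages, 4),
                         stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv_meta(counts_df, file.path(outdir, "abundance_counts.tsv"),
                   meta())
    write_tsv_meta(pct_df, file.path(outdir, "abundance_percent.tsv"),
                   meta(list(denominator = "assigned reads only")))
    write_tsv_meta(calls, file.path(outdir, "active_calls.tsv"),
                   meta(list(persistence_barcode = config$persistence_barcode,
                             min_fraction = config$min_fraction)))
    write_idxstats(tab, sim$genes, file.path(outdir, "idxstats"))
    list(table = tab, calls = calls)
  })

  ## 5. stats --------------------------------------------------------------
  stats_out <- stage("stats", {
    cfu <- sim$cfu
    cfu$strain_id <- "strainA"; cfu$locus <- "rpsL"
    summary <- arf_summary(cfu)
    offt <- offtarget_summary(sim$mutations$colonies,
                              sim$mutations$parental)
    write_tsv_meta(summary, file.path(outdir, "arf_summary.tsv"), meta())
    write_tsv_meta(data.frame(n = offt$n, mean = offt$mean, sd = offt$sd,
                              label = offt$label),
                   file.path(outdir, "offtarget_summary.tsv"), meta())
    list(arf = summary, offtarget = offt)
  })

  ## manifest --------------------------------------------------------------
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(mine = mine, design = design, sim = sim,
                 analysis = analysis, stats = stats_out,
                 manifest = file.path(outdir, "manifest.tsv")))
}
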