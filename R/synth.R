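# Synthetic-data generators standing in for the study's wet-lab and
# UniProtKB inputs: protein families with planted homologs among decoys,
# variant gene sets, genomes, CFU plating counts and per-colony mutation
# tables.

random_protein <- function(len, background = aa_background()) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(DNA4, len, replace = TRUE), collapse = "")
}

# Point-mutate a protein to approximately the requested identity.
mutate_protein <- function(seq, identity, background = aa_background()) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(length(chars) * (1 - identity))
  pos <- sample(length(chars), n_mut)
  chars[pos] <- sample(names(background), n_mut, replace = TRUE,
                       prob = background)
  paste(chars, collapse = "")
}

mutate_dna <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(length(chars) * (1 - identity))
  pos <- sample(length(chars), n_mut)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(DNA4, b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

#' Synthesize a curated seed set of SSAP-like proteins
#'
#' Seven synthetic proteins descended from a common ancestor at moderate
#' identity, mimicking a manually curated cross-superfamily seed list.
#'
#' @param n number of seeds
#' @param length ancestor length in residues
#' @param identity seed-to-ancestor identity
#' @param seed RNG seed
#' @return named character vector
#' @export
synth_seed_set <- function(n = 7, length = 220, identity = 0.6, seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  ancestor <- random_protein(length)
  seeds <- vapply(seq_len(n), function(i) mutate_protein(ancestor, identity),
                  character(1))
  names(seeds) <- sprintf("seed%02d", seq_len(n))
  seeds
}

#' Synthesize a homolog database with planted family members among decoys
#'
#' Planted members are drawn from the seeds' ancestor lineage at
#' 40-70 percent identity to a random seed; decoys are residue-shuffled
#' copies of planted members (same composition, no homology).  Taxonomy
#' labels place most planted members in the target genus (species or
#' phage) and decoys in other genera.
#'
#' @param seeds a [synth_seed_set()] result
#' @param n_planted,n_decoys family members and decoys
#' @param identity_range identity of planted members to their seed
#' @param genus genus used for the taxonomy labels
#' @param p_phage fraction of genus-planted members labelled as phages
#' @param seed RNG seed
#' @return list with `db` (named character vector), `taxonomy`
#'   (data.frame: seq_id, taxonomy, source) and `planted_ids`
#' @export
synth_homolog_db <- function(seeds, n_planted = 50, n_decoys = 200,
                             identity_range = c(0.4, 0.7),
                             genus = "Pseudomonas", p_phage = 0.2,
                             seed = 2) {
  set.seed(seed)
  planted <- vapply(seq_len(n_planted), function(i) {
    src <- seeds[[sample(length(seeds), 1)]]
    mutate_protein(src, runif(1, identity_range[1], identity_range[2]))
  }, character(1))
  names(planted) <- sprintf("planted%03d", seq_len(n_planted))
  decoys <- vapply(seq_len(n_decoys), function(i) {
    shuffle_seq(planted[[sample(n_planted, 1)]])
  }, character(1))
  names(decoys) <- sprintf("decoy%03d", seq_len(n_decoys))

  species <- c("putida", "taiwanensis", "fluorescens", "aeruginosa",
               "duriflava", "sp.")
  is_phage <- runif(n_planted) < p_phage
  planted_tax <- ifelse(is_phage,
                        sprintf("%s phage vB-%03d", genus, seq_len(n_planted)),
                        sprintf("%s %s", genus,
                                sample(species, n_planted, replace = TRUE)))
  other <- c("Escherichia coli", "Bacillus subtilis", "Vibrio cholerae",
             "Salmonella enterica", "Lactococcus lactis")
  decoy_tax <- sample(other, n_decoys, replace = TRUE)
  taxonomy <- data.frame(
    seq_id = c(names(planted), names(decoys)),
    taxonomy = c(planted_tax, decoy_tax),
    source = c(ifelse(is_phage, "phage", "bacterium"),
               rep("other", n_decoys)),
    stringsAsFactors = FALSE)

  list(db = c(planted, decoys), taxonomy = taxonomy,
       planted_ids = names(planted))
}

#' Synthesize a genome and a table of small edits
#'
#' A random genome with a replichore map, plus edit specifications of 1-3
#' substituted bases at well-separated loci, labelled after the classic
#' antibiotic-resistance readouts.
#'
#' @param genome_length genome length in bp
#' @param seed RNG seed
#' @return list with `genome` (named character), `map`
#'   ([replichore_map()]) and `edits` (data.frame: genome_id, position,
#'   ref, alt, label)
#' @export
synth_genome_edits <- function(genome_length = 20000, seed = 3) {
  set.seed(seed)
  genome <- setNames(random_dna(genome_length), "chr")
  # ter off the edit grid so no locus falls exactly on it
  map <- replichore_map(oriC = 1, ter = round(genome_length * 0.52),
                        genome_length)
  labels <- c("rpsL K43T", "rpoB Q518L", "pyrF E50stop", "gyrA D87N",
              "gyrA T83I")
  widths <- c(1L, 1L, 1L, 2L, 3L)
  positions <- round(seq(0.1, 0.9, length.out = length(labels)) *
                       genome_length)
  edits <- do.call(rbind, lapply(seq_along(labels), function(i) {
    k <- widths[i]
    ref <- substr(genome[["chr"]], positions[i], positions[i] + k - 1)
    alt_chars <- vapply(strsplit(ref, "")[[1]], function(b) {
      sample(setdiff(DNA4, b), 1)
    }, character(1))
    data.frame(genome_id = "chr", position = positions[i], ref = ref,
               alt = paste(alt_chars, collapse = ""), label = labels[i],
               stringsAsFactors = FALSE)
  }))
  list(genome = genome, map = map, edits = edits)
}

#' Synthesize a set of variant SSAP genes
#'
#' Variant genes descend from a common ancestral gene at the given
#' identity, giving a realistic family in which references are mutually
#' distinguishable but related.
#'
#' @param n number of variants
#' @param length gene length in nt
#' @param identity variant-to-ancestor identity
#' @param seed RNG seed
#' @return named character vector (`V01`, `V02`, ...)
#' @export
synth_variant_genes <- function(n = 52, length = 750, identity = 0.75,
                                seed = 4) {
  set.seed(seed)
  ancestor <- random_dna(length)
  genes <- vapply(seq_len(n), function(i) mutate_dna(ancestor, identity),
                  character(1))
  names(genes) <- sprintf("V%02d", seq_len(n))
  genes
}

#' Synthesize per-variant screen parameters
#'
#' A small active set (positive `arf`, varied action rates) among inert
#' variants (`arf = 0`), mirroring a screen where only a few SSAPs work.
#'
#' @param variant_ids variant ids (e.g. names of [synth_variant_genes()])
#' @param n_active number of active variants (taken from the start of the
#'   id list)
#' @param arf_range active-variant saturation ARF range
#' @param tau_range active-variant action-rate time constants (hours)
#' @param seed RNG seed
#' @return a [variant_params()] table
#' @export
synth_variant_params <- function(variant_ids, n_active = 4,
                                 arf_range = c(0.008, 0.02),
                                 tau_range = c(0.5, 2), seed = 5) {
  set.seed(seed)
  n <- length(variant_ids)
  stopifnot(n_active <= n)
  arf <- rep(0, n)
  tau <- rep(1, n)
  active <- seq_len(n_active)
  arf[active] <- runif(n_active, arf_range[1], arf_range[2])
  tau[active] <- runif(n_active, tau_range[1], tau_range[2])
  variant_params(variant_ids, arf = arf, tau = tau)
}
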