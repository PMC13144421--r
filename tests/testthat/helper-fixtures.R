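# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A modest simulated tetraploid with every process switched on, reused
# across module tests.
cached_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- simulation_config(
      seed = 424L, n_chromosome_pairs = 2L, genes_per_chromosome = 60L,
      fractionation_prob = 0.2, fractionation_bias = 0,
      residual_prob = 0.3, pseudogenization_prob = 0.12,
      retrocopy_prob = 0.06, tandem_dup_prob = 0,
      te_insertions_per_intron = 0.15)
    .fixture_env$sim <- simulate_wgd_genome(cfg)
  }
  .fixture_env$sim
}

cached_map <- function() {
  if (is.null(.fixture_env$map)) {
    .fixture_env$map <- homoeolog_map(cached_sim()$focal)
  }
  .fixture_env$map
}

cached_scan <- function() {
  if (is.null(.fixture_env$scan)) {
    sim <- cached_sim()
    parents <- select_parents(sim$focal, ancestral_proteins(sim))
    calls <- scan_pseudogenes(sim$focal, cached_map(), parents)
    .fixture_env$scan <- list(parents = parents, calls = calls)
  }
  .fixture_env$scan
}

# A tiny hand-built two-chromosome bundle (one gene per strand).
tiny_bundle <- function() {
  seqs <- c(chrA = paste(rep("ACGT", 600), collapse = ""),
            chrB = paste(rep("TTGCA", 400), collapse = ""))
  genes <- data.frame(
    gene_id = c("gPlus", "gMinus"),
    locus_id = c("gPlus", "gMinus"),
    chromosome = c("chrA", "chrB"),
    strand = c("+", "-"),
    start = c(1001L, 501L), end = c(1400L, 950L),
    is_allele = FALSE, family_id = c("famX", "famY"),
    is_predominant = TRUE, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gPlus", "gPlus", "gMinus"),
    start = c(1001L, 1201L, 501L), end = c(1100L, 1400L, 950L))
  genome_bundle(seqs, genes, exons, exons,
                families = data.frame(family_id = c("famX", "famY"),
                                      gene_id = c("gPlus", "gMinus")))
}

random_cds_str <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_cod <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               c("T", "C", "A", "G")), 1, paste,
                   collapse = "")
  paste0("ATG",
         paste(sample(setdiff(all_cod, stops), n_codons - 2, TRUE),
               collapse = ""),
         sample(stops, 1))
}
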