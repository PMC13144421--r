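quiet_cfg <- function(seed = 7L, ...) {
  simulation_config(seed = seed, n_chromosome_pairs = 2L,
                    genes_per_chromosome = 25L, ...)
}

test_that("a process-free simulation gives two identical-structure copies", {
  cfg <- quiet_cfg(fractionation_prob = 0, pseudogenization_prob = 0,
                   retrocopy_prob = 0, tandem_dup_prob = 0,
                   te_insertions_per_intron = 0, te_intergenic_rate = 0,
                   wgd_divergence = 0)
  sim <- simulate_wgd_genome(cfg)
  expect_setequal(unique(sim$truth$fate), "retained")
  copies <- table(sim$focal$genes$family_id)
  expect_true(all(copies == 2))
  expect_equal(nrow(sim$focal$repeats), 0)
  # zero divergence: H2 CDS identical to H1 CDS
  h1 <- sim$truth$gene_id[sim$truth$copy == "H1"][1:5]
  h2 <- sim$truth$gene_id[sim$truth$copy == "H2"][1:5]
  for (i in 1:5) {
    expect_identical(gene_cds_sequence(sim$focal, h1[i]),
                     gene_cds_sequence(sim$focal, h2[i]))
  }
})

test_that("full H2-biased fractionation deletes every H2 gene", {
  cfg <- quiet_cfg(fractionation_prob = 1, fractionation_bias = 0,
                   residual_prob = 0, pseudogenization_prob = 0,
                   retrocopy_prob = 0, tandem_dup_prob = 0)
  sim <- simulate_wgd_genome(cfg)
  h2 <- sim$truth[sim$truth$copy == "H2", ]
  expect_true(all(h2$fate == "deleted"))
  expect_true(all(is.na(h2$gene_id)))
  # retention vs the diploid outgroup is exactly 0.5 per family
  ret <- retention_table(sim$focal, sim$outgroup)
  expect_true(all(ret$retention == 0.5))
})

test_that("the same seed reproduces emitted files byte-identically", {
  cfg <- quiet_cfg(seed = 99L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_wgd_genome(cfg), d1)
  write_simulation(simulate_wgd_genome(cfg), d2)
  for (f in c("genome.fa", "genes.gff3", "repeats.out", "families.tsv",
              "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("copy conservation: retained + deleted + pseudogenized = 2n", {
  sim <- cached_sim()
  n_anc <- sim$config$n_chromosome_pairs *
    sim$config$genes_per_chromosome
  core <- sim$truth[sim$truth$copy %in% c("H1", "H2"), ]
  expect_equal(nrow(core), 2L * n_anc)
  expect_true(all(core$fate %in%
                    c("retained", "deleted", "pseudogenized")))
})

test_that("empirical H2 deletion fraction recovers f within 3 binomial SE", {
  f <- 0.3
  cfg <- simulation_config(seed = 5L, n_chromosome_pairs = 4L,
                           genes_per_chromosome = 500L,
                           fractionation_prob = f, fractionation_bias = 0,
                           residual_prob = 0, pseudogenization_prob = 0,
                           retrocopy_prob = 0, tandem_dup_prob = 0,
                           te_insertions_per_intron = 0,
                           te_intergenic_rate = 0, outgroup = FALSE)
  sim <- simulate_wgd_genome(cfg)
  h2 <- sim$truth[sim$truth$copy == "H2", ]
  n <- nrow(h2)
  expect_gte(n, 2000)
  f_hat <- mean(h2$fate == "deleted")
  se <- sqrt(f * (1 - f) / n)
  expect_lt(abs(f_hat - f), 3 * se)
})

test_that("emitted files are accepted by the genome_io readers", {
  sim <- cached_sim()
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_no_warning({
    gs <- read_gff3(file.path(d, "genes.gff3"))
    rp <- read_repeatmasker_out(file.path(d, "repeats.out"))
    fam <- read_family_table(file.path(d, "families.tsv"))
  })
  expect_equal(nrow(gs$genes), nrow(sim$focal$genes))
  expect_equal(nrow(rp), nrow(sim$focal$repeats))
  seqs <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  b <- genome_bundle(setNames(as.character(seqs), names(seqs)),
                     gs$genes, gs$exons, gs$cds, rp)
  expect_true(validate_bundle(b))
})

test_that("disablement injection produces the advertised lesions", {
  set.seed(31)
  cds <- "ATGAAATTTCCCGGGTAA"
  st <- inject_disablement(cds, "premature_stop")
  expect_equal(st$n_premature_stops, 1L)
  expect_equal(nchar(st$sequence), nchar(cds))
  codons <- substring(st$sequence, seq(4, nchar(cds) - 5, 3),
                      seq(6, nchar(cds) - 3, 3))
  expect_true(any(codons %in% c("TAA", "TAG", "TGA")))
  prot <- sub("\\*.*$", "",
              paste(Biostrings::GENETIC_CODE[
                substring(st$sequence, seq(1, nchar(cds) - 2, 3),
                          seq(3, nchar(cds), 3))], collapse = ""))
  expect_lt(nchar(prot), nchar(cds) / 3 - 1)

  cds300 <- random_cds_str(100)
  for (i in 1:10) {
    fs <- inject_disablement(cds300, "frameshift")
    expect_true(nchar(fs$sequence) %in% c(298, 299, 301, 302))
    expect_equal(fs$n_frameshifts, 1L)
  }

  pa <- inject_disablement(cds300, "polyA_retrocopy")
  expect_true(pa$has_polyA)
  expect_match(pa$sequence, "A{20,}$")
  expect_error(inject_disablement("ATGTAA", "premature_stop"), ">= 9")
})

test_that("TE landscape placement honours rate, waves and exon exclusion", {
  sim <- cached_sim()
  cfg0 <- simulation_config(seed = 1L, te_insertions_per_intron = 0)
  set.seed(8)
  expect_equal(nrow(sample_te_landscape(sim$focal, cfg0)), 0)

  cfg2 <- simulation_config(
    seed = 1L, te_insertions_per_intron = 40,
    te_wave_ages = data.frame(mean = c(3, 25), sd = c(1, 2),
                              weight = c(0.5, 0.5)))
  set.seed(9)
  te <- sample_te_landscape(sim$focal, cfg2)
  expect_gte(nrow(te), 10000)
  h <- table(floor(te$divergence_pct))
  expect_equal(names(which.max(h[as.numeric(names(h)) < 15])), "3")
  expect_equal(names(which.max(h[as.numeric(names(h)) >= 15])), "25")
  # the valley between the two waves is far below both modes
  valley <- sum(h[names(h) %in% as.character(10:17)]) / 8
  expect_lt(valley, 0.3 * max(h))

  ex <- sim$focal$exons
  for (chrom in unique(te$chromosome)) {
    t1 <- te[te$chromosome == chrom, ]
    e1 <- ex[sim$focal$genes$chromosome[
      match(ex$gene_id, sim$focal$genes$gene_id)] == chrom, ]
    ov <- IRanges::overlapsAny(IRanges::IRanges(t1$start, t1$end),
                               IRanges::IRanges(e1$start, e1$end))
    expect_false(any(ov))
  }
})

test_that("infeasible probabilities are rejected at configuration time", {
  expect_error(simulation_config(fractionation_prob = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(
    te_wave_ages = data.frame(mean = 1, sd = 1, weight = 0.5)),
    "sum to 1")
})
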