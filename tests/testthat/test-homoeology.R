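# Hand-built anchor sets for the chaining operations.
mk_anchors <- function(rank_a, rank_b, chrom_a = "c1", chrom_b = "c2") {
  data.frame(gene_a = sprintf("a%02d", seq_along(rank_a)),
             gene_b = sprintf("b%02d", seq_along(rank_b)),
             chrom_a = chrom_a, chrom_b = chrom_b,
             rank_a = rank_a, rank_b = rank_b, stringsAsFactors = FALSE)
}

test_that("anchor building pairs same-family genes across chromosomes", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    locus_id = sprintf("g%02d", 1:20),
    chromosome = rep(c("c1", "c2"), each = 10),
    strand = "+", start = rep(seq(100, 1000, by = 100), 2),
    end = rep(seq(150, 1050, by = 100), 2),
    is_allele = FALSE, family_id = rep(sprintf("f%02d", 1:10), 2),
    is_predominant = TRUE, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end)
  b <- genome_bundle(c(c1 = strrep("A", 2000), c2 = strrep("A", 2000)),
                     genes, exons,
                     families = genes[, c("family_id", "gene_id")])
  anchors <- build_anchors(b)
  expect_equal(nrow(anchors), 10)
  expect_true(all(anchors$chrom_a == "c1" & anchors$chrom_b == "c2"))

  # a 50-member family exceeds the 8 x ploidy cap and contributes nothing
  big <- data.frame(
    gene_id = sprintf("big%02d", 1:50),
    locus_id = sprintf("big%02d", 1:50),
    chromosome = rep(c("c1", "c2"), 25),
    strand = "+", start = seq(1100, by = 10, length.out = 50),
    end = seq(1105, by = 10, length.out = 50),
    is_allele = FALSE, family_id = "fBIG", is_predominant = TRUE,
    stringsAsFactors = FALSE)
  b2 <- genome_bundle(c(c1 = strrep("A", 3000), c2 = strrep("A", 3000)),
                      rbind(genes, big),
                      rbind(exons, data.frame(gene_id = big$gene_id,
                                              start = big$start,
                                              end = big$end)),
                      families = rbind(genes[, c("family_id", "gene_id")],
                                       big[, c("family_id", "gene_id")]))
  anchors2 <- build_anchors(b2)
  expect_equal(nrow(anchors2), 10)  # 50 > 16: excluded as promiscuous
  # same-chromosome pairs never become anchors
  expect_false(any(anchors2$chrom_a == anchors2$chrom_b))
})

test_that("perfectly collinear anchors chain into one same-orientation block", {
  a <- mk_anchors(1:20, 1:20)
  blk <- chain_blocks(a, min_block_size = 5)
  expect_equal(length(unique(blk$block_id)), 1)
  expect_equal(blk$score[1], 20)
  expect_equal(blk$orientation[1], "same")
})

test_that("reversed ranks chain into one inverted block", {
  a <- mk_anchors(1:20, 20:1)
  blk <- chain_blocks(a, min_block_size = 5)
  expect_equal(length(unique(blk$block_id)), 1)
  expect_equal(blk$orientation[1], "inverted")
  expect_equal(blk$score[1], 20)
})

test_that("an internal inversion splits into two blocks, each optimal", {
  rank_b <- c(1:4, 12:5, 13:16)  # 8-anchor inversion inside 16
  a <- mk_anchors(1:16, rank_b)
  blk <- chain_blocks(a, min_block_size = 3, max_rank_gap = 25)
  expect_equal(length(unique(blk$block_id)), 2)
  sizes <- sort(table(blk$block_id), decreasing = TRUE)
  expect_equal(unname(sizes[1]), chain_oracle_best(1:16, rank_b, 25))
  expect_setequal(unique(blk$orientation), c("same", "inverted"))
})

test_that("block anchors are strictly monotone in both ranks", {
  sim <- cached_sim()
  anchors <- build_anchors(sim$focal)
  blk <- chain_blocks(anchors)
  for (b in split(blk, blk$block_id)) {
    b <- b[order(b$rank_a), ]
    expect_true(all(diff(b$rank_a) > 0))
    d <- diff(b$rank_b)
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("chromosome pairing is greedy on block weight with ties by name", {
  blk <- rbind(
    cbind(mk_anchors(1:6, 1:6, "c1", "c3")),
    cbind(mk_anchors(1:9, 1:9, "c2", "c4")))
  blocks <- chain_blocks(blk, min_block_size = 5)
  pairs <- pair_chromosomes(blocks)
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$chrom_a, pairs$chrom_b),
                  c("c1 c3", "c2 c4"))
  empty <- pair_chromosomes(chain_blocks(mk_anchors(1, 1)),
                            chromosomes = c("c1", "c2"))
  expect_equal(nrow(empty), 0)
  expect_setequal(attr(empty, "unpaired"), c("c1", "c2"))
})

test_that("H2 is the repeat-heavier member; ties break lexicographically", {
  pairs <- data.frame(chrom_a = "cA", chrom_b = "cB")
  reps <- data.frame(chromosome = c("cA", "cB", "cB"),
                     start = c(1, 1, 20001), end = c(10000, 30000, 70000),
                     class_label = "LTR/Gypsy", divergence_pct = 5)
  g <- assign_groups(pairs, reps)
  expect_equal(g$chr_h1, "cA")
  expect_equal(g$chr_h2, "cB")
  # the two cB intervals overlap: [1,30000] u [20001,70000] = 70 kb
  expect_equal(g$repeat_bp_h2, 70000)
  tie <- assign_groups(pairs, reps[0, ])
  expect_equal(tie$chr_h1, "cA")
  # invariant to the order pairs are listed in
  g2 <- assign_groups(data.frame(chrom_a = "cB", chrom_b = "cA"), reps)
  expect_equal(g2$chr_h1, "cA")
})

test_that("a fractionation-free simulation links every gene, none lost", {
  cfg <- simulation_config(seed = 3L, n_chromosome_pairs = 2L,
                           genes_per_chromosome = 40L,
                           fractionation_prob = 0,
                           pseudogenization_prob = 0, retrocopy_prob = 0,
                           tandem_dup_prob = 0, outgroup = FALSE)
  sim <- simulate_wgd_genome(cfg)
  map <- homoeolog_map(sim$focal)
  expect_true(all(!is.na(map$partner)))
  expect_false(any(map$partner == "lost"))
  lr <- link_recovery(sim, map)
  expect_equal(lr$pair_recovery, 1)
  expect_true(lr$chromosome_pairs_correct)
})

test_that("H2-biased loss is recovered as 'lost' links at the right rate", {
  f <- 0.3
  cfg <- simulation_config(seed = 13L, n_chromosome_pairs = 2L,
                           genes_per_chromosome = 150L,
                           fractionation_prob = f, fractionation_bias = 0,
                           residual_prob = 0, pseudogenization_prob = 0,
                           retrocopy_prob = 0, tandem_dup_prob = 0,
                           outgroup = FALSE)
  sim <- simulate_wgd_genome(cfg)
  map <- homoeolog_map(sim$focal)
  h1 <- map[map$group == "H1", ]
  lost_frac <- mean(h1$partner == "lost", na.rm = TRUE)
  se <- sqrt(f * (1 - f) / nrow(h1))
  expect_lt(abs(lost_frac - f), 3 * se)
})

test_that("genes on an unpaired scaffold stay unplaced", {
  sim <- cached_sim()
  b <- sim$focal
  extra_gene <- data.frame(
    gene_id = "scaf_g1", locus_id = "scaf_g1", chromosome = "scaf1",
    strand = "+", start = 101L, end = 400L, is_allele = FALSE,
    family_id = b$genes$family_id[1], is_predominant = TRUE,
    stringsAsFactors = FALSE)
  b$sequences <- c(b$sequences,
                   Biostrings::DNAStringSet(c(scaf1 = strrep("ACGT", 200))))
  b$genes <- rbind(b$genes, extra_gene)
  b$exons <- rbind(b$exons, data.frame(gene_id = "scaf_g1", start = 101L,
                                       end = 400L))
  b$cds <- rbind(b$cds, data.frame(gene_id = "scaf_g1", start = 101L,
                                   end = 400L))
  b$families <- rbind(b$families,
                      data.frame(family_id = extra_gene$family_id,
                                 gene_id = "scaf_g1",
                                 species_or_group = "focal"))
  map <- homoeolog_map(b)
  expect_equal(map$group[map$gene_id == "scaf_g1"], "unplaced")
})
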