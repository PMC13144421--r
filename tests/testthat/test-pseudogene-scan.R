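test_that("parent eligibility uses strict thresholds", {
  expect_true(parent_eligible(41, 0.51, 0.51))
  expect_false(parent_eligible(40.0, 0.51, 0.51))  # strict >
  expect_false(parent_eligible(41, 0.50, 0.51))
  expect_false(parent_eligible(41, 0.51, 0.50))
})

test_that("all genes of a divergence-free simulation are eligible parents", {
  cfg <- simulation_config(seed = 21L, n_chromosome_pairs = 2L,
                           genes_per_chromosome = 15L, wgd_divergence = 0,
                           fractionation_prob = 0,
                           pseudogenization_prob = 0, retrocopy_prob = 0,
                           tandem_dup_prob = 0, outgroup = FALSE)
  sim <- simulate_wgd_genome(cfg)
  parents <- select_parents(sim$focal, ancestral_proteins(sim))
  expect_true(all(parents$eligible))
  expect_error(select_parents(sim$focal, Biostrings::AAStringSet()),
               "empty")
})

test_that("alignment of an exact CDS copy has full coverage and identity", {
  set.seed(51)
  cds <- random_cds_str(120)
  locus <- paste0(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = ""),
                  cds,
                  paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = ""))
  aln <- align_parent_to_locus(cds, locus)
  expect_equal(aln$coverage, 1)
  expect_equal(aln$identity, 100)
  expect_equal(aln$n_premature_stops, 0L)
  expect_equal(aln$n_frameshifts, 0L)
  expect_false(aln$has_polyA)
})

test_that("a half-truncated locus gives coverage 0.5 within 2 bp jitter", {
  set.seed(52)
  for (i in 1:5) {
    cds <- random_cds_str(150)
    half <- substr(cds, 1, nchar(cds) / 2)
    locus <- paste0(strrep("G", 100), half, strrep("C", 100))
    aln <- align_parent_to_locus(cds, locus)
    expect_lt(abs(aln$coverage - 0.5), 2.5 / nchar(cds) + 1e-9)
  }
})

test_that("alignment scores equal the exhaustive Gotoh oracle", {
  set.seed(53)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(10:50, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:50, 1), TRUE),
               collapse = "")
    got <- align_parent_to_locus(a, b, both_strands = FALSE,
                                 min_segment_score = 0)$score
    expect_equal(got, gotoh_local_score(a, b))
  }
})

test_that("disablement calls recover injected lesions", {
  set.seed(54)
  cds <- random_cds_str(150)
  flank <- function(s) paste0(strrep("G", 80), s, strrep("C", 80))

  st <- inject_disablement(cds, "premature_stop")
  aln <- align_parent_to_locus(cds, flank(st$sequence))
  expect_equal(call_disablements(aln),
               list(n_premature_stops = 1L, n_frameshifts = 0L,
                    has_polyA = FALSE))

  fs <- inject_disablement(cds, "frameshift")
  aln2 <- align_parent_to_locus(cds, flank(fs$sequence))
  expect_equal(aln2$n_frameshifts, 1L)
  expect_gte(aln2$n_premature_stops, 0L)
  expect_false(aln2$has_polyA)

  # 25-bp A tail directly downstream of the aligned CDS
  locus3 <- paste0(strrep("G", 80), cds, strrep("A", 25), strrep("C", 80))
  aln3 <- align_parent_to_locus(cds, locus3)
  expect_true(aln3$has_polyA)
})

test_that("classification follows the DUP/FRAG/PSSD evidence rules", {
  # multi-exon parent, contiguous locus alignment, polyA -> processed
  expect_equal(classify_pseudogene(0.95, 98, has_polyA = TRUE,
                                   contiguous = TRUE,
                                   n_parent_segments = 3,
                                   n_aligned_segments = 3), "PSSD")
  # intron loss alone (no tail) is enough for a multi-exon parent
  expect_equal(classify_pseudogene(0.9, 97, FALSE, TRUE, 4, 4), "PSSD")
  # low coverage but high identity -> fragmented remnant
  expect_equal(classify_pseudogene(0.2, 90, FALSE, FALSE, 3, 1), "FRAG")
  # high coverage with retained introns -> duplicated pseudogene
  expect_equal(classify_pseudogene(0.9, 95, FALSE, FALSE, 3, 3), "DUP")
  # single aligned segment of a multi-exon parent is not intron loss
  expect_equal(classify_pseudogene(0.6, 95, FALSE, TRUE, 3, 1), "DUP")
  # identity below 40 never becomes FRAG
  expect_equal(classify_pseudogene(0.2, 35, FALSE, FALSE, 1, 1), "DUP")
})

test_that("fractionation: intact pair 0, truncated 82, deleted 100", {
  sim <- cached_sim()
  map <- cached_map()
  calls <- cached_scan()$calls
  fr <- compute_fractionation(sim$focal, map, calls)
  tr <- sim$truth

  intact <- tr$ancestral_id[tr$copy == "H2" & tr$fate == "retained"]
  h1_intact <- tr$gene_id[tr$copy == "H1" & tr$fate == "retained" &
                            tr$ancestral_id %in% intact]
  est <- fr$fractionation_pct[match(h1_intact, fr$gene_id)]
  expect_true(mean(est < 10, na.rm = TRUE) > 0.95)

  gone <- tr$ancestral_id[tr$copy == "H2" & tr$fate == "deleted" &
                            is.na(tr$locus_chromosome)]
  h1_gone <- tr$gene_id[tr$copy == "H1" & !is.na(tr$gene_id) &
                          tr$ancestral_id %in% gone]
  est2 <- fr$fractionation_pct[match(h1_gone, fr$gene_id)]
  expect_true(mean(est2 == 100, na.rm = TRUE) > 0.9)

  # a locus retaining 18% of the CDS is ~82% fractionated
  set.seed(55)
  cds <- random_cds_str(200)
  kept <- substr(cds, 1, round(0.18 * nchar(cds)))
  locus <- paste0(strrep("G", 150), kept, strrep("C", 150))
  aln <- align_parent_to_locus(cds, locus)
  expect_lt(abs(100 * (1 - aln$coverage) - 82), 2)
})

test_that("every emitted call carries at least one evidence item", {
  calls <- cached_scan()$calls
  expect_gt(nrow(calls), 0)
  evid <- calls$n_premature_stops + calls$n_frameshifts > 0 |
    calls$has_polyA | calls$coverage < 0.8
  expect_true(all(evid))
  expect_true(all(calls$coverage >= 0 & calls$coverage <= 1))
  expect_true(all(calls$class %in% c("DUP", "FRAG", "PSSD")))
})

test_that("haplotype-confusion screening drops unsupported loci", {
  calls <- cached_scan()$calls
  expect_warning(screen_haplotype_confusion(calls, NULL), "unfiltered")
  support <- data.frame(chromosome = calls$chromosome,
                        start = calls$start, end = calls$end,
                        covered = TRUE, max_deletion = 0)
  kept <- screen_haplotype_confusion(calls, support)
  expect_equal(nrow(kept), nrow(calls))
  expect_equal(attr(kept, "n_dropped"), 0L)
  support$covered[1] <- FALSE
  kept2 <- screen_haplotype_confusion(calls, support)
  expect_equal(nrow(kept2), nrow(calls) - 1L)
  expect_equal(attr(kept2, "n_dropped"), 1L)
  expect_equal(attr(kept2, "n_dropped") / nrow(calls), 1 / nrow(calls))
})

test_that("scan recovers injected classes on the cached simulation", {
  sim <- cached_sim()
  rec <- class_recovery(sim, cached_scan()$calls)
  expect_gte(rec$recovery[rec$expected_class == "DUP"], 0.9)
  expect_gte(rec$recovery[rec$expected_class == "PSSD"], 0.9)
  expect_gte(rec$recovery[rec$expected_class == "FRAG"], 0.8)
})
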