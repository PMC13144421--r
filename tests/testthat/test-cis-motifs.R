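# Fixture PWM: the evening-element-like consensus AAAATATCT (a standard
# circadian cis-element consensus used here as a synthetic fixture).
ee_pwm <- function(bg = rep(0.25, 4)) {
  consensus <- strsplit("AAAATATCT", "")[[1]]
  m <- matrix(0.04, 4, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 0.88
  make_pwm(m, "evening_element", bg)
}

test_that("promoters are the 1.5 kb immediately upstream of the TSS", {
  seqs <- Biostrings::DNAStringSet(c(chr = paste(
    rep("ACGT", 2500), collapse = "")))
  g_fwd <- data.frame(gene_id = "g", chromosome = "chr", strand = "+",
                      start = 5000L, end = 6000L)
  p <- extract_promoter(g_fwd, seqs)
  expect_equal(nchar(p), 1500)
  expect_equal(p, substr(as.character(seqs[[1]]), 3500, 4999))

  g_near <- g_fwd
  g_near$start <- 1000L
  expect_equal(nchar(extract_promoter(g_near, seqs)), 999)

  g_rev <- data.frame(gene_id = "g", chromosome = "chr", strand = "-",
                      start = 2000L, end = 3000L)
  p_rev <- extract_promoter(g_rev, seqs)
  expect_equal(nchar(p_rev), 1500)
  expect_equal(substr(p_rev, 1500, 1500),
               chartr("ACGT", "TGCA",
                      substr(as.character(seqs[[1]]), 3001, 3001)))

  g_edge <- g_fwd
  g_edge$start <- 1L
  expect_warning(pe <- extract_promoter(g_edge, seqs), "contig edge")
  expect_equal(pe, "")
})

test_that("the consensus word attains the maximal score and minimal p", {
  pwm <- ee_pwm()
  prom <- paste0(strrep("G", 100), "AAAATATCT", strrep("G", 100))
  hits <- scan_pwm(prom, pwm, p_threshold = 1)
  top <- hits[which.max(hits$score), ]
  d <- pwm_score_distribution(pwm)
  expect_equal(top$score, max(d$score))
  expect_equal(top$p_value, min(d$p_value))
  expect_equal(top$strand, "+")
  # offset: consensus starts 109 bases before the TSS
  expect_equal(top$offset, -(nchar(prom)) + 100)
})

test_that("hard-masked promoters produce no hits", {
  pwm <- ee_pwm()
  expect_equal(nrow(scan_pwm(strrep("N", 300), pwm, 1)), 0)
  # a masked island hides the motif it covers
  prom <- paste0(strrep("G", 50), "AAAANATCT", strrep("G", 50))
  hits <- scan_pwm(prom, pwm, 1)
  expect_false(any(hits$offset == -60))
})

test_that("p-values are monotone non-increasing in score", {
  set.seed(81)
  pwm <- make_pwm(matrix(runif(4 * 6), 4, 6), "m",
                  background = c(0.3, 0.2, 0.2, 0.3))
  d <- pwm_score_distribution(pwm)
  expect_true(all(diff(d$score) <= 0))
  expect_true(all(diff(d$p_value) >= -1e-15))
  expect_equal(d$p_value[nrow(d)], 1)
})

test_that("exact p-values equal brute-force enumeration for widths <= 8", {
  set.seed(82)
  for (w in c(2, 5, 8)) {
    pwm <- make_pwm(matrix(runif(4 * w), 4, w), paste0("w", w),
                    background = rep(0.25, 4))
    en <- pwm_enum(pwm)
    d <- pwm_score_distribution(pwm)
    obs <- sort(unique(en$scores))
    pv_dp <- vapply(obs, function(s) diploscan:::pvalue_lookup(d, s),
                    numeric(1))
    pv_en <- vapply(obs, en$pvalue, numeric(1))
    expect_equal(pv_dp, pv_en, tolerance = 1e-12)
  }
  # width-2 uniform case: all 16 dinucleotide words enumerable by hand
  pwm2 <- make_pwm(matrix(c(0.7, 0.1, 0.1, 0.1,
                            0.1, 0.1, 0.1, 0.7), 4, 2), "di")
  d2 <- pwm_score_distribution(pwm2)
  expect_equal(sum(d2$p_value == 1), 1)
  expect_equal(diploscan:::pvalue_lookup(d2, max(d2$score)), 1 / 16)
})

test_that("reverse-complement scanning mirrors hits with equal scores", {
  pwm <- ee_pwm()
  set.seed(83)
  prom <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  prom <- paste0(substr(prom, 1, 150), "AAAATATCT",
                 substr(prom, 160, 400))
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(prom, "")[[1]]), collapse = ""))
  h1 <- scan_pwm(prom, pwm, 1)
  h2 <- scan_pwm(rc, pwm, 1)
  expect_equal(sort(h1$score), sort(h2$score))
  expect_equal(table(h1$strand)[["+"]], table(h2$strand)[["-"]])
})

test_that("MEME minimal format round-trips a PWM", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF EE_LIKE", "",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.90 0.02 0.04 0.04",
    " 0.05 0.05 0.05 0.85",
    " 0.10 0.40 0.40 0.10"), path)
  pwms <- read_meme(path)
  expect_equal(names(pwms), "EE_LIKE")
  expect_equal(pwms$EE_LIKE$width, 3)
  expect_equal(unname(pwms$EE_LIKE$background),
               c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pwms$EE_LIKE$prob["A", 1]),
               (0.90 + 0.01) / 1.04, tolerance = 1e-12)
})

test_that("presence matrix spots the single homoeolog lacking the motif", {
  pwm <- ee_pwm()
  set.seed(84)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                            collapse = "")
  with_motif <- function() paste0(flank(), "AAAATATCT", flank())
  proms <- c(g1 = with_motif(), g2 = with_motif(), g3 = with_motif(),
             g4 = paste0(flank(), flank()))
  hits <- do.call(rbind, lapply(names(proms), function(g) {
    h <- scan_pwm(proms[[g]], pwm, p_threshold = 1e-4)
    if (nrow(h)) h$gene_id <- g
    h
  }))
  map <- data.frame(gene_id = names(proms),
                    chromosome = "c1", rank = 1:4,
                    group = c("H1", "H1", "H2", "H2"),
                    partner = NA, stringsAsFactors = FALSE)
  fams <- data.frame(family_id = "famEE", gene_id = names(proms))
  pm <- motif_presence_matrix(hits, map, fams, "evening_element",
                              position_window = c(-700, -1))
  expect_equal(sum(!pm$present), 1)
  expect_equal(pm$gene_id[!pm$present], "g4")
  expect_error(motif_presence_matrix(hits, map, fams, "evening_element"),
               "position_window")
  # permuting hit order changes nothing
  pm2 <- motif_presence_matrix(hits[sample(nrow(hits)), ], map, fams,
                               "evening_element", c(-700, -1))
  expect_equal(pm, pm2)
})

test_that("a degenerate background is rejected", {
  expect_error(make_pwm(matrix(0.25, 4, 4), "m",
                        background = c(0.5, 0.5, 0, 0)),
               "degenerate")
})

test_that("promoter background estimates 0-order letter frequencies", {
  p <- promoter_background(c("AACC", "GGTT", "NNNN"))
  expect_equal(sum(p), 1)
  expect_equal(unname(p), rep(0.25, 4))
})
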