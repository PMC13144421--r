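test_that("GFF3 coordinates keep the native 1-based closed convention", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gene:g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1;Parent=gene:g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tParent=g1"), path)
  gs <- read_gff3(path)
  expect_equal(gs$exons$start, 101)
  expect_equal(gs$exons$end, 200)
  expect_equal(gs$genes$strand, "+")
})

test_that("multi-exon minus-strand genes come back in genomic order", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t-\t.\tID=gene:g1",
    "chr1\tsrc\tmRNA\t100\t900\t.\t-\t.\tID=g1;Parent=gene:g1",
    "chr1\tsrc\texon\t700\t900\t.\t-\t.\tParent=g1",
    "chr1\tsrc\texon\t400\t500\t.\t-\t.\tParent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t-\t.\tParent=g1"), path)
  gs <- read_gff3(path)
  expect_equal(gs$genes$strand, "-")
  expect_equal(gs$exons$start, c(100, 400, 700))
  expect_equal(gs$exons$end, c(200, 500, 900))
})

test_that("exon without an mRNA parent is a structured parse error", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gene:g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=g1;Parent=gene:g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gX"), path)
  expect_error(read_gff3(path), "no mRNA parent")
})

test_that("GFF3 round-trips a simulated genome bit-exactly", {
  sim <- cached_sim()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$focal, path)
  gs <- read_gff3(path)
  orig <- sim$focal$genes[order(sim$focal$genes$gene_id), ]
  got <- gs$genes[order(gs$genes$gene_id), ]
  expect_equal(got$gene_id, orig$gene_id)
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  expect_equal(got$family_id, orig$family_id)
  oe <- sim$focal$exons[order(sim$focal$exons$gene_id,
                              sim$focal$exons$start), ]
  ge <- gs$exons[order(gs$exons$gene_id, gs$exons$start), ]
  expect_equal(ge$start, oe$start)
  expect_equal(ge$end, oe$end)
  # second write is byte-identical (coordinate round trip)
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gs, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("total exonic length equals the sum of printed exon spans", {
  sim <- cached_sim()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$focal, path)
  raw <- read.delim(path, header = FALSE, comment.char = "#")
  printed <- sum(raw$V5[raw$V3 == "exon"] - raw$V4[raw$V3 == "exon"] + 1)
  expect_equal(printed,
               sum(sim$focal$exons$end - sim$focal$exons$start + 1))
})

test_that("RepeatMasker rows parse with interval, class and divergence", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query    position in query  matching repeat",
    "score   div. del. ins.  sequence begin end (left) C repeat class/family begin end (left) ID",
    "",
    "1000 5.2 0.0 0.0 chr1 1001 2000 (0) + Gypsy-1 LTR/Gypsy 1 1000 (0) 1",
    "800 12.0 0.0 0.0 chr1 3000 3499 (0) C L1-2 LINE/L1 1 500 (0) 2",
    "500 * 0.0 0.0 chr2 10 59 (0) + Unk Unknown 1 50 (0) 3"), path)
  r <- read_repeatmasker_out(path)
  expect_equal(nrow(r), 3)
  expect_equal(r$start[1], 1001)
  expect_equal(r$end[1], 2000)
  expect_equal(r$class_label[1], "LTR/Gypsy")
  expect_equal(r$divergence_pct[1], 5.2)
  expect_true(is.na(r$divergence_pct[3]))
  expect_equal(sum(r$end - r$start + 1), 1000 + 500 + 50)
})

test_that("header-only RepeatMasker file yields zero features", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("   SW   perc perc", "score   div. del.", ""), path)
  expect_equal(nrow(read_repeatmasker_out(path)), 0)
})

test_that("non-numeric repeat coordinates raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "",
               "1000 5.2 0.0 0.0 chr1 xx 2000 (0) + G LTR/Gypsy 1 1 (0) 1"),
             path)
  expect_error(read_repeatmasker_out(path), "line 4")
})

test_that("family table collapses duplicates and rejects conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tspecies_or_group\tgene_id",
               "f1\tfocal\tg1", "f1\tfocal\tg2", "f1\tfocal\tg2",
               "f2\tfocal\tg3", "f2\tfocal\tg4", "f2\tfocal\tg5"), path)
  fam <- read_family_table(path)
  expect_equal(nrow(fam), 5)
  expect_equal(length(unique(fam$family_id)), 2)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tspecies_or_group\tgene_id",
               "f1\tfocal\tg1", "f2\tfocal\tg1"), bad)
  expect_error(read_family_table(bad), "more than one family")
})

test_that("feature matrices round-trip losslessly and deterministically", {
  df <- data.frame(id = c("b", "a", "c"),
                   x = c(0.1, 2 / 3, 1e-17),
                   n = c(1L, NA, 3L),
                   flag = c(TRUE, FALSE, NA),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(df, path)
  back <- read_feature_matrix(path)
  expect_equal(back, df[order(df$id), ], ignore_attr = TRUE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(df[c(3, 1, 2), ], path2)
  expect_identical(readLines(path), readLines(path2))
  empty <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(df[0, ], empty)
  expect_equal(length(readLines(empty)), 1)
})

test_that("bundle validation catches structural violations", {
  b <- tiny_bundle()
  expect_true(validate_bundle(b))
  broken <- b
  broken$exons$end[2] <- 999999L
  expect_error(validate_bundle(broken), "chromosome bounds")
  broken2 <- b
  broken2$cds <- rbind(broken2$cds,
                       data.frame(gene_id = "gPlus", start = 1150L,
                                  end = 1160L))
  expect_error(validate_bundle(broken2), "CDS outside exons")
  broken3 <- b
  broken3$families <- rbind(broken3$families,
                            data.frame(family_id = "famZ",
                                       gene_id = "ghost"))
  expect_error(validate_bundle(broken3), "unknown genes")
})

test_that("introns are the gaps between exons", {
  ex <- data.frame(start = c(1001L, 1201L, 1501L),
                   end = c(1100L, 1300L, 1600L))
  intr <- gene_introns(ex)
  expect_equal(intr$start, c(1101L, 1301L))
  expect_equal(intr$end, c(1200L, 1500L))
  expect_equal(nrow(gene_introns(ex[1, ])), 0)
})
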