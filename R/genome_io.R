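#' @importFrom methods is
#' @importFrom stats rbinom rexp rnorm rpois runif sd setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# ---------------------------------------------------------------------------
# GenomeBundle: sequences + gene models + repeats + families for one
# (pseudo-)haplotype. All coordinates are 1-based closed on the forward
# strand (the GFF3/RepeatMasker/IRanges convention); conversion never
# happens because every format boundary shares it.
# ---------------------------------------------------------------------------

#' Assemble a genome bundle
#'
#' The container every analysis stage consumes: chromosome sequences, gene
#' models (gene/exon/CDS tables), repeat annotations and gene-family
#' membership for one (pseudo-)haplotype.
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param genes `data.frame` with columns `gene_id`, `locus_id`,
#'   `chromosome`, `strand`, `start`, `end`, `is_allele`, `family_id`,
#'   `is_predominant`. Missing optional columns are filled with defaults.
#' @param exons,cds `data.frame`s with columns `gene_id`, `start`, `end`
#'   (1-based closed, genomic order). `cds` defaults to `exons`.
#' @param repeats Optional `data.frame` with columns `chromosome`, `start`,
#'   `end`, `class_label`, `divergence_pct` (`NA` allowed).
#' @param families Optional `data.frame` with columns `family_id`, `gene_id`.
#' @param species_label Free-text label.
#' @param ploidy Integer >= 1.
#' @param validate Run [validate_bundle()] on the result.
#' @return An object of class `GenomeBundle`.
#' @export
genome_bundle <- function(sequences, genes, exons, cds = exons,
                          repeats = NULL, families = NULL,
                          species_label = "genome", ploidy = 2L,
                          validate = TRUE) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  stopifnot(is(sequences, "DNAStringSet"), !is.null(names(sequences)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$locus_id)) genes$locus_id <- genes$gene_id
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$is_allele)) genes$is_allele <- FALSE
  if (is.null(genes$family_id)) genes$family_id <- NA_character_
  if (is.null(genes$is_predominant)) genes$is_predominant <- TRUE
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  if (is.null(genes$start) || is.null(genes$end)) {
    sp <- gene_spans(exons)
    genes$start <- sp$start[match(genes$gene_id, sp$gene_id)]
    genes$end <- sp$end[match(genes$gene_id, sp$gene_id)]
  }
  if (is.null(repeats)) {
    repeats <- data.frame(chromosome = character(), start = integer(),
                          end = integer(), class_label = character(),
                          divergence_pct = numeric())
  }
  if (is.null(families)) {
    families <- data.frame(family_id = character(), gene_id = character())
  }
  obj <- structure(list(sequences = sequences, genes = genes, exons = exons,
                        cds = cds, repeats = as.data.frame(repeats),
                        families = as.data.frame(families),
                        species_label = species_label,
                        ploidy = as.integer(ploidy)),
                   class = "GenomeBundle")
  if (validate) validate_bundle(obj)
  obj
}

gene_spans <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer()))
  }
  s <- tapply(exons$start, exons$gene_id, min)
  e <- tapply(exons$end, exons$gene_id, max)
  data.frame(gene_id = names(s), start = as.integer(s),
             end = as.integer(e[names(s)]), stringsAsFactors = FALSE)
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle '%s' (ploidy %d)\n", x$species_label, x$ploidy))
  cat(sprintf("  %d chromosomes, %.2f Mb\n", length(x$sequences),
              sum(Biostrings::width(x$sequences)) / 1e6))
  cat(sprintf("  %d gene models (%d predominant), %d repeats, %d families\n",
              nrow(x$genes), sum(x$genes$is_predominant), nrow(x$repeats),
              length(unique(x$families$family_id))))
  invisible(x)
}

#' Validate a genome bundle
#'
#' Checks the structural invariants: exons per gene are sorted,
#' non-overlapping and within chromosome bounds; CDS intervals are contained
#' in the exon union; gene chromosomes exist in `sequences`; family members
#' reference known genes; ploidy >= 1.
#'
#' @param bundle A `GenomeBundle`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "GenomeBundle"))
  if (bundle$ploidy < 1L) stop("ploidy must be >= 1")
  genes <- bundle$genes
  bad_chr <- setdiff(genes$chromosome, names(bundle$sequences))
  if (length(bad_chr)) {
    stop("gene chromosome(s) absent from sequences: ",
         paste(head(bad_chr, 5), collapse = ", "))
  }
  lens <- setNames(Biostrings::width(bundle$sequences),
                   names(bundle$sequences))
  ex <- bundle$exons[order(bundle$exons$gene_id, bundle$exons$start), ]
  if (any(ex$end < ex$start)) {
    stop("exon with end < start in gene ",
         ex$gene_id[which(ex$end < ex$start)[1]])
  }
  n <- nrow(ex)
  if (n > 1) {
    same <- ex$gene_id[-1] == ex$gene_id[-n]
    ov <- same & ex$start[-1] <= ex$end[-n]
    if (any(ov)) stop("overlapping exons in gene ", ex$gene_id[-1][ov][1])
  }
  exchr <- genes$chromosome[match(ex$gene_id, genes$gene_id)]
  oob <- !is.na(exchr) & (ex$start < 1 | ex$end > lens[exchr])
  if (any(oob)) {
    stop("exon outside chromosome bounds in gene ", ex$gene_id[oob][1])
  }
  cds_sorted <- bundle$cds[order(bundle$cds$gene_id, bundle$cds$start),
                           c("gene_id", "start", "end")]
  rownames(cds_sorted) <- rownames(ex) <- NULL
  if (!identical(cds_sorted, ex[, c("gene_id", "start", "end")])) {
    cd <- split(cds_sorted, cds_sorted$gene_id)
    exs <- split(ex, ex$gene_id)
    for (gid in names(cd)) {
      e <- exs[[gid]]
      if (is.null(e)) stop("CDS without exons for gene ", gid)
      exr <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
      cdr <- IRanges::IRanges(cd[[gid]]$start, cd[[gid]]$end)
      if (sum(IRanges::width(cdr)) !=
          sum(IRanges::width(IRanges::intersect(cdr, exr)))) {
        stop("CDS outside exons in gene ", gid)
      }
    }
  }
  unknown <- setdiff(bundle$families$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("family member(s) reference unknown genes: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# GFF3
# ---------------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS features with ID/Parent attributes. One gene
#' model is produced per mRNA; the longest mRNA of each gene locus is
#' flagged `is_predominant` (the "predominant" model that enters scoring),
#' other isoforms are retained but flagged.
#'
#' @param path GFF3 file.
#' @return List with `genes`, `exons`, `cds` data.frames (see
#'   [genome_bundle()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  parent1 <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x)[1] else NA_character_,
           character(1))
  }
  df$parent <- if (!is.null(df$Parent)) parent1(df$Parent) else NA_character_

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0) stop("no mRNA features found in ", path)
  kids <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- is.na(kids$parent) | !(kids$parent %in% mrna$ID)
  if (any(orphan)) {
    k <- kids[orphan, ][1, ]
    stop(sprintf("malformed GFF3 hierarchy: %s at %s:%d-%d has no mRNA parent",
                 k$type, k$seqnames, k$start, k$end))
  }
  gene_of <- setNames(sub("^gene:", "", mrna$parent), mrna$ID)
  gene_of[is.na(gene_of)] <- names(gene_of)[is.na(gene_of)]

  exons <- kids[kids$type == "exon", c("parent", "start", "end")]
  cds <- kids[kids$type == "CDS", c("parent", "start", "end")]
  names(exons)[1] <- names(cds)[1] <- "gene_id"
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  rownames(exons) <- rownames(cds) <- NULL

  exlen <- tapply(exons$end - exons$start + 1L, exons$gene_id, sum)
  genes <- data.frame(
    gene_id = mrna$ID,
    locus_id = unname(gene_of[mrna$ID]),
    chromosome = mrna$seqnames,
    strand = ifelse(mrna$strand %in% c("+", "-"), mrna$strand, "+"),
    start = mrna$start, end = mrna$end,
    is_allele = if (!is.null(mrna$is_allele))
      as.logical(mrna$is_allele) %in% TRUE else FALSE,
    family_id = if (!is.null(mrna$family_id))
      as.character(mrna$family_id) else NA_character_,
    stringsAsFactors = FALSE)
  genes$exonic_bp <- as.integer(exlen[genes$gene_id])
  genes$exonic_bp[is.na(genes$exonic_bp)] <- 0L
  # predominant = longest mRNA per locus, ties broken by gene_id
  ord <- order(genes$locus_id, -genes$exonic_bp, genes$gene_id)
  genes$is_predominant <- FALSE
  genes$is_predominant[ord[!duplicated(genes$locus_id[ord])]] <- TRUE
  genes$exonic_bp <- NULL
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL
  list(genes = genes, exons = exons, cds = cds)
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/exon/CDS rows (1-based closed coordinates) with
#' ID/Parent links; `family_id` and `is_allele` are carried as mRNA
#' attributes so that [read_gff3()] round-trips losslessly.
#'
#' @param x A `GenomeBundle` or a list with `genes`, `exons`, `cds`.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_gff3 <- function(x, path) {
  genes <- x$genes
  exons <- split(x$exons, x$exons$gene_id)
  cds <- split(x$cds, x$cds$gene_id)
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ]
  lines <- character(0)
  row9 <- function(chr, type, s, e, strand, phase, attrs) {
    sprintf("%s\tdiploscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chr, type, as.integer(s), as.integer(e), strand, phase, attrs)
  }
  out <- vector("list", nrow(genes) + 1L)
  out[[1]] <- "##gff-version 3"
  loci <- unique(genes$locus_id)
  blocks <- vector("list", length(loci))
  gsplit <- split(genes, genes$locus_id)
  # keep genome order
  first_start <- vapply(gsplit, function(g) min(g$start), 0)
  chr_of <- vapply(gsplit, function(g) g$chromosome[1], "")
  loci <- names(gsplit)[order(chr_of, first_start, names(gsplit))]
  for (k in seq_along(loci)) {
    g <- gsplit[[loci[k]]]
    chr <- g$chromosome[1]; strand <- g$strand[1]
    blk <- row9(chr, "gene", min(g$start), max(g$end), strand, ".",
                sprintf("ID=gene:%s", loci[k]))
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]
      attrs <- sprintf("ID=%s;Parent=gene:%s", gid, loci[k])
      if (!is.na(g$family_id[i])) {
        attrs <- paste0(attrs, ";family_id=", g$family_id[i])
      }
      if (isTRUE(g$is_allele[i])) attrs <- paste0(attrs, ";is_allele=TRUE")
      blk <- c(blk, row9(chr, "mRNA", g$start[i], g$end[i], strand, ".",
                         attrs))
      e <- exons[[gid]]
      if (!is.null(e)) {
        e <- e[order(e$start), ]
        blk <- c(blk, row9(chr, "exon", e$start, e$end, strand, ".",
                           sprintf("Parent=%s", gid)))
      }
      cc <- cds[[gid]]
      if (!is.null(cc)) {
        cc <- cc[order(cc$start), ]
        w <- cc$end - cc$start + 1L
        if (strand == "-") {
          prev <- rev(cumsum(rev(c(w[-1], 0L))))
        } else {
          prev <- cumsum(c(0L, w[-length(w)]))
        }
        phase <- (3L - prev %% 3L) %% 3L
        blk <- c(blk, row9(chr, "CDS", cc$start, cc$end, strand,
                           as.character(phase), sprintf("Parent=%s", gid)))
      }
    }
    blocks[[k]] <- blk
  }
  writeLines(c("##gff-version 3", unlist(blocks)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# RepeatMasker .out
# ---------------------------------------------------------------------------

#' Read a RepeatMasker `.out`-style annotation
#'
#' Whitespace-delimited dialect with two header lines and one row per
#' repeat hit. Parses the query chromosome, begin/end, repeat
#' class/family label, and the percent-divergence column (Kimura % when
#' the file carries divergence annotation).
#'
#' @param path `.out` file.
#' @return `data.frame` with `chromosome`, `start`, `end`, `class_label`,
#'   `divergence_pct` (`NA` when non-numeric in the file).
#' @export
read_repeatmasker_out <- function(path) {
  raw <- readLines(path)
  out <- list()
  for (i in seq_along(raw)) {
    line <- trimws(raw[i])
    if (nchar(line) == 0) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (grepl("SW|score|perc|query", tok[1], ignore.case = TRUE) ||
        is.na(suppressWarnings(as.numeric(tok[1])))) {
      if (i <= 3) next  # header block
      stop(sprintf("unparsable repeat row at line %d of %s", i, path))
    }
    if (length(tok) < 11) {
      stop(sprintf("too few columns at line %d of %s", i, path))
    }
    begin <- suppressWarnings(as.integer(tok[6]))
    end <- suppressWarnings(as.integer(tok[7]))
    if (is.na(begin) || is.na(end)) {
      stop(sprintf("non-numeric begin/end at line %d of %s", i, path))
    }
    div <- suppressWarnings(as.numeric(tok[2]))
    out[[length(out) + 1L]] <- data.frame(
      chromosome = tok[5], start = begin, end = end,
      class_label = normalize_repeat_class(tok[11]),
      divergence_pct = div, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), class_label = character(),
                      divergence_pct = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# "order/superfamily" normalisation: keep at most two path components.
normalize_repeat_class <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(min(2L, length(p)))],
                                  collapse = "/"), character(1))
}

#' Write repeats in the RepeatMasker `.out` dialect
#' @param repeats `data.frame` as in [genome_bundle()].
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin end    (left)   C     repeat         class/family      begin  end (left)    ID",
    "")
  rows <- character(0)
  if (nrow(repeats)) {
    repeats <- repeats[order(repeats$chromosome, repeats$start,
                             repeats$end), , drop = FALSE]
    div <- ifelse(is.na(repeats$divergence_pct), "*",
                  sprintf("%.1f", repeats$divergence_pct))
    len <- repeats$end - repeats$start + 1L
    rows <- sprintf(
      "1000 %s 0.0 0.0 %s %d %d (0) + %s %s 1 %d (0) %d",
      div, repeats$chromosome, repeats$start, repeats$end,
      sub("/.*$", "", repeats$class_label), repeats$class_label, len,
      seq_len(nrow(repeats)))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene family table
# ---------------------------------------------------------------------------

#' Read a gene-family membership table
#'
#' TSV with columns `family_id`, `species_or_group`, `gene_id`. Duplicate
#' rows are collapsed; a gene listed under two different families is an
#' error (families must partition genes).
#'
#' @param path TSV file.
#' @return `data.frame` with the three columns, duplicates removed.
#' @export
read_family_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("family_id", "species_or_group", "gene_id")
  if (!all(need %in% names(df))) {
    stop("family table must have columns: ", paste(need, collapse = ", "))
  }
  df <- unique(df[, need])
  nfam <- tapply(df$family_id, df$gene_id, function(x) length(unique(x)))
  if (any(nfam > 1)) {
    stop("gene(s) assigned to more than one family: ",
         paste(head(names(nfam)[nfam > 1], 5), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a gene-family membership table
#' @param families `data.frame` with `family_id`, `gene_id` and optionally
#'   `species_or_group` (defaults to "focal").
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_family_table <- function(families, path) {
  if (is.null(families$species_or_group)) families$species_or_group <- "focal"
  df <- unique(families[, c("family_id", "species_or_group", "gene_id")])
  df <- df[order(df$family_id, df$species_or_group, df$gene_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature matrices
# ---------------------------------------------------------------------------

#' Write a feature matrix as deterministic TSV
#'
#' Column order is preserved, rows are sorted lexicographically over all
#' columns, and doubles are formatted losslessly, so the output is
#' byte-identical across reruns and `read_feature_matrix(write(x))`
#' recovers `x` exactly (up to row order).
#'
#' @param records `data.frame` (may have zero rows).
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_feature_matrix <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records <- records[order_rows(records), , drop = FALSE]
  fmt <- as.data.frame(lapply(records, format_lossless),
                       stringsAsFactors = FALSE, optional = TRUE)
  names(fmt) <- names(records)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    writeLines(do.call(paste, c(unname(as.list(fmt)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV file.
#' @return `data.frame` with column types restored by `type.convert`.
#' @export
read_feature_matrix <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Small genomic accessors shared by the analysis modules
# ---------------------------------------------------------------------------

#' Introns of a gene model
#'
#' Gaps between consecutive exons of the model, in genomic order.
#'
#' @param exons `data.frame` of this gene's exons (`start`, `end`).
#' @return `data.frame` with `start`, `end` (possibly zero rows).
#' @export
gene_introns <- function(exons) {
  e <- exons[order(exons$start), , drop = FALSE]
  if (nrow(e) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L)
}

# Extract genomic sequence (forward-strand coordinates); strand "-" returns
# the reverse complement. subseq keeps this O(slice), not O(chromosome).
fetch_sequence <- function(bundle, chromosome, start, end, strand = "+") {
  chr <- bundle$sequences[[chromosome]]
  s <- as.character(Biostrings::subseq(chr, max(1L, start),
                                       min(length(chr), end)))
  if (strand == "-") revcomp(s) else s
}

# Spliced CDS sequence of a gene in reading orientation.
gene_cds_sequence <- function(bundle, gene_id) {
  g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
  if (nrow(g) == 0) stop("unknown gene ", gene_id)
  cc <- bundle$cds[bundle$cds$gene_id == gene_id, , drop = FALSE]
  cc <- cc[order(cc$start), ]
  parts <- vapply(seq_len(nrow(cc)), function(i)
    fetch_sequence(bundle, g$chromosome, cc$start[i], cc$end[i]), "")
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp(s) else s
}
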