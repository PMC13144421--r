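# ---------------------------------------------------------------------------
# Pseudogene detection and classification.
#
# High-confidence parent genes (similarity > 40%, query/subject coverage
# > 50% against a curated protein set) are aligned against candidate
# loci: (a) the syntenic interval opposite each parent (its positional
# homoeolog, or the expected interval between flanking anchors when the
# homoeolog is lost) and (b) annotation-free windows seeded by exact
# k-mer matches of the parent CDS. Disablements (premature stops,
# frameshifts, polyA tails) are called from the alignment and loci are
# classified DUP / FRAG / PSSD. Fractionation of each gene is the
# uncovered fraction of its CDS relative to the homoeologous locus.
# ---------------------------------------------------------------------------

#' Parent-gene eligibility rule
#'
#' Strict thresholds: identity > 40 percent AND query coverage > 50
#' percent AND subject coverage > 50 percent.
#'
#' @param identity Percent amino-acid identity over the aligned region.
#' @param query_coverage,subject_coverage Aligned fractions in `[0, 1]`.
#' @return Logical vector.
#' @export
parent_eligible <- function(identity, query_coverage, subject_coverage) {
  identity > 40 & query_coverage > 0.5 & subject_coverage > 0.5
}

# Translate to the first stop; direct GENETIC_CODE lookup (ambiguous or
# partial codons become X).
translate_cds <- function(s) {
  n <- (nchar(s) %/% 3L) * 3L
  if (n < 3) return("")
  codons <- substring(toupper(s), seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  sub("\\*.*$", "", paste(aa, collapse = ""))
}

#' Select high-confidence parent genes
#'
#' Aligns each predominant gene's translated CDS against the curated
#' reference protein of its family and applies [parent_eligible()].
#'
#' @param bundle A `GenomeBundle`.
#' @param curated_proteins `AAStringSet` named by family id.
#' @return `data.frame` gene_id, family_id, identity, query_coverage,
#'   subject_coverage, eligible. Ineligible genes are retained as
#'   non-parents.
#' @export
select_parents <- function(bundle, curated_proteins) {
  if (length(curated_proteins) == 0) {
    stop("curated protein set must not be empty")
  }
  genes <- bundle$genes[bundle$genes$is_predominant, ]
  mat <- blosum62()
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    fam <- genes$family_id[i]
    res <- data.frame(gene_id = gid, family_id = fam,
                      identity = NA_real_, query_coverage = NA_real_,
                      subject_coverage = NA_real_, eligible = FALSE,
                      stringsAsFactors = FALSE)
    if (is.na(fam) || !(fam %in% names(curated_proteins))) return(res)
    prot <- translate_cds(gene_cds_sequence(bundle, gid))
    ref <- as.character(curated_proteins[[fam]])
    if (nchar(prot) < 10 || nchar(ref) < 10) return(res)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot), Biostrings::AAString(ref),
      type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
    pr <- Biostrings::pattern(aln)
    sr <- Biostrings::subject(aln)
    res$identity <- Biostrings::pid(aln)
    res$query_coverage <-
      (Biostrings::end(pr) - Biostrings::start(pr) + 1L) / nchar(prot)
    res$subject_coverage <-
      (Biostrings::end(sr) - Biostrings::start(sr) + 1L) / nchar(ref)
    res$eligible <- parent_eligible(res$identity, res$query_coverage,
                                    res$subject_coverage)
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# -- alignment core ---------------------------------------------------------

DEFAULT_SCORING <- list(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2)

.scan_cache <- new.env(parent = emptyenv())

nt_submat <- function(scoring) {
  key <- paste0("nt_", scoring$match, "_", scoring$mismatch)
  if (is.null(.scan_cache[[key]])) {
    .scan_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  }
  .scan_cache[[key]]
}

blosum62 <- function() {
  if (is.null(.scan_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .scan_cache$BLOSUM62 <- e$BLOSUM62
  }
  .scan_cache$BLOSUM62
}

#' Affine-gap local alignment of a parent CDS against a locus
#'
#' Smith-Waterman with affine gaps (gap of length L costs
#' `gap_open + gap_ext * L`); default scoring match +2, mismatch -3, gap
#' open -5, gap extend -2. When `segment_lengths` is supplied the CDS is
#' aligned segment-wise (one local alignment per CDS segment, constrained
#' to advance along the locus), which lets multi-exon parents align
#' across intron-sized gaps that a single affine chain would not bridge.
#'
#' @param parent_cds Spliced CDS string (reading orientation).
#' @param locus_sequence Genomic locus string (forward strand).
#' @param segment_lengths Optional CDS segment (exon) lengths in reading
#'   order; `NULL` aligns the CDS as one segment.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param both_strands `TRUE` always tries the reverse complement of the
#'   locus too, `FALSE` never, `"auto"` only when the forward alignment
#'   is weak (coverage < 0.9); the better total score wins.
#' @param min_segment_score Segments scoring below this are left
#'   unaligned.
#' @return List: `score`, `coverage` (aligned parent bp / CDS length),
#'   `identity` (percent over aligned columns), `strand`, `segments`
#'   (per-segment data.frame with parent/subject ranges), `indels`
#'   (widths of sub-intron gaps), `n_premature_stops`, `n_frameshifts`,
#'   `has_polyA`, `contiguous`, `subject_start`, `subject_end`.
#' @export
align_parent_to_locus <- function(parent_cds, locus_sequence,
                                  segment_lengths = NULL,
                                  scoring = DEFAULT_SCORING,
                                  both_strands = TRUE,
                                  min_segment_score = 30) {
  if (nchar(parent_cds) == 0 || nchar(locus_sequence) == 0) {
    stop("empty sequence")
  }
  if (is.null(segment_lengths)) segment_lengths <- nchar(parent_cds)
  if (sum(segment_lengths) != nchar(parent_cds)) {
    stop("segment lengths must sum to the CDS length")
  }
  fwd <- align_spliced_one(parent_cds, locus_sequence, segment_lengths,
                           scoring, min_segment_score)
  best <- fwd
  best$strand <- "+"
  try_rev <- isTRUE(both_strands) ||
    (identical(both_strands, "auto") && fwd$coverage < 0.9)
  if (try_rev) {
    rev <- align_spliced_one(parent_cds, revcomp(locus_sequence),
                             segment_lengths, scoring, min_segment_score)
    if (rev$score > fwd$score) {
      best <- rev
      best$strand <- "-"
    }
  }
  best
}

align_spliced_one <- function(parent_cds, locus, segment_lengths, scoring,
                              min_segment_score, min_intron = 30L) {
  mat <- nt_submat(scoring)
  offs <- cumsum(c(0L, head(segment_lengths, -1)))
  n_seg <- length(segment_lengths)
  cds_len <- nchar(parent_cds)
  empty_segs <- data.frame(segment = integer(), parent_start = integer(),
                           parent_end = integer(),
                           subject_start = integer(),
                           subject_end = integer(), score = numeric())
  seg_str <- substring(parent_cds, offs + 1L, offs + segment_lengths)
  use <- which(nchar(seg_str) >= 8L)
  if (nchar(locus) < 8L || length(use) == 0L) {
    segs <- empty_segs
    sel <- integer(0)
    aln <- NULL
  } else {
    # one vectorised call: every CDS segment against the whole locus
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seg_str[use]), Biostrings::DNAString(locus),
      type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    sc <- Biostrings::score(aln)
    pr <- Biostrings::pattern(aln)
    su <- Biostrings::subject(aln)
    segs <- data.frame(
      segment = use,
      parent_start = offs[use] + Biostrings::start(pr),
      parent_end = offs[use] + Biostrings::end(pr),
      subject_start = Biostrings::start(su),
      subject_end = Biostrings::end(su),
      score = sc)
    ok <- which(sc >= min_segment_score)
    # colinear chain of segments: maximise total score subject to
    # strictly advancing subject positions (small overlaps tolerated)
    sel <- integer(0)
    if (length(ok)) {
      o <- ok[order(segs$segment[ok])]
      n <- length(o)
      best <- segs$score[o]
      prev <- rep(0L, n)
      for (i in seq_len(n)[-1]) {
        for (j in seq_len(i - 1)) {
          compat <- segs$subject_start[o[i]] >
            segs$subject_start[o[j]] &&
            segs$subject_end[o[i]] > segs$subject_end[o[j]] &&
            segs$subject_start[o[i]] >= segs$subject_end[o[j]] - 10L
          if (compat && best[j] + segs$score[o[i]] > best[i]) {
            best[i] <- best[j] + segs$score[o[i]]
            prev[i] <- j
          }
        }
      }
      i <- which.max(best)
      while (i > 0L) {
        sel <- c(o[i], sel)
        i <- prev[i]
      }
    }
  }
  tot_score <- 0
  aligned_bp <- 0L
  match_cols <- 0L
  aligned_cols <- 0L
  n_stops <- 0L
  n_fs <- 0L
  indels <- integer(0)
  if (length(sel)) {
    pat_all <- as.character(Biostrings::pattern(aln))
    sub_all <- as.character(Biostrings::subject(aln))
    for (i in sel) {
      k <- match(i, use)
      pat <- strsplit(pat_all[k], "")[[1]]
      sub <- strsplit(sub_all[k], "")[[1]]
      st <- count_disablements_cols(pat, sub,
                                    segs$parent_start[segs$segment == i] - 1L,
                                    cds_len)
      n_stops <- n_stops + st$n_stops
      gw <- st$gap_widths
      n_fs <- n_fs + sum(gw < min_intron & gw %% 3L != 0L)
      indels <- c(indels, gw[gw < min_intron])
      tot_score <- tot_score + segs$score[segs$segment == i]
      aligned_bp <- aligned_bp + sum(pat != "-")
      match_cols <- match_cols + sum(pat == sub & pat != "-")
      aligned_cols <- aligned_cols + length(pat)
    }
  }
  segs <- segs[segs$segment %in% sel, , drop = FALSE]
  rownames(segs) <- NULL
  inter_gaps <- if (nrow(segs) > 1) {
    segs$subject_start[-1] - segs$subject_end[-nrow(segs)] - 1L
  } else integer(0)
  contiguous <- nrow(segs) > 0 &&
    all(c(inter_gaps, indels) < min_intron)
  has_polyA <- FALSE
  if (nrow(segs) > 0) {
    tail_start <- segs$subject_end[nrow(segs)] + 1L
    tail_seq <- substr(locus, tail_start,
                       min(nchar(locus), tail_start + 49L))
    has_polyA <- detect_polyA(tail_seq)
  }
  list(score = tot_score,
       coverage = aligned_bp / cds_len,
       identity = if (aligned_cols > 0) 100 * match_cols / aligned_cols
         else NA_real_,
       segments = segs,
       indels = indels,
       n_premature_stops = n_stops,
       n_frameshifts = n_fs,
       has_polyA = has_polyA,
       contiguous = contiguous,
       subject_start = if (nrow(segs)) min(segs$subject_start) else NA,
       subject_end = if (nrow(segs)) max(segs$subject_end) else NA)
}

# Walk aligned columns in the parent reading frame: a locus triplet aligned
# to a complete parent codon (no gaps on either side) that is a stop codon,
# strictly before the parent's own stop, is a premature stop. Gap runs are
# returned for frameshift counting.
count_disablements_cols <- function(pat, sub, parent_offset, cds_len) {
  n_stops <- 0L
  gap_widths <- integer(0)
  run <- 0L
  parent_pos <- parent_offset
  codon_sub <- character(3)
  codon_ok <- TRUE
  last_codon <- cds_len %/% 3L  # 1-based index of the parent stop codon
  for (i in seq_along(pat)) {
    gap <- pat[i] == "-" || sub[i] == "-"
    if (gap) {
      run <- run + 1L
    } else if (run > 0L) {
      gap_widths <- c(gap_widths, run)
      run <- 0L
    }
    if (pat[i] != "-") {
      parent_pos <- parent_pos + 1L
      ph <- (parent_pos - 1L) %% 3L + 1L
      if (ph == 1L) codon_ok <- TRUE
      if (sub[i] == "-") codon_ok <- FALSE else codon_sub[ph] <- sub[i]
      if (ph == 3L && codon_ok) {
        codon_idx <- (parent_pos - 1L) %/% 3L + 1L
        if (codon_idx < last_codon &&
            paste(codon_sub, collapse = "") %in% STOP_CODONS) {
          n_stops <- n_stops + 1L
        }
      }
    } else {
      codon_ok <- FALSE
    }
  }
  if (run > 0L) gap_widths <- c(gap_widths, run)
  list(n_stops = n_stops, gap_widths = gap_widths)
}

# polyA rule: some 30-bp window in the 50 bp downstream of the alignment
# end contains >= 24 adenines.
detect_polyA <- function(tail_seq, window = 30L, min_a = 24L) {
  n <- nchar(tail_seq)
  if (n < min_a) return(FALSE)
  ch <- strsplit(toupper(tail_seq), "")[[1]] == "A"
  w <- min(window, n)
  cs <- cumsum(c(0L, ch))
  any(cs[(w + 1L):(n + 1L)] - cs[seq_len(n - w + 1L)] >= min_a)
}

#' Call disablements from an alignment
#'
#' Convenience accessor over [align_parent_to_locus()] output: premature
#' stops (in-frame stop codons strictly before the parent's stop),
#' frameshifts (sub-intron indels with length not divisible by 3) and
#' polyA evidence (>= 24 A in a 30-bp window within 50 bp downstream of
#' the alignment end).
#'
#' @param alignment Result of [align_parent_to_locus()].
#' @return List `n_premature_stops`, `n_frameshifts`, `has_polyA`.
#' @export
call_disablements <- function(alignment) {
  alignment[c("n_premature_stops", "n_frameshifts", "has_polyA")]
}

#' Classify a pseudogene call
#'
#' PSSD (processed/retrotransposed) when polyA evidence is present or at
#' least two CDS segments of a multi-exon parent align contiguously
#' (intron loss); otherwise FRAG (highly fragmented: coverage < 0.5 with
#' amino-acid-level identity >= 40 percent); otherwise DUP (duplicated
#' pseudogene retaining gene structure).
#'
#' @param coverage Aligned fraction of the parent CDS.
#' @param identity Percent identity over aligned columns.
#' @param has_polyA,contiguous Evidence flags from the alignment.
#' @param n_parent_segments Number of CDS segments of the parent.
#' @param n_aligned_segments CDS segments actually aligned; intron loss
#'   can only be evidenced when >= 2 segments align back to back.
#' @param frag_coverage_threshold FRAG coverage cutoff (default 0.5).
#' @return `"PSSD"`, `"FRAG"` or `"DUP"`.
#' @export
classify_pseudogene <- function(coverage, identity, has_polyA, contiguous,
                                n_parent_segments,
                                n_aligned_segments = n_parent_segments,
                                frag_coverage_threshold = 0.5) {
  if (isTRUE(has_polyA) ||
      (n_parent_segments >= 2L && n_aligned_segments >= 2L &&
         isTRUE(contiguous))) {
    return("PSSD")
  }
  if (coverage < frag_coverage_threshold && identity >= 40) return("FRAG")
  "DUP"
}

# -- candidate discovery ----------------------------------------------------

# Exact k-mer seed matches of parent CDSs in annotation-free genome
# windows, clustered into candidate loci per (parent, chromosome).
candidate_windows <- function(bundle, parent_cds, seed_width = 13L,
                              seed_step = 8L, cluster_gap = 2000L,
                              pad = 400L, gene_margin = 50L,
                              min_seeds = 2L) {
  seeds <- list()
  for (gid in names(parent_cds)) {
    s <- parent_cds[[gid]]
    if (nchar(s) < seed_width) next
    st <- seq(1L, nchar(s) - seed_width + 1L, by = seed_step)
    seeds[[gid]] <- substring(s, st, st + seed_width - 1L)
  }
  if (!length(seeds)) return(NULL)
  all_seeds <- unlist(seeds, use.names = FALSE)
  owner <- rep(names(seeds), lengths(seeds))
  keep <- !grepl("[^ACGT]", all_seeds)
  all_seeds <- all_seeds[keep]; owner <- owner[keep]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_seeds))
  gene_iv <- split(IRanges::IRanges(pmax(1L, bundle$genes$start - gene_margin),
                                    bundle$genes$end + gene_margin),
                   bundle$genes$chromosome)
  hits <- list()
  for (chrom in names(bundle$sequences)) {
    chr <- bundle$sequences[[chrom]]
    L <- length(chr)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") chr else Biostrings::reverseComplement(chr)
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0) next
      pos <- IRanges::start(BiocGenerics::unlist(m, use.names = FALSE))
      who <- rep(owner, cnt)
      if (strand == "-") pos <- L - (pos + seed_width - 1L) + 1L
      iv <- IRanges::IRanges(pos, pos + seed_width - 1L)
      if (chrom %in% names(gene_iv)) {
        ov <- IRanges::overlapsAny(iv, gene_iv[[chrom]])
        pos <- pos[!ov]; who <- who[!ov]
      }
      if (length(pos)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chromosome = chrom, parent = who, pos = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  out <- list()
  for (grp in split(hits, paste(hits$chromosome, hits$parent))) {
    p <- sort(unique(grp$pos))
    brk <- c(0L, which(diff(p) > cluster_gap), length(p))
    for (j in seq_len(length(brk) - 1L)) {
      seg <- p[(brk[j] + 1L):brk[j + 1L]]
      if (length(seg) < min_seeds) next  # chance k-mer hits arrive alone
      out[[length(out) + 1L]] <- data.frame(
        chromosome = grp$chromosome[1], parent = grp$parent[1],
        start = max(1L, min(seg) - pad),
        end = max(seg) + seed_width - 1L + pad,
        n_seeds = length(seg), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Expected syntenic interval opposite a gene whose homoeolog is lost:
# spanned by the partners of the nearest linked genes on both flanks.
expected_interval <- function(map, bundle, gene_id, max_len = 60000L) {
  i <- which(map$gene_id == gene_id)
  if (!length(i)) return(NULL)
  chr <- map$chromosome[i]
  rnk <- map$rank[i]
  near <- map[map$chromosome == chr & !is.na(map$partner) &
                map$partner != "lost", , drop = FALSE]
  lo <- near[near$rank < rnk, , drop = FALSE]
  hi <- near[near$rank > rnk, , drop = FALSE]
  if (nrow(lo) == 0 || nrow(hi) == 0) return(NULL)
  p_lo <- lo$partner[which.max(lo$rank)]
  p_hi <- hi$partner[which.min(hi$rank)]
  g <- bundle$genes
  s_lo <- g[g$gene_id == p_lo, ]
  s_hi <- g[g$gene_id == p_hi, ]
  if (nrow(s_lo) == 0 || nrow(s_hi) == 0 ||
      s_lo$chromosome != s_hi$chromosome) return(NULL)
  start <- min(s_lo$start, s_hi$start)
  end <- max(s_lo$end, s_hi$end)
  if (end - start + 1L > max_len) return(NULL)
  list(chromosome = s_lo$chromosome, start = start, end = end)
}

# -- the scan driver --------------------------------------------------------

#' Scan a genome for pseudogenic loci
#'
#' Runs the full detection pipeline: candidate loci opposite each eligible
#' parent (positional homoeolog or expected lost interval) plus
#' seed-matched annotation-free windows; aligns the parent CDS
#' (segment-wise) to each locus; calls disablements; keeps loci with at
#' least one evidence item (stop, frameshift, polyA, or truncated
#' coverage) and classifies them DUP/FRAG/PSSD.
#'
#' @param bundle A `GenomeBundle`.
#' @param map A `HomoeologMap` from [homoeolog_map()].
#' @param parents Output of [select_parents()].
#' @param min_identity Minimum percent identity to keep a call.
#' @param coverage_evidence Coverage below this counts as truncation
#'   evidence (decayed structure).
#' @param min_call_score Minimum summed alignment score for a call;
#'   suppresses chance matches of short CDS stretches in empty intervals.
#' @param locus_pad Flank added around annotated partner loci.
#' @return `data.frame` of `PseudogeneCall`s (one row per locus) with
#'   attribute `syntenic_coverage`: per-parent coverage of its
#'   homoeologous locus (used for fractionation).
#' @export
scan_pseudogenes <- function(bundle, map, parents,
                             min_identity = 40,
                             coverage_evidence = 0.8,
                             min_call_score = 45,
                             locus_pad = 100L) {
  eligible <- parents$gene_id[parents$eligible]
  parent_cds <- setNames(
    lapply(eligible, function(g) gene_cds_sequence(bundle, g)), eligible)
  seg_lens <- setNames(lapply(eligible, function(g) {
    cc <- bundle$cds[bundle$cds$gene_id == g, , drop = FALSE]
    cc <- cc[order(cc$start), ]
    w <- cc$end - cc$start + 1L
    if (bundle$genes$strand[bundle$genes$gene_id == g][1] == "-") rev(w)
    else w
  }), eligible)
  genes <- bundle$genes
  calls <- list()
  syn_cov <- list()
  add_call <- function(parent, chrom, start, end, aln, route) {
    locus_start <- start + aln$subject_start - 1L
    locus_end <- start + aln$subject_end - 1L
    if (aln$strand == "-") {
      w <- end - start + 1L
      locus_start <- start + (w - aln$subject_end)
      locus_end <- start + (w - aln$subject_start)
    }
    calls[[length(calls) + 1L]] <<- data.frame(
      parent_id = parent, chromosome = chrom,
      start = locus_start, end = locus_end, strand = aln$strand,
      coverage = aln$coverage, identity = aln$identity,
      n_premature_stops = aln$n_premature_stops,
      n_frameshifts = aln$n_frameshifts, has_polyA = aln$has_polyA,
      contiguous = aln$contiguous,
      n_aligned_segments = nrow(aln$segments),
      score = aln$score, route = route,
      stringsAsFactors = FALSE)
  }

  # route A: syntenic loci opposite each parent. An annotated partner is
  # compared via its spliced CDS (intron loss is then evidenced by the
  # partner's own single-exon structure and a genomic polyA tail); a lost
  # partner is searched for in the expected genomic interval between the
  # partners of the flanking anchors.
  for (parent in eligible) {
    i <- which(map$gene_id == parent)
    if (!length(i)) next
    partner <- map$partner[i]
    if (is.na(partner)) next
    if (partner != "lost") {
      pg <- genes[genes$gene_id == partner, ]
      if (nrow(pg) == 0) next
      partner_cds <- gene_cds_sequence(bundle, partner)
      if (nchar(partner_cds) < 8) next
      aln <- align_parent_to_locus(parent_cds[[parent]], partner_cds,
                                   seg_lens[[parent]],
                                   both_strands = FALSE)
      syn_cov[[length(syn_cov) + 1L]] <- data.frame(
        gene_id = parent, partner = partner, coverage = aln$coverage,
        stringsAsFactors = FALSE)
      if (nrow(aln$segments) == 0) next
      partner_nex <- sum(bundle$cds$gene_id == partner)
      tail_seq <- if (pg$strand == "-") {
        fetch_sequence(bundle, pg$chromosome, pg$start - 50L,
                       pg$start - 1L, strand = "-")
      } else {
        fetch_sequence(bundle, pg$chromosome, pg$end + 1L, pg$end + 50L)
      }
      calls[[length(calls) + 1L]] <- data.frame(
        parent_id = parent, chromosome = pg$chromosome,
        start = pg$start, end = pg$end, strand = pg$strand,
        coverage = aln$coverage, identity = aln$identity,
        n_premature_stops = aln$n_premature_stops,
        n_frameshifts = aln$n_frameshifts,
        has_polyA = detect_polyA(tail_seq),
        contiguous = partner_nex == 1L,
        n_aligned_segments = nrow(aln$segments),
        score = aln$score, route = "syntenic",
        stringsAsFactors = FALSE)
    } else {
      win <- expected_interval(map, bundle, parent)
      if (is.null(win)) next
      locus <- fetch_sequence(bundle, win$chromosome, win$start, win$end)
      aln <- align_parent_to_locus(parent_cds[[parent]], locus,
                                   seg_lens[[parent]],
                                   both_strands = "auto")
      syn_cov[[length(syn_cov) + 1L]] <- data.frame(
        gene_id = parent, partner = partner, coverage = aln$coverage,
        stringsAsFactors = FALSE)
      if (nrow(aln$segments) == 0) next
      add_call(parent, win$chromosome, win$start, win$end, aln, "syntenic")
    }
  }

  # route B: annotation-free seed windows (retrocopies, stray residuals)
  wins <- candidate_windows(bundle, parent_cds)
  if (!is.null(wins)) {
    for (k in seq_len(nrow(wins))) {
      parent <- wins$parent[k]
      chrlen <- Biostrings::width(
        bundle$sequences[wins$chromosome[k]])
      s <- wins$start[k]
      e <- min(wins$end[k], chrlen)
      locus <- fetch_sequence(bundle, wins$chromosome[k], s, e)
      aln <- align_parent_to_locus(parent_cds[[parent]], locus,
                                   seg_lens[[parent]],
                                   both_strands = "auto")
      if (nrow(aln$segments) == 0) next
      add_call(parent, wins$chromosome[k], s, e, aln, "seed")
    }
  }

  empty <- data.frame(parent_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), coverage = numeric(),
                      identity = numeric(), n_premature_stops = integer(),
                      n_frameshifts = integer(), has_polyA = logical(),
                      contiguous = logical(), n_aligned_segments = integer(),
                      score = numeric(), route = character(),
                      class = character(), overlaps_gene_model = logical())
  syn_cov <- if (length(syn_cov)) do.call(rbind, syn_cov) else
    data.frame(gene_id = character(), partner = character(),
               coverage = numeric())
  if (!length(calls)) {
    attr(empty, "syntenic_coverage") <- syn_cov
    return(empty)
  }
  calls <- do.call(rbind, calls)

  # evidence rule: no pseudogene call without at least one evidence item
  evid <- calls$n_premature_stops + calls$n_frameshifts > 0 |
    calls$has_polyA | calls$coverage < coverage_evidence
  calls <- calls[evid & calls$identity >= min_identity &
                   calls$coverage >= 0.05 &
                   calls$score >= min_call_score, , drop = FALSE]

  # one call per locus: overlapping calls (e.g. both homoeologous family
  # members aligning to the same residual) keep the best-scoring parent
  if (nrow(calls) > 1) {
    keep <- rep(TRUE, nrow(calls))
    ord <- order(-calls$score)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      later <- ord[-seq_len(a)]
      dup <- later[calls$chromosome[later] == calls$chromosome[i] &
                     calls$start[later] <= calls$end[i] &
                     calls$end[later] >= calls$start[i]]
      keep[dup] <- FALSE
    }
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls) == 0) {
    attr(empty, "syntenic_coverage") <- syn_cov
    return(empty)
  }
  n_seg <- vapply(calls$parent_id, function(g) length(seg_lens[[g]]), 0L)
  calls$class <- vapply(seq_len(nrow(calls)), function(i)
    classify_pseudogene(calls$coverage[i], calls$identity[i],
                        calls$has_polyA[i], calls$contiguous[i], n_seg[i],
                        calls$n_aligned_segments[i]),
    "")
  ov <- rep(FALSE, nrow(calls))
  for (chrom in unique(calls$chromosome)) {
    ci <- which(calls$chromosome == chrom)
    gg <- genes[genes$chromosome == chrom, ]
    if (nrow(gg) == 0) next
    ov[ci] <- IRanges::overlapsAny(
      IRanges::IRanges(calls$start[ci], calls$end[ci]),
      IRanges::IRanges(gg$start, gg$end))
  }
  calls$overlaps_gene_model <- ov
  calls <- calls[order(calls$chromosome, calls$start, calls$parent_id), ]
  rownames(calls) <- NULL
  attr(calls, "syntenic_coverage") <- syn_cov
  calls
}

#' Fractionation relative to the corresponding homoeolog
#'
#' `fractionation_pct = 100 * (1 - covered)` where `covered` is the
#' fraction of the gene's CDS aligned by its homoeologous locus (the
#' partner gene, or the pseudogenic/residual locus opposite it); a fully
#' absent homoeolog gives 100; unplaced genes are flagged not computable
#' (`NA`).
#'
#' @param bundle A `GenomeBundle`.
#' @param map A `HomoeologMap`.
#' @param calls Output of [scan_pseudogenes()] (uses its
#'   `syntenic_coverage` attribute).
#' @return `data.frame` gene_id, homoeolog_id, fractionation_pct,
#'   computable.
#' @export
compute_fractionation <- function(bundle, map, calls) {
  syn <- attr(calls, "syntenic_coverage")
  out <- data.frame(gene_id = map$gene_id,
                    homoeolog_id = map$partner,
                    fractionation_pct = NA_real_,
                    computable = FALSE, stringsAsFactors = FALSE)
  cov_of <- setNames(syn$coverage, syn$gene_id)
  # at a lost locus only an evidence-backed call counts as residual
  # coverage; a weak chance alignment must not rescue a deleted homoeolog
  call_cov <- numeric(0)
  if (nrow(calls)) {
    syn_calls <- calls[calls$route == "syntenic", , drop = FALSE]
    if (nrow(syn_calls)) {
      call_cov <- tapply(syn_calls$coverage, syn_calls$parent_id, max)
    }
  }
  for (i in seq_len(nrow(out))) {
    partner <- out$homoeolog_id[i]
    if (is.na(partner)) next
    g <- out$gene_id[i]
    if (partner == "lost") {
      cov <- if (g %in% names(call_cov)) call_cov[[g]] else 0
      out$fractionation_pct[i] <- 100 * (1 - min(1, cov))
      out$computable[i] <- TRUE
    } else {
      cov <- if (g %in% names(cov_of)) cov_of[[g]] else NA_real_
      if (!is.na(cov)) {
        out$fractionation_pct[i] <- 100 * (1 - min(1, cov))
        out$computable[i] <- TRUE
      }
    }
  }
  out
}

#' Filter calls for haplotype confusion
#'
#' Drops pseudogene calls whose locus lacks alignment support from an
#' independent (secondary) assembly or shows deletions above a threshold
#' there, mimicking the screen for erroneous mixing/collapsing/switching
#' between haplotypes.
#'
#' @param calls Pseudogene call table.
#' @param support Optional `data.frame` with `chromosome`, `start`,
#'   `end`, `covered` (logical) and `max_deletion` (bp) for each locus;
#'   `NULL` is a no-op with a warning.
#' @param max_deletion Largest tolerated deletion in the secondary
#'   alignment.
#' @return Filtered calls; attribute `n_dropped` reports the count.
#' @export
screen_haplotype_confusion <- function(calls, support = NULL,
                                       max_deletion = 5000L) {
  if (is.null(support)) {
    warning("no secondary-assembly support supplied; calls left unfiltered")
    attr(calls, "n_dropped") <- 0L
    return(calls)
  }
  ok <- vapply(seq_len(nrow(calls)), function(i) {
    s <- support[support$chromosome == calls$chromosome[i] &
                   support$start <= calls$end[i] &
                   support$end >= calls$start[i], , drop = FALSE]
    nrow(s) > 0 && any(s$covered & s$max_deletion <= max_deletion)
  }, logical(1))
  res <- calls[ok, , drop = FALSE]
  attr(res, "syntenic_coverage") <- attr(calls, "syntenic_coverage")
  attr(res, "n_dropped") <- sum(!ok)
  res
}
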