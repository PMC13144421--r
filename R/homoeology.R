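# ---------------------------------------------------------------------------
# Homoeologous chromosome pairing and positional homoeolog linking.
#
# Collinearity is assessed in gene-rank space (genes ranked by start
# position along each chromosome), which is robust to the large physical
# size differences TE accumulation creates between homoeologous
# chromosomes. Same-family genes on different chromosomes seed candidate
# anchors; maximal monotone chains of anchors form synteny blocks;
# chromosomes are paired greedily by summed block score; within each pair
# the member carrying more repeat-masked bp is labelled H2.
# ---------------------------------------------------------------------------

#' Gene ranks along chromosomes
#'
#' Ranks predominant gene models by start coordinate within each
#' chromosome (1 = closest to the chromosome start).
#'
#' @param bundle A `GenomeBundle`.
#' @return `data.frame` gene_id, chromosome, rank.
#' @export
gene_ranks <- function(bundle) {
  g <- bundle$genes[bundle$genes$is_predominant, ]
  g <- g[order(g$chromosome, g$start, g$gene_id), ]
  rk <- stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along)
  data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
             rank = as.integer(rk), stringsAsFactors = FALSE)
}

#' Candidate anchors between chromosomes
#'
#' Every cross-chromosome pair of genes from the same family becomes a
#' candidate anchor, except members of promiscuous families with more
#' than `8 * ploidy` genes (the same overdispersion rule used for the
#' retention analysis), which would seed spurious chains.
#'
#' @param bundle A `GenomeBundle` with family assignments.
#' @param max_family_size Promiscuity cap; default `8 * ploidy`.
#' @return `data.frame` gene_a, gene_b, chrom_a, chrom_b, rank_a, rank_b
#'   with `chrom_a < chrom_b`.
#' @export
build_anchors <- function(bundle, max_family_size = 8L * bundle$ploidy) {
  rk <- gene_ranks(bundle)
  fam <- bundle$families[bundle$families$gene_id %in% rk$gene_id, ]
  sizes <- table(fam$family_id)
  fam <- fam[fam$family_id %in% names(sizes)[sizes <= max_family_size], ]
  info <- merge(fam, rk, by = "gene_id")
  out <- list()
  for (f in split(info, info$family_id)) {
    if (nrow(f) < 2) next
    idx <- utils::combn(nrow(f), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      if (f$chromosome[i] == f$chromosome[j]) next
      if (f$chromosome[i] > f$chromosome[j]) { tmp <- i; i <- j; j <- tmp }
      out[[length(out) + 1L]] <- data.frame(
        gene_a = f$gene_id[i], gene_b = f$gene_id[j],
        chrom_a = f$chromosome[i], chrom_b = f$chromosome[j],
        rank_a = f$rank[i], rank_b = f$rank[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      rank_a = integer(), rank_b = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom_a, res$chrom_b, res$rank_a, res$rank_b), ]
  rownames(res) <- NULL
  res
}

# Longest monotone chain (strictly increasing in rank_a; increasing or
# decreasing in rank_b per `direction`) with consecutive rank gaps at most
# `max_gap` on both axes. O(n^2) dynamic programme; returns member indices.
longest_chain <- function(rank_a, rank_b, direction, max_gap) {
  n <- length(rank_a)
  if (n == 0) return(integer(0))
  sgn <- if (direction == "same") 1 else -1
  L <- rep(1L, n)
  prev <- rep(0L, n)
  ord <- order(rank_a, sgn * rank_b)
  ra <- rank_a[ord]; rb <- sgn * rank_b[ord]
  for (i in seq_len(n)[-1]) {
    ok <- which(ra[seq_len(i - 1)] < ra[i] &
                  rb[seq_len(i - 1)] < rb[i] &
                  ra[i] - ra[seq_len(i - 1)] <= max_gap &
                  abs(rb[i] - rb[seq_len(i - 1)]) <= max_gap)
    if (length(ok)) {
      j <- ok[which.max(L[ok])]
      L[i] <- L[j] + 1L
      prev[i] <- j
    }
  }
  i <- which.max(L)
  chain <- integer(0)
  while (i > 0) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  ord[chain]
}

#' Chain anchors into synteny blocks
#'
#' Iteratively extracts maximal monotone chains (same or inverted
#' orientation) under a rank-gap constraint; each anchor joins at most one
#' block and chains shorter than `min_block_size` are discarded.
#'
#' @param anchors Output of [build_anchors()].
#' @param min_block_size Minimum anchors per block (default 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return `data.frame` of anchors annotated with `block_id` and
#'   `orientation`; blocks numbered per chromosome pair in decreasing
#'   score order.
#' @export
chain_blocks <- function(anchors, min_block_size = 5L, max_rank_gap = 25L) {
  empty <- cbind(anchors[0, ],
                 data.frame(block_id = character(), orientation = character(),
                            score = integer()))
  if (nrow(anchors) == 0) return(empty)
  out <- list()
  for (ap in split(anchors, paste(anchors$chrom_a, anchors$chrom_b))) {
    remaining <- ap
    bnum <- 0L
    repeat {
      up <- longest_chain(remaining$rank_a, remaining$rank_b, "same",
                          max_rank_gap)
      dn <- longest_chain(remaining$rank_a, remaining$rank_b, "inverted",
                          max_rank_gap)
      if (length(up) >= length(dn)) {
        idx <- up; orient <- "same"
      } else {
        idx <- dn; orient <- "inverted"
      }
      if (length(idx) < min_block_size) break
      bnum <- bnum + 1L
      blk <- remaining[idx, ]
      blk$block_id <- sprintf("%s|%s|%02d", blk$chrom_a[1], blk$chrom_b[1],
                              bnum)
      blk$orientation <- orient
      blk$score <- length(idx)
      out[[length(out) + 1L]] <- blk
      remaining <- remaining[-idx, ]
      if (nrow(remaining) == 0) break
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$block_id, res$rank_a), ]
  rownames(res) <- NULL
  res
}

#' Pair homoeologous chromosomes
#'
#' Greedy maximum-weight matching on the summed block scores between each
#' chromosome pair; ties broken by chromosome name order. Unmatched
#' chromosomes are reported in the `unpaired` attribute, not an error.
#'
#' @param blocks Output of [chain_blocks()].
#' @param chromosomes Optional full chromosome set (so block-less
#'   chromosomes are reported unpaired).
#' @return `data.frame` chrom_a, chrom_b, weight; attribute `unpaired`.
#' @export
pair_chromosomes <- function(blocks, chromosomes = NULL) {
  if (nrow(blocks) == 0) {
    res <- data.frame(chrom_a = character(), chrom_b = character(),
                      weight = numeric())
    attr(res, "unpaired") <- chromosomes %||% character(0)
    return(res)
  }
  w <- aggregate(score ~ chrom_a + chrom_b,
                 data = unique(blocks[, c("chrom_a", "chrom_b", "block_id",
                                          "score")]),
                 FUN = sum)
  w <- w[order(-w$score, w$chrom_a, w$chrom_b), ]
  used <- character(0)
  keep <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    if (w$chrom_a[i] %in% used || w$chrom_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, w$chrom_a[i], w$chrom_b[i])
  }
  res <- w[keep, c("chrom_a", "chrom_b", "score")]
  names(res)[3] <- "weight"
  res <- res[order(res$chrom_a), ]
  rownames(res) <- NULL
  all_chr <- unique(c(chromosomes, blocks$chrom_a, blocks$chrom_b))
  attr(res, "unpaired") <- setdiff(all_chr, used)
  res
}

#' Assign H1/H2 labels to chromosome pairs
#'
#' Within each pair the member with the larger merged repeat-covered bp is
#' labelled H2 (the repeat-affected group), the other H1; equal coverage
#' falls back to lexicographic name order (smaller name = H1). The
#' H1/H2 polarity is a fixed convention; downstream statistics are
#' label-swap invariant.
#'
#' @param pairs Output of [pair_chromosomes()].
#' @param repeats Repeat `data.frame` (`chromosome`, `start`, `end`).
#' @return `data.frame` chr_h1, chr_h2, repeat_bp_h1, repeat_bp_h2.
#' @export
assign_groups <- function(pairs, repeats) {
  rep_bp <- function(chr) {
    r <- repeats[repeats$chromosome == chr, , drop = FALSE]
    merged_interval_bp(r$start, r$end)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$chrom_a[i]; b <- pairs$chrom_b[i]
    ba <- rep_bp(a); bb <- rep_bp(b)
    if (bb > ba || (bb == ba && a < b)) {
      data.frame(chr_h1 = a, chr_h2 = b, repeat_bp_h1 = ba,
                 repeat_bp_h2 = bb, stringsAsFactors = FALSE)
    } else {
      data.frame(chr_h1 = b, chr_h2 = a, repeat_bp_h1 = bb,
                 repeat_bp_h2 = ba, stringsAsFactors = FALSE)
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chr_h1 = character(), chr_h2 = character(),
               repeat_bp_h1 = numeric(), repeat_bp_h2 = numeric())
  res <- res[order(res$chr_h1), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Link positional homoeologs
#'
#' Genes joined by an anchor inside a block are linked; a gene lying
#' strictly inside a block (anchors on both flanks) whose family has no
#' partner in the syntenic interval is linked to `"lost"`; all remaining
#' genes are unplaced (non-syntenic).
#'
#' @param blocks Output of [chain_blocks()].
#' @param bundle The `GenomeBundle`.
#' @param groups Output of [assign_groups()] (H1/H2 labelled pairs).
#' @return Object of class `HomoeologMap`: `data.frame` gene_id,
#'   chromosome, group (H1/H2/unplaced), partner (gene_id, `"lost"`, or
#'   `NA` for unplaced); plus the `pairs` attribute.
#' @export
link_positional_homoeologs <- function(blocks, bundle, groups) {
  rk <- gene_ranks(bundle)
  group_of <- c(setNames(rep("H1", nrow(groups)), groups$chr_h1),
                setNames(rep("H2", nrow(groups)), groups$chr_h2))
  paired_with <- c(setNames(groups$chr_h2, groups$chr_h1),
                   setNames(groups$chr_h1, groups$chr_h2))
  map <- data.frame(gene_id = rk$gene_id, chromosome = rk$chromosome,
                    rank = rk$rank, stringsAsFactors = FALSE)
  map$group <- group_of[map$chromosome]
  map$group[is.na(map$group)] <- "unplaced"
  map$partner <- NA_character_

  # anchors within retained blocks that connect a labelled pair
  pair_key <- paste(pmin(groups$chr_h1, groups$chr_h2),
                    pmax(groups$chr_h1, groups$chr_h2))
  blk <- blocks[paste(blocks$chrom_a, blocks$chrom_b) %in% pair_key, ,
                drop = FALSE]
  # one partner per gene: prefer the anchor inside the highest-score block
  blk <- blk[order(-blk$score, blk$block_id), ]
  seen_a <- seen_b <- character(0)
  for (i in seq_len(nrow(blk))) {
    ga <- blk$gene_a[i]; gb <- blk$gene_b[i]
    if (ga %in% seen_a || gb %in% seen_b) next
    map$partner[map$gene_id == ga] <- gb
    map$partner[map$gene_id == gb] <- ga
    seen_a <- c(seen_a, ga); seen_b <- c(seen_b, gb)
  }

  # "lost" calls: unlinked genes strictly inside a block footprint whose
  # family is absent from the opposite syntenic interval
  fam_of <- setNames(bundle$families$family_id, bundle$families$gene_id)
  rank_of <- setNames(rk$rank, rk$gene_id)
  chrom_rk <- split(rk, rk$chromosome)
  for (i in which(is.na(map$partner) & map$group != "unplaced")) {
    g <- map$gene_id[i]
    chr <- map$chromosome[i]
    other <- paired_with[[chr]]
    cand <- blk[(blk$chrom_a == chr & blk$chrom_b == other) |
                  (blk$chrom_b == chr & blk$chrom_a == other), ,
                drop = FALSE]
    if (nrow(cand) == 0) next
    a_side <- cand$chrom_a[1] == chr
    r_self <- if (a_side) cand$rank_a else cand$rank_b
    r_oth <- if (a_side) cand$rank_b else cand$rank_a
    inside <- any(r_self < map$rank[i]) && any(r_self > map$rank[i])
    if (!inside) next
    # opposite syntenic interval: partner ranks of the flanking anchors
    lo <- max(which(r_self < map$rank[i]))
    hi <- min(which(r_self > map$rank[i]))
    rng <- sort(c(r_oth[lo], r_oth[hi]))
    fam <- fam_of[[g]]
    if (is.null(fam) || is.na(fam)) next
    members <- bundle$families$gene_id[bundle$families$family_id == fam]
    opp <- chrom_rk[[other]]
    present <- any(opp$gene_id %in% members &
                     opp$rank >= rng[1] & opp$rank <= rng[2])
    if (!present) map$partner[i] <- "lost"
  }
  map$group[map$group != "unplaced" & is.na(map$partner) &
              !(map$chromosome %in% names(paired_with))] <- "unplaced"
  res <- map[, c("gene_id", "chromosome", "rank", "group", "partner")]
  attr(res, "pairs") <- groups
  class(res) <- c("HomoeologMap", "data.frame")
  res
}

#' Full homoeolog-mapping pipeline
#'
#' [build_anchors()] -> [chain_blocks()] -> [pair_chromosomes()] ->
#' [assign_groups()] -> [link_positional_homoeologs()].
#'
#' @param bundle A `GenomeBundle`.
#' @param min_block_size,max_rank_gap Chaining parameters.
#' @return A `HomoeologMap`.
#' @export
homoeolog_map <- function(bundle, min_block_size = 5L, max_rank_gap = 25L) {
  anchors <- build_anchors(bundle)
  blocks <- chain_blocks(anchors, min_block_size, max_rank_gap)
  pairs <- pair_chromosomes(blocks, names(bundle$sequences))
  groups <- assign_groups(pairs, bundle$repeats)
  link_positional_homoeologs(blocks, bundle, groups)
}
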