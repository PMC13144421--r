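# ---------------------------------------------------------------------------
# Kimura 2-parameter divergence and copy-divergence repeat landscapes.
# ---------------------------------------------------------------------------

#' Kimura 2-parameter distance from substitution proportions
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with transition
#' proportion `P` and transversion proportion `Q`. Outside the estimable
#' region (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined
#' and an explicit "saturated" error is raised rather than returning NaN.
#'
#' @param P,Q Transition / transversion proportions in `[0, 1)`.
#' @return Kimura distance in substitutions per site.
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0 | Q < 0 | P >= 1 | Q >= 1)) {
    stop("P and Q must lie in [0, 1)")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0 | w2 <= 0)) {
    stop("saturated: sequences too diverged for the K2P estimator")
  }
  -0.5 * log(w1 * sqrt(w2))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Kimura 2-parameter divergence between aligned sequences
#'
#' Counts transitions (P) and transversions (Q) over ungapped,
#' unambiguous columns of an aligned pair (e.g. a repeat copy against its
#' consensus) and evaluates the K2P closed form.
#'
#' @param copy_sequence,consensus_sequence Equal-length aligned strings;
#'   `-`/`.` columns and non-ACGT letters are excluded.
#' @return List with `P`, `Q`, `K`, and `n_sites` (columns used).
#' @export
kimura2p <- function(copy_sequence, consensus_sequence) {
  a <- toupper(strsplit(copy_sequence, "")[[1]])
  b <- toupper(strsplit(consensus_sequence, "")[[1]])
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length")
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0) stop("no comparable columns")
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / length(a)
  Q <- sum(diff & !is_transition(a, b)) / length(a)
  list(P = P, Q = Q, K = k2p_distance(P, Q), n_sites = length(a))
}

#' Copy-divergence repeat landscape
#'
#' Bins repeat-covered bp by Kimura divergence (integer percent bins
#' `[k, k+1)`) per repeat class and normalises by the assembly length,
#' reproducing the classic interspersed-repeat landscape. Overlapping
#' repeats of the same class and bin are merged before summation;
#' features lacking divergence are excluded and counted.
#'
#' @param repeats Repeat `data.frame` (`chromosome`, `start`, `end`,
#'   `class_label`, `divergence_pct`).
#' @param genome_length Total assembly length in bp.
#' @param bin_width Bin width in percent (default 1).
#' @return `data.frame` class_label, kimura_bin, bp, genome_fraction;
#'   attribute `n_missing_divergence`.
#' @export
repeat_landscape <- function(repeats, genome_length, bin_width = 1) {
  miss <- is.na(repeats$divergence_pct)
  r <- repeats[!miss, , drop = FALSE]
  if (nrow(r) == 0) {
    out <- data.frame(class_label = character(), kimura_bin = numeric(),
                      bp = numeric(), genome_fraction = numeric())
    attr(out, "n_missing_divergence") <- sum(miss)
    return(out)
  }
  r$kimura_bin <- floor(r$divergence_pct / bin_width) * bin_width
  key <- paste(r$class_label, r$kimura_bin, r$chromosome)
  bp <- vapply(split(r, key), function(g)
    merged_interval_bp(g$start, g$end), 0)
  meta <- do.call(rbind, lapply(split(r, key), function(g)
    g[1, c("class_label", "kimura_bin")]))
  agg <- aggregate(bp ~ class_label + kimura_bin,
                   data = cbind(meta, bp = bp), FUN = sum)
  agg$genome_fraction <- agg$bp / genome_length
  agg <- agg[order(agg$class_label, agg$kimura_bin), ]
  rownames(agg) <- NULL
  attr(agg, "n_missing_divergence") <- sum(miss)
  agg
}

#' Intronic repeat bp of a gene
#'
#' Total repeat-covered bp within the introns of the predominant model;
#' overlapping repeats are merged across classes first (a bp is
#' intronic-repeat once), so the result never exceeds the intron length.
#'
#' @param exons This gene's exon `data.frame` (`start`, `end`).
#' @param repeats Repeat features on the gene's chromosome.
#' @return Integer bp.
#' @export
intronic_repeat_bp <- function(exons, repeats) {
  introns <- gene_introns(exons)
  if (nrow(introns) == 0 || nrow(repeats) == 0) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(repeats$start, repeats$end))
  ii <- IRanges::IRanges(introns$start, introns$end)
  sum(IRanges::width(IRanges::intersect(ir, ii)))
}
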