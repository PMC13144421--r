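# ---------------------------------------------------------------------------
# Promoter extraction and PWM scanning for circadian cis-elements.
#
# Promoters are the 1.5 kb upstream of the annotated TSS. Scanning is a
# log-odds scan against a 0-order background on both strands; p-values
# come from the exact distribution of word scores under the background
# model, computed by dynamic programming over the per-column score sums
# (partial sums are accumulated column-by-column exactly as a full
# enumeration would, so for small widths the p-values are bit-identical
# to brute-force enumeration over all 4^w words).
# ---------------------------------------------------------------------------

PWM_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' @param matrix 4 x w numeric matrix (rows A, C, G, T) of counts or
#'   probabilities; columns are normalised to sum to 1 after adding
#'   `pseudocount`.
#' @param motif_id Identifier.
#' @param background Length-4 background probabilities (rows A,C,G,T);
#'   must be strictly positive and sum to 1.
#' @param pseudocount Added to every cell before normalisation.
#' @return Object of class `PWM` with the probability matrix and
#'   log-odds scores.
#' @export
make_pwm <- function(matrix, motif_id = "motif",
                     background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(nrow(matrix) == 4)
  if (any(background <= 0)) {
    stop("degenerate background: all four letters need probability > 0")
  }
  background <- background / sum(background)
  m <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  rownames(m) <- PWM_BASES
  lo <- log2(m / background)
  structure(list(motif_id = motif_id, width = ncol(m), prob = m,
                 background = setNames(background, PWM_BASES),
                 log_odds = lo),
            class = "PWM")
}

#' Read PWMs from MEME minimal text format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and
#' the optional `Background letter frequencies` line.
#'
#' @param path MEME-format text file.
#' @param pseudocount Passed to [make_pwm()].
#' @return Named list of `PWM` objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    lab <- toupper(tok[which(is.na(vals)) ])
    num <- vals[!is.na(vals)]
    if (length(num) == 4) bg[match(lab, PWM_BASES)] <- num
  }
  motif_at <- grep("^MOTIF", lines)
  out <- list()
  for (i in seq_along(motif_at)) {
    id <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]][2]
    j <- motif_at[i]
    while (j <= length(lines) &&
           !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) next
    rows <- list()
    k <- j + 1L
    while (k <= length(lines)) {
      tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) != 4 || any(is.na(vals))) break
      rows[[length(rows) + 1L]] <- vals
      k <- k + 1L
    }
    if (!length(rows)) next
    mat <- t(do.call(rbind, rows))  # rows A,C,G,T; columns positions
    out[[id]] <- make_pwm(mat, id, bg, pseudocount)
  }
  out
}

#' Reverse complement of a PWM
#' @param pwm A `PWM`.
#' @return The reverse-complemented `PWM`.
#' @export
reverse_complement_pwm <- function(pwm) {
  m <- pwm$prob[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(m) <- PWM_BASES
  make_pwm(m, paste0(pwm$motif_id, "_rc"), pwm$background, pseudocount = 0)
}

#' Extract a promoter sequence
#'
#' The `length` bp immediately upstream of the annotated TSS (the gene's
#' 5' end): `[start-length, start-1]` for forward-strand genes, the
#' reverse complement of `[end+1, end+length]` for reverse-strand genes.
#' Truncated at contig edges; masked characters (lower case, `N`) are
#' preserved.
#'
#' @param gene One-row slice of a bundle's `genes` table.
#' @param sequences The bundle's `DNAStringSet` (or named character).
#' @param length Promoter length in bp (default 1500).
#' @return Promoter string, 5' to 3' towards the TSS; empty (with a
#'   warning) for a gene at the contig edge.
#' @export
extract_promoter <- function(gene, sequences, length = 1500L) {
  chr <- as.character(sequences[[gene$chromosome]])
  if (gene$strand == "-") {
    s <- gene$end + 1L
    e <- min(nchar(chr), gene$end + length)
    if (s > nchar(chr)) {
      warning("gene at contig edge: empty promoter for ", gene$gene_id)
      return("")
    }
    revcomp(substr(chr, s, e))
  } else {
    e <- gene$start - 1L
    s <- max(1L, gene$start - length)
    if (e < 1L) {
      warning("gene at contig edge: empty promoter for ", gene$gene_id)
      return("")
    }
    substr(chr, s, e)
  }
}

# Integer-encode a promoter (A=1..T=4, anything else NA).
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], PWM_BASES)
}

# Sliding log-odds scores of a PWM over an encoded sequence; windows
# containing non-ACGT letters (hard-masked) score NA.
window_scores <- function(enc, lo) {
  w <- ncol(lo)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    col <- lo[, j][enc[j:(j + n - 1L)]]
    sc <- sc + col
  }
  sc
}

#' Exact score distribution of a PWM under its background
#'
#' Dynamic programme over per-column log-odds sums: the set of attainable
#' partial scores is extended one column at a time (exactly the
#' left-to-right summation order of a full word enumeration) and equal
#' partial scores are merged with their background probabilities. For
#' widths where the state set would exceed `max_states`, column scores
#' are first rounded to a fine grid (documented approximation).
#'
#' @param pwm A `PWM`.
#' @param max_states State-merge threshold before grid rounding.
#' @return `data.frame` with `score` (descending) and `p_value`
#'   (= P(S >= score), non-increasing in score).
#' @export
pwm_score_distribution <- function(pwm, max_states = 5e5) {
  lo <- pwm$log_odds
  if (4^pwm$width > max_states) {
    lo <- round(lo / 1e-6) * 1e-6
  }
  bg <- pwm$background
  scores <- 0
  probs <- 1
  for (j in seq_len(ncol(lo))) {
    s <- as.vector(outer(scores, lo[, j], "+"))
    p <- as.vector(outer(probs, bg, "*"))
    grp <- match(s, s)  # merge bit-identical partial sums
    scores <- s[!duplicated(grp)]
    probs <- as.vector(rowsum(p, grp)[, 1])
    probs <- probs[order(unique(grp))]
    if (length(scores) > max_states) {
      s2 <- round(scores / 1e-6) * 1e-6
      grp <- match(s2, s2)
      scores <- s2[!duplicated(grp)]
      probs <- as.vector(rowsum(probs, grp)[, 1])
      probs <- probs[order(unique(grp))]
    }
  }
  ord <- order(-scores)
  data.frame(score = scores[ord], p_value = cumsum(probs[ord]))
}

pvalue_lookup <- function(dist, score) {
  # P(S >= score): largest tail mass among scores >= observed
  vapply(score, function(s) {
    i <- which(dist$score >= s)
    if (!length(i)) 0 else dist$p_value[max(i)]
  }, numeric(1))
}

#' Scan a promoter with a PWM
#'
#' Log-odds scan of both strands against the 0-order background with
#' exact p-values from [pwm_score_distribution()]; hard-masked (non-ACGT)
#' windows are skipped. Offsets are reported relative to the TSS
#' (position -1 is the base immediately upstream).
#'
#' @param promoter Promoter string as returned by [extract_promoter()].
#' @param pwm A `PWM`.
#' @param p_threshold Report hits with `p_value <= p_threshold`.
#' @return `data.frame` motif_id, offset, strand, score, p_value.
#' @export
scan_pwm <- function(promoter, pwm, p_threshold = 1e-4) {
  empty <- data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric())
  n <- nchar(promoter)
  if (n < pwm$width) return(empty)
  enc <- encode_dna(promoter)
  rc <- reverse_complement_pwm(pwm)
  dist_f <- pwm_score_distribution(pwm)
  dist_r <- pwm_score_distribution(rc)
  out <- list()
  for (strand in c("+", "-")) {
    lo <- if (strand == "+") pwm$log_odds else rc$log_odds
    dist <- if (strand == "+") dist_f else dist_r
    sc <- window_scores(enc, lo)
    ok <- which(!is.na(sc))
    if (!length(ok)) next
    pv <- pvalue_lookup(dist, sc[ok])
    hit <- ok[pv <= p_threshold]
    if (!length(hit)) next
    out[[strand]] <- data.frame(
      motif_id = pwm$motif_id,
      offset = hit - n - 1L,   # window start relative to TSS
      strand = strand,
      score = sc[hit],
      p_value = pv[pv <= p_threshold],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Scan all promoters of a genome for a set of motifs
#'
#' @param bundle A `GenomeBundle`.
#' @param pwms Named list of `PWM`s.
#' @param promoter_length Promoter window (default 1500 bp).
#' @param p_threshold Hit threshold.
#' @return `data.frame` of hits with a `gene_id` column.
#' @export
scan_promoters <- function(bundle, pwms, promoter_length = 1500L,
                           p_threshold = 1e-4) {
  genes <- bundle$genes[bundle$genes$is_predominant, ]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    prom <- extract_promoter(genes[i, ], bundle$sequences, promoter_length)
    if (nchar(prom) == 0) next
    for (pwm in pwms) {
      h <- scan_pwm(prom, pwm, p_threshold)
      if (nrow(h)) {
        h$gene_id <- genes$gene_id[i]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), gene_id = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Presence/absence matrix of a motif across homoeologous groups
#'
#' Presence means >= 1 hit of the motif within the stated positional
#' window of the promoter; rows are family x group, columns report each
#' member gene, making single-gene absences (e.g. one homoeolog lacking
#' the evening element at a position) directly visible.
#'
#' @param hits Output of [scan_promoters()].
#' @param map A `HomoeologMap`.
#' @param families Family table (`family_id`, `gene_id`).
#' @param motif_id Motif to tabulate.
#' @param position_window `c(from, to)` offsets relative to the TSS
#'   (negative upstream); required, no default.
#' @return `data.frame` family_id, group, gene_id, present.
#' @export
motif_presence_matrix <- function(hits, map, families, motif_id,
                                  position_window) {
  if (missing(position_window) || length(position_window) != 2) {
    stop("position_window = c(from, to) is required")
  }
  h <- hits[hits$motif_id == motif_id &
              hits$offset >= position_window[1] &
              hits$offset <= position_window[2], , drop = FALSE]
  out <- families[, c("family_id", "gene_id")]
  m <- match(out$gene_id, map$gene_id)
  out$group <- ifelse(is.na(m), "unplaced", map$group[m])
  out$present <- out$gene_id %in% h$gene_id
  out <- out[order(out$family_id, out$group, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' 0-order background from a promoter set
#'
#' Letter frequencies over a (seedable) random subset of promoters;
#' masked/ambiguous letters excluded.
#'
#' @param promoters Character vector of promoter sequences.
#' @param n_sample Subset size (default all).
#' @return Length-4 probability vector (A, C, G, T).
#' @export
promoter_background <- function(promoters, n_sample = length(promoters)) {
  if (n_sample < length(promoters)) {
    promoters <- sample(promoters, n_sample)
  }
  ch <- strsplit(toupper(paste(promoters, collapse = "")), "")[[1]]
  tab <- table(factor(ch, levels = PWM_BASES))
  p <- as.numeric(tab)
  if (sum(p) == 0) stop("no unmasked bases in promoter set")
  setNames(p / sum(p), PWM_BASES)
}
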