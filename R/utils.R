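`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random DNA string
#'
#' Uniform i.i.d. nucleotides; used by the genome simulator for intergenic
#' spacers, introns and transposable-element bodies.
#'
#' @param n Length in bp.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA character string
#' @param x Character string (A/C/G/T/N, case preserved).
#' @return Reverse-complemented string.
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Format a numeric vector so that read.delim() recovers it bit-exactly while
# keeping "nice" numbers short.
format_lossless <- function(x) {
  if (is.double(x)) {
    out <- as.character(x)
    back <- suppressWarnings(as.numeric(out))
    bad <- !is.na(x) & (is.na(back) | back != x)
    out[bad] <- sprintf("%.17g", x[bad])
    out[is.na(x)] <- "NA"
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

# Merged (union) width of a set of 1-based closed intervals.
merged_interval_bp <- function(start, end) {
  if (length(start) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start, end))))
}

# Sorted total order over all columns of a data.frame, for deterministic
# row order in emitted feature matrices.
order_rows <- function(df) {
  if (nrow(df) == 0 || ncol(df) == 0) return(seq_len(nrow(df)))
  do.call(order, unname(as.list(df)))
}

# Stage seeds derived from one master seed; keeps every pseudo-random stream
# (gene fates, sequences, repeats, ...) independent of the others.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1013L * as.integer(stage)) %% 2147483629L
}
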