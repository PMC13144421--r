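# ---------------------------------------------------------------------------
# Truth-table comparison helpers: how well does the scan recover the
# events a simulation injected?
# ---------------------------------------------------------------------------

truth_locus <- function(sim, row) {
  if (!is.na(row$gene_id)) {
    g <- sim$focal$genes[sim$focal$genes$gene_id == row$gene_id, ]
    if (nrow(g) == 0) return(NULL)
    list(chromosome = g$chromosome[1], start = g$start[1], end = g$end[1])
  } else if (!is.na(row$locus_chromosome)) {
    list(chromosome = row$locus_chromosome, start = row$locus_start,
         end = row$locus_end)
  } else {
    NULL
  }
}

best_call_at <- function(calls, locus) {
  k <- which(calls$chromosome == locus$chromosome &
               calls$start <= locus$end & calls$end >= locus$start)
  if (!length(k)) return(NULL)
  calls[k[which.max(calls$score[k])], ]
}

#' Pseudogene class recovery against simulation truth
#'
#' Matches scan calls to the loci of injected events (disabled gene
#' copies, retrocopies, truncated residuals) and reports, per expected
#' class, how many were detected and how many were assigned the expected
#' class (DUP for stop/frameshift duplicates, PSSD for retrocopies, FRAG
#' for residuals).
#'
#' @param sim A `WGDSimulation`.
#' @param calls Output of [scan_pseudogenes()] on `sim$focal`.
#' @return `data.frame` with `expected_class`, `n_injected`,
#'   `n_detected`, `n_correct`, `recovery` (= n_correct / n_injected).
#' @export
class_recovery <- function(sim, calls) {
  tr <- sim$truth
  sets <- list(
    DUP = tr[tr$fate == "pseudogenized", , drop = FALSE],
    PSSD = tr[tr$fate == "retrocopy", , drop = FALSE],
    FRAG = tr[tr$fate == "deleted" & !is.na(tr$locus_chromosome), ,
              drop = FALSE])
  out <- lapply(names(sets), function(cls) {
    rows <- sets[[cls]]
    det <- cor <- 0L
    for (i in seq_len(nrow(rows))) {
      loc <- truth_locus(sim, rows[i, ])
      if (is.null(loc)) next
      b <- best_call_at(calls, loc)
      if (is.null(b)) next
      det <- det + 1L
      if (b$class == cls) cor <- cor + 1L
    }
    data.frame(expected_class = cls, n_injected = nrow(rows),
               n_detected = det, n_correct = cor,
               recovery = if (nrow(rows)) cor / nrow(rows) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fractionation recovery against simulation truth
#'
#' Compares estimated fractionation of each H1 gene (relative to its H2
#' homoeologous locus) with the true CDS fraction removed there.
#'
#' @param sim A `WGDSimulation`.
#' @param fractionation Output of [compute_fractionation()].
#' @return List: `mae_pp` (mean absolute error, percentage points), `n`,
#'   and the per-gene `data.frame`.
#' @export
fractionation_recovery <- function(sim, fractionation) {
  tr <- sim$truth
  h1 <- tr[tr$copy == "H1" & !is.na(tr$gene_id), ]
  h2 <- tr[tr$copy == "H2", ]
  truef <- 100 * h2$true_fractionation[match(h1$ancestral_id,
                                             h2$ancestral_id)]
  est <- fractionation$fractionation_pct[
    match(h1$gene_id, fractionation$gene_id)]
  ok <- !is.na(est) & !is.na(truef)
  list(mae_pp = mean(abs(est - truef)[ok]), n = sum(ok),
       detail = data.frame(gene_id = h1$gene_id[ok],
                           estimated = est[ok], true = truef[ok],
                           stringsAsFactors = FALSE))
}

#' Homoeolog-link recovery against simulation truth
#'
#' @param sim A `WGDSimulation`.
#' @param map A `HomoeologMap` of `sim$focal`.
#' @return List: `pair_recovery` (fraction of true H1/H2 gene pairs
#'   linked), `lost_recovery` (fraction of truly lost homoeologs called
#'   "lost"), `lost_recovery_resolvable` (the same fraction restricted
#'   to genes strictly inside a block footprint — genes at block edges
#'   are by design left unplaced rather than risk miscalling losses),
#'   `chromosome_pairs_correct` (logical).
#' @export
link_recovery <- function(sim, map) {
  tr <- sim$truth
  h1 <- tr[tr$copy == "H1" & !is.na(tr$gene_id), ]
  h2 <- tr[tr$copy == "H2" & !is.na(tr$gene_id), ]
  both <- merge(h1[, c("ancestral_id", "gene_id")],
                h2[, c("ancestral_id", "gene_id")], by = "ancestral_id")
  got <- map$partner[match(both$gene_id.x, map$gene_id)]
  pair_rec <- if (nrow(both)) mean(got == both$gene_id.y, na.rm = TRUE) *
    mean(!is.na(got)) else NA_real_
  lost_true <- h1$gene_id[!(h1$ancestral_id %in% h2$ancestral_id)]
  lost_got <- map$partner[match(lost_true, map$gene_id)]
  lost_rec <- if (length(lost_true)) mean(lost_got == "lost", na.rm = TRUE) *
    mean(!is.na(lost_got)) else NA_real_
  # a lost call is only possible with linked flanks on both sides
  resolvable <- vapply(lost_true, function(g) {
    i <- match(g, map$gene_id)
    if (is.na(i)) return(FALSE)
    nb <- map[map$chromosome == map$chromosome[i] &
                !is.na(map$partner) & map$partner != "lost", , drop = FALSE]
    any(nb$rank < map$rank[i]) && any(nb$rank > map$rank[i])
  }, logical(1))
  lost_rec_res <- if (any(resolvable)) {
    mean(lost_got[resolvable] == "lost", na.rm = TRUE) *
      mean(!is.na(lost_got[resolvable]))
  } else NA_real_
  gp <- attr(map, "pairs")
  truep <- sim$pairs
  ok_pairs <- nrow(gp) == nrow(truep) &&
    all(paste(pmin(gp$chr_h1, gp$chr_h2), pmax(gp$chr_h1, gp$chr_h2)) %in%
          paste(pmin(truep$chr_h1, truep$chr_h2),
                pmax(truep$chr_h1, truep$chr_h2)))
  list(pair_recovery = pair_rec, lost_recovery = lost_rec,
       lost_recovery_resolvable = lost_rec_res,
       chromosome_pairs_correct = ok_pairs)
}
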