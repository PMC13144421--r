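# ---------------------------------------------------------------------------
# Family-level diploidization scoring: genome-wide z-scores of intron and
# intronic-repeat lengths, mean fractionation, disablement counts, the
# "highly affected" flag, gene-family retention against a diploid
# outgroup, and the family-definition/overdispersion filters.
# ---------------------------------------------------------------------------

#' Genome-wide z-scores
#'
#' `z = (x - mean) / sd` with the sample sd (denominator n-1), over the
#' full population of predominant gene models (zeros included). A
#' zero-spread input returns all-zero z-scores with a warning.
#'
#' @param values Numeric vector (>= 2 values).
#' @return Numeric vector of z-scores.
#' @export
zscore_genomewide <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero spread; returning all-zero z-scores")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' The "highly affected" rule
#'
#' A family x group is highly affected when the maximum genome-wide
#' z-score of intronic repeats is >= 1 (inclusive) and/or there is any
#' evidence of pseudogenization (disablement count > 0).
#'
#' @param max_intronic_repeat_z Numeric.
#' @param total_disablements Integer.
#' @return Logical vector.
#' @export
highly_affected <- function(max_intronic_repeat_z, total_disablements) {
  max_intronic_repeat_z >= 1 | total_disablements > 0
}

#' Per-gene diploidization features
#'
#' Computes, for every predominant gene model: total intron bp, intronic
#' repeat bp, their genome-wide z-scores (population = all predominant
#' models, zeros included, both homoeologous groups jointly), the H1/H2
#' group, fractionation, and the disablement count of pseudogene calls
#' overlapping the gene's locus.
#'
#' @param bundle A `GenomeBundle`.
#' @param map A `HomoeologMap`.
#' @param calls Output of [scan_pseudogenes()].
#' @return `data.frame`, one row per predominant gene.
#' @export
gene_features <- function(bundle, map, calls) {
  genes <- bundle$genes[bundle$genes$is_predominant, ]
  ex <- split(bundle$exons, bundle$exons$gene_id)
  rep_by_chr <- split(bundle$repeats, bundle$repeats$chromosome)
  intron_bp <- intronic_rep <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    e <- ex[[genes$gene_id[i]]]
    introns <- gene_introns(e)
    intron_bp[i] <- if (nrow(introns)) sum(introns$end - introns$start + 1L)
      else 0L
    rr <- rep_by_chr[[genes$chromosome[i]]]
    intronic_rep[i] <- if (is.null(rr)) 0L else intronic_repeat_bp(e, rr)
  }
  frac <- compute_fractionation(bundle, map, calls)
  m <- match(genes$gene_id, map$gene_id)
  res <- data.frame(
    gene_id = genes$gene_id,
    family_id = genes$family_id,
    group = ifelse(is.na(m), "unplaced", map$group[m]),
    intron_bp = intron_bp,
    intronic_repeat_bp = intronic_rep,
    intron_z = zscore_genomewide(intron_bp),
    intronic_repeat_z = zscore_genomewide(intronic_rep),
    fractionation_pct =
      frac$fractionation_pct[match(genes$gene_id, frac$gene_id)],
    stringsAsFactors = FALSE)
  res$n_disablements <- 0L
  if (nrow(calls)) {
    for (chrom in unique(calls$chromosome)) {
      gi <- which(genes$chromosome == chrom)
      if (!length(gi)) next
      ci <- which(calls$chromosome == chrom)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(genes$start[gi], genes$end[gi]),
        IRanges::IRanges(calls$start[ci], calls$end[ci]))
      if (length(ov)) {
        d <- calls$n_premature_stops[ci] + calls$n_frameshifts[ci] +
          as.integer(calls$has_polyA[ci])
        add <- tapply(d[S4Vectors::subjectHits(ov)],
                      S4Vectors::queryHits(ov), sum)
        res$n_disablements[gi[as.integer(names(add))]] <-
          res$n_disablements[gi[as.integer(names(add))]] + as.integer(add)
      }
    }
  }
  res
}

#' Aggregate gene features into family x group records
#'
#' Individual gene copies within each homoeologous group are summarised
#' to their maximum intron / intronic-repeat z-score, the mean percent of
#' fractionation (not-computable copies ignored), and the summed
#' disablement count; the [highly_affected()] flag is attached. Empty
#' groups yield no record.
#'
#' @param features Output of [gene_features()].
#' @return `data.frame`, one row per family x group, sorted.
#' @export
aggregate_family <- function(features) {
  f <- features[!is.na(features$family_id), , drop = FALSE]
  if (nrow(f) == 0) {
    return(data.frame(family_id = character(), group = character(),
                      n_genes = integer(), max_intron_z = numeric(),
                      max_intronic_repeat_z = numeric(),
                      mean_fractionation_pct = numeric(),
                      total_disablements = integer(),
                      highly_affected = logical()))
  }
  grp <- split(f, paste(f$family_id, f$group, sep = "\r"))
  out <- lapply(grp, function(g) {
    fr <- g$fractionation_pct[!is.na(g$fractionation_pct)]
    data.frame(
      family_id = g$family_id[1], group = g$group[1],
      n_genes = nrow(g),
      max_intron_z = max(g$intron_z),
      max_intronic_repeat_z = max(g$intronic_repeat_z),
      mean_fractionation_pct = if (length(fr)) mean(fr) else NA_real_,
      total_disablements = sum(g$n_disablements),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$highly_affected <- highly_affected(res$max_intronic_repeat_z,
                                         res$total_disablements)
  res <- res[order(res$family_id, res$group), ]
  rownames(res) <- NULL
  res
}

#' Gene-family retention against the outgroup
#'
#' `retention = 1 - (n_outgroup - n_group) / n_outgroup`: 1 when the
#' family kept as many genes as the outgroup, 0.5 when half were lost,
#' above 1 for expansions. Families without any outgroup gene are
#' excluded (flagged, retention `NA`).
#'
#' @param group_count,outgroup_count Integer vectors (recycled).
#' @return Numeric vector of retention values (`NA` where
#'   `outgroup_count` is 0).
#' @export
family_retention <- function(group_count, outgroup_count) {
  ifelse(outgroup_count >= 1,
         1 - (outgroup_count - group_count) / outgroup_count,
         NA_real_)
}

#' Overdispersed-family filter
#'
#' Families with more than `8 * ploidy` genes per homoeologous group or
#' species (e.g. transposase families) are dropped.
#'
#' @param count Genes in the family for one group/species.
#' @param ploidy Integer ploidy.
#' @return Logical: `TRUE` to keep, `FALSE` to drop.
#' @export
filter_overdispersed <- function(count, ploidy) {
  count <= 8 * ploidy
}

#' Define gene families from orthogroups
#'
#' An orthogroup qualifies as a gene family when at least half of all
#' sampled species are present in it.
#'
#' @param species_present Integer vector: species with >= 1 gene per
#'   orthogroup.
#' @param n_species Total sampled species.
#' @return Logical vector.
#' @export
define_families <- function(species_present, n_species) {
  species_present >= ceiling(n_species / 2)
}

#' Retention table for a focal genome against its outgroup
#'
#' Counts family members per homoeologous group (H1/H2 from the map) and
#' in the outgroup, applies the overdispersion filter and the
#' outgroup-presence rule, and evaluates retention per family x group.
#'
#' @param bundle Focal `GenomeBundle`.
#' @param outgroup Outgroup `GenomeBundle`.
#' @param map A `HomoeologMap` for the focal genome (or `NULL` to count
#'   the whole focal genome as one group).
#' @return `data.frame` family_id, group, n_group, n_outgroup, retention,
#'   kept (overdispersion filter).
#' @export
retention_table <- function(bundle, outgroup, map = NULL) {
  fam_f <- bundle$families
  if (!is.null(map)) {
    fam_f$group <- map$group[match(fam_f$gene_id, map$gene_id)]
    fam_f$group[is.na(fam_f$group)] <- "unplaced"
  } else {
    fam_f$group <- "focal"
  }
  cnt <- aggregate(gene_id ~ family_id + group, data = fam_f, FUN = length)
  names(cnt)[3] <- "n_group"
  out_cnt <- table(outgroup$families$family_id)
  # families absent from a group have zero genes there: complete the grid
  fams <- sort(unique(c(fam_f$family_id, names(out_cnt))))
  groups <- sort(unique(cnt$group))
  grid <- expand.grid(family_id = fams, group = groups,
                      stringsAsFactors = FALSE)
  grid$n_group <- cnt$n_group[match(paste(grid$family_id, grid$group),
                                    paste(cnt$family_id, cnt$group))]
  grid$n_group[is.na(grid$n_group)] <- 0L
  grid$n_outgroup <- as.integer(out_cnt[grid$family_id])
  grid$n_outgroup[is.na(grid$n_outgroup)] <- 0L
  grid$retention <- family_retention(grid$n_group, grid$n_outgroup)
  grid$kept <- filter_overdispersed(grid$n_group, bundle$ploidy) &
    grid$n_outgroup >= 1
  grid <- grid[order(grid$family_id, grid$group), ]
  rownames(grid) <- NULL
  grid
}

#' End-to-end diploidization scoring pipeline
#'
#' Homoeolog mapping, pseudogene scanning, per-gene features and
#' family x group aggregation in one deterministic pass; reruns on the
#' same inputs are byte-identical after [write_feature_matrix()].
#'
#' @param bundle Focal `GenomeBundle`.
#' @param curated_proteins `AAStringSet` for parent selection (defaults
#'   to the translated predominant proteins keyed by family — self-parents).
#' @param map Optional precomputed `HomoeologMap`.
#' @param calls Optional precomputed pseudogene calls.
#' @return List with `map`, `parents`, `calls`, `features`, `records`.
#' @export
score_pipeline <- function(bundle, curated_proteins = NULL, map = NULL,
                           calls = NULL) {
  if (is.null(map)) map <- homoeolog_map(bundle)
  if (is.null(calls)) {
    if (is.null(curated_proteins)) {
      stop("either pseudogene calls or a curated protein set is required")
    }
    parents <- select_parents(bundle, curated_proteins)
    calls <- scan_pseudogenes(bundle, map, parents)
  } else {
    parents <- NULL
  }
  features <- gene_features(bundle, map, calls)
  records <- aggregate_family(features)
  list(map = map, parents = parents, calls = calls, features = features,
       records = records)
}
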