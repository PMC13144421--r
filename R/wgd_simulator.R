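# ---------------------------------------------------------------------------
# Whole-genome-duplication genome simulator.
#
# Emulates a diploidized tetraploid: an ancestral gene complement is
# duplicated into two homoeologous chromosome sets (H1/H2), H2 accumulates
# substitutions against H1, genes are stochastically deleted
# (fractionation, optionally leaving decaying residuals), disabled
# (premature stops / frameshifts), retrotransposed (processed copies with
# polyA tails) or tandem-duplicated, and transposable elements carrying
# divergence ages drawn from one or two amplification waves are inserted
# into introns and intergenic space. Every event is recorded in a truth
# table for parameter-recovery tests.
# ---------------------------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                c("T", "C", "A", "G")), 1, paste,
                    collapse = "")
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Simulation configuration
#'
#' Defaults describe a modest diploidized tetraploid; all probabilities are
#' per-event as documented for each field.
#'
#' @param seed Master seed; every pseudo-random stream (gene fates,
#'   sequences, repeats) derives its own seed from it, so e.g. adding TE
#'   simulation does not perturb gene fates.
#' @param n_chromosome_pairs Homoeologous chromosome pairs.
#' @param genes_per_chromosome Ancestral genes per chromosome.
#' @param cds_codons_mean,exon_count_mean Gene geometry (Poisson means).
#' @param intron_len_mean,min_intron_len,intergenic_len_mean Lengths in bp.
#' @param wgd_divergence Per-site substitution probability separating H2
#'   from H1 (2:1 transition:transversion; coding substitutions never
#'   create stop codons so that "retained" is honest truth).
#' @param fractionation_prob Per-H2-gene deletion probability (f).
#' @param fractionation_bias Ratio of the H1 to the H2 deletion
#'   probability in `[0, 1]`; 0 concentrates all loss on H2.
#' @param residual_prob Probability that a deleted gene leaves a truncated
#'   unannotated residual (the decaying-fragment route to FRAG calls)
#'   instead of clean removal by recombination.
#' @param residual_keep_range CDS fraction retained by a residual.
#' @param pseudogenization_prob Per-retained-H2-copy disablement
#'   probability (p).
#' @param retrocopy_prob Per-ancestral-gene probability of a processed
#'   retrocopy of the H1 copy landing elsewhere in the genome (r).
#' @param retro_divergence Substitution rate applied to retrocopies.
#' @param tandem_dup_prob Per-ancestral-gene probability of a tandem
#'   duplicate next to the H1 copy (t).
#' @param te_insertions_per_intron Poisson mean of TE insertions per
#'   intron (lambda).
#' @param te_intergenic_rate Poisson mean of TE insertions per intergenic
#'   gap.
#' @param te_h2_multiplier Multiplier on both TE rates for the H2
#'   chromosome set (makes H2 the repeat-affected group, the criterion the
#'   H1/H2 labelling uses).
#' @param te_len_mean,te_len_min TE length distribution (shifted
#'   exponential), bp.
#' @param te_wave_ages `data.frame(mean, sd, weight)` of Kimura-%
#'   amplification waves; weights must sum to 1.
#' @param inversion_rate Per-H2-chromosome probability of one inverted
#'   gene-order segment.
#' @param inversion_span Min/max genes per inverted segment.
#' @param outgroup Emit a pre-WGD diploid outgroup genome (both haplotypes
#'   annotated, i.e. two genes per ancestral family).
#' @param outgroup_divergence Substitution rate separating the outgroup
#'   from the ancestor.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosome_pairs = 2L,
                              genes_per_chromosome = 50L,
                              cds_codons_mean = 150,
                              exon_count_mean = 3,
                              intron_len_mean = 180,
                              min_intron_len = 60,
                              intergenic_len_mean = 400,
                              wgd_divergence = 0.05,
                              fractionation_prob = 0.15,
                              fractionation_bias = 0.5,
                              residual_prob = 0.25,
                              residual_keep_range = c(0.12, 0.42),
                              pseudogenization_prob = 0.10,
                              retrocopy_prob = 0.05,
                              retro_divergence = 0.01,
                              tandem_dup_prob = 0.03,
                              te_insertions_per_intron = 0.15,
                              te_intergenic_rate = 0.20,
                              te_h2_multiplier = 2,
                              te_len_mean = 600,
                              te_len_min = 50,
                              te_wave_ages = data.frame(
                                mean = c(8, 28), sd = c(3, 5),
                                weight = c(0.7, 0.3)),
                              inversion_rate = 0,
                              inversion_span = c(5L, 15L),
                              outgroup = TRUE,
                              outgroup_divergence = 0.08) {
  cfg <- as.list(environment())
  probs <- c(cfg$wgd_divergence, cfg$fractionation_prob,
             cfg$fractionation_bias, cfg$residual_prob,
             cfg$pseudogenization_prob, cfg$retrocopy_prob,
             cfg$tandem_dup_prob, cfg$retro_divergence,
             cfg$outgroup_divergence, cfg$inversion_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$te_wave_ages$weight) - 1) > 1e-9) {
    stop("TE wave weights must sum to 1")
  }
  if (cfg$te_insertions_per_intron < 0) stop("lambda must be >= 0")
  structure(cfg, class = "SimulationConfig")
}

# -- sequence-level helpers -------------------------------------------------

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# i.i.d. substitutions with a 2:1 transition:transversion ratio. With
# coding = TRUE the terminal stop codon is protected and substitutions that
# would create an internal stop are reverted, so "retained" gene copies
# carry no incidental disablements.
mutate_dna <- function(s, rate, coding = FALSE) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  elig <- seq_len(n)
  if (coding) elig <- elig[elig <= n - 3L]  # protect terminal stop
  k <- rbinom(1L, length(elig), rate)
  if (k == 0) return(s)
  sites <- sample(elig, k)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  is_ts <- runif(k) < 2 / 3
  old <- ch[sites]
  new <- ifelse(is_ts, ts[old],
                vapply(old, function(b) sample(tv[[b]], 1L), ""))
  ch[sites] <- new
  if (coding) {
    cod <- unique((sites - 1L) %/% 3L)
    for (ci in cod) {
      idx <- ci * 3L + 1:3
      if (idx[3] <= n && paste(ch[idx], collapse = "") %in% STOP_CODONS) {
        ch[idx] <- strsplit(substr(s, idx[1], idx[3]), "")[[1]]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Inject a disabling mutation into a CDS
#'
#' The three disablement kinds scored by the pseudogene scan: a premature
#' stop converts one internal codon to a stop codon; a frameshift inserts
#' or deletes 1-2 bp; `polyA_retrocopy` returns the (already spliced) CDS
#' with a >= 20 bp poly-adenine tail appended, emulating processed
#' retrotransposition.
#'
#' @param cds_sequence In-frame CDS string (length >= 9, multiple of 3 for
#'   the codon-level kinds).
#' @param kind One of `"premature_stop"`, `"frameshift"`,
#'   `"polyA_retrocopy"`.
#' @return List with `sequence` and the truth annotation
#'   (`n_premature_stops`, `n_frameshifts`, `has_polyA`, `position`).
#' @export
inject_disablement <- function(cds_sequence,
                               kind = c("premature_stop", "frameshift",
                                        "polyA_retrocopy")) {
  kind <- match.arg(kind)
  n <- nchar(cds_sequence)
  if (kind == "premature_stop" && (n < 9 || n %% 3 != 0)) {
    stop("CDS must be >= 9 bp and a multiple of 3")
  }
  if (kind == "frameshift" && n < 9) stop("CDS must be >= 9 bp")
  ann <- list(n_premature_stops = 0L, n_frameshifts = 0L, has_polyA = FALSE,
              position = NA_integer_)
  if (kind == "premature_stop") {
    k <- sample(2:(n %/% 3 - 1L), 1L)       # internal codon
    pos <- (k - 1L) * 3L + 1L
    seq <- paste0(substr(cds_sequence, 1, pos - 1L),
                  sample(STOP_CODONS, 1L),
                  substr(cds_sequence, pos + 3L, n))
    ann$n_premature_stops <- 1L
    ann$position <- pos
  } else if (kind == "frameshift") {
    len <- sample(1:2, 1L)
    pos <- sample(4:(n - 3L), 1L)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(cds_sequence, 1, pos),
                    random_dna(len),
                    substr(cds_sequence, pos + 1L, n))
    } else {
      seq <- paste0(substr(cds_sequence, 1, pos - 1L),
                    substr(cds_sequence, pos + len, n))
    }
    ann$n_frameshifts <- 1L
    ann$position <- pos
  } else {
    seq <- paste0(cds_sequence, strrep("A", sample(25:35, 1L)))
    ann$has_polyA <- TRUE
  }
  c(list(sequence = seq), ann)
}

sample_te_divergence <- function(n, waves) {
  if (n == 0) return(numeric(0))
  w <- sample.int(nrow(waves), n, replace = TRUE, prob = waves$weight)
  pmax(0, rnorm(n, waves$mean[w], waves$sd[w]))
}

sample_te <- function(n, config) {
  classes <- c("LTR/Gypsy", "LTR/Copia", "LINE/L1", "DNA/hAT", "Unknown")
  cw <- c(0.45, 0.20, 0.15, 0.12, 0.08)
  data.frame(
    class_label = sample(classes, n, replace = TRUE, prob = cw),
    length = config$te_len_min +
      as.integer(round(rexp(n, 1 / (config$te_len_mean - config$te_len_min)))),
    divergence_pct = round(sample_te_divergence(n, config$te_wave_ages), 1),
    stringsAsFactors = FALSE)
}

# -- cassette machinery -----------------------------------------------------
# A cassette holds one gene copy as exon/intron strings (all exons phase-0,
# codon-aligned). Assembly into chromosomes happens piece-wise so every
# emitted feature gets exact absolute coordinates.

make_ancestral_gene <- function(config) {
  n_cod <- max(60L, rpois(1L, config$cds_codons_mean))
  n_ex <- max(1L, 1L + rpois(1L, config$exon_count_mean - 1))
  n_ex <- min(n_ex, n_cod %/% 8L)
  split <- as.vector(stats::rmultinom(1L, n_cod - 5L * n_ex,
                                      rep(1, n_ex))) + 5L
  cds <- random_cds(n_cod)
  bounds <- cumsum(split) * 3L
  starts <- c(1L, head(bounds, -1) + 1L)
  exons <- substring(cds, starts, bounds)
  introns <- if (n_ex > 1) {
    vapply(seq_len(n_ex - 1L), function(i)
      random_dna(config$min_intron_len +
                   as.integer(round(rexp(1, 1 / config$intron_len_mean)))),
      "")
  } else character(0)
  list(exons = exons, introns = introns)
}

cassette_mutate <- function(cas, rate) {
  if (rate <= 0) return(cas)
  # mutate the spliced CDS codon-aware, then re-split at exon boundaries
  lens <- nchar(cas$exons)
  cds <- mutate_dna(paste(cas$exons, collapse = ""), rate, coding = TRUE)
  bounds <- cumsum(lens)
  cas$exons <- substring(cds, c(1L, head(bounds, -1) + 1L), bounds)
  cas$introns <- vapply(cas$introns, mutate_dna, "", rate = rate,
                        USE.NAMES = FALSE)
  cas
}

cassette_cds <- function(cas) paste(cas$exons, collapse = "")

# Disable one gene copy in place; kinds drawn without replacement.
cassette_disable <- function(cas, n_events = NULL) {
  if (is.null(n_events)) n_events <- sample(1:2, 1L)
  kinds <- sample(c("premature_stop", "frameshift"), n_events,
                  replace = n_events > 2)
  # stops before frameshifts: a frameshift breaks codon phase downstream
  kinds <- kinds[order(kinds != "premature_stop")]
  ann <- list(n_premature_stops = 0L, n_frameshifts = 0L)
  for (kind in kinds) {
    lens <- nchar(cas$exons)
    elig <- if (kind == "premature_stop")
      which(lens >= 9 & lens %% 3 == 0) else which(lens >= 9)
    if (!length(elig)) next
    ex <- if (length(elig) == 1L) elig else
      sample(elig, 1L, prob = lens[elig])
    res <- inject_disablement(cas$exons[ex], kind)
    cas$exons[ex] <- res$sequence
    ann$n_premature_stops <- ann$n_premature_stops + res$n_premature_stops
    ann$n_frameshifts <- ann$n_frameshifts + res$n_frameshifts
  }
  c(list(cassette = cas), ann)
}

# Truncated genomic residual of a deleted copy: a contiguous slice keeping
# `keep` of the CDS, anchored at the 5' or 3' end.
cassette_residual <- function(cas, keep, from_start = TRUE) {
  types <- rep(c("E", "I"), length.out = 2L * length(cas$exons) - 1L)
  seqs <- character(length(types))
  seqs[types == "E"] <- cas$exons
  if (length(cas$introns)) seqs[types == "I"] <- cas$introns
  cds_total <- sum(nchar(cas$exons))
  target <- max(30L, as.integer(round(keep * cds_total)))
  if (!from_start) {
    seqs <- rev(seqs); types <- rev(types)
  }
  acc <- 0L
  out <- character(0)
  for (i in seq_along(seqs)) {
    if (types[i] == "E") {
      take <- min(nchar(seqs[i]), target - acc)
      if (take <= 0) break
      out <- c(out, if (!from_start)
        substr(seqs[i], nchar(seqs[i]) - take + 1L, nchar(seqs[i]))
        else substr(seqs[i], 1L, take))
      acc <- acc + take
      if (acc >= target) break
    } else {
      out <- c(out, seqs[i])
    }
  }
  if (!from_start) out <- rev(out)
  list(seq = paste(out, collapse = ""), kept_cds = acc / cds_total)
}

# Insert TEs into the intron strings of a cassette; returns the cassette
# as a flat piece list plus per-intron TE metadata.
cassette_pieces <- function(cas, gene_id, lambda, config) {
  pieces <- list()
  n_te <- 0L
  add <- function(type, seq, meta = NULL) {
    pieces[[length(pieces) + 1L]] <<- c(list(type = type, seq = seq,
                                             gene_id = gene_id), meta)
  }
  for (i in seq_along(cas$exons)) {
    add("exon", cas$exons[i], list(exon_index = i))
    if (i <= length(cas$introns)) {
      intron <- cas$introns[i]
      k <- if (lambda > 0) rpois(1L, lambda) else 0L
      if (k == 0) {
        add("intron", intron)
      } else {
        n_te <- n_te + k
        te <- sample_te(k, config)
        cuts <- sort(sample.int(nchar(intron) + 1L, k, replace = TRUE)) - 1L
        prev <- 0L
        for (j in seq_len(k)) {
          add("intron", substr(intron, prev + 1L, cuts[j]))
          add("te", random_dna(te$length[j]),
              list(class_label = te$class_label[j],
                   divergence_pct = te$divergence_pct[j]))
          prev <- cuts[j]
        }
        add("intron", substr(intron, prev + 1L, nchar(intron)))
      }
    }
  }
  list(pieces = pieces, n_te = n_te)
}

gap_pieces <- function(len, lambda, config, extra = list()) {
  pieces <- list()
  add <- function(type, seq, meta = NULL) {
    pieces[[length(pieces) + 1L]] <<- c(list(type = type, seq = seq,
                                             gene_id = NA_character_), meta)
  }
  k <- if (lambda > 0) rpois(1L, lambda) else 0L
  seqs <- random_dna(len)
  if (k > 0) {
    te <- sample_te(k, config)
    cuts <- sort(sample.int(len + 1L, k, replace = TRUE)) - 1L
    prev <- 0L
    for (j in seq_len(k)) {
      add("intergenic", substr(seqs, prev + 1L, cuts[j]))
      add("te", random_dna(te$length[j]),
          list(class_label = te$class_label[j],
               divergence_pct = te$divergence_pct[j]))
      prev <- cuts[j]
    }
    add("intergenic", substr(seqs, prev + 1L, len))
  } else {
    add("intergenic", seqs)
  }
  c(pieces, extra)
}

# Assemble a piece list into one chromosome: sequence + feature tables.
assemble_chromosome <- function(chrom, pieces) {
  seqs <- vapply(pieces, `[[`, "", "seq")
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  types <- vapply(pieces, `[[`, "", "type")
  fld_chr <- function(idx, fld) {
    vapply(pieces[idx], function(p) p[[fld]] %||% NA_character_, "")
  }
  ei <- which(types == "exon" & lens > 0)
  ti <- which(types == "te" & lens > 0)
  li <- which(types %in% c("residual", "retro") & lens > 0)
  list(
    sequence = paste(seqs, collapse = ""),
    exons = data.frame(
      gene_id = fld_chr(ei, "gene_id"),
      chromosome = rep(chrom, length(ei)),
      start = starts[ei], end = ends[ei],
      exon_index = vapply(pieces[ei], function(p) p$exon_index, 0L),
      stringsAsFactors = FALSE),
    repeats = data.frame(
      chromosome = rep(chrom, length(ti)),
      start = starts[ti], end = ends[ti],
      class_label = fld_chr(ti, "class_label"),
      divergence_pct = vapply(pieces[ti], function(p) p$divergence_pct, 0),
      stringsAsFactors = FALSE),
    loci = data.frame(
      kind = types[li],
      ancestral_id = fld_chr(li, "ancestral_id"),
      copy = fld_chr(li, "copy"),
      chromosome = rep(chrom, length(li)),
      start = starts[li], end = ends[li],
      strand = fld_chr(li, "strand"),
      stringsAsFactors = FALSE))
}

# -- the simulator ----------------------------------------------------------

#' Simulate a diploidized tetraploid genome with ground truth
#'
#' Runs the full generative model described in [simulation_config()] and
#' returns the focal genome, an optional diploid outgroup, and the truth
#' table of per-copy fates used by the recovery tests. Deterministic for a
#' fixed seed.
#'
#' @param config A `SimulationConfig`.
#' @return List of class `WGDSimulation` with elements `focal`
#'   (`GenomeBundle`), `outgroup` (`GenomeBundle` or `NULL`), `truth`
#'   (`data.frame`, one row per gene copy), `pairs` (true homoeologous
#'   chromosome pairs with the repeat-richer member labelled H2), and
#'   `config`.
#' @export
simulate_wgd_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  ncp <- config$n_chromosome_pairs
  gpc <- config$genes_per_chromosome
  n_genes <- ncp * gpc
  anc_id <- sprintf("ag%04d", seq_len(n_genes))
  fam_id <- sprintf("f%04d", seq_len(n_genes))
  anc_chrom <- rep(seq_len(ncp), each = gpc)

  # --- stream 1: ancestral sequences ---------------------------------------
  set.seed(stage_seed(config$seed, 1L))
  ancestors <- lapply(seq_len(n_genes), function(i)
    make_ancestral_gene(config))
  gap_len <- function() {
    100L + as.integer(round(rexp(1L, 1 / config$intergenic_len_mean)))
  }
  gaps_h <- lapply(seq_len(2L * ncp), function(c)
    vapply(seq_len(gpc + 1L), function(i) gap_len(), 0L))
  gaps_out <- lapply(seq_len(2L * ncp), function(c)
    vapply(seq_len(gpc + 1L), function(i) gap_len(), 0L))

  # --- stream 2: gene fates ------------------------------------------------
  set.seed(stage_seed(config$seed, 2L))
  f <- config$fractionation_prob
  del_h2 <- runif(n_genes) < f
  del_h1 <- runif(n_genes) < f * config$fractionation_bias
  res_h2 <- del_h2 & runif(n_genes) < config$residual_prob
  res_h1 <- del_h1 & runif(n_genes) < config$residual_prob
  res_keep <- runif(n_genes, config$residual_keep_range[1],
                    config$residual_keep_range[2])
  res_from_start <- runif(n_genes) < 0.5
  pseudo_h2 <- !del_h2 & runif(n_genes) < config$pseudogenization_prob
  retro <- !del_h1 & runif(n_genes) < config$retrocopy_prob
  tandem <- !del_h1 & runif(n_genes) < config$tandem_dup_prob
  retro_chrom <- sample.int(2L * ncp, n_genes, replace = TRUE)
  retro_gap <- vapply(seq_len(n_genes), function(i)
    sample.int(gpc + 1L, 1L), 0L)
  retro_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  inv_segments <- lapply(seq_len(ncp), function(c) {
    if (runif(1) >= config$inversion_rate) return(NULL)
    span <- sample(config$inversion_span[1]:config$inversion_span[2], 1L)
    span <- min(span, gpc)
    at <- sample.int(gpc - span + 1L, 1L)
    c(at, at + span - 1L)
  })

  # --- stream 3: per-copy sequence evolution -------------------------------
  set.seed(stage_seed(config$seed, 3L))
  h1_cas <- ancestors
  h2_cas <- lapply(ancestors, cassette_mutate, rate = config$wgd_divergence)
  disable_ann <- vector("list", n_genes)
  for (i in which(pseudo_h2)) {
    d <- cassette_disable(h2_cas[[i]])
    h2_cas[[i]] <- d$cassette
    disable_ann[[i]] <- d
  }
  residual_h1 <- residual_h2 <- vector("list", n_genes)
  for (i in which(res_h1)) {
    residual_h1[[i]] <- cassette_residual(h1_cas[[i]], res_keep[i],
                                          res_from_start[i])
  }
  for (i in which(res_h2)) {
    residual_h2[[i]] <- cassette_residual(h2_cas[[i]], res_keep[i],
                                          res_from_start[i])
  }
  tandem_cas <- vector("list", n_genes)
  for (i in which(tandem)) {
    tandem_cas[[i]] <- cassette_mutate(h1_cas[[i]], 0.005)
  }
  retro_seq <- vector("list", n_genes)
  for (i in which(retro)) {
    s <- mutate_dna(cassette_cds(h1_cas[[i]]), config$retro_divergence)
    s <- paste0(s, strrep("A", sample(25:35, 1L)))
    if (retro_strand[i] == "-") s <- revcomp(s)
    retro_seq[[i]] <- s
  }
  out_a <- out_b <- NULL
  if (config$outgroup) {
    out_a <- lapply(ancestors, cassette_mutate,
                    rate = config$outgroup_divergence)
    out_b <- lapply(ancestors, cassette_mutate,
                    rate = config$outgroup_divergence)
  }

  # --- stream 4: TE placement + assembly -----------------------------------
  set.seed(stage_seed(config$seed, 4L))
  chrom_names <- sprintf("chr%02d", seq_len(2L * ncp))
  n_te_gene <- setNames(integer(0), character(0))
  build_set <- function(h) {
    mult <- if (h == 2L) config$te_h2_multiplier else 1
    lam_i <- config$te_insertions_per_intron * mult
    lam_g <- config$te_intergenic_rate * mult
    res <- list()
    for (c in seq_len(ncp)) {
      chrom <- chrom_names[(h - 1L) * ncp + c]
      idx <- which(anc_chrom == c)
      seg <- inv_segments[[c]]
      if (h == 2L && !is.null(seg)) {
        idx <- c(idx[seq_len(seg[1] - 1L)],
                 rev(idx[seg[1]:seg[2]]),
                 if (seg[2] < gpc) idx[(seg[2] + 1L):gpc])
      }
      pieces <- list()
      gaps <- gaps_h[[(h - 1L) * ncp + c]]
      for (slot in seq_along(idx)) {
        i <- idx[slot]
        # retrocopies land mid-gap, padded away from flanking genes
        landing <- which(retro & retro_chrom == (h - 1L) * ncp + c &
                           retro_gap == slot)
        half <- gaps[slot] %/% 2L
        if (length(landing)) {
          pieces <- c(pieces, gap_pieces(max(150L, half), lam_g, config))
          for (r in landing) {
            pieces <- c(pieces, list(list(type = "retro",
                                          seq = retro_seq[[r]],
                                          gene_id = NA_character_,
                                          ancestral_id = anc_id[r],
                                          copy = "RETRO",
                                          strand = retro_strand[r])))
          }
          pieces <- c(pieces, gap_pieces(max(150L, gaps[slot] - half),
                                         lam_g, config))
        } else {
          pieces <- c(pieces, gap_pieces(gaps[slot], lam_g, config))
        }
        deleted <- if (h == 1L) del_h1[i] else del_h2[i]
        resid <- if (h == 1L) residual_h1[[i]] else residual_h2[[i]]
        if (deleted) {
          if (!is.null(resid)) {
            pieces <- c(pieces, list(list(type = "residual",
                                          seq = resid$seq,
                                          gene_id = NA_character_,
                                          ancestral_id = anc_id[i],
                                          copy = sprintf("H%d", h),
                                          strand = "+")))
          }
          next
        }
        gid <- sprintf("%sh%d", sub("^ag", "g", anc_id[i]), h)
        cas <- if (h == 1L) h1_cas[[i]] else h2_cas[[i]]
        cp <- cassette_pieces(cas, gid, lam_i, config)
        n_te_gene[[gid]] <<- cp$n_te
        pieces <- c(pieces, cp$pieces)
        if (h == 1L && tandem[i]) {
          tid <- sprintf("%st1", sub("^ag", "g", anc_id[i]))
          pieces <- c(pieces, gap_pieces(150L, 0, config))
          tp <- cassette_pieces(tandem_cas[[i]], tid, lam_i, config)
          n_te_gene[[tid]] <<- tp$n_te
          pieces <- c(pieces, tp$pieces)
        }
      }
      pieces <- c(pieces,
                  gap_pieces(gaps[length(gaps)], lam_g, config))
      landing <- which(retro & retro_chrom == (h - 1L) * ncp + c &
                         retro_gap == gpc + 1L)
      for (r in landing) {
        pieces <- c(pieces, list(list(type = "retro", seq = retro_seq[[r]],
                                      gene_id = NA_character_,
                                      ancestral_id = anc_id[r],
                                      copy = "RETRO",
                                      strand = retro_strand[r])))
      }
      res[[chrom]] <- assemble_chromosome(chrom, pieces)
    }
    res
  }
  asm <- c(build_set(1L), build_set(2L))

  sequences <- Biostrings::DNAStringSet(
    vapply(asm, `[[`, "", "sequence"))
  exons <- do.call(rbind, lapply(asm, `[[`, "exons"))
  repeats <- do.call(rbind, lapply(asm, `[[`, "repeats"))
  loci <- do.call(rbind, lapply(asm, `[[`, "loci"))
  rownames(exons) <- rownames(repeats) <- rownames(loci) <- NULL

  gene_chrom <- tapply(exons$chromosome, exons$gene_id, `[`, 1L)
  genes <- data.frame(gene_id = names(gene_chrom),
                      chromosome = as.character(gene_chrom),
                      stringsAsFactors = FALSE)
  genes$locus_id <- genes$gene_id
  genes$strand <- "+"
  sp <- gene_spans(exons[, c("gene_id", "start", "end")])
  genes$start <- as.integer(sp$start[match(genes$gene_id, sp$gene_id)])
  genes$end <- as.integer(sp$end[match(genes$gene_id, sp$gene_id)])
  genes$is_allele <- FALSE
  anc_of_gene <- sub("(h[12]|t1)$", "", genes$gene_id)
  genes$family_id <- fam_id[match(sub("^g", "ag", anc_of_gene), anc_id)]
  genes$is_predominant <- TRUE
  genes <- genes[order(genes$chromosome, genes$start), ]
  rownames(genes) <- NULL

  families <- data.frame(family_id = genes$family_id,
                         gene_id = genes$gene_id,
                         species_or_group = "focal",
                         stringsAsFactors = FALSE)
  exo <- exons[order(exons$gene_id, exons$start),
               c("gene_id", "start", "end")]
  rownames(exo) <- NULL
  focal <- genome_bundle(sequences, genes, exo, exo, repeats, families,
                         species_label = "focal_tetraploid", ploidy = 2L)

  # --- outgroup ------------------------------------------------------------
  outgroup <- NULL
  if (config$outgroup) {
    og <- list()
    for (h in 1:2) {
      cass <- if (h == 1L) out_a else out_b
      for (c in seq_len(ncp)) {
        chrom <- sprintf("og%02d%s", c, c("a", "b")[h])
        idx <- which(anc_chrom == c)
        pieces <- list()
        gaps <- gaps_out[[(h - 1L) * ncp + c]]
        for (slot in seq_along(idx)) {
          i <- idx[slot]
          pieces <- c(pieces, gap_pieces(gaps[slot], 0, config))
          gid <- sprintf("%so%s", sub("^ag", "g", anc_id[i]),
                         c("a", "b")[h])
          cp <- cassette_pieces(cass[[i]], gid, 0, config)
          pieces <- c(pieces, cp$pieces)
        }
        pieces <- c(pieces, gap_pieces(gaps[length(gaps)], 0, config))
        og[[chrom]] <- assemble_chromosome(chrom, pieces)
      }
    }
    oseq <- Biostrings::DNAStringSet(vapply(og, `[[`, "", "sequence"))
    oex <- do.call(rbind, lapply(og, `[[`, "exons"))
    rownames(oex) <- NULL
    ochr <- tapply(oex$chromosome, oex$gene_id, `[`, 1L)
    ogenes <- data.frame(gene_id = names(ochr),
                         chromosome = as.character(ochr),
                         stringsAsFactors = FALSE)
    ogenes$locus_id <- ogenes$gene_id
    ogenes$strand <- "+"
    osp <- gene_spans(oex[, c("gene_id", "start", "end")])
    ogenes$start <- as.integer(osp$start[match(ogenes$gene_id, osp$gene_id)])
    ogenes$end <- as.integer(osp$end[match(ogenes$gene_id, osp$gene_id)])
    ogenes$is_allele <- FALSE
    oanc <- sub("o[ab]$", "", ogenes$gene_id)
    ogenes$family_id <- fam_id[match(sub("^g", "ag", oanc), anc_id)]
    ogenes$is_predominant <- TRUE
    ofam <- data.frame(family_id = ogenes$family_id,
                       gene_id = ogenes$gene_id,
                       species_or_group = "outgroup",
                       stringsAsFactors = FALSE)
    oexo <- oex[order(oex$gene_id, oex$start), c("gene_id", "start", "end")]
    rownames(oexo) <- NULL
    outgroup <- genome_bundle(oseq, ogenes, oexo, oexo, families = ofam,
                              species_label = "outgroup_diploid",
                              ploidy = 2L)
  }

  # --- truth table ---------------------------------------------------------
  truth <- list()
  trow <- function(i, copy, gene_id, fate, n_stop = 0L, n_fs = 0L,
                   polyA = FALSE, frac = 0, kept = NA_real_) {
    data.frame(ancestral_id = anc_id[i], family_id = fam_id[i], copy = copy,
               gene_id = gene_id, fate = fate, n_premature_stops = n_stop,
               n_frameshifts = n_fs, has_polyA = polyA,
               true_fractionation = frac, residual_kept_frac = kept,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_genes)) {
    g1 <- sprintf("%sh1", sub("^ag", "g", anc_id[i]))
    g2 <- sprintf("%sh2", sub("^ag", "g", anc_id[i]))
    truth[[length(truth) + 1L]] <-
      if (del_h1[i]) {
        kept <- if (!is.null(residual_h1[[i]]))
          residual_h1[[i]]$kept_cds else 0
        trow(i, "H1", NA_character_, "deleted", frac = 1 - kept, kept = kept)
      } else trow(i, "H1", g1, "retained")
    truth[[length(truth) + 1L]] <-
      if (del_h2[i]) {
        kept <- if (!is.null(residual_h2[[i]]))
          residual_h2[[i]]$kept_cds else 0
        trow(i, "H2", NA_character_, "deleted", frac = 1 - kept, kept = kept)
      } else if (pseudo_h2[i]) {
        d <- disable_ann[[i]]
        trow(i, "H2", g2, "pseudogenized", d$n_premature_stops,
             d$n_frameshifts)
      } else trow(i, "H2", g2, "retained")
    if (retro[i]) {
      truth[[length(truth) + 1L]] <-
        trow(i, "RETRO", NA_character_, "retrocopy", polyA = TRUE)
    }
    if (tandem[i]) {
      truth[[length(truth) + 1L]] <-
        trow(i, "TANDEM", sprintf("%st1", sub("^ag", "g", anc_id[i])),
             "tandem_duplicate")
    }
  }
  truth <- do.call(rbind, truth)
  truth$n_te_intronic <- as.integer(
    n_te_gene[truth$gene_id])
  truth$n_te_intronic[is.na(truth$n_te_intronic)] <- 0L
  # absolute coordinates of unannotated truth loci (residuals, retrocopies),
  # matched on (ancestral gene, copy)
  key_truth <- paste(truth$ancestral_id, truth$copy)
  key_loci <- paste(loci$ancestral_id, loci$copy)
  m <- match(key_truth, key_loci)
  truth$locus_chromosome <- loci$chromosome[m]
  truth$locus_start <- loci$start[m]
  truth$locus_end <- loci$end[m]
  truth$locus_strand <- loci$strand[m]
  truth <- truth[order(truth$ancestral_id, truth$copy), ]
  rownames(truth) <- NULL

  pairs <- data.frame(chr_h1 = chrom_names[seq_len(ncp)],
                      chr_h2 = chrom_names[ncp + seq_len(ncp)],
                      stringsAsFactors = FALSE)
  structure(list(focal = focal, outgroup = outgroup, truth = truth,
                 pairs = pairs, config = config),
            class = "WGDSimulation")
}

#' Disablement-injection benchmark conditions
#'
#' The simulation configuration used for pseudogene-class and
#' fractionation recovery benchmarks: a tetraploid of about a thousand
#' annotated gene models in which deletions (with decaying residuals),
#' disabling mutations and retrocopies are injected against intact H1
#' parent copies. Deletion bias is fully on H2 and tandem duplication is
#' off, so every injected event has an unambiguous intact parent — the
#' setting in which class recovery is a well-posed question.
#'
#' @param seed Master seed.
#' @param wgd_divergence Homoeolog divergence (default 0.05).
#' @return A `SimulationConfig`.
#' @export
injection_benchmark_config <- function(seed, wgd_divergence = 0.05) {
  simulation_config(
    seed = seed,
    n_chromosome_pairs = 4L,
    genes_per_chromosome = 125L,
    wgd_divergence = wgd_divergence,
    fractionation_prob = 0.15,
    fractionation_bias = 0,
    residual_prob = 0.35,
    pseudogenization_prob = 0.12,
    retrocopy_prob = 0.06,
    tandem_dup_prob = 0,
    te_insertions_per_intron = 0.1,
    te_intergenic_rate = 0.15)
}

#' Ancestral (curated) proteins of a simulation
#'
#' Translates each ancestral CDS; serves as the "manually curated" parent
#' reference set in pseudogene-scan tests. Named by family id.
#'
#' @param sim A `WGDSimulation`.
#' @return `AAStringSet` named by family id.
#' @export
ancestral_proteins <- function(sim) {
  h1 <- sim$truth[sim$truth$copy == "H1" & !is.na(sim$truth$gene_id), ]
  seqs <- vapply(h1$gene_id, function(g)
    gene_cds_sequence(sim$focal, g), "")
  # fall back to H2/outgroup copies for genes whose H1 copy was deleted
  missing_fam <- setdiff(sim$truth$family_id, h1$family_id)
  if (length(missing_fam) > 0) {
    other <- sim$truth[sim$truth$family_id %in% missing_fam &
                         !is.na(sim$truth$gene_id) &
                         sim$truth$fate == "retained", ]
    other <- other[!duplicated(other$family_id), ]
    if (nrow(other)) {
      seqs <- c(seqs, vapply(other$gene_id, function(g)
        gene_cds_sequence(sim$focal, g), ""))
      h1 <- rbind(h1[, c("family_id", "gene_id")],
                  other[, c("family_id", "gene_id")])
    }
  } else {
    h1 <- h1[, c("family_id", "gene_id")]
  }
  aa <- vapply(seqs, translate_cds, "", USE.NAMES = FALSE)
  out <- Biostrings::AAStringSet(aa)
  names(out) <- h1$family_id
  out[!duplicated(names(out))]
}

#' Write simulated genome files
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.out`, `families.tsv`
#' (focal + outgroup membership) and `truth.tsv` into a directory; all
#' writers are deterministic, so a fixed-seed simulation reproduces the
#' files byte-identically.
#'
#' @param sim A `WGDSimulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$focal$sequences, p("genome.fa"))
  write_gff3(sim$focal, p("genes.gff3"))
  write_repeatmasker_out(sim$focal$repeats, p("repeats.out"))
  fam <- sim$focal$families
  if (!is.null(sim$outgroup)) fam <- rbind(fam, sim$outgroup$families)
  write_family_table(fam, p("families.tsv"))
  write_feature_matrix(sim$truth, p("truth.tsv"))
  invisible(vapply(c("genome.fa", "genes.gff3", "repeats.out",
                     "families.tsv", "truth.tsv"), p, ""))
}

#' Place a transposable-element landscape into a genome
#'
#' Samples TE features into the intronic and intergenic space of an
#' existing bundle (annotation only; sequences are untouched). Insertion
#' counts are Poisson per intron/gap, each TE carries a Kimura divergence
#' drawn from the configured amplification-wave mixture, and TEs never
#' overlap exons.
#'
#' @param bundle A `GenomeBundle`.
#' @param config A `SimulationConfig` (uses the TE fields).
#' @return `data.frame` of repeat features.
#' @export
sample_te_landscape <- function(bundle, config = simulation_config()) {
  lam <- config$te_insertions_per_intron
  out <- list()
  ex_by_gene <- split(bundle$exons, bundle$exons$gene_id)
  chrom_of <- setNames(bundle$genes$chromosome, bundle$genes$gene_id)
  for (gid in names(ex_by_gene)) {
    introns <- gene_introns(ex_by_gene[[gid]])
    for (j in seq_len(nrow(introns))) {
      k <- if (lam > 0) rpois(1L, lam) else 0L
      if (k == 0) next
      te <- sample_te(k, config)
      ilen <- introns$end[j] - introns$start[j] + 1L
      # clip TE footprints to the intron so exons are never touched
      s <- introns$start[j] +
        sort(sample.int(max(1L, ilen), k, replace = TRUE)) - 1L
      e <- pmin(s + te$length - 1L, introns$end[j])
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom_of[[gid]], start = s, end = e,
        class_label = te$class_label,
        divergence_pct = te$divergence_pct)
    }
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
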