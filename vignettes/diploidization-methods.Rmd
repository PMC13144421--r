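---
title: "Quantifying genic diploidization after whole-genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genic diploidization after whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a whole-genome duplication (WGD), a polyploid genome drifts back
toward diploid-like genetics. Duplicated gene pairs (homoeologs) are
resolved by *fractionation* — physical loss of one copy, typically by
illegitimate recombination — or by *pseudogenization*, in which a copy
remains in place but accumulates premature stop codons, frameshifts, or
arrives as an intronless processed retrocopy with a poly-adenine tail.
Transposable elements (TEs) amplify in waves and pile into introns,
inflating some loci by tens of kilobases. `diploscan` measures these
signals in an annotated genome: it pairs homoeologous chromosomes from
gene-rank collinearity, labels the repeat-richer member of each pair H2,
detects and classifies pseudogenic loci (DUP / FRAG / PSSD), computes
per-gene fractionation against the corresponding homoeologous locus,
z-scores intron and intronic-repeat lengths genome-wide, and summarises
everything per gene family and homoeologous group, including family
retention against a diploid outgroup. A self-contained WGD simulator
provides ground truth for every stage.

## Coordinate and data model

All coordinates are 1-based closed on the forward strand, the native
convention of GFF3, RepeatMasker `.out` and the IRanges/Biostrings stack
this package is built on; no conversion layer exists because no format
boundary needs one. The unit of analysis is the `GenomeBundle`:
chromosome sequences, gene models (one per mRNA; the longest mRNA of a
locus is the *predominant* model and the only one that enters scoring),
repeat features, and family membership. Only CDS intervals count toward
fractionation and disablement calling — genic diploidization is a
statement about coding capacity, so UTRs and introns contribute length
(and TE burden) but never coverage.

## Homoeolog resolution

Collinearity is assessed in gene-rank space: genes are ranked by start
coordinate along each chromosome and every cross-chromosome pair of
same-family genes is a candidate anchor. Rank space is deliberately
insensitive to the large physical-size asymmetries TE accumulation
creates between homoeologous chromosomes. Families larger than
`8 * ploidy` members are excluded as promiscuous — the same
overdispersion rule the retention analysis applies, reused so that
transposase-like families cannot seed spurious chains.

Anchors are chained by an iterative longest-monotone-chain dynamic
programme (increasing or decreasing in partner rank, consecutive rank
gaps at most `max_rank_gap = 25`); chains shorter than
`min_block_size = 5` are discarded, so single-gene transpositions never
found a block. Chromosomes are then paired greedily by summed block
score (ties broken by name), which is adequate because the homoeologous
signal dominates every alternative pairing by an order of magnitude; a
true optimal assignment would change nothing on genomes with recognisable
homoeology, and the greedy choice is deterministic. Within a pair, the
member carrying more merged repeat-covered bp becomes H2. Whether the
repeat-richer member is "H1" or "H2" is an arbitrary convention;
every downstream statistic is invariant under swapping the labels, and
the test suite asserts that invariance.

Genes joined by an anchor are positional homoeologs. A gene lying
strictly inside a block whose family has no member in the opposite
syntenic interval is linked to `"lost"`. The both-sided flanking
requirement means a first- or last-rank gene whose partner was deleted
stays `unplaced` rather than `lost`; this forgoes a handful of calls at
chromosome ends in exchange for never mistaking a block edge for a
loss.

## Pseudogene detection and classification

Parent genes are the high-confidence set: translated CDS with identity
> 40% and query and subject coverage > 50% (all strict) against a
curated reference protein of the same family. Candidate pseudogenic
loci come from two routes:

* **Syntenic**: the locus opposite each parent. An annotated partner is
  compared through its spliced CDS; a lost partner is searched for in
  the genomic interval spanned by the partners of the flanking anchors.
* **Seed windows**: annotation-free regions containing at least two
  exact 13-mer matches of a parent CDS (sampled every 8 bp, both
  strands), clustered into windows. Requiring two seeds suppresses the
  chance k-mer hits that arrive alone.

The alignment core is affine-gap local alignment (match +2, mismatch
-3, gap open -5, gap extend -2; a gap of length L costs
`open + ext * L`). Under this scoring a single local alignment will
not bridge an intron — the gap penalty always exceeds the downstream
exon's gain — so multi-exon parents are aligned segment-wise: every CDS
segment is aligned to the locus in one vectorised pass and the
highest-scoring colinear chain of segments is kept. Segments scoring
below 30 (about a 15 bp perfect match) are left unaligned; chance
segments essentially never reach that bar, while genuine residual
fragments of 30 bp at ~95% identity comfortably do.

Disablements are read off the aligned columns in the parent reading
frame: a locus triplet aligned to a complete parent codon that is a
stop, strictly before the parent's own stop, is a premature stop;
sub-intron indels (< 30 bp) whose length is not a multiple of 3 are
frameshifts; a 30-bp window containing at least 24 adenines within
50 bp downstream of the alignment end is polyA evidence. The polyA rule
is fixed here because the upstream literature leaves it unstated, and it
is configurable.

Classification is deterministic: **PSSD** if polyA evidence is present
or at least two CDS segments of a multi-exon parent align back to back
(intron loss); otherwise **FRAG** if coverage < 0.5 with identity at or
above 40%; otherwise **DUP**. A locus with no evidence at all (no
stop, no frameshift, no tail, coverage at least 0.8) is not a
pseudogene and is never reported — an invariant asserted on every run.

Fractionation of a gene is `100 * (1 - covered)`, where `covered` is
the fraction of its CDS aligned by the homoeologous locus; a fully
absent homoeolog scores 100, and at a lost locus only an evidence-backed
call counts as residual coverage, so a weak chance alignment cannot
rescue a deleted homoeolog. Unplaced genes are flagged not computable
and excluded from aggregation rather than imputed to 100: unplaced is
not the same observation as lost.

## Family-level summaries

Per predominant gene model we record intron bp, intronic repeat bp
(overlapping repeats merged across classes first, so a bp is
intronic-repeat once and the total can never exceed the intron length),
genome-wide z-scores of both (sample sd, population = all predominant
models of both groups jointly, zeros included — excluding zero-intron
genes would inflate the z of modest insertions), fractionation, and the
summed disablement count of overlapping pseudogene calls. Records are
aggregated per family and group: maxima for the z-scores, mean for
fractionation, sum for disablements. A family-group is **highly
affected** when `max intronic-repeat z >= 1` (inclusive) or any
disablement evidence exists. "Evidence of pseudogenization" counts
disablements only; a FRAG call without a disablement does not trip the
flag by itself.

Retention per family is `1 - (n_outgroup - n_group) / n_outgroup`
against a diploid outgroup; families with no outgroup gene are excluded,
families with more than `8 * ploidy` members per group are dropped as
overdispersed, and orthogroups qualify as families when at least half
the sampled species are present. Values above 1 are meaningful
(expansions). A diploidized tetraploid that lost one member of each
pair therefore shows a retention point mass at exactly 0.5.

## Repeat divergence and landscapes

Kimura 2-parameter divergence is computed from transition (P) and
transversion (Q) proportions over ungapped columns,
`K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`; outside the estimable region
the function raises an explicit "saturated" error instead of returning
NaN. Only plain K2P is implemented (no CpG-adjusted variant); the
landscape bins merged repeat bp per class into integer-percent
divergence bins normalised by total assembly length. Normalising by
mappable rather than total length would scale all bins by a common
factor and change no shape.

## Promoter motif scanning

Promoters are the 1.5 kb immediately upstream of the annotated TSS
(strand-aware, truncated at contig edges, masked characters preserved).
Scanning is a log-odds scan against a 0-order background on both
strands. P-values are exact: the score distribution under the
background is built by dynamic programming over per-column score sums,
extending partial sums column by column in exactly the left-to-right
order a word enumeration would use, and merging bit-identical partial
sums — so for any width whose state set fits in memory the p-values are
*floating-point identical* to brute-force enumeration over all 4^w
words (the suite asserts this up to width 8). Beyond `max_states`
(default 5e5) column scores are rounded to a 1e-6 grid first; the
worst-case p-value perturbation is the probability mass within `w *
1e-6` of the threshold, negligible for biological motifs. Windows
containing non-ACGT letters (hard-masked) never contribute hits. The
evening-element-like consensus used in examples and tests
(`AAAATATCT`) is a synthetic fixture from the standard circadian
literature, not a measured matrix, and the positional window for
presence/absence matrices is a required argument with no default.

## Physiological assays

The flow-cytometry 1C value is the ratio of G0/1 peak mean fluorescence
intensities times the internal standard's 1C value (e.g. *Pisum
sativum*, 4.42 pg). Net CO2 assimilation is assimilation minus
respiration; gas-exchange post-processing clamps negative stomatal
conductance to zero and averages non-overlapping windows of five
records.

Titratable acidity converts each titration step's A615/A445 ratio to pH
through a monotone (Hyman-filtered spline; linear available)
interpolation of the buffer-standard calibration, locates the NaOH
volume reaching pH 7.0 by linear interpolation between the bracketing
1-uL steps, and scales from aliquot to extract per gram fresh weight,
reported explicitly as umol H+ per g FW. The forward simulator used in
recovery checks models the aliquot as a malate-like mixture of weak
acids (pKa 3.8 / 5.2 / 6.4) scaled so that exactly the nominal H+
equivalents titrate to pH 7.0 — the assay's own definition of TA. The
mixture matters: a single-pKa acid makes the pH jump across 7.0 inside
one 1-uL step and the interpolation error alone would exceed 2%,
whereas a buffered mixture keeps the recovery error well under 2%
(observed: < 1.7% worst case over 100 random curves).

## The simulator and what passing tests mean

The generator emulates a diploidized tetraploid end to end: ancestral
genes (Poisson exon counts, mean ~3; codon-resolution CDS of mean ~150
codons; intron and intergenic lengths shifted-exponential with means
180 and 400 bp) are duplicated into two chromosome sets; H2 accumulates
i.i.d. substitutions at `wgd_divergence` (default 0.05) with a 2:1
transition:transversion ratio so K2P estimation is exercised with
Q > 0; coding substitutions that would create a stop are reverted so
"retained" truth is honest. Per H2 gene, deletion occurs with
probability `f` (default 0.15; the H1:H2 odds knob defaults to 0.5 —
the direction of biased fractionation is exposed but no literature value
is asserted); a deleted copy leaves a truncated residual with
probability 0.25 keeping 12-42% of its CDS, anchored at either end.
Retained H2 copies are disabled with probability 0.1 (one or two
premature stops / frameshifts, stops injected before frameshifts so the
codon grid is intact); retrocopies (probability 0.05 per ancestral
gene) are spliced H1 copies at 1% divergence with 25-35 bp A-tails —
at least the 20 bp processed copies carry, and long enough that the
24-of-30 polyA window rule can evidence them — inserted mid-gap on a
random strand; tandem duplications append a lightly diverged copy next
to its template. TEs are drawn from a two-wave Kimura-age mixture
(means 8% and 28% by default), inserted Poisson-per-intron and
per-intergenic-gap with a doubled rate on H2, which is what makes H2
the repeat-affected group the labelling step should recover. The
pre-WGD diploid outgroup annotates both haplotypes — two genes per
ancestral family — so that loss of one homoeolog in the tetraploid
reads as retention 0.5.

Every stochastic stage draws from its own seed derived from the master
seed, so switching TE simulation on or off does not perturb gene fates;
a fixed seed reproduces all emitted files byte-identically. Simulated
genes all sit on the forward strand (strand handling of readers,
writers and promoter extraction is exercised with hand-built fixtures;
retrocopies do land on random strands), exon boundaries are
codon-aligned, and there is no selection, recombination map, or
rate heterogeneity along the sequence. Passing recovery tests on this
generator therefore demonstrates that the estimators invert the stated
generative model at realistic signal strengths — not that they are
robust to assembly artefacts, annotation error, or deep divergence
saturation in real genomes, which the haplotype-confusion screen and
the saturation errors only partially address.

Benchmark problem sizes used by the tests and the acceptance script:
class-recovery runs use three ~1,000-gene-model tetraploids
(`injection_benchmark_config()`: 4 chromosome pairs x 125 ancestral
genes, deletion bias fully on H2 and tandem duplication off so every
injected event has an unambiguous intact parent); the retention
signature uses 2,000 families; homoeolog recovery uses 300-480
ancestral genes with and without 5%-per-chromosome inversions;
fractionation recovery uses 500 constructed truncations; alignment,
PWM, K2P and titration checks use 200 pairs, all 4^w words (w <= 8),
10 kb sequences, and 100 random curves respectively.

## Known limitations

* Greedy (not optimal) chromosome matching; adequate for dominant
  homoeologous signal, documented above.
* Lost-homoeolog calls require both-sided flanking anchors, so losses at
  block edges are reported unplaced.
* The PseudoPipe-style genome-wide six-frame search is replaced by
  syntenic intervals plus seeded windows; a processed copy landing
  inside another annotated gene would be attributed to that gene's
  locus rather than discovered independently.
* Premature stops are counted in the parent-projected frame; after an
  upstream frameshift the locus's own reading frame differs, so stop
  counts downstream of a frameshift are approximate (the disablement
  decision is unaffected).
* No Ks-based block dating, no k-mer subgenome phasing, no transcription
  evidence; triplet (hexaploid) chaining is pairwise only.
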