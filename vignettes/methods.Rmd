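---
title: "Models and methods behind bsdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bsdiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

bsdiverge analyses comparative whole-genome bisulfite sequencing (BS-Seq)
studies of four related plant lines — two cultivated, two wild — together
with NlaIII digital gene expression (DGE) tag libraries.  This vignette
explains the statistical models, the parameters that matter, the design
choices made where the design was genuinely open, and what the built-in
synthetic study does and does not emulate.

## The bisulfite alignment model

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while methylated cytosine stays C.  A directional paired-end library
therefore sequences two strand populations: fragments from the plus
strand, whose mate 1 carries C→T signatures, and fragments from the
minus strand, whose evidence appears as G→A in plus coordinates.  We map
in "three-letter" space: every read pair is converted (mate 1 C→T,
mate 2 G→A) and placed end-to-end against two converted references — the
T-genome (reference C→T; the plus-strand target) and the A-genome
(reference G→A; the minus-strand target).

The aligner is an exact seed-and-extend k-mismatch search: each
converted mate is split into `cap + 1` non-overlapping seeds (pigeonhole:
any placement with at most `cap` mismatches matches at least one seed
exactly), candidate diagonals are gathered from a k-mer index of the
converted reference, and candidates are verified by direct Hamming
counting.  At the genome sizes this package targets (up to a few hundred
kilobases) this search is exhaustive-accurate: the test suite proves it
equal to a full Hamming scan over every offset of both converted genomes.
The per-mate mismatch cap defaults to 2 for 44-nt reads and 4 for 75-nt
reads.  Mates are paired in forward–reverse orientation on the same
converted genome with a fragment length of at most `max_insert`
(default 600 bp).

*Uniqueness.* A pair is kept only when one placement has **strictly**
fewer total mismatches than every other placement across both converted
genomes and all positions; equal-best placements anywhere make the pair
ambiguous and it is discarded.  This is the conservative reading of
"uniquely mapped"; the alternative (tolerate equal-best ties within one
genome) would admit reads from repeats.

*Clonal duplicates.* Pairs sharing contig, both mates' start positions
and origin strand are treated as PCR clones; the survivor is the pair
with the highest mean base quality, ties broken by input order.  The
operation is idempotent and never merges distinct placements.

*Restoration.* Kept pairs are restored to original bases and paired
column-wise with the original reference on the originating strand, where
bisulfite conversion is always "read T over reference C"; such columns
are flagged as conversions, not mismatches.

## Methylcytosine calling

For each reference cytosine on either strand, covered by quality-passing
(≥ Q20) reads of the matching origin, the methylation level is
`n_meth / n_total` where `n_meth` counts reads showing C.  Q20 means a
base is called correctly with at least 99% probability
(`phred_accuracy(20) == 0.99`), a conservative floor for pileup bases.
When mates of one pair overlap, the overlapping bases are counted once
(mate 1 kept): a single molecule should not vote twice.

Two error processes can mimic methylation at an unmethylated site:
bisulfite non-conversion and T→C sequencing error.  Only their sum
matters for calling, and the unmethylated chloroplast genome provides a
natural estimate: pooling all covered chloroplast cytosines (both
strands, all contexts) gives `p_err = Σ n_meth / Σ n_total`.  The pooled
estimator is a single scalar per sample — per-context error rates are
deliberately out of scope since the two error processes are
context-free.  Each site is then tested against
`P(X >= n_meth | X ~ Binomial(n_total, p_err))` and called methylated
when `n_meth >= 1` and the p-value is below α = 0.05.

*Per-site α, not FDR.*  The 5% bound is implemented as a per-site test
level with no genome-wide correction.  The calibration suite verifies
the realized false-positive rate on null simulations is below 5% at
every depth (the discrete test is conservative, so the realized rate is
nearer 2%).  A false-discovery-rate variant would change the set of
called sites but not any downstream definition.

*SNP interference.*  A C→T substitution is indistinguishable from an
unmethylated cytosine, so sites where the sample's own genotype call is
non-reference can be masked from methylation calling
(`call_methylation(..., snp_mask = )`).  Masking is optional because the
procedure is also well-defined without it.

## SNP genotyping from bisulfite reads

Reads mapped to the T-genome carry plus-strand sequence and reads mapped
to the A-genome carry minus-strand sequence.  On the plus strand,
conversion only corrupts C (to T); on the minus strand, only G (read as
A in plus coordinates).  Consequently genotypes whose sample base is A
or G are trustworthy from the plus-strand pileup, and sample bases C or
T from the minus-strand pileup.  The caller stratifies pileups by origin
strand (Q30 bases only), takes a per-stratum majority consensus (depth
≥ 5, majority fraction ≥ 0.9) and resolves: plus consensus in {A, G}
wins; otherwise minus consensus in {C, T}; a plus consensus of C/T or a
minus consensus of A/G is conversion-ambiguous and never decides a call.
Confident but contradictory calls from the two strands (possible only
through sequencing error) are flagged as conflicts and excluded rather
than arbitrated.  The model is homozygous-only — appropriate for inbred,
self-pollinating lines; heterozygote support is a non-goal.  The
conversion-immunity invariant (no false SNP under pure conversion, any
methylation truth, any depth) is enforced by test.

## Region metrics and profiles

Two region-level summaries are used throughout, both built from the
levels of called methylcytosines only:

* absolute level = Σ site levels / region length (per-bp units);
* relative level = Σ site levels / number of cytosine sites in the
  region (per-site units).

The identity `absolute = relative × n_c_sites / length` holds exactly
for every emitted region and is asserted in the tests.  Promoters are
200 bp upstream of the TSS and TTRs 200 bp downstream of the TTS,
strand-aware; a site belongs to at most one of promoter/body/TTR per
gene because the generator keeps gene flanks disjoint from all other
features.

Metagene profiles rescale each region to percent coordinates and pool
sites in an overlapping sliding window of 5% of the region length at a
2.5% step — 39 body bins, with the same scheme applied to the 2 kb gene
(0.5 kb TE) flanks.  Bin membership is by site position in percent
coordinates, so a site falls in one or two bins (the scheme overlaps by
construction); minus-strand regions are flipped to run 5'→3'.  Regions
shorter than 40 bp would have degenerate bins and are skipped.  Both
absolute and relative per-bin profiles are emitted, since either
convention is defensible for pooled display.

Genome windows are 50 kb with a 25 kb step.  A terminal partial window
is kept only when it is at least one step long **and** extends past the
last full window — so a 100 kb contig yields starts {0, 25, 50} kb (the
would-be fourth window adds no new bases) while a 40 kb contig yields
one 40 kb window.

Cross-sample stability is summarised by the coefficient of variation
(sd/mean over the four samples, n−1 denominator); units with zero mean
are excluded (undefined CV), and the level-vs-CV correlation uses
log2-transformed strictly positive pairs only.

## Expression

The DGE model is SAGE-like: the reference tag database contains every
CATG + 17 nt tag derivable from the full-length cDNAs; tags found in
two or more genes are ambiguous.  Mapping is exact (perfect 21-mer
match) and a gene's count sums all tags unique to it, including unique
tags from internal CATG sites — the 3'-site rank histogram is the
diagnostic for how often internal sites fire.  Expression is normalised
to tags per million (values over counted genes sum to 1e6 exactly).
Tags are matched on the sense strand only, as the NlaIII protocol reads
the transcript.

## Comparative analytics

The two-sample Wilcoxon rank-sum test is the workhorse.  It enumerates
the full permutation distribution of the rank sum when m + n ≤ 20
(two-sided p = min(1, 2·min(P(W ≤ w), P(W ≥ w))); ties through average
ranks), and otherwise uses the normal approximation with tie and
continuity correction.  The test suite proves the exact branch equal to
an independent recursive enumeration for every size up to 12.

Trees: methylation and expression trees use 1 − Spearman correlation as
the distance and complete-linkage agglomeration (the linkage is
configurable; complete linkage is the package default where only the
clustering family, not the linkage, is dictated by the analysis).
Genomic trees use neighbor-joining on p-distances (fraction of co-called
positions with differing genotypes).  Trees are deterministic given the
input order and round-trip through the Newick writer/parser.

Divergence windows report π = (Σ over the 6 sample pairs of co-called
differing positions) / (6 × window length) — i.e. positions not called
in a pair count as non-differing, matching a SNP-table-based π — and the
mean pairwise Spearman correlation of per-cytosine levels over sites
covered ≥ 5× in both samples (pairs with fewer than 10 shared sites are
omitted).  Windows are then sorted by π into 20 equal-count groups
(remainder spread over the first groups) for the divergence-vs-
methylation summary.

Differentially methylated genes: per gene region with more than 80% of
its cytosine sites covered in **all four** samples (coverage is defined
over cytosine sites, not bases, since the level vectors are per-site),
per-cytosine level vectors are compared for all six sample pairs.  A
gene is DM when the four cultivated-vs-wild tests are significant at
α = 0.05 with a consistent direction (sign of the median difference,
falling back to the mean difference under median ties) and the two
within-group tests are not significant at the same α.  Only covered
cytosines enter the level vectors — levels are undefined elsewhere.  The
overlap with expression counts a DM gene as "methylation-correlated"
when mean cultivated and wild tags-per-million differ at least 2-fold in
the direction implied by the region: methylation gain in promoter or TTR
implies expression loss; gene-body methylation may act in either
direction.  A pseudocount of one per-million unit guards the ratios.

## The synthetic study

The generator's defaults describe the study conditions the analysis
assumes: a directional Illumina-era protocol with 44-nt (optionally
75-nt) paired reads, ~15× mean per-strand depth, fragment lengths
uniform in 150–250 bp (the protocol's size selection is not modelled
beyond a fixed range), a combined non-conversion + T→C error rate of
1.12% lumped into a single C-retention probability (only the sum is
identifiable, and only the sum is used), 0.1% independent sequencing
error, 10% exact clonal duplication, constant Q40 qualities with an
optional low-Q admixture to exercise the Q20/Q30 filters, and
homozygous-only SNPs planted per branch of the fixed
((cult1,cult2),(wild1,wild2)) topology with wild branches faster than
cultivated ones.  Compartment-by-context methylation means follow the
rice-like ordering TE ≫ gene body > flanks with CG > CHG ≫ CHH and are
jittered per site by a Beta distribution with concentration 20, which
preserves the configured means exactly and gives high-mean sites
proportionally smaller jitter.  Planted differential methylation shifts
the configured region (promoter by default) by 0.4 in one group, half
the selected genes up in cultivated and half down.  Expression is
log-normal (meanlog 3, sdlog 1.2) with a 4-fold group change in 30% of
genes and a 0.5 probability that a planted DM gene receives the
expression change implied by its methylation direction.

What the generator does **not** emulate — hence what passing tests do
not show about real data: indels and structural variation, heterozygous
sites, context-dependent or fragment-length-dependent conversion
failure, PCR bias beyond exact clones, coverage biases (GC, mappability)
on a repetitive genome, antisense or degraded DGE tags, and biological
correlation structure beyond the planted effects.  Oracle equivalence
and calibration results transfer to real data; recovery rates are
specific to these simulated conditions.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based fully-closed in
  every text output.
* RNG streams are derived per stage and sample from one master seed
  (kept below 2^31), so identical configurations are bit-reproducible
  and adding a sample does not shift other samples' streams.
* Context is assigned from the reference, "unknown" within 2 bp of a
  contig end; unknown-context sites participate in calling but not in
  per-context summaries.
* Zero-depth input yields valid empty outputs; zero chloroplast coverage
  is an explicit calibration error; a zero-length region, a zero DGE
  library, fewer than 3 regions for a correlation, fewer than 20 windows
  for the divergence grouping, and a constant profile in a correlation
  tree are all explicit errors naming the offending input.
* Wilcoxon p-values are clamped to (0, 1]; all-tied inputs give p = 1.
* Quantile groups and window groups spread any remainder over the first
  groups, so sizes differ by at most one.

The test suite runs the full four-sample study at a deliberately small
scale — a ~106 kb genome (60 + 40 kb nuclear, 6 kb chloroplast), 30
genes, 15× per-strand depth — plus an error-free 40 kb genotyping study
with ~500 planted SNPs at 10×/strand and a 20 kb single-sample study at
30× for recovery checks.  These sizes were chosen so the whole suite
exercises every stage end-to-end in about a minute and a half while
keeping enough sites for three-standard-error recovery bounds.

## Known limitations

The aligner is ungapped and exact by design; it is not suitable for
chromosome-scale references or indel-rich comparisons.  The DM procedure
tests per-cytosine level vectors, which treats sites within a region as
exchangeable and ignores their spatial autocorrelation; its per-gene
power therefore grows with region cytosine count.  The per-site binomial
caller ignores overdispersion (no beta-binomial), and the single pooled
error rate assumes conversion efficiency is homogeneous along the
genome.  The pipeline holds per-sample data in memory, which is ample at
desk scale but not genome scale.
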