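# Configuration object for the synthetic four-sample BS-Seq study.

#' Default compartment-by-context methylation means
#'
#' Mean methylation probabilities used by the synthetic truth generator,
#' chosen to mirror the broad methylome structure of a selfing grass:
#' transposable elements heavily methylated in all contexts, gene bodies
#' enriched for CG methylation, promoters/terminators and intergenic space
#' lightly methylated, and CHH low everywhere.
#'
#' @return A `data.table` with columns `compartment`, `context`, `level`.
#' @export
default_methylation_levels <- function() {
  data.table::data.table(
    compartment = rep(c("TE", "gene_body", "promoter", "TTR", "intergenic"),
                      each = 3L),
    context = rep(c("CG", "CHG", "CHH"), times = 5L),
    level = c(
      0.85, 0.65, 0.15,   # TE
      0.45, 0.10, 0.03,   # gene_body
      0.15, 0.08, 0.03,   # promoter
      0.15, 0.08, 0.03,   # TTR
      0.25, 0.12, 0.04    # intergenic
    )
  )
}

#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the miniature four-sample design: the reference
#' (one contig flagged as the unmethylated chloroplast control), feature
#' counts, compartment-by-context methylation means, planted
#' cultivated-vs-wild methylation shifts, per-branch substitution rates for
#' the fixed ((cult1,cult2),(wild1,wild2)) topology, the directional
#' paired-end bisulfite read model, and the NlaIII DGE tag model.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   stream from it, so identical configurations give bit-identical output.
#' @param contigs `data.frame` with columns `name`, `length`,
#'   `is_chloroplast`; exactly one contig must be flagged as chloroplast and
#'   all lengths must be at least 1000 bp.
#' @param gene_count,te_count,smrna_count Numbers of gene models, TE
#'   intervals and small-RNA loci to place on nuclear contigs (all placed
#'   features are mutually disjoint).
#' @param gene_length,te_length,smrna_length Length ranges (bp) sampled
#'   uniformly per feature.
#' @param promoter_bp,ttr_bp Promoter (upstream of TSS) and transcriptional
#'   termination region (downstream of TTS) sizes; 200 bp each by default.
#' @param methylation_levels Compartment-by-context mean methylation table,
#'   see [default_methylation_levels()].
#' @param meth_concentration Beta concentration for per-site jitter around
#'   the compartment mean (site prob ~ Beta with this total concentration,
#'   so the configured mean is preserved exactly in expectation).
#' @param dm_fraction Fraction of genes given a planted cultivated-vs-wild
#'   methylation shift of size `dm_shift` in region `dm_region`
#'   (half shifted up in cultivated, half down).
#' @param dm_shift,dm_region Size and genic region ("promoter",
#'   "gene_body" or "TTR") of the planted shift.
#' @param snp_branch_rates Named per-branch substitution probabilities per
#'   base for branches `cult1`, `cult2`, `wild1`, `wild2`, `cult_stem`,
#'   `wild_stem` of the fixed 4-taxon tree.
#' @param read_length Bisulfite read length, 44 or 75 nt.
#' @param depth Mean per-strand read depth.
#' @param insert_range Fragment (insert) length range in bp; the lower bound
#'   must be at least `read_length`.
#' @param non_conversion_rate,seq_error_rate Probability that an
#'   unmethylated cytosine escapes conversion (and is read as C), and the
#'   independent per-base sequencing error rate.  At cytosine sites the two
#'   act together as a single C-retention null rate, which is exactly what
#'   the chloroplast control estimates downstream.
#' @param clonal_fraction Probability that a fragment is duplicated exactly
#'   (PCR clone); duplicates share both mates' start positions.
#' @param low_q_fraction Per-base probability of emitting a low-quality
#'   (Q15) base, to exercise the Q20/Q30 filters; 0 by default (constant
#'   Q40).
#' @param expression List of log-normal expression parameters: `meanlog`,
#'   `sdlog`, `group_fraction` (fraction of genes with a cultivated-vs-wild
#'   expression fold change), `group_fold`, `within_sd` (log-scale noise
#'   within groups) and `dm_coupling` (probability that a planted
#'   differentially methylated gene also receives the expression fold
#'   change implied by its methylation direction).
#' @param tag_count DGE library size (number of tags sampled).
#' @param tag_internal_p Probability that a tag is emitted from an internal
#'   (non-3'-most) CATG site, exercising the tag position diagnostic.
#' @param tag_error_rate Per-base sequencing error rate for DGE tags.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       contigs = data.frame(
                         name = c("chr1", "chr2", "chrC"),
                         length = c(60000L, 40000L, 8000L),
                         is_chloroplast = c(FALSE, FALSE, TRUE)),
                       gene_count = 40L,
                       gene_length = c(600L, 1500L),
                       te_count = 30L,
                       te_length = c(300L, 1200L),
                       smrna_count = 20L,
                       smrna_length = c(50L, 200L),
                       promoter_bp = 200L,
                       ttr_bp = 200L,
                       methylation_levels = default_methylation_levels(),
                       meth_concentration = 20,
                       dm_fraction = 0.2,
                       dm_shift = 0.4,
                       dm_region = "promoter",
                       snp_branch_rates = c(cult1 = 5e-4, cult2 = 5e-4,
                                            wild1 = 1.5e-3, wild2 = 1.5e-3,
                                            cult_stem = 1e-3,
                                            wild_stem = 2e-3),
                       read_length = 44L,
                       depth = 15,
                       insert_range = c(150L, 250L),
                       non_conversion_rate = 0.0112,
                       seq_error_rate = 0.001,
                       clonal_fraction = 0.1,
                       low_q_fraction = 0,
                       expression = list(meanlog = 3, sdlog = 1.2,
                                         group_fraction = 0.3,
                                         group_fold = 4,
                                         within_sd = 0.2,
                                         dm_coupling = 0.5),
                       tag_count = 50000L,
                       tag_internal_p = 0.05,
                       tag_error_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), contigs = as.data.frame(contigs),
    gene_count = as.integer(gene_count), gene_length = as.integer(gene_length),
    te_count = as.integer(te_count), te_length = as.integer(te_length),
    smrna_count = as.integer(smrna_count),
    smrna_length = as.integer(smrna_length),
    promoter_bp = as.integer(promoter_bp), ttr_bp = as.integer(ttr_bp),
    methylation_levels = data.table::as.data.table(methylation_levels),
    meth_concentration = meth_concentration,
    dm_fraction = dm_fraction, dm_shift = dm_shift, dm_region = dm_region,
    snp_branch_rates = snp_branch_rates,
    read_length = as.integer(read_length), depth = depth,
    insert_range = as.integer(insert_range),
    non_conversion_rate = non_conversion_rate,
    seq_error_rate = seq_error_rate,
    clonal_fraction = clonal_fraction, low_q_fraction = low_q_fraction,
    expression = expression,
    tag_count = as.integer(tag_count), tag_internal_p = tag_internal_p,
    tag_error_rate = tag_error_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ctg <- cfg$contigs
  if (!all(c("name", "length", "is_chloroplast") %in% names(ctg)))
    stop("contigs needs columns name, length, is_chloroplast")
  if (sum(ctg$is_chloroplast) != 1L)
    stop("exactly one contig must be flagged as chloroplast")
  if (any(ctg$length < 1000L))
    stop("contig lengths must be >= 1000 bp")
  if (!cfg$read_length %in% c(44L, 75L))
    stop("read_length must be 44 or 75")
  probs <- c(cfg$non_conversion_rate, cfg$seq_error_rate, cfg$clonal_fraction,
             cfg$low_q_fraction, cfg$dm_fraction, cfg$tag_internal_p,
             cfg$tag_error_rate, cfg$snp_branch_rates,
             cfg$methylation_levels$level)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (length(cfg$insert_range) != 2L || cfg$insert_range[1] > cfg$insert_range[2])
    stop("insert_range must be an increasing pair")
  if (cfg$insert_range[1] < cfg$read_length)
    stop("insert_range lower bound must be >= read_length")
  expected <- c("cult1", "cult2", "wild1", "wild2", "cult_stem", "wild_stem")
  if (!all(expected %in% names(cfg$snp_branch_rates)))
    stop("snp_branch_rates must name all branches: ",
         paste(expected, collapse = ", "))
  if (!cfg$dm_region %in% c("promoter", "gene_body", "TTR"))
    stop("dm_region must be one of promoter, gene_body, TTR")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  nuc <- sum(x$contigs$length[!x$contigs$is_chloroplast])
  cat("Synthetic BS-Seq study configuration\n",
      sprintf("  contigs: %d (%d bp nuclear + chloroplast control)\n",
              nrow(x$contigs), nuc),
      sprintf("  features: %d genes, %d TEs, %d smRNA loci\n",
              x$gene_count, x$te_count, x$smrna_count),
      sprintf("  reads: %d nt paired, depth %.1fx/strand, insert %d-%d bp\n",
              x$read_length, x$depth, x$insert_range[1], x$insert_range[2]),
      sprintf("  null C-retention: %.4f (+ seq error %.4f)\n",
              x$non_conversion_rate, x$seq_error_rate),
      sprintf("  planted DM: %.0f%% of genes, shift %.2f in %s\n",
              100 * x$dm_fraction, x$dm_shift, x$dm_region),
      sep = "")
  invisible(x)
}
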