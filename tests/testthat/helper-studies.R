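# Shared synthetic studies, built once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.study_cache[[name]])) .study_cache[[name]] <- builder()
  .study_cache[[name]]
}

# small two-contig config for cheap unit tests
tiny_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         contigs = data.frame(name = c("chr1", "chrC"),
                              length = c(20000L, 5000L),
                              is_chloroplast = c(FALSE, TRUE)),
         gene_count = 8L, te_count = 6L, smrna_count = 4L, depth = 10),
    list(...))
  do.call(sim_config, args)
}

# the main four-sample study: planted DM genes, SNPs, group-structured
# expression; used by recovery and comparative tests
main_config <- function() {
  sim_config(
    seed = 42L,
    contigs = data.frame(name = c("chr1", "chr2", "chrC"),
                         length = c(60000L, 40000L, 6000L),
                         is_chloroplast = c(FALSE, FALSE, TRUE)),
    gene_count = 30L, gene_length = c(600L, 1200L),
    te_count = 15L, smrna_count = 10L,
    depth = 15, dm_fraction = 0.5, dm_shift = 0.4, dm_region = "promoter")
}

main_study <- function() cached("main", function() {
  cfg <- main_config()
  gen <- generate_genome(cfg)
  truth <- assign_methylation_truth(gen$genome, gen$annotation, cfg)
  geno <- plant_snps(gen$genome, cfg)
  refs <- build_converted_references(gen$genome)
  chloro <- "chrC"
  sites <- list(); snps <- list(); aligned <- list()
  restored_cult1 <- NULL
  for (s in BSD_SAMPLES) {
    pr <- simulate_bs_reads(gen$genome, truth, s, cfg, geno, gen$annotation)
    aln <- dedupe_clonal(align_read_pairs(pr, refs))
    res <- restore_alignments(aln, gen$genome)
    st <- pileup_cytosines(res, gen$genome)
    err <- estimate_error_rate(st, chloro)
    called <- call_methylation(st, err$p_err)
    data.table::setattr(called, "p_err", err$p_err)
    sites[[s]] <- called
    snps[[s]] <- call_snps(res, gen$genome)
    aligned[[s]] <- aln[, .(read_id, contig, frag_start, frag_end, origin,
                            mm)]
    if (s == "cult1") restored_cult1 <- res
  }
  cdnas <- extract_cdnas(gen$genome, gen$annotation)
  expr_truth <- simulate_expression_truth(gen$annotation, cfg,
                                          attr(truth, "dm_genes"))
  db <- build_tag_database(cdnas)
  expression <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES),
                       function(s) {
    tg <- simulate_dge_library(cdnas, expr_truth[[s]], cfg, s)
    normalize_per_million(map_tags(tg, db))
  })
  cyt <- reference_cytosines(gen$genome)
  list(cfg = cfg, genome = gen$genome, annotation = gen$annotation,
       truth = truth, genotypes = geno, sites = sites, snps = snps,
       aligned = aligned, restored_cult1 = restored_cult1,
       cdnas = cdnas, tag_db = db, expr_truth = expr_truth,
       expression = expression, cytosines = cyt,
       dm_genes = attr(truth, "dm_genes"))
})

# error-free single-sample study with ~500 planted SNPs at 10x/strand
snp_study <- function() cached("snp", function() {
  cfg <- sim_config(
    seed = 5L,
    contigs = data.frame(name = c("chr1", "chrC"),
                         length = c(40000L, 4000L),
                         is_chloroplast = c(FALSE, TRUE)),
    gene_count = 0L, te_count = 0L, smrna_count = 0L,
    depth = 10, seq_error_rate = 0, clonal_fraction = 0,
    dm_fraction = 0,
    snp_branch_rates = c(cult1 = 0.0125, cult2 = 0, wild1 = 0, wild2 = 0,
                         cult_stem = 0, wild_stem = 0))
  gen <- generate_genome(cfg)
  truth <- assign_methylation_truth(gen$genome, gen$annotation, cfg)
  geno <- plant_snps(gen$genome, cfg)
  pr <- simulate_bs_reads(gen$genome, truth, "cult1", cfg, geno,
                          gen$annotation)
  refs <- build_converted_references(gen$genome)
  aln <- dedupe_clonal(align_read_pairs(pr, refs))
  res <- restore_alignments(aln, gen$genome)
  list(cfg = cfg, genome = gen$genome, truth = truth, genotypes = geno,
       pairs = pr, aligned = aln, restored = res,
       calls = call_snps(res, gen$genome))
})

# single sample at 30x depth for compartment-mean and error-rate recovery
deep_study <- function() cached("deep", function() {
  cfg <- tiny_config(seed = 13L, depth = 30, dm_fraction = 0)
  gen <- generate_genome(cfg)
  truth <- assign_methylation_truth(gen$genome, gen$annotation, cfg)
  pr <- simulate_bs_reads(gen$genome, truth, "cult1", cfg, NULL,
                          gen$annotation)
  refs <- build_converted_references(gen$genome)
  res <- restore_alignments(dedupe_clonal(align_read_pairs(pr, refs)),
                            gen$genome)
  st <- pileup_cytosines(res, gen$genome)
  err <- estimate_error_rate(st, "chrC")
  list(cfg = cfg, genome = gen$genome, annotation = gen$annotation,
       truth = truth, pairs = pr, restored = res, sites = st, err = err,
       called = call_methylation(st, err$p_err),
       cytosines = reference_cytosines(gen$genome))
})
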