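# End-to-end orchestration: configuration loading with validated defaults
# and a staged simulate -> align -> callmeth -> callsnp -> metrics -> dge
# -> compare pipeline with a reproducibility manifest.

.PIPELINE_STAGES <- c("simulate", "align", "callmeth", "callsnp", "metrics",
                      "dge", "compare")

.default_pipeline_config <- function() {
  list(
    out_dir = "bsdiverge_out",
    stages = .PIPELINE_STAGES,
    thresholds = list(
      q_mc = 20L, q_snp = 30L, snp_depth = 5L, snp_fraction = 0.9,
      alpha = 0.05, coverage = 0.8, fold = 2, window = 50000L,
      step = 25000L, promoter_bp = 200L, ttr_bp = 200L, bin_pct = 5,
      bin_step_pct = 2.5, flank_gene = 2000L, flank_te = 500L,
      mismatch_44 = 2L, mismatch_75 = 4L, max_insert = 600L),
    sim = list(seed = 1L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file of pipeline settings, fills omitted keys with the
#' defaults (the mC base quality Q20, SNP base quality Q30, SNP depth 5
#' with 0.9 consensus fraction, alpha 0.05, 80% region coverage, 2-fold
#' expression change, 50 kb/25 kb windows, 200 bp promoter/TTR, 5%/2.5%
#' metagene bins, mismatch caps 2/4 for 44/75 nt reads) and validates
#' them.  An empty or missing file yields the pure defaults.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional named list merged over the file values.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_pipeline_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path) %||% list()
  }
  user <- utils::modifyList(user, overrides)
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(user$thresholds)) {
    badt <- setdiff(names(user$thresholds), names(cfg$thresholds))
    if (length(badt)) stop("unknown threshold key(s): ",
                           paste(badt, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, user)
  th <- cfg$thresholds
  if (!(th$alpha > 0 && th$alpha < 1)) stop("invalid value for alpha")
  if (!(th$coverage > 0 && th$coverage <= 1))
    stop("invalid value for coverage")
  for (k in c("q_mc", "q_snp", "snp_depth", "fold", "window", "step",
              "promoter_bp", "ttr_bp", "bin_pct", "bin_step_pct",
              "flank_gene", "flank_te", "mismatch_44", "mismatch_75",
              "max_insert"))
    if (!(is.numeric(th[[k]]) && th[[k]] > 0))
      stop("invalid value for ", k)
  if (!(th$snp_fraction > 0.5 && th$snp_fraction <= 1))
    stop("invalid value for snp_fraction")
  bad_stage <- setdiff(cfg$stages, .PIPELINE_STAGES)
  if (length(bad_stage)) stop("unknown stage(s): ",
                              paste(bad_stage, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialise a pipeline configuration back to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
dump_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

.require_artifact <- function(env, name, stage_needed) {
  if (is.null(env[[name]]))
    stop("missing upstream artifact '", name, "': run stage '",
         stage_needed, "' first")
  env[[name]]
}

#' Run the analysis pipeline on the built-in synthetic study
#'
#' Executes the requested stages in fixed order (simulate, align,
#' callmeth, callsnp, metrics, dge, compare), writing tab-delimited
#' reports, FASTA/FASTQ/BED/GFF3 files and Newick trees under
#' `config$out_dir`, plus a manifest of output file checksums and the
#' seeds used.  Stage dependencies are enforced: requesting a stage whose
#' inputs were not produced (in this call) raises an error naming the
#' stage to run first.
#'
#' @param config A `pipeline_config` from [load_config()].
#' @param stages Stages to run (default from the config).
#' @return Invisibly, an environment holding the in-memory artifacts
#'   (`sim`, `alignments`, `sites`, `snps`, `expression`, ...).
#' @export
run_pipeline <- function(config, stages = config$stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf("[bsdiverge +%.1fs] ",
                                           as.numeric(Sys.time() - t0)), ...)

  if ("simulate" %in% stages) {
    log_msg("simulate: generating the synthetic four-sample study")
    scfg <- do.call(sim_config, config$sim)
    gen <- generate_genome(scfg)
    truth <- assign_methylation_truth(gen$genome, gen$annotation, scfg)
    geno <- plant_snps(gen$genome, scfg)
    env$sim_config <- scfg
    env$sim <- list(genome = gen$genome, annotation = gen$annotation,
                    truth = truth, genotypes = geno)
    write_fasta(gen$genome, file.path(config$out_dir, "genome.fa"))
    write_gff3(gen$annotation$genes, file.path(config$out_dir, "genes.gff3"))
    write_bed(gen$annotation$tes, file.path(config$out_dir, "te.bed"),
              name_col = "te_id")
    write_bed(gen$annotation$smrnas, file.path(config$out_dir, "smrna.bed"),
              name_col = "smrna_id")
    cdnas <- extract_cdnas(gen$genome, gen$annotation)
    if (length(cdnas))
      write_fasta(cdnas, file.path(config$out_dir, "cdnas.fa"))
    env$cdnas <- cdnas
    env$reads <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES),
                        function(s) {
      pr <- simulate_bs_reads(gen$genome, truth, s, scfg, geno,
                              gen$annotation)
      write_fastq_pairs(pr,
                        file.path(config$out_dir, paste0(s, "_1.fastq")),
                        file.path(config$out_dir, paste0(s, "_2.fastq")))
      pr
    })
    env$expr_truth <- simulate_expression_truth(gen$annotation, scfg,
                                                attr(truth, "dm_genes"))
    env$tags <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES),
                       function(s)
      simulate_dge_library(cdnas, env$expr_truth[[s]], scfg, s))
  }

  if ("align" %in% stages) {
    log_msg("align: three-letter mapping and clonal dedup")
    sim <- .require_artifact(env, "sim", "simulate")
    refs <- build_converted_references(sim$genome)
    env$refs <- refs
    cap <- if (env$sim_config$read_length <= 44L) th$mismatch_44
           else th$mismatch_75
    env$alignments <- lapply(env$reads, function(pr) {
      aln <- align_read_pairs(pr, refs, max_mismatches = cap,
                              max_insert = th$max_insert)
      dedupe_clonal(aln)
    })
    for (s in names(env$alignments))
      write_alignment_report(env$alignments[[s]],
                             file.path(config$out_dir,
                                       paste0(s, "_alignments.tsv")))
  }

  if ("callmeth" %in% stages) {
    log_msg("callmeth: pileup, chloroplast calibration, binomial calls")
    sim <- .require_artifact(env, "sim", "simulate")
    alns <- .require_artifact(env, "alignments", "align")
    chloro <- sim$annotation$contigs$name[sim$annotation$contigs$is_chloroplast]
    env$restored <- lapply(alns, restore_alignments, genome = sim$genome)
    env$sites <- lapply(env$restored, function(r) {
      st <- pileup_cytosines(r, sim$genome, q_min = th$q_mc)
      err <- estimate_error_rate(st, chloro)
      out <- call_methylation(st, err$p_err, alpha = th$alpha)
      data.table::setattr(out, "p_err", err$p_err)
      out
    })
    for (s in names(env$sites))
      write_site_report(env$sites[[s]],
                        file.path(config$out_dir, paste0(s, "_sites.tsv")))
  }

  if ("callsnp" %in% stages) {
    log_msg("callsnp: strand-resolved genotype calls")
    sim <- .require_artifact(env, "sim", "simulate")
    restored <- .require_artifact(env, "restored", "callmeth")
    env$snps <- lapply(restored, function(r)
      call_snps(r, sim$genome, q_min = th$q_snp, min_depth = th$snp_depth,
                min_fraction = th$snp_fraction))
    for (s in names(env$snps))
      write_genotype_report(env$snps[[s]],
                            file.path(config$out_dir,
                                      paste0(s, "_genotypes.tsv")))
  }

  if ("metrics" %in% stages) {
    log_msg("metrics: region levels, windows, metagene profiles")
    sim <- .require_artifact(env, "sim", "simulate")
    sites <- .require_artifact(env, "sites", "callmeth")
    cyt <- reference_cytosines(sim$genome)
    env$cytosines <- cyt
    regions <- annotation_regions(sim$annotation)
    env$regions <- regions
    lens <- stats::setNames(sim$annotation$contigs$length,
                            sim$annotation$contigs$name)
    env$windows <- sliding_windows(lens, th$window, th$step)
    env$region_meth <- lapply(sites, region_levels, regions = regions,
                              cytosines = cyt)
    env$window_meth <- lapply(sites, region_levels, regions = env$windows,
                              cytosines = cyt)
    for (s in names(env$region_meth)) {
      data.table::fwrite(env$region_meth[[s]],
                         file.path(config$out_dir,
                                   paste0(s, "_region_methylation.tsv")),
                         sep = "\t")
      data.table::fwrite(
        env$window_meth[[s]][, .(contig, start0, end0, absolute_level)],
        file.path(config$out_dir, paste0(s, "_windows.bedgraph")),
        sep = "\t", col.names = FALSE)
    }
  }

  if ("dge" %in% stages) {
    log_msg("dge: tag database, mapping, per-million normalisation")
    cdnas <- .require_artifact(env, "cdnas", "simulate")
    tags <- .require_artifact(env, "tags", "simulate")
    db <- build_tag_database(cdnas)
    env$tag_db <- db
    env$expression <- lapply(tags, function(tg) {
      prof <- map_tags(tg, db)
      normalize_per_million(prof)
    })
    for (s in names(env$expression))
      data.table::fwrite(env$expression[[s]],
                         file.path(config$out_dir,
                                   paste0(s, "_expression.tsv")),
                         sep = "\t")
  }

  if ("compare" %in% stages) {
    log_msg("compare: trees, divergence windows, DM genes")
    sim <- .require_artifact(env, "sim", "simulate")
    sites <- .require_artifact(env, "sites", "callmeth")
    snps <- .require_artifact(env, "snps", "callsnp")
    wmeth <- .require_artifact(env, "window_meth", "metrics")
    expr <- .require_artifact(env, "expression", "dge")
    cyt <- env$cytosines
    # genotype matrix over the union of called positions
    geno_wide <- Reduce(function(a, b) merge(a, b, by = c("contig", "pos0"),
                                             all = TRUE),
                        lapply(BSD_SAMPLES, function(s)
                          snps[[s]][status == "called",
                                    .(contig, pos0, x = sample_base)][
                            , stats::setNames(.SD, c("contig", "pos0", s))]))
    env$geno_wide <- geno_wide
    meth_mat <- Reduce(cbind, lapply(BSD_SAMPLES, function(s)
      wmeth[[s]]$absolute_level))
    colnames(meth_mat) <- BSD_SAMPLES
    expr_mat <- Reduce(cbind, lapply(BSD_SAMPLES, function(s)
      log2(expr[[s]]$per_million + 1)))
    colnames(expr_mat) <- BSD_SAMPLES
    env$trees <- list(
      methylation = tryCatch(correlation_tree(meth_mat),
                             error = function(e) NULL),
      expression = tryCatch(correlation_tree(expr_mat),
                            error = function(e) NULL),
      genomic = tryCatch(nj_tree(geno_wide), error = function(e) NULL))
    for (nm in names(env$trees))
      if (!is.null(env$trees[[nm]]))
        writeLines(env$trees[[nm]]$newick,
                   file.path(config$out_dir, paste0("tree_", nm, ".nwk")))
    env$divergence <- divergence_windows(geno_wide, sites, env$windows)
    data.table::fwrite(env$divergence,
                       file.path(config$out_dir, "divergence_windows.tsv"),
                       sep = "\t")
    gene_regions <- env$regions[kind %in% c("promoter", "gene_body", "TTR")]
    env$dm <- identify_dm_genes(sites, gene_regions, cyt,
                                alpha = th$alpha,
                                min_coverage = th$coverage)
    data.table::fwrite(env$dm$results,
                       file.path(config$out_dir, "dm_genes.tsv"), sep = "\t")
    expr_wide <- Reduce(function(a, b) merge(a, b, by = "gene"),
                        lapply(BSD_SAMPLES, function(s)
                          expr[[s]][, stats::setNames(.(gene, per_million),
                                                      c("gene", s))]))
    env$dm_overlap <- dm_expression_overlap(env$dm$results, expr_wide,
                                            fold = th$fold)
  }

  # manifest: seed + md5 of every emitted file
  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    seed = config$sim$seed %||% NA_integer_,
    stages = stages,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(env)
}

#' True per-sample expression abundances for the synthetic study
#'
#' Gene abundances are log-normal; a configured fraction of genes carries
#' a cultivated-vs-wild fold change (random direction), planted DM genes
#' are coupled to an expression change in the direction implied by their
#' methylation shift with probability `expression$dm_coupling`, and
#' samples within a group differ by independent log-normal noise.
#'
#' @param annotation Annotation list.
#' @param config The [sim_config()].
#' @param dm_genes Optional `data.table` (`gene_id`, `direction`) of
#'   planted DM genes.
#' @return Named list (per sample) of named abundance vectors.
#' @export
simulate_expression_truth <- function(annotation, config, dm_genes = NULL) {
  set.seed(derive_seed(config$seed, "expression"))
  g <- annotation$genes$gene_id
  ex <- config$expression
  base <- stats::rlnorm(length(g), ex$meanlog, ex$sdlog)
  names(base) <- g
  fold <- rep(1, length(g))
  names(fold) <- g
  n_grp <- round(ex$group_fraction * length(g))
  if (n_grp > 0L) {
    sel <- sample(g, n_grp)
    up <- stats::runif(n_grp) < 0.5
    fold[sel] <- ifelse(up, ex$group_fold, 1 / ex$group_fold)
  }
  if (!is.null(dm_genes) && nrow(dm_genes)) {
    couple <- dm_genes[stats::runif(nrow(dm_genes)) < ex$dm_coupling]
    if (nrow(couple)) {
      # methylation gain in cultivated implies expression loss there
      fold[couple$gene_id] <- ifelse(couple$direction == "up_in_cultivated",
                                     1 / ex$group_fold, ex$group_fold)
    }
  }
  out <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES), function(s) {
    # split the fold symmetrically: cultivated x sqrt(fold), wild / sqrt(fold)
    grp_fold <- if (s %in% BSD_CULTIVATED) sqrt(fold) else 1 / sqrt(fold)
    noise <- stats::rlnorm(length(g), 0, ex$within_sd)
    stats::setNames(base * grp_fold * noise, g)
  })
  out
}
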