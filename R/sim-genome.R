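# Synthetic reference genome, annotation, methylation truth and planted SNPs.

#' Generate a synthetic reference genome and annotation
#'
#' Draws seeded random contig sequences over A/C/G/T and places
#' non-overlapping gene models (with strand-aware 200 bp promoters and
#' TTRs), TE intervals and smRNA loci on the nuclear contigs.  The
#' chloroplast contig carries no features.  All features, including gene
#' flanks, are mutually disjoint so that every cytosine belongs to exactly
#' one compartment.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (named character vector of contig
#'   sequences), `annotation` (list of `data.table`s `genes`, `tes`,
#'   `smrnas`, plus the `contigs` table) — coordinates are 0-based
#'   half-open internally.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  ctg <- config$contigs
  genome <- vapply(seq_len(nrow(ctg)), function(i) {
    paste(sample(DNA_BASES, ctg$length[i], replace = TRUE), collapse = "")
  }, character(1L))
  names(genome) <- ctg$name

  nuc <- ctg[!ctg$is_chloroplast, , drop = FALSE]
  # one occupancy mask per nuclear contig; features claim their span plus a
  # pad so compartments (incl. promoters/TTRs) never touch
  masks <- lapply(seq_len(nrow(nuc)), function(i) logical(nuc$length[i]))
  names(masks) <- nuc$name

  place <- function(n, len_range, pad, what) {
    out <- vector("list", n)
    if (n == 0L) {
      return(data.table::data.table(contig = character(), start0 = integer(),
                                    end0 = integer()))
    }
    w <- nuc$length / sum(nuc$length)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        ci <- sample(nrow(nuc), 1L, prob = w)
        cname <- nuc$name[ci]
        L <- nuc$length[ci]
        len <- sample(len_range[1]:len_range[2], 1L)
        lo <- pad + 1L
        hi <- L - len - pad
        if (hi < lo) next
        s <- sample(lo:hi, 1L)  # 1-based start of feature
        span <- (s - pad):(s + len - 1L + pad)
        if (any(masks[[cname]][span])) next
        masks[[cname]][span] <<- TRUE
        out[[i]] <- data.table::data.table(contig = cname, start0 = s - 1L,
                                           end0 = s - 1L + len)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", what, " #", i,
             ": configuration requests more features than fit")
    }
    data.table::rbindlist(out)
  }

  gene_pad <- max(config$promoter_bp, config$ttr_bp) + 50L
  genes <- place(config$gene_count, config$gene_length, gene_pad, "gene")
  if (nrow(genes)) {
    genes[, gene_id := sprintf("g%03d", .I)]
    genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    pb <- config$promoter_bp; tb <- config$ttr_bp
    genes[, `:=`(
      prom_start0 = ifelse(strand == "+", start0 - pb, end0),
      prom_end0   = ifelse(strand == "+", start0, end0 + pb),
      ttr_start0  = ifelse(strand == "+", end0, start0 - tb),
      ttr_end0    = ifelse(strand == "+", end0 + tb, start0)
    )]
    data.table::setcolorder(genes, c("gene_id", "contig", "start0", "end0",
                                     "strand"))
  } else {
    genes <- data.table::data.table(
      gene_id = character(), contig = character(), start0 = integer(),
      end0 = integer(), strand = character(), prom_start0 = integer(),
      prom_end0 = integer(), ttr_start0 = integer(), ttr_end0 = integer())
  }

  tes <- place(config$te_count, config$te_length, 10L, "TE")
  if (nrow(tes)) tes[, te_id := sprintf("te%03d", .I)]
  else tes[, te_id := character()]
  smrnas <- place(config$smrna_count, config$smrna_length, 5L, "smRNA locus")
  if (nrow(smrnas)) smrnas[, smrna_id := sprintf("sm%03d", .I)]
  else smrnas[, smrna_id := character()]

  list(genome = genome,
       annotation = list(genes = genes[], tes = tes[], smrnas = smrnas[],
                         contigs = ctg))
}

#' Tabulate reference cytosines on both strands with sequence context
#'
#' Context is derived from the reference alone: the one/two bases following
#' the cytosine on its own strand give CG, CHG or CHH (H = A, C or T);
#' sites within 2 bp of a contig end are labelled "unknown".
#'
#' @param genome Named character vector of contig sequences.
#' @return Keyed `data.table` with columns `contig`, `pos0` (0-based, plus
#'   strand coordinates), `strand`, `context`.
#' @export
reference_cytosines <- function(genome) {
  res <- lapply(names(genome), function(ctg) {
    v <- strsplit(genome[[ctg]], NULL, fixed = TRUE)[[1L]]
    L <- length(v)
    cp <- which(v == "C")   # 1-based
    cm <- which(v == "G")
    ctx_p <- rep("CHH", length(cp))
    nxt1 <- ifelse(cp + 1L <= L, v[cp + 1L], "")
    nxt2 <- ifelse(cp + 2L <= L, v[pmin(cp + 2L, L)], "")
    ctx_p[nxt1 == "G"] <- "CG"
    ctx_p[nxt1 != "G" & nxt2 == "G"] <- "CHG"
    ctx_p[cp > L - 2L] <- "unknown"
    ctx_m <- rep("CHH", length(cm))
    prv1 <- ifelse(cm - 1L >= 1L, v[pmax(cm - 1L, 1L)], "")
    prv2 <- ifelse(cm - 2L >= 1L, v[pmax(cm - 2L, 1L)], "")
    ctx_m[prv1 == "C"] <- "CG"
    ctx_m[prv1 != "C" & prv2 == "C"] <- "CHG"
    ctx_m[cm < 3L] <- "unknown"
    data.table::data.table(
      contig = ctg,
      pos0 = c(cp, cm) - 1L,
      strand = rep(c("+", "-"), c(length(cp), length(cm))),
      context = c(ctx_p, ctx_m))
  })
  out <- data.table::rbindlist(res)
  data.table::setkey(out, contig, pos0, strand)
  out[]
}

#' Long-format genic/TE region table from an annotation
#'
#' @param annotation Annotation list from [generate_genome()].
#' @param kinds Region kinds to emit (subset of promoter, gene_body, TTR,
#'   TE, smRNA).
#' @return `data.table` with `region_id`, `gene_id` (NA for TEs/smRNAs),
#'   `kind`, `contig`, `start0`, `end0`, `strand`.
#' @export
annotation_regions <- function(annotation,
                               kinds = c("promoter", "gene_body", "TTR",
                                         "TE", "smRNA")) {
  g <- annotation$genes
  parts <- list()
  if ("promoter" %in% kinds && nrow(g))
    parts$promoter <- g[, .(region_id = paste0(gene_id, ":promoter"),
                            gene_id, kind = "promoter", contig,
                            start0 = prom_start0, end0 = prom_end0, strand)]
  if ("gene_body" %in% kinds && nrow(g))
    parts$gene_body <- g[, .(region_id = paste0(gene_id, ":gene_body"),
                             gene_id, kind = "gene_body", contig,
                             start0, end0, strand)]
  if ("TTR" %in% kinds && nrow(g))
    parts$ttr <- g[, .(region_id = paste0(gene_id, ":TTR"),
                       gene_id, kind = "TTR", contig,
                       start0 = ttr_start0, end0 = ttr_end0, strand)]
  if ("TE" %in% kinds && nrow(annotation$tes))
    parts$te <- annotation$tes[, .(region_id = te_id, gene_id = NA_character_,
                                   kind = "TE", contig, start0, end0,
                                   strand = "*")]
  if ("smRNA" %in% kinds && nrow(annotation$smrnas))
    parts$sm <- annotation$smrnas[, .(region_id = smrna_id,
                                      gene_id = NA_character_, kind = "smRNA",
                                      contig, start0, end0, strand = "*")]
  out <- data.table::rbindlist(parts, use.names = TRUE)
  if (nrow(out) == 0L)
    out <- data.table::data.table(region_id = character(),
                                  gene_id = character(), kind = character(),
                                  contig = character(), start0 = integer(),
                                  end0 = integer(), strand = character())
  out[]
}

# per-contig compartment label vectors (length = contig length)
compartment_map <- function(genome, annotation) {
  ctg <- annotation$contigs
  maps <- lapply(seq_len(nrow(ctg)), function(i) {
    L <- ctg$length[i]
    if (ctg$is_chloroplast[i]) return(rep("chloroplast", L))
    m <- rep("intergenic", L)
    reg <- annotation_regions(annotation)
    reg <- reg[contig == ctg$name[i]]
    # smRNA loci are not a methylation compartment of their own
    for (k in c("TE", "promoter", "gene_body", "TTR")) {
      r <- reg[kind == k]
      if (nrow(r)) {
        idx <- unlist(Map(function(s, e) (s + 1L):e, r$start0, r$end0))
        m[idx] <- k
      }
    }
    m
  })
  names(maps) <- ctg$name
  maps
}

#' Assign per-sample methylation truth probabilities
#'
#' Every reference cytosine (both strands) receives a methylation
#' probability drawn from a Beta distribution whose mean is the
#' compartment-by-context mean in the configuration (so sample means
#' recover the configured values).  The per-site draw is shared across the
#' four samples; genes selected for planted differential methylation get
#' the configured shift added in the designated region for one group
#' (half of the selected genes are shifted up in the cultivated pair, half
#' up in the wild pair).  Chloroplast cytosines are fixed at probability 0.
#'
#' @param genome,annotation Output of [generate_genome()].
#' @param config The [sim_config()].
#' @return Keyed `data.table` with `contig`, `pos0`, `strand`, `context`,
#'   `compartment`, `gene_id`, `gene_kind`, `base_prob` and one probability
#'   column per sample; attribute `dm_genes` records the planted genes and
#'   their direction.
#' @export
assign_methylation_truth <- function(genome, annotation, config) {
  set.seed(derive_seed(config$seed, "methylation"))
  cyt <- reference_cytosines(genome)
  cmap <- compartment_map(genome, annotation)
  cyt[, compartment := cmap[[.BY$contig]][pos0 + 1L], by = contig]

  # genic membership (for DM bookkeeping); features are disjoint so a site
  # maps to at most one gene region
  reg <- annotation_regions(annotation, c("promoter", "gene_body", "TTR"))
  cyt[, `:=`(gene_id = NA_character_, gene_kind = NA_character_)]
  if (nrow(reg)) {
    reg2 <- data.table::copy(reg)[, `:=`(xstart = start0, xend = end0 - 1L)]
    pts <- cyt[, .(contig, xstart = pos0, xend = pos0)]
    ov <- overlap_which(pts, reg2)
    cyt[ov$xid, `:=`(gene_id = reg2$gene_id[ov$yid],
                     gene_kind = reg2$kind[ov$yid])]
  }

  lv <- config$methylation_levels
  lv_map <- lv[, stats::setNames(level, paste(compartment, context, sep = "|"))]
  key <- paste(cyt$compartment,
               ifelse(cyt$context == "unknown", "CHH", cyt$context), sep = "|")
  mu <- unname(lv_map[key])
  mu[cyt$compartment == "chloroplast"] <- 0
  mu[is.na(mu)] <- 0

  k <- config$meth_concentration
  p <- numeric(length(mu))
  pos <- mu > 0 & mu < 1
  p[pos] <- stats::rbeta(sum(pos), mu[pos] * k, (1 - mu[pos]) * k)
  p[mu >= 1] <- 1
  cyt[, base_prob := p]

  for (s in BSD_SAMPLES) cyt[, (s) := base_prob]

  dm_genes <- data.table::data.table(gene_id = character(),
                                     direction = character())
  ng <- nrow(annotation$genes)
  n_dm <- round(config$dm_fraction * ng)
  if (n_dm > 0L) {
    ids <- sample(annotation$genes$gene_id, n_dm)
    dirs <- rep(c("up_in_cultivated", "down_in_cultivated"),
                length.out = n_dm)
    dm_genes <- data.table::data.table(gene_id = ids, direction = dirs,
                                       region = config$dm_region)
    up <- ids[dirs == "up_in_cultivated"]
    dn <- ids[dirs == "down_in_cultivated"]
    sel_up <- cyt$gene_id %in% up & cyt$gene_kind == config$dm_region
    sel_dn <- cyt$gene_id %in% dn & cyt$gene_kind == config$dm_region
    for (s in BSD_CULTIVATED)
      cyt[sel_up, (s) := clip01(base_prob + config$dm_shift)]
    for (s in BSD_WILD)
      cyt[sel_dn, (s) := clip01(base_prob + config$dm_shift)]
  }
  data.table::setkey(cyt, contig, pos0, strand)
  data.table::setattr(cyt, "dm_genes", dm_genes)
  cyt[]
}

.BRANCH_CLADES <- list(cult1 = "cult1", cult2 = "cult2",
                       wild1 = "wild1", wild2 = "wild2",
                       cult_stem = c("cult1", "cult2"),
                       wild_stem = c("wild1", "wild2"))

#' Plant phylogenetically structured homozygous SNPs
#'
#' Substitutions are drawn independently per branch of the fixed
#' ((cult1,cult2),(wild1,wild2)) topology at the configured per-base rates
#' and applied to every sample descending from that branch.  All planted
#' SNPs are homozygous and restricted to nuclear contigs; positions are
#' sampled without replacement so the planted count equals the sum of
#' per-branch draws exactly.
#'
#' @param genome Named character vector from [generate_genome()].
#' @param config The [sim_config()].
#' @return `data.table` with `contig`, `pos0`, `ref`, `alt`, `branch` and
#'   one genotype column per sample; attribute `branch_counts` holds the
#'   per-branch draw counts.
#' @export
plant_snps <- function(genome, config) {
  set.seed(derive_seed(config$seed, "snp"))
  ctg <- config$contigs
  nuc <- ctg[!ctg$is_chloroplast, , drop = FALSE]
  offsets <- cumsum(c(0L, nuc$length))[seq_len(nrow(nuc))]
  L_tot <- sum(nuc$length)
  rates <- config$snp_branch_rates[names(.BRANCH_CLADES)]
  n_b <- stats::rbinom(length(rates), L_tot, rates)
  names(n_b) <- names(rates)
  tot <- sum(n_b)
  empty <- data.table::data.table(
    contig = character(), pos0 = integer(), ref = character(),
    alt = character(), branch = character())
  for (s in BSD_SAMPLES) empty[, (s) := character()]
  if (tot == 0L) {
    data.table::setattr(empty, "branch_counts", n_b)
    return(empty[])
  }
  gidx <- sample.int(L_tot, tot)            # global nuclear coordinates
  # contig index such that offset < gidx <= offset + length
  ci <- findInterval(gidx, offsets + 1L)
  pos1 <- gidx - offsets[ci]                # 1-based within contig
  branch <- rep(names(n_b), n_b)
  ref <- substring(genome[nuc$name[ci]], pos1, pos1)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                character(1L), USE.NAMES = FALSE)
  out <- data.table::data.table(contig = nuc$name[ci], pos0 = pos1 - 1L,
                                ref = ref, alt = alt, branch = branch)
  for (s in BSD_SAMPLES)
    out[, (s) := ifelse(vapply(branch, function(b) s %in% .BRANCH_CLADES[[b]],
                               logical(1L)), alt, ref)]
  data.table::setorder(out, contig, pos0)
  data.table::setattr(out, "branch_counts", n_b)
  out[]
}

#' Apply a sample's planted genotypes to the reference genome
#'
#' @param genome Named character vector of contig sequences.
#' @param genotypes Output of [plant_snps()] (may have zero rows).
#' @param sample Sample name.
#' @return Named character vector: the sample's genome.
#' @export
make_sample_genome <- function(genome, genotypes, sample) {
  out <- genome
  if (is.null(genotypes) || nrow(genotypes) == 0L) return(out)
  gs <- genotypes[get(sample) != ref]
  for (ctg in unique(gs$contig)) {
    v <- strsplit(out[[ctg]], NULL, fixed = TRUE)[[1L]]
    rows <- gs[contig == ctg]
    v[rows$pos0 + 1L] <- rows[[sample]]
    out[[ctg]] <- paste(v, collapse = "")
  }
  out
}

#' Extract full-length cDNA sequences from gene models
#'
#' The transcript is the gene-body sequence read 5' to 3' (reverse
#' complemented for minus-strand genes), taken from the reference genome.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotation Annotation list from [generate_genome()].
#' @return Named character vector of cDNA sequences (names = gene ids).
#' @export
extract_cdnas <- function(genome, annotation) {
  g <- annotation$genes
  if (nrow(g) == 0L) return(stats::setNames(character(0L), character(0L)))
  seqs <- substring(genome[g$contig], g$start0 + 1L, g$end0)
  minus <- g$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])
  stats::setNames(seqs, g$gene_id)
}
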