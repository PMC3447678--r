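# Cross-sample analytics: rank tests, methylation-vs-expression profiles,
# divergence trees, genetic-vs-methylation divergence windows, and
# differential-methylation gene identification.

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided p-value by full enumeration of group assignments when
#' m + n <= `exact_max` (ties handled through average ranks), otherwise the
#' normal approximation with tie and continuity correction.  The exact
#' two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))` over the
#' permutation distribution of the rank sum of `x`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Maximum combined size for exact enumeration.
#' @return A p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y)
  all_v <- c(x, y)
  if (data.table::uniqueN(all_v) == 1L) return(1)
  if (m + n <= exact_max) {
    r <- rank(all_v)
    w_obs <- sum(r[seq_len(m)])
    combs <- utils::combn(m + n, m)
    ws <- colSums(matrix(r[combs], nrow = m))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
    return(max(p, .Machine$double.xmin))
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  if (is.na(p)) 1 else max(min(p, 1), .Machine$double.xmin)
}

#' Group genes by region methylation and compare expression
#'
#' Splits genes of one region kind into an unmethylated set and five
#' equal-size quantile groups of methylated genes by absolute methylation
#' level (Group 1 = lowest 20%, Group 5 = highest; ties broken by gene
#' identifier), and tests unmethylated vs methylated expression with the
#' Wilcoxon rank-sum test on log2(count + 1).
#'
#' @param region_meth [region_levels()] output for one region kind, with
#'   `gene_id` resolvable from `region_id` (`"<gene>:<kind>"`).
#' @param expression `data.table` with `gene`, `count` (and optionally
#'   `per_million`) for one sample.
#' @return List: `groups` (`gene_id`, `group` with 0 = unmethylated),
#'   `group_expression` (per-group log2 expression values) and
#'   `p_unmeth_vs_meth` (NA when either set is empty).
#' @export
group_genes_by_methylation <- function(region_meth, expression) {
  rm <- data.table::as.data.table(region_meth)
  if (!"gene_id" %in% names(rm) || all(is.na(rm$gene_id)))
    rm[, gene_id := sub(":.*$", "", region_id)]
  expr <- data.table::as.data.table(expression)
  g <- merge(rm[, .(gene_id, absolute_level)],
             expr[, .(gene_id = gene, count)], by = "gene_id")
  g[, log2_expr := log2(count + 1)]
  unmeth <- g[absolute_level == 0]
  meth <- g[absolute_level > 0]
  if (nrow(meth) > 0L && nrow(meth) < 5L)
    stop("fewer than 5 methylated genes: cannot form quantile groups")
  groups <- data.table::data.table(gene_id = character(), group = integer())
  if (nrow(unmeth))
    groups <- rbind(groups, unmeth[, .(gene_id, group = 0L)])
  if (nrow(meth)) {
    data.table::setorder(meth, absolute_level, gene_id)
    n <- nrow(meth)
    sizes <- rep(n %/% 5L, 5L)
    rem <- n %% 5L
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    meth[, group := rep(1:5, times = sizes)]
    groups <- rbind(groups, meth[, .(gene_id, group)])
  }
  ge <- merge(groups, g[, .(gene_id, log2_expr)], by = "gene_id")
  p <- if (nrow(unmeth) && nrow(meth))
    wilcoxon_rank_sum(unmeth$log2_expr, meth$log2_expr) else NA_real_
  list(groups = groups[], group_expression = ge[], p_unmeth_vs_meth = p)
}

#' Methylation-expression correlation profile along the metagene
#'
#' For every metagene bin, the Spearman correlation across genes between
#' the gene's methylation level in that bin and its expression
#' (log2(count + 1)); genes can be restricted to a set (e.g. genes without
#' promoter methylation) and the excluded genes contribute to no bin.
#'
#' @param per_region `per_region` table from [metagene_profile()] (one
#'   sample), with region ids `"<gene>:gene_body"` or gene ids.
#' @param expression `data.table` with `gene`, `count`.
#' @param measure "abs_level" or "rel_level".
#' @param exclude Optional character vector of gene ids to drop.
#' @param min_genes Minimum genes with data required per bin (default 10).
#' @return `data.table` with `zone`, `bin`, `rho`, `n`.
#' @export
methylation_expression_correlation <- function(per_region, expression,
                                               measure = "abs_level",
                                               exclude = NULL,
                                               min_genes = 10L) {
  pr <- data.table::copy(data.table::as.data.table(per_region))
  pr[, gene_id := sub(":.*$", "", region_id)]
  if (!is.null(exclude)) pr <- pr[!gene_id %in% exclude]
  expr <- data.table::as.data.table(expression)
  expr <- expr[, .(gene_id = gene, log2_expr = log2(count + 1))]
  pr <- merge(pr, expr, by = "gene_id")
  out <- pr[!is.na(get(measure)),
            .(rho = if (.N >= min_genes && stats::sd(get(measure)) > 0 &&
                        stats::sd(log2_expr) > 0)
                stats::cor(get(measure), log2_expr, method = "spearman")
              else NA_real_,
              n = .N),
            by = .(zone, bin)]
  data.table::setorder(out, zone, bin)
  out[]
}

#' Correlation-distance dendrogram of the four samples
#'
#' Distance between samples is 1 minus the pairwise Spearman correlation
#' of their profiles (window methylation levels, per-site mC levels at
#' >= 5x coverage, or expression); samples are clustered agglomeratively
#' (complete linkage by default) and the tree is returned as hclust,
#' phylo and Newick.
#'
#' @param mat Numeric matrix, units in rows, one column per sample.
#' @param linkage hclust linkage method (default "complete").
#' @return List with `hclust`, `phylo`, `newick`, `dist`.
#' @export
correlation_tree <- function(mat, linkage = "complete") {
  mat <- as.matrix(mat)
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop("constant profile for sample(s): ",
         paste(colnames(mat)[is.na(sds) | sds == 0], collapse = ", "),
         " (correlation undefined)")
  d <- 1 - stats::cor(mat, method = "spearman",
                      use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph),
       dist = stats::as.dist(d))
}

#' Pairwise p-distances between samples from genotype calls
#'
#' p-distance = fraction of positions called in both samples whose
#' genotypes differ.
#'
#' @param geno_wide `data.table` with `contig`, `pos0` and one called-base
#'   column per sample (NA = no call).
#' @param samples Sample columns to use.
#' @return Symmetric distance matrix.
#' @export
p_distance_matrix <- function(geno_wide, samples = BSD_SAMPLES) {
  d <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (j <= i) next
    a <- geno_wide[[samples[i]]]
    b <- geno_wide[[samples[j]]]
    both <- !is.na(a) & !is.na(b)
    if (sum(both) == 0L)
      stop("no co-called positions for pair ", samples[i], "/", samples[j])
    d[i, j] <- d[j, i] <- sum(a[both] != b[both]) / sum(both)
  }
  d
}

#' Neighbor-joining genomic tree from genotype calls
#'
#' @param geno_wide As for [p_distance_matrix()].
#' @param samples Sample columns.
#' @return List with `phylo` (unrooted NJ tree), `newick`, `dist`.
#' @export
nj_tree <- function(geno_wide, samples = BSD_SAMPLES) {
  d <- p_distance_matrix(geno_wide, samples)
  ph <- ape::nj(stats::as.dist(d))
  list(phylo = ph, newick = ape::write.tree(ph), dist = d)
}

#' Genetic and methylation divergence in genome windows
#'
#' Per window: pi, the average number of nucleotide differences per site
#' (summed over the 6 sample pairs' co-called differing positions and
#' divided by 6 times the window length — uncalled positions count as
#' non-differing), and the average pairwise Spearman correlation of
#' per-cytosine methylation levels over sites covered at least
#' `min_depth` times in both samples (pairs with fewer than `min_shared`
#' shared sites are omitted from the average).
#'
#' @param geno_wide Genotype calls (`contig`, `pos0`, sample columns).
#' @param site_tables Named list (per sample) of called site tables.
#' @param windows Window table from [sliding_windows()].
#' @param samples Sample names.
#' @param min_depth Minimum coverage per site and sample (default 5).
#' @param min_shared Minimum shared sites per pair per window (default 10).
#' @param contexts Optional context filter for the methylation component.
#' @return The window table with `pi_value`, `mean_r` and `n_pairs_r`.
#' @export
divergence_windows <- function(geno_wide, site_tables, windows,
                               samples = BSD_SAMPLES, min_depth = 5L,
                               min_shared = 10L, contexts = NULL) {
  win <- data.table::copy(data.table::as.data.table(windows))
  pairs <- utils::combn(samples, 2L, simplify = FALSE)
  win[, `:=`(pi_value = 0, mean_r = NA_real_, n_pairs_r = 0L)]

  # genetic component
  if (!is.null(geno_wide) && nrow(geno_wide)) {
    diffs <- lapply(pairs, function(p) {
      a <- geno_wide[[p[1]]]; b <- geno_wide[[p[2]]]
      geno_wide[!is.na(a) & !is.na(b) & a != b, .(contig, pos0)]
    })
    diffs <- data.table::rbindlist(diffs)
    if (nrow(diffs)) {
      rg <- win[, .(region_id, contig, xstart = start0, xend = end0 - 1L)]
      pts <- diffs[, .(contig, xstart = pos0, xend = pos0)]
      ov <- overlap_which(pts, rg)
      if (nrow(ov)) {
        cnt <- data.table::data.table(region_id = rg$region_id[ov$yid])[
          , .(n_diff = .N), by = region_id]
        win[cnt, pi_value := n_diff / (6 * (end0 - start0)),
            on = "region_id"]
      }
    }
  }

  # methylation component
  st <- lapply(site_tables[samples], function(s) {
    s <- s[n_total >= min_depth]
    if (!is.null(contexts)) s <- s[context %in% contexts]
    s[, .(contig, pos0, strand, level)]
  })
  rsum <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    j <- merge(st[[p[1]]], st[[p[2]]], by = c("contig", "pos0", "strand"),
               suffixes = c("_a", "_b"))
    if (nrow(j) == 0L) next
    rg <- win[, .(region_id, contig, xstart = start0, xend = end0 - 1L)]
    pts <- j[, .(contig, xstart = pos0, xend = pos0)]
    ov <- overlap_which(pts, rg)
    if (nrow(ov) == 0L) next
    jj <- cbind(j[ov$xid], region_id = rg$region_id[ov$yid])
    rsum[[k]] <- jj[, {
      ok <- .N >= min_shared && stats::sd(level_a) > 0 &&
        stats::sd(level_b) > 0
      .(r = if (ok) stats::cor(level_a, level_b, method = "spearman")
        else NA_real_)
    }, by = region_id]
  }
  rs <- data.table::rbindlist(rsum[!vapply(rsum, is.null, logical(1L))])
  if (nrow(rs)) {
    agg <- rs[!is.na(r), .(mean_r = mean(r), n_pairs_r = .N), by = region_id]
    win[agg, `:=`(mean_r = i.mean_r, n_pairs_r = i.n_pairs_r),
        on = "region_id"]
  }
  win[]
}

#' Group windows by genetic divergence and summarise methylation divergence
#'
#' Windows are sorted by pi and split into `n_groups` equal-count groups
#' (remainder spread over the first groups); per group the mean pi and the
#' mean correlation are reported.
#'
#' @param windows Output of [divergence_windows()].
#' @param n_groups Number of groups (default 20).
#' @return `data.table` with `group`, `n`, `mean_pi`, `mean_r`.
#' @export
divergence_vs_methylation <- function(windows, n_groups = 20L) {
  w <- data.table::as.data.table(windows)
  if (nrow(w) < n_groups)
    stop("need at least ", n_groups, " windows")
  data.table::setorder(w, pi_value)
  n <- nrow(w)
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  w[, group := rep(seq_len(n_groups), times = sizes)]
  out <- w[, .(n = .N, mean_pi = mean(pi_value),
               mean_r = mean(mean_r, na.rm = TRUE)), by = group]
  out[is.nan(mean_r), mean_r := NA_real_]
  out[]
}

.DM_CROSS_PAIRS <- list(c("cult1", "wild1"), c("cult1", "wild2"),
                        c("cult2", "wild1"), c("cult2", "wild2"))
.DM_WITHIN_PAIRS <- list(c("cult1", "cult2"), c("wild1", "wild2"))

#' Identify differentially methylated genes between groups
#'
#' For each gene region (promoter, gene body, TTR) covered above
#' `min_coverage` (fraction of the region's cytosine sites with at least
#' one read) in all four samples, per-cytosine methylation levels are
#' compared between every sample pair with the Wilcoxon rank-sum test.  A
#' gene is methylation-up (or -down) in the cultivated group when all four
#' cultivated-vs-wild comparisons are significant at `alpha` with a
#' consistent direction while neither within-group comparison is
#' significant.
#'
#' @param site_tables Named list (per sample) of called site tables.
#' @param regions Gene region table ([annotation_regions()] restricted to
#'   promoter/gene_body/TTR).
#' @param cytosines Reference cytosine table.
#' @param alpha Significance level (default 0.05).
#' @param min_coverage Minimum per-sample coverage fraction (default 0.8).
#' @param contexts Optional context filter.
#' @return List: `results` (per region kind: gene, direction, the six
#'   p-values, coverage fractions) and `genes` (non-redundant union of DM
#'   gene ids).
#' @export
identify_dm_genes <- function(site_tables, regions, cytosines,
                              alpha = 0.05, min_coverage = 0.8,
                              contexts = NULL) {
  reg <- data.table::as.data.table(regions)
  reg <- reg[kind %in% c("promoter", "gene_body", "TTR")]
  cyt <- if (is.null(contexts)) cytosines
         else cytosines[context %in% contexts]

  # per-region per-sample level vectors and coverage
  persample <- lapply(BSD_SAMPLES, function(s) {
    st <- site_tables[[s]]
    if (!is.null(contexts)) st <- st[context %in% contexts]
    .sites_in_regions(st, reg)
  })
  names(persample) <- BSD_SAMPLES
  ncs <- .sites_in_regions(cyt, reg)
  ncount <- if (nrow(ncs)) ncs[, .(n_c = .N), by = region_id]
            else data.table::data.table(region_id = character(),
                                        n_c = integer())

  results <- list()
  for (rid in ncount[n_c > 0L, region_id]) {
    vecs <- lapply(persample, function(p)
      if (nrow(p)) p[region_id == rid, level] else numeric(0L))
    n_c <- ncount[region_id == rid, n_c]
    covg <- vapply(vecs, length, integer(1L)) / n_c
    if (any(covg <= min_coverage)) next
    p_cross <- vapply(.DM_CROSS_PAIRS, function(pr)
      wilcoxon_rank_sum(vecs[[pr[1]]], vecs[[pr[2]]]), numeric(1L))
    p_within <- vapply(.DM_WITHIN_PAIRS, function(pr)
      wilcoxon_rank_sum(vecs[[pr[1]]], vecs[[pr[2]]]), numeric(1L))
    dirs <- vapply(.DM_CROSS_PAIRS, function(pr) {
      dlt <- stats::median(vecs[[pr[1]]]) - stats::median(vecs[[pr[2]]])
      if (dlt == 0) dlt <- mean(vecs[[pr[1]]]) - mean(vecs[[pr[2]]])
      sign(dlt)
    }, numeric(1L))
    is_dm <- all(p_cross < alpha) && all(p_within >= alpha) &&
      length(unique(dirs)) == 1L && dirs[1] != 0
    row <- data.table::data.table(
      region_id = rid,
      gene_id = reg[region_id == rid, gene_id][1L],
      kind = reg[region_id == rid, kind][1L],
      is_dm = is_dm,
      direction = if (!is_dm) NA_character_
                  else if (dirs[1] > 0) "up_in_cultivated"
                  else "down_in_cultivated",
      p_c1w1 = p_cross[1], p_c1w2 = p_cross[2],
      p_c2w1 = p_cross[3], p_c2w2 = p_cross[4],
      p_c1c2 = p_within[1], p_w1w2 = p_within[2],
      cov_cult1 = covg[["cult1"]], cov_cult2 = covg[["cult2"]],
      cov_wild1 = covg[["wild1"]], cov_wild2 = covg[["wild2"]])
    results[[rid]] <- row
  }
  res <- data.table::rbindlist(results)
  if (nrow(res) == 0L)
    res <- data.table::data.table(
      region_id = character(), gene_id = character(), kind = character(),
      is_dm = logical(), direction = character(), p_c1w1 = numeric(),
      p_c1w2 = numeric(), p_c2w1 = numeric(), p_c2w2 = numeric(),
      p_c1c2 = numeric(), p_w1w2 = numeric(), cov_cult1 = numeric(),
      cov_cult2 = numeric(), cov_wild1 = numeric(), cov_wild2 = numeric())
  list(results = res[], genes = unique(res[is_dm == TRUE, gene_id]))
}

#' Overlap between differential methylation and expression change
#'
#' A DM gene shows a methylation-correlated expression change when its
#' mean cultivated and mean wild per-million expression differ by at least
#' `fold` in the direction implied by the region: methylation gain in
#' promoter or TTR implies expression loss, while gene-body methylation
#' may act in either direction.  The background is the fraction of all
#' analyzable genes with at least a `fold` change in either direction.
#' A pseudocount of 1 per-million unit guards ratios against zeros.
#'
#' @param dm_results `results` table from [identify_dm_genes()] (rows with
#'   `is_dm`).
#' @param expression_wide `data.table` with `gene` and per-sample
#'   per-million columns.
#' @param fold Fold-change threshold (default 2).
#' @return List with `overlap` (per DM gene), `n_overlap`,
#'   `fraction_overlap`, `background_fraction`.
#' @export
dm_expression_overlap <- function(dm_results, expression_wide, fold = 2) {
  expr <- data.table::as.data.table(expression_wide)
  cult <- rowMeans(as.matrix(expr[, BSD_CULTIVATED, with = FALSE])) + 1
  wild <- rowMeans(as.matrix(expr[, BSD_WILD, with = FALSE])) + 1
  fc <- cult / wild   # >1 = higher expression in cultivated
  ed <- data.table::data.table(gene_id = expr$gene, fc = fc)
  background <- mean(pmax(fc, 1 / fc) >= fold)

  dm <- data.table::as.data.table(dm_results)[is_dm == TRUE]
  if (nrow(dm) == 0L)
    return(list(overlap = data.table::data.table(), n_overlap = 0L,
                fraction_overlap = NA_real_,
                background_fraction = background))
  dm <- merge(dm, ed, by = "gene_id")
  dm[, expected_down := data.table::fifelse(
    kind %in% c("promoter", "TTR"),
    direction == "up_in_cultivated", NA)]
  dm[, hit := data.table::fifelse(
    kind == "gene_body", pmax(fc, 1 / fc) >= fold,
    data.table::fifelse(expected_down, fc <= 1 / fold, fc >= fold))]
  list(overlap = dm[, .(gene_id, kind, direction, fc, hit)],
       n_overlap = dm[, sum(hit)],
       fraction_overlap = dm[, mean(hit)],
       background_fraction = background)
}
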