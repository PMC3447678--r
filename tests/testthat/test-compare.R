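# Rank tests, grouping, trees, divergence windows and DM identification.

test_that("wilcoxon p-values match exhaustive enumeration for all small cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(91)
  for (rep in 1:200) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    vals <- sample(1:4, m + n, replace = TRUE)  # heavy ties on purpose
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    expect_equal(wilcoxon_rank_sum(x, y), enum_wilcox(x, y),
                 tolerance = 1e-12,
                 info = paste(c(x, "|", y), collapse = ","))
  }
  # large-sample branch returns a valid p and agrees with wilcox.test
  set.seed(92)
  x <- stats::rnorm(30); y <- stats::rnorm(35, 0.5)
  p <- wilcoxon_rank_sum(x, y)
  expect_equal(p, stats::wilcox.test(x, y, exact = FALSE,
                                     correct = TRUE)$p.value)
})

test_that("methylation quantile groups are balanced and expression-ordered", {
  set.seed(93)
  n <- 100L
  rm <- data.table::data.table(
    region_id = sprintf("g%03d:promoter", 1:120),
    absolute_level = c(rep(0, 20), stats::runif(n, 0.01, 0.6)))
  # plant monotone suppression: the more methylation the less expression
  expr <- data.table::data.table(
    gene = sprintf("g%03d", 1:120),
    count = as.integer(round(1000 * exp(-5 * rm$absolute_level) +
                               stats::rpois(120, 5))))
  g <- group_genes_by_methylation(rm, expr)
  tab <- table(g$groups$group)
  expect_equal(unname(tab[["0"]]), 20L)
  expect_true(all(tab[as.character(1:5)] == 20L))
  expect_lt(g$p_unmeth_vs_meth, 0.05)
  med <- g$group_expression[group %in% c(1L, 5L),
                            stats::median(log2_expr), by = group]
  expect_gt(med[group == 1L, V1], med[group == 5L, V1])

  # all unmethylated: no groups, test skipped
  rm0 <- data.table::copy(rm)[, absolute_level := 0]
  g0 <- group_genes_by_methylation(rm0, expr)
  expect_true(all(g0$groups$group == 0L))
  expect_true(is.na(g0$p_unmeth_vs_meth))
})

test_that("correlation trees are rank-invariant and recover planted groups", {
  set.seed(94)
  base <- stats::rnorm(300)
  mat <- cbind(cult1 = base + stats::rnorm(300, 0, 0.1),
               cult2 = base + stats::rnorm(300, 0, 0.1),
               wild1 = base + 1.5 * stats::rnorm(300, 0, 1),
               wild2 = base + 1.5 * stats::rnorm(300, 0, 1))
  mat[, "wild1"] <- mat[, "wild1"] + mat[, "wild2"]  # correlate the wilds
  tr <- correlation_tree(mat)
  expect_true(has_split(tr$phylo, c("cult1", "cult2")))
  # invariant under a common monotone transform
  tr2 <- correlation_tree(exp(mat / 2))
  expect_equal(tr2$newick, tr$newick)
  # identical samples merge at zero height
  mat2 <- cbind(a = base, b = base, c = stats::rnorm(300),
                d = stats::rnorm(300))
  tr3 <- correlation_tree(mat2)
  expect_equal(min(tr3$hclust$height), 0)
  expect_error(correlation_tree(cbind(a = rep(1, 10), b = stats::rnorm(10),
                                      c = stats::rnorm(10),
                                      d = stats::rnorm(10))), "constant")
})

test_that("p-distances and NJ behave on degenerate and planted inputs", {
  gw <- data.table::data.table(
    contig = "chr", pos0 = 1:50,
    cult1 = "A", cult2 = "A", wild1 = "A", wild2 = "A")
  d <- p_distance_matrix(gw)
  expect_true(all(d == 0))
  tr <- nj_tree(gw)
  expect_true(all(tr$phylo$edge.length < 1e-12))

  ms <- main_study()
  geno_wide <- Reduce(function(a, b) merge(a, b, by = c("contig", "pos0")),
                      lapply(BSD_SAMPLES, function(s)
                        ms$snps[[s]][status == "called",
                                     .(contig, pos0, x = sample_base)][
                          , stats::setNames(.SD, c("contig", "pos0", s))]))
  tr2 <- nj_tree(geno_wide)
  expect_true(has_split(tr2$phylo, c("cult1", "cult2")))
  expect_true(has_split(tr2$phylo, c("wild1", "wild2")))
  # 4-taxon NJ equals the best least-squares topology on these distances
  d2 <- p_distance_matrix(geno_wide)
  lsq <- function(split) {
    # sum of within-split distances underestimates across-split ones in
    # the correct topology; score = across minus within
    others <- setdiff(BSD_SAMPLES, split)
    d2[split[1], split[2]] + d2[others[1], others[2]]
  }
  scores <- c(cc = lsq(c("cult1", "cult2")), cw = lsq(c("cult1", "wild1")),
              cx = lsq(c("cult1", "wild2")))
  expect_equal(names(which.min(scores)), "cc")
})

test_that("divergence windows match the per-base oracle and planted structure", {
  # 3-window toy with hand-planted genotypes
  gw <- data.table::data.table(
    contig = "chr",
    pos0 = c(10L, 20L, 120L, 130L, 220L),
    cult1 = c("A", "C", "G", "T", "A"),
    cult2 = c("A", "C", "G", "T", "A"),
    wild1 = c("T", "C", "G", "T", "A"),
    wild2 = c("T", "G", "G", NA, "A"))
  win <- data.table::data.table(
    region_id = c("w1", "w2", "w3"), kind = "window", contig = "chr",
    start0 = c(0L, 100L, 200L), end0 = c(100L, 200L, 300L), strand = "*")
  sites0 <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES), function(s)
    data.table::data.table(contig = character(), pos0 = integer(),
                           strand = character(), context = character(),
                           n_meth = integer(), n_total = integer(),
                           level = numeric()))
  dv <- divergence_windows(gw, sites0, win)
  expect_equal(dv$pi_value, brute_pi(gw, win))
  # window w1: pos 10 differs in 4 pairs (c1w1,c1w2,c2w1,c2w2), pos 20 in
  # 3 pairs (w2 vs others co-called)... the oracle is the ground truth;
  # also check the all-zero case
  gw0 <- data.table::copy(gw)[, `:=`(wild1 = cult1, wild2 = cult1)]
  dv0 <- divergence_windows(gw0, sites0, win)
  expect_true(all(dv0$pi_value == 0))

  # methylation component: identical site tables give r = 1
  set.seed(95)
  st <- data.table::data.table(
    contig = "chr", pos0 = sort(sample(0:299, 60)), strand = "+",
    context = "CG", n_meth = 3L, n_total = 6L,
    level = stats::runif(60))
  sites1 <- lapply(stats::setNames(BSD_SAMPLES, BSD_SAMPLES),
                   function(s) data.table::copy(st))
  dv1 <- divergence_windows(gw, sites1, win)
  expect_true(all(abs(dv1$mean_r - 1) < 1e-12))
})

test_that("divergence grouping yields balanced groups with monotone planted trend", {
  set.seed(96)
  w <- data.table::data.table(
    region_id = sprintf("w%02d", 1:40), pi_value = stats::runif(40))
  w[, mean_r := 1 - pi_value + stats::rnorm(40, 0, 0.01)]
  g <- divergence_vs_methylation(w, n_groups = 20L)
  expect_equal(nrow(g), 20L)
  expect_true(all(g$n == 2L))
  expect_true(all(diff(g$mean_pi) > 0))
  expect_lt(stats::cor(g$mean_pi, g$mean_r), -0.9)
  expect_error(divergence_vs_methylation(w[1:10], 20L), "at least 20")
  # group sizes differ by at most one for non-divisible counts
  g2 <- divergence_vs_methylation(w[1:33], 20L)
  expect_lte(diff(range(g2$n)), 1L)
})

test_that("planted DM genes are recovered and the rule is label-symmetric", {
  ms <- main_study()
  gene_regions <- annotation_regions(ms$annotation,
                                     c("promoter", "gene_body", "TTR"))
  dm <- identify_dm_genes(ms$sites, gene_regions, ms$cytosines)
  planted <- ms$dm_genes
  found <- dm$results[is_dm == TRUE & kind == "promoter"]
  recall <- mean(planted$gene_id %in% found$gene_id)
  expect_gte(recall, 0.8)
  # direction agrees with the planted shift
  dir <- merge(found, planted, by = "gene_id")
  expect_true(all(dir$direction.x == dir$direction.y))
  # false calls among unshifted genes stay near zero
  false_calls <- found[!gene_id %in% planted$gene_id]
  expect_lte(nrow(false_calls), 1L)

  # swapping the two cultivated samples leaves the result unchanged
  swapped <- ms$sites[c("cult2", "cult1", "wild1", "wild2")]
  names(swapped) <- BSD_SAMPLES
  dm2 <- identify_dm_genes(swapped, gene_regions, ms$cytosines)
  expect_setequal(dm2$genes, dm$genes)
})

test_that("under-covered regions are excluded from DM testing", {
  ms <- main_study()
  gene_regions <- annotation_regions(ms$annotation, "promoter")[1:5]
  # cripple coverage of one region in one sample
  target <- gene_regions[1]
  sites_mod <- ms$sites
  sites_mod$cult1 <- ms$sites$cult1[!(contig == target$contig &
                                        pos0 >= target$start0 &
                                        pos0 < target$end0)]
  dm <- identify_dm_genes(sites_mod, gene_regions, ms$cytosines)
  expect_false(target$region_id %in% dm$results$region_id)
})

test_that("DM-expression overlap honours direction and the fold threshold", {
  dm <- data.table::data.table(
    region_id = c("g1:promoter", "g2:TTR", "g3:gene_body"),
    gene_id = c("g1", "g2", "g3"),
    kind = c("promoter", "TTR", "gene_body"),
    is_dm = TRUE,
    direction = c("up_in_cultivated", "down_in_cultivated",
                  "up_in_cultivated"))
  expr <- data.table::data.table(
    gene = c("g1", "g2", "g3", "g4"),
    cult1 = c(10, 400, 50, 100), cult2 = c(12, 420, 60, 110),
    wild1 = c(100, 100, 10, 100), wild2 = c(120, 110, 12, 105))
  ov <- dm_expression_overlap(dm, expr, fold = 2)
  # g1: promoter up-meth in cultivated, expression 11 vs 110: down => hit
  # g2: TTR down-meth, expression up in cultivated => hit
  # g3: body, >2-fold either way => hit
  expect_equal(ov$n_overlap, 3L)
  expect_equal(ov$fraction_overlap, 1)
  # degenerate threshold counts every expressed DM gene
  ov1 <- dm_expression_overlap(dm, expr, fold = 1)
  expect_equal(ov1$n_overlap, 3L)
  # no DM genes: zero overlap
  ov0 <- dm_expression_overlap(dm[0], expr)
  expect_equal(ov0$n_overlap, 0L)
})
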