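# Pileup, error-rate calibration and binomial methylcytosine calling.

test_that("pileup counts respect the base-quality filter", {
  genome <- c(chr = "AACGTACGTAAC")
  # hand-built restored rows over the plus-strand C at pos0 = 2
  restored <- data.table::data.table(
    read_id = sprintf("r%02d", 1:10), contig = "chr", pos0 = 2L,
    origin = "+", mate = 1L, base = "C", base_plus = "C",
    qual = c(rep(40L, 7L), rep(15L, 3L)))
  st <- pileup_cytosines(restored, genome, q_min = 20L)
  site <- st[pos0 == 2L & strand == "+"]
  expect_equal(site$n_total, 7L)
  expect_equal(site$n_meth, 7L)
  expect_equal(site$level, 1)
  # with all bases passing, the full 10 count
  st0 <- pileup_cytosines(restored, genome, q_min = 0L)
  expect_equal(st0[pos0 == 2L & strand == "+", n_total], 10L)
})

test_that("context assignment partitions covered cytosines away from ends", {
  deep <- deep_study()
  cyt <- deep$cytosines
  lens <- c(chr1 = 20000L, chrC = 5000L)
  inner <- cyt[pos0 >= 2 & pos0 <= lens[contig] - 3L]  # away from ends
  expect_true(all(inner$context %in% c("CG", "CHG", "CHH")))
  # spot-check against the sequence
  v <- strsplit(deep$genome[["chr1"]], NULL)[[1]]
  cg <- cyt[contig == "chr1" & strand == "+" & context == "CG"][1:50]
  expect_true(all(v[cg$pos0 + 2L] == "G"))
  chg <- cyt[contig == "chr1" & strand == "+" & context == "CHG"][1:50]
  expect_true(all(v[chg$pos0 + 2L] != "G" & v[chg$pos0 + 3L] == "G"))
  # minus-strand CG sites sit one base after a plus C
  cgm <- cyt[contig == "chr1" & strand == "-" & context == "CG"][1:50]
  expect_true(all(v[cgm$pos0] == "C"))
})

test_that("the pooled error estimator equals the weighted per-site mean", {
  deep <- deep_study()
  cp <- deep$sites[contig == "chrC"]
  est <- estimate_error_rate(deep$sites, "chrC")
  expect_equal(est$p_err, sum(cp$level * cp$n_total) / sum(cp$n_total))
  expect_equal(est$n_observations, sum(cp$n_total))
  expect_error(estimate_error_rate(deep$sites[contig == "chr1"], "chrC"),
               "chloroplast")
})

test_that("binomial p-values equal the exact tail summation oracle", {
  tail_oracle <- function(m, n, p) sum(stats::dbinom(m:n, n, p))
  for (case in list(c(1, 5), c(2, 5), c(0, 8), c(3, 12), c(10, 10))) {
    m <- case[1]; n <- case[2]
    got <- binomial_call(m, n, 0.0112)
    want <- if (m == 0) 1 else tail_oracle(m, n, 0.0112)
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
  # worked examples at the default combined error rate
  r1 <- binomial_call(1L, 5L, 0.0112)
  expect_equal(r1$p_value, 0.0548, tolerance = 1e-2)
  expect_false(r1$is_mC)
  r2 <- binomial_call(2L, 5L, 0.0112)
  expect_equal(r2$p_value, 0.00123, tolerance = 1e-2)
  expect_true(r2$is_mC)
  r0 <- binomial_call(0L, 5L, 0.0112)
  expect_equal(r0$p_value, 1)
  expect_false(r0$is_mC)
  expect_error(binomial_call(1L, 5L, 1.5), "p_err")
})

test_that("calling is monotone in n_meth and anti-monotone in p_err", {
  for (n in c(3L, 8L, 20L)) {
    calls <- binomial_call(0:n, rep(n, n + 1L), 0.0112)$is_mC
    expect_true(all(diff(calls) >= 0))   # non-decreasing in n_meth
  }
  for (m in 1:5) {
    lo <- binomial_call(m, 6L, 0.005)$is_mC
    hi <- binomial_call(m, 6L, 0.05)$is_mC
    expect_true(lo >= hi)   # raising p_err never creates a call
  }
})

test_that("null sites are called at a rate bounded by alpha at every depth", {
  set.seed(99)
  p_err <- 0.0112
  for (n in c(1L, 3L, 10L, 30L)) {
    m <- stats::rbinom(20000L, n, p_err)
    fpr <- mean(binomial_call(m, rep(n, length(m)), p_err)$is_mC)
    expect_lte(fpr, 0.05)
  }
})

test_that("methylome summary matches hand arithmetic on a toy table", {
  toy <- data.table::data.table(
    contig = "chr", pos0 = 1:6, strand = "+",
    context = c("CG", "CG", "CHG", "CHH", "CG", "CHH"),
    n_meth = c(5L, 0L, 3L, 1L, 4L, 0L),
    n_total = c(5L, 6L, 6L, 8L, 4L, 3L))
  toy[, level := n_meth / n_total]
  toy[, is_mC := c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)]
  s <- summarize_methylome(toy)$summary
  expect_equal(s["CG", n_mC], 2L)
  expect_equal(s["CG", covered], 3L)
  expect_equal(s["CG", density], 2 / 3)
  expect_equal(s["CG", mean_level_mC], mean(c(1, 1)))
  expect_equal(s["CHH", n_mC], 0L)
  expect_equal(s["CHH", density], 0)
  hist <- summarize_methylome(toy)$histogram
  expect_equal(hist[, sum(frac), by = context][, unique(V1)], 1)
})

test_that("compartment-context methylation is recovered at 30x depth", {
  deep <- deep_study()
  j <- merge(deep$sites,
             deep$truth[, .(contig, pos0, strand, compartment,
                            tp = cult1)],
             by = c("contig", "pos0", "strand"))
  for (sel in list(c("TE", "CG"), c("gene_body", "CG"),
                   c("intergenic", "CHH"))) {
    sub <- j[compartment == sel[1] & context == sel[2]]
    expect_gt(nrow(sub), 50L)
    pooled <- sub[, sum(n_meth) / sum(n_total)]
    tmean <- mean(sub$tp)
    # retention inflates the observed rate slightly above truth
    expect_val <- tmean + (1 - tmean) * deep$cfg$non_conversion_rate
    se <- sqrt(expect_val * (1 - expect_val) / sum(sub$n_total)) +
      stats::sd(sub$tp) / sqrt(nrow(sub))
    expect_lt(abs(pooled - expect_val), 3 * se + 0.01)
  }
})

test_that("SNP masking removes non-reference sites from calling", {
  deep <- deep_study()
  mask <- deep$sites[1:5, .(contig, pos0)]
  called <- call_methylation(deep$sites, 0.0112, snp_mask = mask)
  expect_true(all(called[paste(contig, pos0) %in% paste(mask$contig, mask$pos0),
                         masked]))
  expect_false(any(called[masked == TRUE, is_mC]))
})
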