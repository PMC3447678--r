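# Region levels, sliding windows, metagene profiles, densities, CV.

test_that("region levels follow the printed definitions", {
  genome <- c(chr = "ACGTACGTAC")        # 10 bp, C at 1,5,9; G at 2,6
  cyt <- reference_cytosines(genome)
  expect_equal(nrow(cyt), 5L)            # 3 plus C + 2 minus C (G)
  sites <- data.table::data.table(
    contig = "chr", pos0 = c(1L, 5L), strand = "+",
    context = c("CG", "CG"), n_meth = c(1L, 2L), n_total = c(2L, 2L),
    level = c(0.5, 1.0), is_mC = TRUE)
  # pretend the region has 4 cytosine sites by restricting the context
  reg <- data.table::data.table(region_id = "r1", kind = "window",
                                contig = "chr", start0 = 0L, end0 = 10L,
                                strand = "*")
  rl <- region_levels(sites, reg, cyt[1:4])
  expect_equal(rl$meth_sum, 1.5)
  expect_equal(rl$absolute_level, 0.15)
  expect_equal(rl$relative_level, 1.5 / 4)
  expect_equal(rl$n_covered_c_sites, 2L)
  # no methylation: both levels zero
  sites0 <- data.table::copy(sites)[, is_mC := FALSE]
  rl0 <- region_levels(sites0, reg, cyt)
  expect_equal(rl0$absolute_level, 0)
  expect_equal(rl0$relative_level, 0)
  expect_error(region_levels(sites, data.table::data.table(
    region_id = "bad", contig = "chr", start0 = 3L, end0 = 3L), cyt),
    "length")
})

test_that("absolute = relative * n_c_sites / length on simulated regions", {
  ms <- main_study()
  regions <- annotation_regions(ms$annotation)
  rl <- region_levels(ms$sites$cult1, regions, ms$cytosines)
  expect_gt(nrow(rl), 50L)
  expect_equal(rl$absolute_level,
               rl$relative_level * rl$n_c_sites / rl$length_bp,
               tolerance = 1e-12)
  expect_true(all(rl$n_covered_c_sites <= rl$n_c_sites))
  expect_true(all(rl[, n_covered_c_sites / pmax(n_c_sites, 1)] <= 1))
})

test_that("sliding windows tile the genome with the documented boundary rule", {
  w1 <- sliding_windows(c(chr = 100000L))
  expect_equal(w1$start0, c(0L, 25000L, 50000L))
  expect_true(all(w1$end0 - w1$start0 == 50000L))
  w2 <- sliding_windows(c(chr = 40000L))
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$end0 - w2$start0, 40000L)
  w3 <- sliding_windows(c(chr = 110000L))
  expect_equal(w3$start0, c(0L, 25000L, 50000L, 75000L))
  expect_equal(w3$end0[4], 110000L)
  # coverage scan: every base in >= 1 and (interior) <= 2 windows
  cover <- integer(110000L)
  for (i in seq_len(nrow(w3)))
    cover[(w3$start0[i] + 1L):w3$end0[i]] <-
      cover[(w3$start0[i] + 1L):w3$end0[i]] + 1L
  expect_true(all(cover >= 1L))
  expect_true(all(cover <= 2L))
})

test_that("metagene profiles have 39 body bins and match a brute-force binning", {
  ms <- main_study()
  regions <- annotation_regions(ms$annotation, "gene_body")
  lens <- stats::setNames(ms$annotation$contigs$length,
                          ms$annotation$contigs$name)
  mg <- metagene_profile(regions, ms$sites$cult1, ms$cytosines,
                         flank_bp = 2000L, contexts = "CG",
                         contig_lengths = lens)
  expect_equal(nrow(mg$profile[zone == "body"]), 39L)
  expect_equal(nrow(mg$profile), 117L)

  # brute-force check on a handful of genes: every mC lands in exactly the
  # bins whose percent interval covers its midpoint coordinate
  sub <- regions[1:5]
  for (i in seq_len(nrow(sub))) {
    g <- sub[i]
    sites_g <- ms$sites$cult1[contig == g$contig & pos0 >= g$start0 &
                                pos0 < g$end0 & context == "CG" &
                                is_mC == TRUE]
    if (nrow(sites_g) == 0L) next
    len <- g$end0 - g$start0
    pct <- if (g$strand == "-") (g$end0 - 1 - sites_g$pos0) / len * 100
           else (sites_g$pos0 - g$start0) / len * 100
    manual <- sum(vapply(pct, function(p)
      sum((0:38) * 2.5 <= p & p < (0:38) * 2.5 + 5), numeric(1L)))
    got <- mg$per_region[region_id == g$region_id & zone == "body",
                         sum(meth_sum)]
    want <- sum(vapply(seq_along(pct), function(k)
      sites_g$level[k] * sum((0:38) * 2.5 <= pct[k] &
                               pct[k] < (0:38) * 2.5 + 5), numeric(1L)))
    expect_equal(got, want, tolerance = 1e-9)
    expect_lte(manual, 2L * nrow(sites_g))
  }
})

test_that("gene bodies show the planted CG enrichment over flanks", {
  ms <- main_study()
  regions <- annotation_regions(ms$annotation, "gene_body")
  lens <- stats::setNames(ms$annotation$contigs$length,
                          ms$annotation$contigs$name)
  mg <- metagene_profile(regions, ms$sites$cult1, ms$cytosines,
                         flank_bp = 2000L, contexts = "CG",
                         contig_lengths = lens)
  prof <- mg$profile
  body <- prof[zone == "body", mean(rel_level, na.rm = TRUE)]
  flank <- prof[zone != "body", mean(rel_level, na.rm = TRUE)]
  expect_gt(body, flank)
})

test_that("feature density equals brute-force per-base membership", {
  set.seed(71)
  feats <- data.table::data.table(
    contig = "chr",
    start0 = c(100L, 400L, 900L),
    end0 = c(200L, 650L, 1200L))
  spans <- data.table::data.table(
    region_id = sprintf("s%d", 1:4), contig = "chr",
    start0 = c(0L, 150L, 500L, 800L), end0 = c(100L, 250L, 600L, 1300L))
  fd <- feature_density(feats, spans)
  # per-base oracle
  mask <- logical(2000L)
  for (i in seq_len(nrow(feats)))
    mask[(feats$start0[i] + 1L):feats$end0[i]] <- TRUE
  want <- vapply(seq_len(nrow(spans)), function(i)
    mean(mask[(spans$start0[i] + 1L):spans$end0[i]]), numeric(1L))
  expect_equal(fd$density, want)
  # a span fully inside a TE has density 1
  inside <- feature_density(feats, data.table::data.table(
    region_id = "in", contig = "chr", start0 = 410L, end0 = 460L))
  expect_equal(inside$density, 1)
})

test_that("length correlation is a rank statistic", {
  rm <- data.table::data.table(
    region_id = letters[1:6], length_bp = c(10L, 20L, 30L, 40L, 50L, 60L),
    absolute_level = c(0.01, 0.02, 0.03, 0.05, 0.08, 0.13),
    relative_level = c(0.1, 0.2, 0.3, 0.5, 0.8, 0.9))
  r <- length_methylation_correlation(rm)
  expect_equal(r$rho_absolute, 1)
  # invariant under monotone transforms
  rm2 <- data.table::copy(rm)[, absolute_level := absolute_level^3]
  expect_equal(length_methylation_correlation(rm2)$rho_absolute, 1)
  expect_error(length_methylation_correlation(rm[1:2]), "at least 3")
})

test_that("cross-sample CV follows hand arithmetic and excludes zero means", {
  lw <- data.table::data.table(
    unit_id = c("u1", "u2", "u3"), context = "CG",
    cult1 = c(0.2, 0.3, 0), cult2 = c(0.2, 0.3, 0),
    wild1 = c(0.4, 0.3, 0), wild2 = c(0.4, 0.3, 0))
  cv <- cv_stats(lw)
  u1 <- cv$stats[unit_id == "u1"]
  expect_equal(u1$mean_level, 0.3)
  expect_equal(u1$sd_level, sqrt(sum((c(.2, .2, .4, .4) - .3)^2) / 3))
  expect_equal(u1$cv, u1$sd_level / 0.3, tolerance = 1e-12)
  expect_equal(round(u1$cv, 3), 0.385)
  expect_equal(cv$stats[unit_id == "u2", cv], 0)      # identical levels
  expect_false("u3" %in% cv$stats$unit_id)            # zero mean excluded
})
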