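# Three-letter alignment: conversion, unique-best mapping, dedup,
# restoration.

test_that("converted references follow the C->T / G->A definitions", {
  refs <- build_converted_references(c(x = "ACGT"))
  expect_equal(unname(refs$t_genome), "ATGT")
  expect_equal(unname(refs$a_genome), "ACAT")
  refs2 <- build_converted_references(c(x = "AAAA"))
  expect_equal(unname(refs2$t_genome), "AAAA")
  expect_equal(unname(refs2$a_genome), "AAAA")

  set.seed(1)
  g <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  refs3 <- build_converted_references(c(chr = g))
  v <- strsplit(g, NULL)[[1]]
  tv <- strsplit(refs3$t_genome[["chr"]], NULL)[[1]]
  expect_identical(which(v != tv), which(v == "C"))
  expect_false(grepl("C", refs3$t_genome[["chr"]]))
  expect_false(grepl("G", refs3$a_genome[["chr"]]))
})

test_that("read-pair conversion is mate-asymmetric and restorable", {
  cv <- convert_read_pair("CCGA", "CCGA")
  expect_equal(cv$conv1, "TTGA")
  expect_equal(cv$conv2, "CCAA")
  expect_equal(cv$orig1, "CCGA")
  cv2 <- convert_read_pair("TGAT", "AAAA")
  expect_equal(cv2$conv1, "TGAT")
})

test_that("mapping matches the exhaustive Hamming-scan oracle", {
  cfg <- sim_config(
    seed = 31L,
    contigs = data.frame(name = c("c1", "cp"), length = c(3000L, 1000L),
                         is_chloroplast = c(FALSE, TRUE)),
    gene_count = 2L, gene_length = c(300L, 500L),
    te_count = 2L, te_length = c(150L, 300L),
    smrna_count = 1L, smrna_length = c(30L, 80L),
    depth = 2, seq_error_rate = 0.02, clonal_fraction = 0)
  gen <- generate_genome(cfg)
  truth <- assign_methylation_truth(gen$genome, gen$annotation, cfg)
  pr <- simulate_bs_reads(gen$genome, truth, "cult1", cfg,
                          annotation = gen$annotation)
  pr <- pr[1:min(.N, 80L)]
  refs <- build_converted_references(gen$genome)
  aln <- align_read_pairs(pr, refs)
  for (i in seq_len(nrow(pr))) {
    oracle <- brute_align_pair(pr$seq1[i], pr$seq2[i], refs, cap = 2L)
    got <- aln[read_id == pr$read_id[i]]
    expect_equal(got$status, oracle$status, info = pr$read_id[i])
    if (oracle$status == "mapped") {
      expect_equal(got$contig, oracle$contig)
      expect_equal(got$frag_start, oracle$frag_start)
      expect_equal(got$frag_end, oracle$frag_end)
      expect_equal(got$origin, oracle$origin)
      expect_equal(got$mm, oracle$mm)
    }
  }
})

test_that("reads over the mismatch cap are unmapped; repeats are ambiguous", {
  set.seed(32)
  core <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                collapse = "")
  dupseg <- substring(core, 301, 600)
  genome <- c(chr = paste0(core, "TTTT", dupseg))
  refs <- build_converted_references(genome)
  # an error-free plus-strand fragment from a unique part of the genome
  frag <- substring(core, 1001, 1200)
  seq1 <- chartr("C", "T", substring(frag, 1, 44))
  m2region <- substring(frag, 157, 200)
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("C", "T", m2region))))
  pairs <- data.table::data.table(
    read_id = "ok", seq1 = seq1, qual1 = strrep("I", 44),
    seq2 = seq2, qual2 = strrep("I", 44))
  expect_equal(align_read_pairs(pairs, refs)$status, "mapped")

  # inject 3 mismatches into mate 1: over the 44 nt cap of 2
  s1bad <- seq1
  for (p in c(5L, 15L, 25L))
    substring(s1bad, p, p) <- setdiff(c("A", "G"),
                                      substring(s1bad, p, p))[1]
  bad <- data.table::copy(pairs)[, seq1 := s1bad]
  expect_equal(align_read_pairs(bad, refs)$status, "unmapped")

  # a fragment inside the duplicated segment maps equally twice
  dfrag <- substring(core, 321, 520)
  d1 <- chartr("C", "T", substring(dfrag, 1, 44))
  d2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("C", "T", substring(dfrag, 157, 200)))))
  dup <- data.table::data.table(
    read_id = "dup", seq1 = d1, qual1 = strrep("I", 44),
    seq2 = d2, qual2 = strrep("I", 44))
  expect_equal(align_read_pairs(dup, refs)$status, "ambiguous")
})

test_that("error-free reads are never assigned the wrong origin strand", {
  ss <- snp_study()
  m <- merge(ss$aligned[, .(read_id, origin)],
             ss$pairs[, .(read_id, true_strand)], by = "read_id")
  expect_true(all(m$origin == m$true_strand))
})

test_that("clonal dedup keeps one pair per placement and is idempotent", {
  cfg <- tiny_config(seed = 33L, clonal_fraction = 0.3, depth = 4)
  gen <- generate_genome(cfg)
  truth <- assign_methylation_truth(gen$genome, gen$annotation, cfg)
  pr <- simulate_bs_reads(gen$genome, truth, "cult1", cfg,
                          annotation = gen$annotation)
  refs <- build_converted_references(gen$genome)
  aln <- align_read_pairs(pr, refs)
  dd <- dedupe_clonal(aln)
  expect_equal(anyDuplicated(dd[, .(contig, frag_start, frag_end, origin)]),
               0L)
  # post-dedup count equals the number of distinct mapped placements
  mapped <- aln[status == "mapped"]
  expect_equal(nrow(dd),
               nrow(unique(mapped[, .(contig, frag_start, frag_end,
                                      origin)])))
  dd2 <- dedupe_clonal(dd)
  expect_equal(nrow(dd2), nrow(dd))
  expect_setequal(dd2$read_id, dd$read_id)
})

test_that("restored columns are equal bases or flagged conversions when error-free", {
  ss <- snp_study()   # seq_error = 0
  aln <- ss$aligned[status == "mapped"][1:20]
  for (i in seq_len(nrow(aln))) {
    cols <- restore_alignment(aln[i], ss$genome)
    # every column either matches the (sample) reference or is a bisulfite
    # conversion column or a planted SNP column; against the reference
    # genome, non-matching non-conversion columns must all be planted SNPs
    bad <- cols[match == FALSE & bisulfite_consistent == FALSE]
    if (nrow(bad)) {
      snp_pos <- ss$genotypes[contig == aln$contig[i], pos0]
      expect_true(all(bad$pos0 %in% snp_pos))
    }
  }
  # and a plus-origin read T over reference C is flagged, not a mismatch
  one <- restore_alignment(ss$aligned[status == "mapped"][1], ss$genome)
  conv <- one[bisulfite_consistent == TRUE]
  if (nrow(conv)) expect_true(all(conv$base == "T" & conv$ref_base == "C"))
})
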