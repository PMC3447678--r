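# Independent brute-force oracles used to validate the implementations.

# exhaustive Hamming scan of one query over every offset of one sequence
brute_scan <- function(query, subject) {
  q <- utf8ToInt(query)
  g <- utf8ToInt(subject)
  rl <- length(q)
  L <- length(g)
  if (L < rl) return(data.table::data.table(pos0 = integer(),
                                            mm = integer()))
  offs <- 0:(L - rl)
  mm <- vapply(offs, function(o) sum(g[o + seq_len(rl)] != q), integer(1L))
  data.table::data.table(pos0 = offs, mm = mm)
}

# exhaustive paired three-letter alignment of one read pair; mirrors the
# pairing/uniqueness rules but searches every offset of both genomes
brute_align_pair <- function(seq1, seq2, refs, cap, max_insert = 600L) {
  rl <- nchar(seq1)
  f1 <- chartr("C", "T", seq1)
  f2 <- chartr("C", "T", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq2))))
  g2 <- chartr("G", "A", seq2)
  g1 <- chartr("G", "A", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq1))))
  cands <- list()
  for (ctg in names(refs$t_genome)) {
    hf1 <- brute_scan(f1, refs$t_genome[[ctg]])
    hf2 <- brute_scan(f2, refs$t_genome[[ctg]])
    hf1 <- hf1[mm <= cap]; hf2 <- hf2[mm <= cap]
    if (nrow(hf1) && nrow(hf2)) {
      for (i in seq_len(nrow(hf1))) {
        ok <- hf2[pos0 >= hf1$pos0[i] & pos0 + rl - hf1$pos0[i] <= max_insert]
        if (nrow(ok))
          cands[[length(cands) + 1L]] <- data.table::data.table(
            contig = ctg, frag_start = hf1$pos0[i], frag_end = ok$pos0 + rl,
            origin = "+", mm_total = hf1$mm[i] + ok$mm)
      }
    }
    hg2 <- brute_scan(g2, refs$a_genome[[ctg]])
    hg1 <- brute_scan(g1, refs$a_genome[[ctg]])
    hg2 <- hg2[mm <= cap]; hg1 <- hg1[mm <= cap]
    if (nrow(hg2) && nrow(hg1)) {
      for (i in seq_len(nrow(hg2))) {
        ok <- hg1[pos0 >= hg2$pos0[i] & pos0 + rl - hg2$pos0[i] <= max_insert]
        if (nrow(ok))
          cands[[length(cands) + 1L]] <- data.table::data.table(
            contig = ctg, frag_start = hg2$pos0[i], frag_end = ok$pos0 + rl,
            origin = "-", mm_total = hg2$mm[i] + ok$mm)
      }
    }
  }
  if (length(cands) == 0L) return(list(status = "unmapped"))
  all <- data.table::rbindlist(cands)
  best <- min(all$mm_total)
  top <- all[mm_total == best]
  if (nrow(top) > 1L) return(list(status = "ambiguous"))
  list(status = "mapped", contig = top$contig, frag_start = top$frag_start,
       frag_end = top$frag_end, origin = top$origin, mm = best)
}

# exact two-sided Wilcoxon p-value by recursive subset enumeration
# (independent of the combn-based implementation)
enum_wilcox <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  n_tot <- length(r)
  w_obs <- sum(r[seq_len(m)])
  sums <- numeric(0)
  rec <- function(idx, k, acc) {
    if (k == 0L) {
      sums[length(sums) + 1L] <<- acc
      return(invisible())
    }
    if (idx > n_tot || n_tot - idx + 1L < k) return(invisible())
    rec(idx + 1L, k - 1L, acc + r[idx])
    rec(idx + 1L, k, acc)
  }
  rec(1L, m, 0)
  eps <- 1e-9
  if (length(unique(r)) == 1L) return(1)
  min(1, 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps)))
}

# naive tag dictionary: scan every cDNA, collect CATG+17 tags, mark
# multi-gene tags ambiguous
naive_tag_db <- function(cdnas) {
  rows <- list()
  for (g in names(cdnas)) {
    s <- cdnas[[g]]
    for (p in seq_len(max(0L, nchar(s) - 3L))) {
      if (substring(s, p, p + 3L) == "CATG" && p + 20L <= nchar(s))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, tag = substring(s, p, p + 20L))
    }
  }
  d <- do.call(rbind, rows)
  if (is.null(d)) return(data.frame(tag = character(), gene = character()))
  agg <- stats::aggregate(gene ~ tag, d,
                          function(gg) if (length(unique(gg)) > 1L)
                            "AMBIGUOUS" else unique(gg))
  agg
}

# per-base pair-counting oracle for pi in windows
brute_pi <- function(geno_wide, windows, samples = BSD_SAMPLES) {
  out <- numeric(nrow(windows))
  pairs <- utils::combn(samples, 2L, simplify = FALSE)
  for (w in seq_len(nrow(windows))) {
    tot <- 0L
    for (p in pairs) {
      g <- geno_wide[contig == windows$contig[w] &
                       pos0 >= windows$start0[w] & pos0 < windows$end0[w]]
      a <- g[[p[1]]]; b <- g[[p[2]]]
      tot <- tot + sum(!is.na(a) & !is.na(b) & a != b)
    }
    out[w] <- tot / (6 * (windows$end0[w] - windows$start0[w]))
  }
  out
}

comp_base_for_test <- function(b) chartr("ACGT", "TGCA", b)

# does an unrooted 4-taxon tree contain the split {a1,a2} | {b1,b2}?
has_split <- function(phylo, pair) {
  un <- ape::unroot(phylo)
  parts <- ape::prop.part(un)
  labs <- un$tip.label
  target <- sort(match(pair, labs))
  any(vapply(parts, function(p) identical(sort(p), target) ||
               identical(sort(setdiff(seq_along(labs), p)), target),
             logical(1L)))
}
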