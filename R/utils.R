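# Shared low-level helpers: base/strand arithmetic, Phred scores, seeding.

# data.table is used via :: throughout; mark the namespace as aware so
# DT[...] syntax resolves correctly when the package is installed
.datatable.aware <- TRUE

#' Sample names used throughout the package
#'
#' The four-sample design is fixed: two "cultivated" lines forming one group
#' and two "wild" lines forming the other, related as ((cult1,cult2),(wild1,wild2)).
#' @export
BSD_SAMPLES <- c("cult1", "cult2", "wild1", "wild2")

#' @rdname BSD_SAMPLES
#' @export
BSD_CULTIVATED <- c("cult1", "cult2")

#' @rdname BSD_SAMPLES
#' @export
BSD_WILD <- c("wild1", "wild2")

DNA_BASES <- c("A", "C", "G", "T")

# integer complement lookup indexed by utf8 code (A<->T, C<->G)
.COMP_INT <- local({
  v <- integer(128L)
  v[utf8ToInt("A")] <- utf8ToInt("T")
  v[utf8ToInt("T")] <- utf8ToInt("A")
  v[utf8ToInt("C")] <- utf8ToInt("G")
  v[utf8ToInt("G")] <- utf8ToInt("C")
  v[utf8ToInt("N")] <- utf8ToInt("N")
  v
})

comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split equal-width strings into a character matrix (one row per string)
#' @keywords internal
char_matrix <- function(x, width = NULL) {
  if (is.null(width)) width <- nchar(x[1L])
  matrix(unlist(strsplit(x, NULL, fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

collapse_rows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Hamming distance between paired equal-width strings
#'
#' Vectorised over pairs; `a` and `b` must have the same element-wise widths.
#' @keywords internal
mismatch_count <- function(a, b) {
  if (length(a) == 0L) return(integer(0L))
  w <- nchar(a[1L])
  am <- char_matrix(a, w)
  bm <- char_matrix(b, w)
  as.integer(rowSums(am != bm))
}

#' Phred base-calling accuracy at a quality cutoff
#'
#' Probability that a base with Phred quality `q` is correctly called,
#' `1 - 10^(-q/10)`.  At the methylcytosine base-quality cutoff of Q20 this
#' is 0.99, i.e. a 99% accuracy floor for every base entering a pileup.
#'
#' @param q Phred quality score(s).
#' @return Numeric vector of accuracies in \[0, 1\].
#' @export
phred_accuracy <- function(q) 1 - 10^(-q / 10)

# constant-quality string of length n at Phred q (Sanger +33 encoding)
phred_string <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)

# stream-specific RNG seed derived from a master seed; kept below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483562)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# point/interval overlap join: x and y must both carry contig/xstart/xend;
# returns the xid/yid index pairs
overlap_which <- function(x, y) {
  data.table::setkey(y, contig, xstart, xend)
  data.table::foverlaps(x, y, by.x = c("contig", "xstart", "xend"),
                        type = "within", nomatch = NULL, which = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# silence R CMD check notes about data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "contig", "pos0", "strand", "context", "compartment",
  "gene_id", "gene_kind", "base_prob", "read_id", "seq1", "seq2", "qual1",
  "qual2", "is_clone", "qidx", "gpos0", "kmer", "mm", "mm_total", "frag_start",
  "frag_end", "origin", "status", "pos0_l", "pos0_r", "best", "n_best", "meanq",
  "base", "qual", "base_plus", "n_meth", "n_total", "level", "p_value", "is_mC",
  "n_mC", "covered", "density", "depth", "frac", "cons", "plus_base",
  "minus_base", "ref", "sample_base", "strand_used", "is_snp", "depth_used",
  "start0", "end0", "region_id", "kind", "length_bp", "absolute_level",
  "relative_level", "n_c_sites", "n_covered_c_sites", "meth_sum", "zone", "bin",
  "bin_len", "n_c", "n_regions", "abs_level", "rel_level", "pct", "b0", "b1",
  "window_id", "pi_value", "mean_r", "group", "cv", "mean_level", "sd_level",
  "tag", "rank3p", "count", "per_million", "gene", "direction", "i.start0",
  "i.end0", "ov", "true_strand", "true_start0", "true_end0", "mate", "alt",
  "branch", "te_id", "smrna_id", "p_adj", "xstart", "xend", "masked",
  "i.gene_id", "i.kind", "i.strand", "i.region_id", "n_sites", "width",
  "zone_len", "ovlen", "bases", "unit_id", "rho", "pos1", "log2_expr",
  "n_genes", "n_tags", "frac_tags", "n_diff", "level_a", "level_b", "r",
  "mean_pi", "is_dm", "fc", "expected_down", "hit", "pos", "offset", "n",
  "i.mean_r", "n_pairs_r", "lo", "prom_start0", "prom_end0", "ttr_start0",
  "ttr_end0", "i.xstart", "i.xend", "mm_l", "mm_r", "mean_level_mC",
  "mean_level_all", "has_catg", "zstart", "zend", "flip"
))
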