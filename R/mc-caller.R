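# Per-cytosine pileup, chloroplast error-rate calibration, binomial
# methylcytosine calling and methylome summaries.

#' Pile up restored read bases over reference cytosines
#'
#' Every reference cytosine on either strand covered by at least one
#' quality-passing read of the matching origin receives a site record.
#' Plus-strand cytosines collect evidence from plus-origin reads (read C =
#' potential mC, read T = converted); minus-strand cytosines from
#' minus-origin reads, in minus-strand base space.  Bases with Phred
#' quality below `q_min` are excluded from both counts; at Q20 every
#' counted base is called correctly with at least 99% probability.
#'
#' @param restored Long per-base table from [restore_alignments()].
#' @param genome Original reference (named character vector).
#' @param q_min Minimum base quality (default 20).
#' @return `data.table` of covered cytosine sites: `contig`, `pos0`,
#'   `strand`, `context`, `n_meth`, `n_total`, `level`.
#' @export
pileup_cytosines <- function(restored, genome, q_min = 20L) {
  cyt <- reference_cytosines(genome)
  r <- restored[qual >= q_min]
  empty <- data.table::data.table(
    contig = character(), pos0 = integer(), strand = character(),
    context = character(), n_meth = integer(), n_total = integer(),
    level = numeric())
  if (nrow(r) == 0L) return(empty)
  r[, strand := origin]
  agg <- r[, .(n_meth = sum(base == "C"), n_total = .N),
           by = .(contig, pos0, strand)]
  sites <- merge(cyt, agg, by = c("contig", "pos0", "strand"))
  if (nrow(sites) == 0L) return(empty)
  sites[, level := n_meth / n_total]
  data.table::setkey(sites, contig, pos0, strand)
  sites[]
}

#' Estimate the combined non-conversion and T-to-C error rate
#'
#' Pools all covered cytosines of the unmethylated chloroplast contig
#' (both strands, all contexts) into a single per-sample null rate:
#' the total methylated-call count divided by the total read-base count.
#' This is the binomial null parameter for methylcytosine calling.
#'
#' @param sites Site table from [pileup_cytosines()].
#' @param chloroplast Name of the chloroplast contig.
#' @return List with `p_err` and `n_observations`.
#' @export
estimate_error_rate <- function(sites, chloroplast) {
  cp <- sites[contig == chloroplast]
  if (nrow(cp) == 0L || sum(cp$n_total) == 0L)
    stop("no covered chloroplast cytosines: cannot calibrate the caller")
  list(p_err = sum(cp$n_meth) / sum(cp$n_total),
       n_observations = sum(cp$n_total))
}

#' Binomial methylcytosine test
#'
#' For each site, the p-value is the upper binomial tail
#' P(X >= n_meth | X ~ Binomial(n_total, p_err)); a site is called
#' methylated when it shows at least one methylated read and the p-value
#' falls below `alpha`, bounding the false positive rate at 5% by default.
#'
#' @param n_meth,n_total Integer vectors of methylated and total counts.
#' @param p_err Null C-retention rate from [estimate_error_rate()].
#' @param alpha Per-site significance level (default 0.05).
#' @return List of vectors `p_value` and `is_mC`.
#' @export
binomial_call <- function(n_meth, n_total, p_err, alpha = 0.05) {
  if (length(p_err) != 1L || is.na(p_err) || p_err < 0 || p_err > 1)
    stop("p_err must be a single probability in [0, 1]")
  stopifnot(all(n_meth >= 0L), all(n_meth <= n_total))
  p <- ifelse(n_meth == 0L, 1,
              stats::pbinom(n_meth - 1L, n_total, p_err, lower.tail = FALSE))
  list(p_value = p, is_mC = n_meth >= 1L & p < alpha)
}

#' Call methylcytosines over a site table
#'
#' Applies [binomial_call()] to every covered cytosine.  Sites whose
#' sample genotype is non-reference can be masked out (a C-to-T
#' substitution is indistinguishable from an unmethylated cytosine), which
#' is the default behaviour when `snp_mask` is supplied.
#'
#' @param sites Site table from [pileup_cytosines()].
#' @param p_err Null rate (scalar).
#' @param alpha Significance level.
#' @param snp_mask Optional `data.table` of positions (`contig`, `pos0`) to
#'   mask (e.g. non-reference genotype calls); masked sites keep their
#'   counts but get `is_mC = FALSE`, `p_value = NA` and `masked = TRUE`.
#' @return The site table with `p_value`, `is_mC` and `masked` columns.
#' @export
call_methylation <- function(sites, p_err, alpha = 0.05, snp_mask = NULL) {
  out <- data.table::copy(sites)
  res <- binomial_call(out$n_meth, out$n_total, p_err, alpha)
  out[, `:=`(p_value = res$p_value, is_mC = res$is_mC, masked = FALSE)]
  if (!is.null(snp_mask) && nrow(snp_mask)) {
    key <- paste(snp_mask$contig, snp_mask$pos0)
    hit <- paste(out$contig, out$pos0) %in% key
    out[hit, `:=`(p_value = NA_real_, is_mC = FALSE, masked = TRUE)]
  }
  out[]
}

#' Summarise a called methylome by sequence context
#'
#' Per context: number of methylcytosines, methylation density (mCs per
#' covered cytosine), mean methylation level of mCs and of all covered
#' cytosines, plus a 10%-bin histogram of methylation levels for mCs
#' covered by at least `min_depth_hist` reads.
#'
#' @param sites Called site table from [call_methylation()].
#' @param min_depth_hist Minimum coverage for the level histogram
#'   (default 5).
#' @return List with `summary` and `histogram` `data.table`s.
#' @export
summarize_methylome <- function(sites, min_depth_hist = 5L) {
  ctxs <- c("CG", "CHG", "CHH")
  s <- sites[context %in% ctxs]
  summ <- s[, .(n_mC = sum(is_mC), covered = .N,
                density = if (.N) sum(is_mC) / .N else 0,
                mean_level_mC = if (any(is_mC)) mean(level[is_mC]) else NA_real_,
                mean_level_all = if (.N) mean(level) else NA_real_),
            by = context]
  missing <- setdiff(ctxs, summ$context)
  if (length(missing))
    summ <- data.table::rbindlist(list(
      summ, data.table::data.table(context = missing, n_mC = 0L,
                                   covered = 0L, density = 0,
                                   mean_level_mC = NA_real_,
                                   mean_level_all = NA_real_)))
  data.table::setkey(summ, context)
  h <- s[is_mC == TRUE & n_total >= min_depth_hist]
  if (nrow(h)) {
    h[, bin := cut(level, seq(0, 1, 0.1), include.lowest = TRUE)]
    hist <- h[, .(n = .N), by = .(context, bin)]
    hist[, frac := n / sum(n), by = context]
    data.table::setorder(hist, context, bin)
  } else {
    hist <- data.table::data.table(context = character(), bin = factor(),
                                   n = integer(), frac = numeric())
  }
  list(summary = summ[], histogram = hist)
}
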