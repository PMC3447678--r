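# Homozygous genotype calling from bisulfite reads with strand resolution:
# reads mapped to the T-genome carry plus-strand sequence, reads mapped to
# the A-genome carry minus-strand sequence, and each genotype class is
# called from the strand on which bisulfite conversion cannot mimic it.

#' Strand-stratified base pileups
#'
#' Counts read bases per position separately for plus-origin and
#' minus-origin reads, with minus-origin bases projected onto plus-strand
#' coordinates (complemented), keeping only bases with quality at least
#' `q_min` (Q30 by default).
#'
#' @param restored Long per-base table from [restore_alignments()].
#' @param q_min Minimum base quality (default 30).
#' @return `data.table` with `contig`, `pos0`, `origin`, `base` (projected
#'   to plus strand), `count`.
#' @export
strand_pileups <- function(restored, q_min = 30L) {
  r <- restored[qual >= q_min]
  if (nrow(r) == 0L)
    return(data.table::data.table(contig = character(), pos0 = integer(),
                                  origin = character(), base = character(),
                                  count = integer()))
  out <- r[, .(count = .N), by = .(contig, pos0, origin, base = base_plus)]
  data.table::setkey(out, contig, pos0, origin)
  out[]
}

#' Majority consensus within one strand stratum
#'
#' Returns the majority base when the stratum depth reaches `min_depth`
#' (at least 5 reads by default) and the majority fraction reaches
#' `min_fraction`; otherwise no call (NA).
#'
#' @param pileup Output of [strand_pileups()] (one or both strata).
#' @param min_depth Minimum stratum depth (default 5).
#' @param min_fraction Minimum majority fraction (default 0.9).
#' @return `data.table` with `contig`, `pos0`, `origin`, `depth`, `cons`
#'   (NA when no call).
#' @export
strand_consensus <- function(pileup, min_depth = 5L, min_fraction = 0.9) {
  if (nrow(pileup) == 0L)
    return(data.table::data.table(contig = character(), pos0 = integer(),
                                  origin = character(), depth = integer(),
                                  cons = character()))
  cons <- pileup[, {
    d <- sum(count)
    top <- which.max(count)
    ok <- d >= min_depth && count[top] / d >= min_fraction
    .(depth = d, cons = if (ok) base[top] else NA_character_)
  }, by = .(contig, pos0, origin)]
  data.table::setkey(cons, contig, pos0, origin)
  cons[]
}

#' Resolve a genotype from the two strand consensi
#'
#' Genotypes whose sample base is A or G are immune to C-to-T conversion on
#' the plus strand and are called from the plus consensus; sample bases C
#' or T are immune to G-to-A conversion artefacts on the minus strand and
#' are called from the minus consensus (projected to plus coordinates).  A
#' plus consensus of C/T, or a minus consensus of A/G, is
#' conversion-ambiguous and never decides a call.  Confident but
#' contradictory calls from the two strands are flagged as conflicts and
#' excluded from the SNP list.
#'
#' @param plus_cons,minus_cons Character vectors of strand consensi (NA =
#'   no call), minus projected to plus-strand space.
#' @param ref_base Reference base(s) at the position(s).
#' @return `data.table` with `sample_base`, `strand_used`, `is_snp`,
#'   `status` ("called", "no_call" or "conflict").
#' @export
resolve_genotype <- function(plus_cons, minus_cons, ref_base) {
  plus_ok <- !is.na(plus_cons) & plus_cons %in% c("A", "G")
  minus_ok <- !is.na(minus_cons) & minus_cons %in% c("C", "T")
  conflict <- plus_ok & minus_ok   # the two resolvable sets are disjoint
  sample_base <- rep(NA_character_, length(ref_base))
  strand_used <- rep(NA_character_, length(ref_base))
  use_p <- plus_ok & !conflict
  use_m <- minus_ok & !conflict & !plus_ok
  sample_base[use_p] <- plus_cons[use_p]
  strand_used[use_p] <- "+"
  sample_base[use_m] <- minus_cons[use_m]
  strand_used[use_m] <- "-"
  status <- ifelse(conflict, "conflict",
                   ifelse(is.na(sample_base), "no_call", "called"))
  data.table::data.table(
    sample_base = sample_base, strand_used = strand_used,
    is_snp = !is.na(sample_base) & sample_base != ref_base,
    status = status)
}

#' Call homozygous genotypes genome-wide from restored alignments
#'
#' Runs [strand_pileups()], [strand_consensus()] and [resolve_genotype()]
#' over every covered position.
#'
#' @param restored Long per-base table from [restore_alignments()].
#' @param genome Original reference.
#' @param q_min,min_depth,min_fraction Quality and consensus thresholds
#'   (defaults Q30, depth 5, fraction 0.9).
#' @return `data.table` with `contig`, `pos0`, `ref`, `sample_base`,
#'   `strand_used`, `depth_used`, `is_snp`, `status`; attribute
#'   `n_conflicts` counts excluded strand conflicts.
#' @export
call_snps <- function(restored, genome, q_min = 30L, min_depth = 5L,
                      min_fraction = 0.9) {
  empty <- data.table::data.table(
    contig = character(), pos0 = integer(), ref = character(),
    sample_base = character(), strand_used = character(),
    depth_used = integer(), is_snp = logical(), status = character())
  pil <- strand_pileups(restored, q_min)
  if (nrow(pil) == 0L) {
    data.table::setattr(empty, "n_conflicts", 0L)
    return(empty[])
  }
  cons <- strand_consensus(pil, min_depth, min_fraction)
  wide <- data.table::dcast(cons, contig + pos0 ~ origin,
                            value.var = c("cons", "depth"))
  for (col in c("cons_+", "cons_-"))
    if (!col %in% names(wide)) wide[, (col) := NA_character_]
  for (col in c("depth_+", "depth_-"))
    if (!col %in% names(wide)) wide[, (col) := NA_integer_]
  refc <- substring(genome[wide$contig], wide$pos0 + 1L, wide$pos0 + 1L)
  res <- resolve_genotype(wide[["cons_+"]], wide[["cons_-"]], refc)
  out <- data.table::data.table(
    contig = wide$contig, pos0 = wide$pos0, ref = refc,
    sample_base = res$sample_base, strand_used = res$strand_used,
    depth_used = data.table::fifelse(
      res$strand_used == "+", wide[["depth_+"]], wide[["depth_-"]]),
    is_snp = res$is_snp, status = res$status)
  n_conf <- sum(out$status == "conflict")
  data.table::setkey(out, contig, pos0)
  data.table::setattr(out, "n_conflicts", n_conf)
  out[]
}
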