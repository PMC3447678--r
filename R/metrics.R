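# Region- and window-level methylation metrics, metagene profiles,
# feature density, length correlations and cross-sample variation.

# point-in-interval overlap of site positions against regions
.sites_in_regions <- function(sites, regions) {
  if (nrow(sites) == 0L || nrow(regions) == 0L)
    return(data.table::data.table())
  rg <- regions[, .(region_id, contig, xstart = start0, xend = end0 - 1L)]
  pts <- sites[, .(contig, xstart = pos0, xend = pos0)]
  ov <- overlap_which(pts, rg)
  if (nrow(ov) == 0L) return(data.table::data.table())
  cbind(sites[ov$xid], region_id = rg$region_id[ov$yid])
}

#' Absolute and relative methylation level of regions
#'
#' The absolute level of a region is the sum of the methylation levels of
#' its methylcytosines divided by the region length; the relative level is
#' the same sum divided by the total number of cytosine sites (both
#' strands) in the region.  The identity
#' `absolute = relative * n_c_sites / length` therefore holds exactly.
#'
#' @param sites Called site table ([call_methylation()]) for one sample.
#' @param regions Region table (`region_id`, `kind`, `contig`, `start0`,
#'   `end0`, `strand`), e.g. from [annotation_regions()] or
#'   [sliding_windows()].
#' @param cytosines Reference cytosine table ([reference_cytosines()]).
#' @param contexts Optional context filter (e.g. "CG").
#' @return `data.table` with one row per region: identifiers, span,
#'   `length_bp`, `n_c_sites`, `n_covered_c_sites`, `meth_sum`,
#'   `absolute_level`, `relative_level`.
#' @export
region_levels <- function(sites, regions, cytosines, contexts = NULL) {
  regions <- data.table::as.data.table(regions)
  if (any(regions$end0 <= regions$start0))
    stop("zero- or negative-length region")
  cyt <- cytosines
  st <- sites
  if (!is.null(contexts)) {
    cyt <- cyt[context %in% contexts]
    st <- st[context %in% contexts]
  }
  base <- regions[, .(region_id, kind = if ("kind" %in% names(regions)) kind
                      else "region",
                      contig, start0, end0,
                      strand = if ("strand" %in% names(regions)) strand
                      else "*",
                      length_bp = end0 - start0)]
  nc <- .sites_in_regions(cyt, regions)
  ncount <- if (nrow(nc)) nc[, .(n_c_sites = .N), by = region_id]
            else data.table::data.table(region_id = character(),
                                        n_c_sites = integer())
  sv <- .sites_in_regions(st, regions)
  if (nrow(sv)) {
    scount <- sv[, .(n_covered_c_sites = .N,
                     meth_sum = sum(level[is_mC])), by = region_id]
  } else {
    scount <- data.table::data.table(region_id = character(),
                                     n_covered_c_sites = integer(),
                                     meth_sum = numeric())
  }
  out <- merge(base, ncount, by = "region_id", all.x = TRUE)
  out <- merge(out, scount, by = "region_id", all.x = TRUE)
  out[is.na(n_c_sites), n_c_sites := 0L]
  out[is.na(n_covered_c_sites), n_covered_c_sites := 0L]
  out[is.na(meth_sum), meth_sum := 0]
  out[, absolute_level := meth_sum / length_bp]
  out[, relative_level := data.table::fifelse(n_c_sites > 0L,
                                              meth_sum / n_c_sites, 0)]
  data.table::setorder(out, contig, start0)
  out[]
}

#' Genome-wide sliding windows
#'
#' Half-open windows starting at 0 with the given step (50 kb windows,
#' 25 kb step by default).  A terminal partial window is emitted only when
#' it is at least one step long and extends past the last full window.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window,step Window and step sizes in bp.
#' @return Region `data.table` (`region_id`, `kind` = "window", `contig`,
#'   `start0`, `end0`, `strand` = "*").
#' @export
sliding_windows <- function(contig_lengths, window = 50000L, step = 25000L) {
  out <- lapply(names(contig_lengths), function(ctg) {
    L <- as.integer(contig_lengths[[ctg]])
    starts <- seq(0L, max(0L, L - 1L), by = step)
    full <- starts[starts + window <= L]
    last_end <- if (length(full)) max(full) + window else 0L
    part <- setdiff(starts, full)
    part <- part[(L - part >= step) & (L > last_end)]
    part <- if (length(part)) min(part) else integer(0L)
    s <- c(full, part)
    if (length(s) == 0L) s <- 0L  # contig shorter than a step: one window
    data.table::data.table(contig = ctg, start0 = as.integer(s),
                           end0 = as.integer(pmin(s + window, L)))
  })
  out <- data.table::rbindlist(out)
  out[, `:=`(region_id = sprintf("%s:%d-%d", contig, start0, end0),
             kind = "window", strand = "*")]
  data.table::setcolorder(out, c("region_id", "kind", "contig", "start0",
                                 "end0", "strand"))
  out[]
}

# percent-coordinate bin assignment for one zone of a set of regions.
# Overlapping scheme: bins of `bin_pct`% width every `step_pct`%; a point
# at percent p lies in every bin whose [start, start + bin_pct) covers it.
.zone_bins <- function(bin_pct = 5, step_pct = 2.5) {
  n_bins <- as.integer((100 - bin_pct) / step_pct) + 1L
  data.table::data.table(bin = seq_len(n_bins),
                         lo = (seq_len(n_bins) - 1L) * step_pct)
}

# site-to-(region, zone, bin) assignment table
.metagene_assign <- function(sites, zones, bin_pct, step_pct) {
  # zones: region_id, contig, zstart, zend, flip (TRUE for minus strand)
  if (nrow(sites) == 0L || nrow(zones) == 0L)
    return(data.table::data.table())
  rg <- zones[, .(region_id, zone, contig, xstart = zstart, xend = zend - 1L,
                  zstart, zend, flip)]
  pts <- sites[, .(contig, xstart = pos0, xend = pos0)]
  ov <- overlap_which(pts, rg)
  if (nrow(ov) == 0L) return(data.table::data.table())
  hit <- cbind(sites[ov$xid, .(pos0, level = if ("level" %in% names(sites))
                               level else NA_real_,
                               is_mC = if ("is_mC" %in% names(sites))
                               is_mC else NA)],
               rg[ov$yid, .(region_id, zone, zstart, zend, flip)])
  hit[, pct := data.table::fifelse(
    flip, (zend - 1L - pos0) / (zend - zstart) * 100,
    (pos0 - zstart) / (zend - zstart) * 100)]
  n_bins <- as.integer((100 - bin_pct) / step_pct) + 1L
  hit[, b1 := pmin(floor(pct / step_pct) + 1L, n_bins)]
  hit[, b0 := b1 - 1L]
  long <- data.table::rbindlist(list(
    hit[, .(region_id, zone, pos0, level, is_mC, pct, bin = b1)],
    hit[b0 >= 1L, .(region_id, zone, pos0, level, is_mC, pct, bin = b0)]))
  long <- long[(bin - 1L) * step_pct <= pct &
                 pct < (bin - 1L) * step_pct + bin_pct]
  long
}

# zone spans (upstream flank / body / downstream flank) for a region table
.metagene_zones <- function(regions, flank_bp, contig_lengths) {
  r <- data.table::as.data.table(regions)
  r <- r[end0 - start0 >= 40L]  # shorter regions have degenerate bins
  if (nrow(r) == 0L) return(r)
  flip <- r$strand == "-"
  zones <- data.table::rbindlist(list(
    r[, .(region_id, zone = "body", contig, zstart = start0, zend = end0,
          flip = strand == "-")],
    r[, .(region_id, zone = ifelse(strand == "-", "downstream", "upstream"),
          contig, zstart = start0 - flank_bp, zend = start0,
          flip = strand == "-")],
    r[, .(region_id, zone = ifelse(strand == "-", "upstream", "downstream"),
          contig, zstart = end0, zend = end0 + flank_bp,
          flip = strand == "-")]))
  lens <- contig_lengths
  zones <- zones[zstart >= 0L & zend <= lens[contig]]
  zones
}

#' Pooled metagene / meta-TE methylation profile
#'
#' Regions are rescaled to percent coordinates and scanned with an
#' overlapping sliding window of 5% of the region length at a 2.5% step
#' (39 bins), separately for the body and for flanking sequence of the
#' given size (2 kb for genes, 0.5 kb for TEs, by convention).
#' Minus-strand regions are flipped so bins run 5' to 3'.  Per bin, levels
#' of methylcytosines are pooled across regions and divided by the summed
#' bin length (absolute) or the summed cytosine-site count (relative).
#'
#' @param regions Region table (body spans) with `strand`.
#' @param sites Called site table for one sample.
#' @param cytosines Reference cytosine table.
#' @param flank_bp Flank length in bp (default 2000).
#' @param contexts Optional context filter.
#' @param contig_lengths Named contig lengths (required to clip flanks).
#' @param bin_pct,step_pct Window and step, in percent of the zone length.
#' @return List: `profile` (pooled per zone and bin) and `per_region`
#'   (per-region per-bin absolute/relative levels, used for
#'   methylation-expression correlation profiles).
#' @export
metagene_profile <- function(regions, sites, cytosines, flank_bp = 2000L,
                             contexts = NULL, contig_lengths = NULL,
                             bin_pct = 5, step_pct = 2.5) {
  if (is.null(contig_lengths))
    stop("contig_lengths is required")
  st <- if (is.null(contexts)) sites else sites[context %in% contexts]
  cy <- if (is.null(contexts)) cytosines
        else cytosines[context %in% contexts]
  zones <- .metagene_zones(regions, flank_bp, contig_lengths)
  if (nrow(zones) == 0L) stop("no usable regions (all shorter than 40 bp)")
  zones[, zone_len := zend - zstart]
  meth <- .metagene_assign(st[is_mC == TRUE], zones, bin_pct, step_pct)
  csites <- .metagene_assign(cy[, .(contig, pos0)], zones, bin_pct, step_pct)
  zl <- zones[, .(region_id, zone, zone_len)]
  n_bins <- as.integer((100 - bin_pct) / step_pct) + 1L
  grid <- data.table::CJ(zone = c("upstream", "body", "downstream"),
                         bin = seq_len(n_bins))

  msum <- if (nrow(meth)) meth[, .(meth_sum = sum(level)),
                               by = .(region_id, zone, bin)]
          else data.table::data.table(region_id = character(),
                                      zone = character(), bin = integer(),
                                      meth_sum = numeric())
  ccnt <- if (nrow(csites)) csites[, .(n_c = .N), by = .(region_id, zone, bin)]
          else data.table::data.table(region_id = character(),
                                      zone = character(), bin = integer(),
                                      n_c = integer())
  # per (region, zone, bin) frame over all regions that have the zone
  frame <- zl[, data.table::CJ(bin = seq_len(n_bins)), by = .(region_id, zone,
                                                              zone_len)]
  per <- merge(frame, msum, by = c("region_id", "zone", "bin"), all.x = TRUE)
  per <- merge(per, ccnt, by = c("region_id", "zone", "bin"), all.x = TRUE)
  per[is.na(meth_sum), meth_sum := 0]
  per[is.na(n_c), n_c := 0L]
  per[, bin_len := zone_len * bin_pct / 100]
  per[, abs_level := meth_sum / bin_len]
  per[, rel_level := data.table::fifelse(n_c > 0L, meth_sum / n_c, NA_real_)]

  prof <- per[, .(abs_level = sum(meth_sum) / sum(bin_len),
                  rel_level = if (sum(n_c) > 0L) sum(meth_sum) / sum(n_c)
                              else NA_real_,
                  n_regions = data.table::uniqueN(region_id)),
              by = .(zone, bin)]
  prof <- merge(grid, prof, by = c("zone", "bin"), all.x = TRUE)
  prof[, zone := factor(zone, levels = c("upstream", "body", "downstream"))]
  data.table::setorder(prof, zone, bin)
  list(profile = prof[], per_region = per[])
}

#' Fraction of span bases covered by features
#'
#' Density of TEs or smRNA loci over spans: the number of bases of a span
#' that fall inside any feature interval, divided by the span length.
#'
#' @param features Interval table (`contig`, `start0`, `end0`).
#' @param spans Span table (`region_id`, `contig`, `start0`, `end0`).
#' @return The spans with an added `density` column in \[0, 1\].
#' @export
feature_density <- function(features, spans) {
  spans <- data.table::as.data.table(spans)
  out <- data.table::copy(spans)
  out[, density := 0]
  if (nrow(features) == 0L || nrow(spans) == 0L) return(out[])
  f <- data.table::as.data.table(features)[, .(contig, xstart = start0,
                                               xend = end0 - 1L)]
  data.table::setkey(f, contig, xstart, xend)
  s <- out[, .(region_id, contig, xstart = start0, xend = end0 - 1L)]
  ov <- data.table::foverlaps(s, f, by.x = c("contig", "xstart", "xend"),
                              type = "any", nomatch = NULL)
  if (nrow(ov)) {
    ov[, ovlen := pmin(xend, i.xend) - pmax(xstart, i.xstart) + 1L]
    d <- ov[, .(bases = sum(ovlen)), by = region_id]
    out[d, density := bases / (end0 - start0), on = "region_id"]
  }
  out[]
}

#' Rank correlation between region length and methylation level
#'
#' Spearman correlation (average ranks for ties) of region length against
#' absolute and relative methylation level.
#'
#' @param region_meth Output of [region_levels()]; at least 3 regions.
#' @return List with `rho_absolute` and `rho_relative`.
#' @export
length_methylation_correlation <- function(region_meth) {
  if (nrow(region_meth) < 3L)
    stop("need at least 3 regions")
  list(rho_absolute = stats::cor(region_meth$length_bp,
                                 region_meth$absolute_level,
                                 method = "spearman"),
       rho_relative = stats::cor(region_meth$length_bp,
                                 region_meth$relative_level,
                                 method = "spearman"))
}

#' Cross-sample coefficient of variation of methylation levels
#'
#' For each unit (gene, region or window) with levels measured in all four
#' samples, computes the mean, sample standard deviation (n - 1) and
#' CV = sd/mean across samples (units with zero mean are excluded: their
#' CV is undefined), plus the Spearman correlation between
#' log2-transformed level and log2-transformed CV per context, which
#' measures whether highly methylated units are evolutionarily more
#' stable.
#'
#' @param levels_wide `data.table` with `unit_id`, optional `context`, and
#'   one level column per sample (`BSD_SAMPLES`).
#' @return List: `stats` (per-unit mean/sd/cv) and `correlation` (per
#'   context, Spearman rho of log2 level vs log2 CV and n).
#' @export
cv_stats <- function(levels_wide) {
  lw <- data.table::as.data.table(levels_wide)
  if (!"context" %in% names(lw)) lw[, context := "all"]
  m <- as.matrix(lw[, BSD_SAMPLES, with = FALSE])
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  st <- lw[, .(unit_id, context)]
  st[, `:=`(mean_level = mu, sd_level = sdv,
            cv = data.table::fifelse(mu > 0, sdv / mu, NA_real_))]
  st <- st[!is.na(cv)]
  corr <- st[cv > 0 & mean_level > 0,
             .(rho = if (.N >= 3L)
                 stats::cor(log2(mean_level), log2(cv),
                            method = "spearman") else NA_real_,
               n = .N),
             by = context]
  list(stats = st[], correlation = corr[])
}
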