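# Directional paired-end bisulfite read simulation and NlaIII DGE tags.

# per-position C-retention probabilities for one contig of one sample:
# list(plus = numeric(L), minus = numeric(L)) with NA at non-cytosines.
.site_probs <- function(sample_seq, ctg, truth, sample, config, cmap) {
  v <- utf8ToInt(sample_seq)
  L <- length(v)
  pp <- rep(NA_real_, L)
  pm <- rep(NA_real_, L)
  tr <- truth[.(ctg)]
  if (nrow(tr)) {
    trp <- tr[strand == "+"]
    trm <- tr[strand == "-"]
    pp[trp$pos0 + 1L] <- trp[[sample]]
    pm[trm$pos0 + 1L] <- trm[[sample]]
  }
  isC <- v == 67L
  isG <- v == 71L
  # drop truth entries where the sample genotype is no longer a cytosine
  pp[!isC] <- NA_real_
  pm[!isG] <- NA_real_
  # SNP-created cytosines absent from the truth table get the compartment
  # mean for their (sample-genome) context
  new_p <- which(isC & is.na(pp))
  new_m <- which(isG & is.na(pm))
  if (length(new_p) || length(new_m)) {
    lv <- config$methylation_levels
    lv_map <- lv[, stats::setNames(level,
                                   paste(compartment, context, sep = "|"))]
    comp_vec <- cmap[[ctg]]
    ctx_plus <- function(i) {
      ifelse(i > L - 2L, "CHH",
             ifelse(v[pmin(i + 1L, L)] == 71L, "CG",
                    ifelse(v[pmin(i + 2L, L)] == 71L, "CHG", "CHH")))
    }
    ctx_minus <- function(i) {
      ifelse(i < 3L, "CHH",
             ifelse(v[pmax(i - 1L, 1L)] == 67L, "CG",
                    ifelse(v[pmax(i - 2L, 1L)] == 67L, "CHG", "CHH")))
    }
    fill <- function(idx, ctx) {
      key <- paste(comp_vec[idx], ctx, sep = "|")
      val <- unname(lv_map[key])
      val[comp_vec[idx] == "chloroplast" | is.na(val)] <- 0
      val
    }
    if (length(new_p)) pp[new_p] <- fill(new_p, ctx_plus(new_p))
    if (length(new_m)) pm[new_m] <- fill(new_m, ctx_minus(new_m))
  }
  list(plus = pp, minus = pm)
}

# bisulfite-convert + sequencing-error emission over a position matrix.
# vi: genome int codes; probvec: per-position retention prob (strand of
# origin); minus_space: emit minus-strand bases (complement) if TRUE.
.emit <- function(vi, probvec, posmat, minus_space, nc) {
  b <- matrix(vi[posmat], nrow = nrow(posmat))
  if (minus_space) b <- matrix(.COMP_INT[b], nrow = nrow(posmat))
  isC <- b == 67L
  if (any(isC)) {
    pr <- matrix(probvec[posmat], nrow = nrow(posmat))
    pr[is.na(pr)] <- 0
    u <- matrix(stats::runif(length(b)), nrow = nrow(posmat))
    retain <- isC & (u < (pr + (1 - pr) * nc))
    b[isC] <- 84L               # converted to T
    b[retain] <- 67L            # methylated or non-converted: stays C
  }
  b
}

.apply_seq_errors <- function(b, rate) {
  if (rate <= 0) return(b)
  err <- which(stats::runif(length(b)) < rate)
  if (length(err)) {
    codes <- utf8ToInt(paste(DNA_BASES, collapse = ""))
    cur <- match(b[err], codes)
    b[err] <- codes[((cur - 1L + sample.int(3L, length(err),
                                            replace = TRUE)) %% 4L) + 1L]
  }
  b
}

.int_to_strings <- function(b) {
  ch <- matrix(intToUtf8(as.integer(t(b)), multiple = TRUE),
               nrow = nrow(b), byrow = TRUE)
  collapse_rows(ch)
}

.qual_strings <- function(n, rl, low_q_fraction) {
  if (low_q_fraction <= 0) return(rep(phred_string(40L, rl), n))
  qc <- matrix(rawToChar(as.raw(33L + 40L)), nrow = n, ncol = rl)
  low <- matrix(stats::runif(n * rl) < low_q_fraction, nrow = n)
  qc[low] <- rawToChar(as.raw(33L + 15L))
  collapse_rows(qc)
}

#' Simulate directional paired-end bisulfite reads for one sample
#'
#' Fragments are drawn uniformly from both strands of the sample's genome
#' (reference plus its planted genotypes).  On the originating strand each
#' cytosine is emitted as C with probability
#' `methylation_prob + (1 - methylation_prob) * non_conversion_rate`, else
#' T; mate 1 reads the 5' end of the converted strand and mate 2 the
#' reverse-complement of its 3' end, so mate 1 carries C-to-T and mate 2
#' G-to-A conversion signatures.  Independent per-base sequencing errors
#' are then applied, qualities are constant Q40 (with an optional low-Q
#' admixture), and a configurable fraction of fragments is duplicated
#' exactly to emulate PCR clones.
#'
#' @param genome Reference genome (named character vector).
#' @param truth Methylation truth table from [assign_methylation_truth()].
#' @param sample Sample name (one of `BSD_SAMPLES`).
#' @param config The [sim_config()].
#' @param genotypes Optional planted genotypes from [plant_snps()].
#' @param annotation Optional annotation (needed to assign compartment
#'   means to SNP-created cytosines; without it they default to the truth
#'   table only).
#' @return `data.table` with one row per read pair: `read_id`, `contig`,
#'   `true_start0`, `true_end0`, `true_strand`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `is_clone`.  Zero depth yields a valid empty table.
#' @export
simulate_bs_reads <- function(genome, truth, sample, config,
                              genotypes = NULL, annotation = NULL) {
  stopifnot(sample %in% BSD_SAMPLES)
  set.seed(derive_seed(config$seed, paste0("reads_", sample)))
  rl <- config$read_length
  nc <- config$non_conversion_rate
  sampg <- make_sample_genome(genome, genotypes, sample)
  cmap <- if (!is.null(annotation)) compartment_map(genome, annotation)
          else stats::setNames(
            lapply(names(genome), function(n) rep("intergenic", nchar(genome[[n]]))),
            names(genome))
  if (!is.null(annotation)) {
    ctgs <- annotation$contigs
    for (i in seq_len(nrow(ctgs)))
      if (ctgs$is_chloroplast[i])
        cmap[[ctgs$name[i]]] <- rep("chloroplast", ctgs$length[i])
  }

  out <- list()
  for (ctg in names(genome)) {
    gseq <- sampg[[ctg]]
    vi <- utf8ToInt(gseq)
    L <- length(vi)
    probs <- .site_probs(gseq, ctg, truth, sample, config, cmap)
    n <- as.integer(round(config$depth * L / (2 * rl)))
    if (n == 0L) next
    for (strd in c("+", "-")) {
      ins <- sample(config$insert_range[1]:config$insert_range[2], n,
                    replace = TRUE)
      ins <- pmin(ins, L)
      s0 <- floor(stats::runif(n) * (L - ins + 1))   # 0-based fragment start
      if (strd == "+") {
        m1 <- .emit(vi, probs$plus, outer(s0, 1:rl, `+`), FALSE, nc)
        e2 <- .emit(vi, probs$plus, outer(s0 + ins - rl, 1:rl, `+`), FALSE, nc)
        m2 <- matrix(.COMP_INT[e2[, rl:1, drop = FALSE]], nrow = n)
      } else {
        # mate 1 reads the minus strand from the fragment's right end
        m1 <- .emit(vi, probs$minus, outer(s0 + ins + 1L, 1:rl, `-`), TRUE, nc)
        e2 <- .emit(vi, probs$minus, outer(s0, 1:rl, `+`), TRUE, nc)
        m2 <- matrix(.COMP_INT[e2], nrow = n)
      }
      m1 <- .apply_seq_errors(m1, config$seq_error_rate)
      m2 <- .apply_seq_errors(m2, config$seq_error_rate)
      dt <- data.table::data.table(
        read_id = sprintf("%s:%s:%s:%06d", sample, ctg, strd, seq_len(n)),
        contig = ctg, true_start0 = as.integer(s0),
        true_end0 = as.integer(s0 + ins), true_strand = strd,
        seq1 = .int_to_strings(m1),
        qual1 = .qual_strings(n, rl, config$low_q_fraction),
        seq2 = .int_to_strings(m2),
        qual2 = .qual_strings(n, rl, config$low_q_fraction),
        is_clone = FALSE)
      out[[paste(ctg, strd)]] <- dt
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(
      read_id = character(), contig = character(), true_start0 = integer(),
      true_end0 = integer(), true_strand = character(), seq1 = character(),
      qual1 = character(), seq2 = character(), qual2 = character(),
      is_clone = logical()))
  }
  pairs <- data.table::rbindlist(out)
  if (config$clonal_fraction > 0 && nrow(pairs)) {
    dup <- which(stats::runif(nrow(pairs)) < config$clonal_fraction)
    if (length(dup)) {
      clones <- data.table::copy(pairs[dup])
      clones[, `:=`(read_id = paste0(read_id, ":dup"), is_clone = TRUE)]
      pairs <- data.table::rbindlist(list(pairs, clones))
    }
  }
  pairs[]
}

#' CATG anchor sites of a set of cDNAs
#'
#' @param cdnas Named character vector of transcript sequences.
#' @return `data.table` with `gene`, `pos1` (1-based position of the CATG),
#'   `tag` (CATG + following 17 nt) and `rank3p` (1 = 3'-most tag-emitting
#'   site); transcripts whose CATG lacks 17 following bases emit no tag.
#' @keywords internal
catg_sites <- function(cdnas) {
  hits <- gregexpr("CATG", cdnas, fixed = TRUE)
  out <- lapply(seq_along(cdnas), function(i) {
    p <- hits[[i]]
    if (p[1L] == -1L) return(NULL)
    p <- p[p + 20L <= nchar(cdnas[[i]])]
    if (length(p) == 0L) return(NULL)
    data.table::data.table(
      gene = names(cdnas)[i], pos1 = as.integer(p),
      tag = substring(cdnas[[i]], p, p + 20L),
      rank3p = rev(seq_along(p)))
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L)
    out <- data.table::data.table(gene = character(), pos1 = integer(),
                                  tag = character(), rank3p = integer())
  out[]
}

#' Simulate an NlaIII DGE tag library
#'
#' Tags (CATG plus the following 17 nt) are sampled in proportion to true
#' transcript abundance; each tag comes from the 3'-most CATG site of its
#' transcript, or, with probability `tag_internal_p`, from a random
#' internal site.  Transcripts lacking a usable CATG emit no tags.
#'
#' @param cdnas Named character vector of transcript sequences.
#' @param expression Named numeric vector of true abundances (same gene
#'   universe as `cdnas`).
#' @param config The [sim_config()].
#' @param sample Sample name (only used to derive the RNG stream).
#' @return Character vector of 21-nt tag sequences; attribute `truth` is a
#'   `data.table` of per-gene sampled counts.
#' @export
simulate_dge_library <- function(cdnas, expression, config,
                                 sample = "cult1") {
  set.seed(derive_seed(config$seed, paste0("dge_", sample)))
  sites <- catg_sites(cdnas)
  ok <- intersect(names(expression)[expression > 0], unique(sites$gene))
  truth <- data.table::data.table(gene = character(), count = integer())
  if (length(ok) == 0L || config$tag_count == 0L) {
    res <- character(0L)
    data.table::setattr(res, "truth", truth)
    return(res)
  }
  prob <- expression[ok] / sum(expression[ok])
  counts <- as.integer(stats::rmultinom(1L, config$tag_count, prob))
  names(counts) <- ok
  tags <- vector("list", length(ok))
  for (i in seq_along(ok)) {
    g <- ok[i]; n <- counts[i]
    if (n == 0L) next
    st <- sites[gene == g]
    primary <- st$tag[st$rank3p == 1L]
    if (nrow(st) > 1L && config$tag_internal_p > 0) {
      k <- stats::rbinom(1L, n, config$tag_internal_p)
      internal <- st$tag[st$rank3p > 1L]
      tags[[i]] <- c(rep(primary, n - k),
                     sample(internal, k, replace = TRUE))
    } else {
      tags[[i]] <- rep(primary, n)
    }
  }
  res <- unlist(tags) %||% character(0L)
  if (config$tag_error_rate > 0 && length(res)) {
    m <- char_matrix(res, 21L)
    err <- which(stats::runif(length(m)) < config$tag_error_rate)
    if (length(err))
      m[err] <- vapply(m[err], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1L))
    res <- collapse_rows(m)
  }
  truth <- data.table::data.table(gene = ok, count = counts)
  data.table::setattr(res, "truth", truth)
  res
}
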