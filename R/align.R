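# Three-letter bisulfite alignment: converted references, read conversion,
# unique-best ungapped paired placement, clonal dedup, base restoration.

#' Build bisulfite-converted reference sequences
#'
#' The T-genome (every C replaced by T) is the alignment target for reads
#' originating from the plus strand; the A-genome (every G replaced by A)
#' targets minus-strand reads.  The original sequence is retained for
#' restoring alignments.
#'
#' @param genome Named character vector of contig sequences.
#' @return List of class `converted_reference` with elements `t_genome`,
#'   `a_genome`, `original`.
#' @export
build_converted_references <- function(genome) {
  if (length(genome) == 0L || any(nchar(genome) == 0L))
    stop("genome must be non-empty")
  structure(list(t_genome = chartr("C", "T", genome),
                 a_genome = chartr("G", "A", genome),
                 original = genome),
            class = "converted_reference")
}

#' In-silico convert a read pair for three-letter mapping
#'
#' Mate 1 has every observed C replaced by T; mate 2 every observed G
#' replaced by A.  Originals are preserved alongside for restoration.
#'
#' @param seq1,seq2 Character vectors of mate sequences.
#' @return List with `conv1`, `conv2`, `orig1`, `orig2`.
#' @export
convert_read_pair <- function(seq1, seq2) {
  list(conv1 = chartr("C", "T", seq1),
       conv2 = chartr("G", "A", seq2),
       orig1 = seq1, orig2 = seq2)
}

# default per-mate mismatch cap by read length
default_mismatch_cap <- function(read_length) {
  if (read_length <= 44L) 2L else 4L
}

# all placements of each query with <= cap mismatches against one converted
# genome, via (cap+1)-way seed pigeonhole over an exact k-mer index
seed_hits <- function(queries, target, cap, rl) {
  k <- max(8L, rl %/% (cap + 1L))
  n_seeds <- cap + 1L
  offsets <- (seq_len(n_seeds) - 1L) * k
  idx <- data.table::rbindlist(lapply(names(target), function(ctg) {
    L <- nchar(target[[ctg]])
    if (L < k) return(NULL)
    data.table::data.table(
      contig = ctg,
      gpos0 = 0:(L - k),
      kmer = substring(target[[ctg]], 1:(L - k + 1L), k:L))
  }))
  data.table::setkey(idx, kmer)
  seeds <- data.table::rbindlist(lapply(seq_len(n_seeds), function(i) {
    data.table::data.table(
      qidx = seq_along(queries),
      offset = offsets[i],
      kmer = substring(queries, offsets[i] + 1L, offsets[i] + k))
  }))
  cand <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L)
    return(data.table::data.table(qidx = integer(), contig = character(),
                                  pos0 = integer(), mm = integer()))
  cand[, pos0 := gpos0 - offset]
  cand <- unique(cand[, .(qidx, contig, pos0)])
  lens <- stats::setNames(nchar(target), names(target))
  cand <- cand[pos0 >= 0L & pos0 + rl <= lens[contig]]
  if (nrow(cand) == 0L)
    return(data.table::data.table(qidx = integer(), contig = character(),
                                  pos0 = integer(), mm = integer()))
  sub <- substring(target[cand$contig], cand$pos0 + 1L, cand$pos0 + rl)
  cand[, mm := mismatch_count(queries[qidx], sub)]
  cand[mm <= cap][]
}

#' Align converted read pairs to both converted genomes
#'
#' Ungapped end-to-end placement of both mates in forward-reverse
#' orientation on each converted genome (T-genome = plus-strand origin,
#' A-genome = minus-strand origin), allowing up to `max_mismatches` per
#' mate (default 2 for 44 nt reads, 4 for 75 nt).  A pair is reported
#' mapped only when one placement has strictly fewer total mismatches than
#' every other placement across both genomes and all positions; equal-best
#' placements anywhere give status "ambiguous", no placement within the
#' cap gives "unmapped".
#'
#' @param pairs Read-pair `data.table` (columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`; extra columns are carried along).
#' @param refs A `converted_reference` from [build_converted_references()].
#' @param max_mismatches Per-mate mismatch cap; `NULL` selects the
#'   read-length default.
#' @param max_insert Maximum fragment length considered when pairing mates.
#' @return `data.table` with one row per input pair: `read_id`, `status`
#'   ("mapped"/"ambiguous"/"unmapped"), and for mapped pairs `contig`,
#'   `frag_start` / `frag_end` (0-based half-open fragment span),
#'   `origin` ("+" when the T-genome matched, "-" for the A-genome),
#'   `mm` (total mismatches in converted space), plus the original
#'   sequences and qualities.
#' @export
align_read_pairs <- function(pairs, refs, max_mismatches = NULL,
                             max_insert = 600L) {
  stopifnot(inherits(refs, "converted_reference"))
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L)
    return(data.table::data.table(
      read_id = character(), status = character(), contig = character(),
      frag_start = integer(), frag_end = integer(), origin = character(),
      mm = integer(), seq1 = character(), qual1 = character(),
      seq2 = character(), qual2 = character()))
  rls <- unique(nchar(pairs$seq1))
  if (length(rls) != 1L || !identical(rls, unique(nchar(pairs$seq2))))
    stop("all mates must share a single read length")
  rl <- rls
  cap <- max_mismatches %||% default_mismatch_cap(rl)

  conv <- convert_read_pair(pairs$seq1, pairs$seq2)
  f1 <- conv$conv1                                  # plus origin, left mate
  f2 <- chartr("C", "T", revcomp_chr(pairs$seq2))   # plus origin, right mate
  g2 <- conv$conv2                                  # minus origin, left end
  g1 <- chartr("G", "A", revcomp_chr(pairs$seq1))   # minus origin, right end

  h_f1 <- seed_hits(f1, refs$t_genome, cap, rl)
  h_f2 <- seed_hits(f2, refs$t_genome, cap, rl)
  h_g2 <- seed_hits(g2, refs$a_genome, cap, rl)
  h_g1 <- seed_hits(g1, refs$a_genome, cap, rl)

  pair_up <- function(left, right, orig) {
    m <- merge(left, right, by = c("qidx", "contig"),
               allow.cartesian = TRUE, suffixes = c("_l", "_r"))
    m <- m[pos0_r >= pos0_l & pos0_r + rl - pos0_l <= max_insert]
    if (nrow(m) == 0L)
      return(data.table::data.table(qidx = integer(), contig = character(),
                                    frag_start = integer(),
                                    frag_end = integer(), origin = character(),
                                    mm_total = integer()))
    m[, .(qidx, contig, frag_start = pos0_l, frag_end = pos0_r + rl,
          origin = orig, mm_total = mm_l + mm_r)]
  }
  cand <- data.table::rbindlist(list(pair_up(h_f1, h_f2, "+"),
                                     pair_up(h_g2, h_g1, "-")))

  base <- pairs[, .(read_id, seq1, qual1, seq2, qual2)]
  base[, qidx := .I]
  if (nrow(cand) == 0L) {
    out <- base[, .(read_id, status = "unmapped", contig = NA_character_,
                    frag_start = NA_integer_, frag_end = NA_integer_,
                    origin = NA_character_, mm = NA_integer_,
                    seq1, qual1, seq2, qual2)]
    return(out[])
  }
  cand[, best := min(mm_total), by = qidx]
  summ <- cand[mm_total == best,
               .(n_best = .N, contig = contig[1L], frag_start = frag_start[1L],
                 frag_end = frag_end[1L], origin = origin[1L],
                 mm = best[1L]), by = qidx]
  out <- merge(base, summ, by = "qidx", all.x = TRUE)
  out[, status := data.table::fifelse(
    is.na(n_best), "unmapped",
    data.table::fifelse(n_best > 1L, "ambiguous", "mapped"))]
  out[status != "mapped", `:=`(contig = NA_character_,
                               frag_start = NA_integer_,
                               frag_end = NA_integer_,
                               origin = NA_character_, mm = NA_integer_)]
  out[, .(read_id, status, contig, frag_start, frag_end, origin, mm,
          seq1, qual1, seq2, qual2)][]
}

#' Remove clonal duplicates among aligned pairs
#'
#' Pairs mapped to the same start position for both ends (same contig,
#' fragment start, fragment end and origin strand) are regarded as PCR
#' clones; the pair with the highest mean base quality survives, ties
#' broken by input order.  Idempotent, and never merges records with
#' distinct placements.
#'
#' @param alignments Mapped alignment `data.table` from
#'   [align_read_pairs()] (rows with status "mapped").
#' @return The surviving records; attribute `n_removed` counts clones
#'   dropped.
#' @export
dedupe_clonal <- function(alignments) {
  aln <- data.table::as.data.table(alignments)[status == "mapped"]
  if (nrow(aln) == 0L) {
    data.table::setattr(aln, "n_removed", 0L)
    return(aln[])
  }
  aln[, meanq := vapply(paste0(qual1, qual2),
                        function(s) mean(utf8ToInt(s)) - 33, numeric(1L))]
  ord <- order(-aln$meanq, seq_len(nrow(aln)))
  aln <- aln[ord]
  kept <- aln[!duplicated(aln[, .(contig, frag_start, frag_end, origin)])]
  n_removed <- nrow(aln) - nrow(kept)
  kept[, meanq := NULL]
  data.table::setorder(kept, contig, frag_start, frag_end)
  data.table::setattr(kept, "n_removed", n_removed)
  kept[]
}

#' Restore aligned pairs to original bases, one row per read base
#'
#' Transforms each uniquely mapped pair and the reference back to their
#' original forms and pairs them column-wise.  Bases are reported in the
#' origin-strand space, where bisulfite conversion is always "read T over
#' reference C": `base` is the read base along the originating strand and
#' `base_plus` its projection onto plus-strand coordinates
#' (complemented for minus-origin reads).  Overlapping mate bases are
#' counted once (mate 1 kept).
#'
#' @param alignments Deduplicated mapped alignments.
#' @param genome Original reference (named character vector).
#' @return `data.table` with `read_id`, `contig`, `pos0`, `origin`, `mate`,
#'   `base`, `base_plus`, `qual` (integer Phred).
#' @export
restore_alignments <- function(alignments, genome) {
  aln <- data.table::as.data.table(alignments)[status == "mapped"]
  if (nrow(aln) == 0L)
    return(data.table::data.table(
      read_id = character(), contig = character(), pos0 = integer(),
      origin = character(), mate = integer(), base = character(),
      base_plus = character(), qual = integer()))
  rl <- nchar(aln$seq1[1L])

  build <- function(sub, mate) {
    n <- nrow(sub)
    if (n == 0L) return(NULL)
    plus <- sub$origin == "+"
    s <- sub$frag_start; e <- sub$frag_end
    if (mate == 1L) {
      seqm <- char_matrix(sub$seq1, rl)
      qm <- matrix(utf8ToInt(paste(sub$qual1, collapse = "")),
                   nrow = n, byrow = TRUE) - 33L
      # plus origin: mate1 spans [s, s+rl) left-to-right;
      # minus origin: mate1 reads the minus strand from the right end
      posm <- matrix(NA_integer_, n, rl)
      posm[plus, ] <- outer(s[plus], 0:(rl - 1L), `+`)
      posm[!plus, ] <- outer(e[!plus] - 1L, 0:(rl - 1L), `-`)
      basem <- seqm
    } else {
      seqm <- char_matrix(sub$seq2, rl)
      qm <- matrix(utf8ToInt(paste(sub$qual2, collapse = "")),
                   nrow = n, byrow = TRUE) - 33L
      posm <- matrix(NA_integer_, n, rl)
      basem <- matrix(NA_character_, n, rl)
      qm2 <- qm
      # plus origin: mate2 is the reverse complement of the fragment's
      # right end; project back onto plus coordinates
      if (any(plus)) {
        posm[plus, ] <- outer(e[plus] - rl, 0:(rl - 1L), `+`)
        basem[plus, ] <- comp_chr(seqm[plus, rl:1, drop = FALSE])
        qm2[plus, ] <- qm[plus, rl:1, drop = FALSE]
      }
      # minus origin: mate2 covers the fragment's left end; its reverse
      # complement is the minus-strand sequence at ascending plus coords
      if (any(!plus)) {
        posm[!plus, ] <- outer(s[!plus], 0:(rl - 1L), `+`)
        basem[!plus, ] <- comp_chr(seqm[!plus, , drop = FALSE])
      }
      qm <- qm2
    }
    data.table::data.table(
      read_id = rep(sub$read_id, rl),
      contig = rep(sub$contig, rl),
      pos0 = as.integer(posm),
      origin = rep(sub$origin, rl),
      mate = mate,
      base = as.character(basem),
      qual = as.integer(qm),
      frag_start = rep(s, rl), frag_end = rep(e, rl))
  }
  long <- data.table::rbindlist(list(build(aln, 1L), build(aln, 2L)))
  # count overlapping mate bases once: drop mate-2 rows inside mate 1's span
  long <- long[!(mate == 2L & origin == "+" & pos0 < frag_start + rl)]
  long <- long[!(mate == 2L & origin == "-" & pos0 >= frag_end - rl)]
  long[, base_plus := data.table::fifelse(origin == "+", base,
                                          comp_chr(base))]
  long[, c("frag_start", "frag_end") := NULL]
  data.table::setkey(long, contig, pos0)
  long[]
}

#' Column-wise restoration of a single alignment record
#'
#' Pairs every original read base with the original reference base on the
#' originating strand and flags bisulfite-consistent columns (read T over
#' reference C in origin-strand space), which are conversions rather than
#' mismatches.
#'
#' @param record One row of a mapped alignment table.
#' @param genome Original reference.
#' @return `data.table` with `pos0`, `mate`, `base`, `ref_base`, `qual`,
#'   `bisulfite_consistent`, `match`.
#' @export
restore_alignment <- function(record, genome) {
  long <- restore_alignments(record, genome)
  refv <- strsplit(genome[[record$contig[1L]]], NULL, fixed = TRUE)[[1L]]
  long[, ref_base := data.table::fifelse(origin == "+", refv[pos0 + 1L],
                                         comp_chr(refv[pos0 + 1L]))]
  long[, bisulfite_consistent := base == "T" & ref_base == "C"]
  long[, match := base == ref_base]
  long[, .(pos0, mate, base, ref_base, qual, bisulfite_consistent, match)][]
}
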