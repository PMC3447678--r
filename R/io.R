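# Text-format interfaces: FASTA/FASTQ via Biostrings, BED6/GFF3 writers,
# tab-delimited site/genotype/truth tables (1-based in files).

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path Input path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write read pairs to a pair of FASTQ files (Phred+33)
#' @param pairs Read-pair table (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  wr(pairs$seq1, pairs$qual1, pairs$read_id, path1)
  wr(pairs$seq2, pairs$qual2, pairs$read_id, path2)
  invisible(c(path1, path2))
}

#' Read a pair of FASTQ files into a read-pair table
#' @param path1,path2 Mate FASTQ paths.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    # coercion drops the (empty) metadata columns; silence that notice
    suppressWarnings({
      x <- Biostrings::readQualityScaledDNAStringSet(p)
      data.table::data.table(read_id = names(x),
                             seq = as.character(x),
                             qual = as.character(Biostrings::quality(x)))
    })
  }
  a <- rd(path1); b <- rd(path2)
  stopifnot(identical(a$read_id, b$read_id))
  data.table::data.table(read_id = a$read_id, seq1 = a$seq, qual1 = a$qual,
                         seq2 = b$seq, qual2 = b$qual)
}

#' Write an interval table as BED6 (0-based half-open)
#' @param intervals Table with `contig`, `start0`, `end0`, optional
#'   id/strand columns.
#' @param path Output path.
#' @param name_col Column used for the BED name field.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  x <- data.table::as.data.table(intervals)
  nm <- if (!is.null(name_col)) as.character(x[[name_col]])
        else sprintf("feat%05d", seq_len(nrow(x)))
  bed <- data.table::data.table(
    x$contig, x$start0, x$end0, nm, 0L,
    if ("strand" %in% names(x)) x$strand else ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (1-based inclusive)
#' @param genes Gene table from [generate_genome()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tbsdiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig, genes$start0 + 1L, genes$end0,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-cytosine site report (CX-report-like dialect)
#'
#' Tab-delimited, one row per covered cytosine: contig, 1-based position,
#' strand, context, methylated count, total count, level, p-value, is_mC.
#' @param sites Called site table.
#' @param path Output path.
#' @export
write_site_report <- function(sites, path) {
  out <- sites[, .(contig, pos = pos0 + 1L, strand, context, n_meth,
                   n_total, level,
                   p_value = if ("p_value" %in% names(sites)) p_value
                             else NA_real_,
                   is_mC = if ("is_mC" %in% names(sites)) is_mC else NA)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a site report written by [write_site_report()]
#' @param path Input path.
#' @export
read_site_report <- function(path) {
  x <- data.table::fread(path)
  x[, pos0 := pos - 1L]
  x[, pos := NULL]
  data.table::setcolorder(x, c("contig", "pos0", "strand", "context",
                               "n_meth", "n_total", "level"))
  data.table::setkey(x, contig, pos0, strand)
  x[]
}

#' Write genotype calls (VCF-like tab-delimited, 1-based)
#' @param calls Genotype call table from [call_snps()].
#' @param path Output path.
#' @export
write_genotype_report <- function(calls, path) {
  out <- calls[, .(contig, pos = pos0 + 1L, ref, sample_base, strand_used,
                   depth_used, is_snp, status)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write an alignment table (SAM-like tab-delimited, 1-based starts)
#' @param alignments Alignment table.
#' @param path Output path.
#' @export
write_alignment_report <- function(alignments, path) {
  out <- alignments[, .(read_id, status, contig,
                        start = frag_start + 1L, end = frag_end,
                        origin, mm, seq1, qual1, seq2, qual2)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
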