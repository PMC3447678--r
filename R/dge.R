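# SAGE-style digital gene expression: CATG+17nt reference tag database,
# perfect-match unique-tag counting, per-million normalisation and
# 3'-site diagnostics.

#' Build the reference tag database from full-length cDNAs
#'
#' Every CATG occurrence followed by at least 17 nt emits a 21-mer tag
#' (CATG + the following 17 nt).  Tags found in two or more genes are
#' marked ambiguous; genes without any usable CATG are flagged.
#'
#' @param cdnas Named character vector of cDNA sequences.
#' @return List of class `tag_database`: `tags` (`tag`, `gene` or
#'   "AMBIGUOUS", `rank3p` = 3'-end site rank of the tag within its gene),
#'   `genes` (`gene`, `has_catg`, `n_sites`).
#' @export
build_tag_database <- function(cdnas) {
  sites <- catg_sites(cdnas)
  genes <- data.table::data.table(gene = names(cdnas))
  if (nrow(sites)) {
    gs <- sites[, .(n_sites = .N), by = gene]
    genes <- merge(genes, gs, by = "gene", all.x = TRUE)
  } else genes[, n_sites := NA_integer_]
  genes[is.na(n_sites), n_sites := 0L]
  genes[, has_catg := n_sites > 0L]
  if (nrow(sites)) {
    # a tag repeated within one gene keeps its 3'-most rank
    tags <- sites[, .(gene = gene[1L], rank3p = min(rank3p),
                      n_genes = data.table::uniqueN(gene)), by = tag]
    tags[n_genes > 1L, `:=`(gene = "AMBIGUOUS", rank3p = NA_integer_)]
    tags[, n_genes := NULL]
  } else {
    tags <- data.table::data.table(tag = character(), gene = character(),
                                   rank3p = integer())
  }
  data.table::setkey(tags, tag)
  structure(list(tags = tags[], genes = genes[], sites = sites),
            class = "tag_database")
}

#' Map DGE tag reads against the tag database
#'
#' Exact 21-mer lookup; only perfect matches to a tag unique to one gene
#' are counted.  Ambiguous tags, tags absent from the database and reads
#' shorter than 21 nt are discarded and tallied.
#'
#' @param tag_reads Character vector of raw tag reads (>= 21 nt; only the
#'   first 21 nt are used).
#' @param db A `tag_database`.
#' @return List of class `expression_profile`: `counts` (`gene`, `count`
#'   for every gene in the database), `stats` (total, mapped, ambiguous,
#'   absent, short) and `mapped` (per-tag table with `tag`, `gene`,
#'   `rank3p`, `count`).
#' @export
map_tags <- function(tag_reads, db) {
  stopifnot(inherits(db, "tag_database"))
  total <- length(tag_reads)
  short <- nchar(tag_reads) < 21L
  t21 <- substring(tag_reads[!short], 1L, 21L)
  obs <- data.table::data.table(tag = t21)[, .(count = .N), by = tag]
  hit <- merge(obs, db$tags, by = "tag", all.x = TRUE)
  absent <- hit[is.na(gene), sum(count)]
  ambiguous <- hit[!is.na(gene) & gene == "AMBIGUOUS", sum(count)]
  mapped <- hit[!is.na(gene) & gene != "AMBIGUOUS"]
  counts <- merge(db$genes[, .(gene)],
                  mapped[, .(count = sum(count)), by = gene],
                  by = "gene", all.x = TRUE)
  counts[is.na(count), count := 0L]
  stats <- data.table::data.table(
    total = total, mapped = mapped[, sum(count)],
    ambiguous = ambiguous %||% 0L, absent = absent %||% 0L,
    short = sum(short))
  structure(list(counts = counts[], stats = stats,
                 mapped = mapped[, .(tag, gene, rank3p, count)]),
            class = "expression_profile")
}

#' Normalise raw tag counts to tags per million
#'
#' @param profile An `expression_profile` from [map_tags()], or a
#'   `data.table` with `gene` and `count`.
#' @return `data.table` with `gene`, `count`, `per_million`; values over
#'   genes with counted tags sum to 1e6.
#' @export
normalize_per_million <- function(profile) {
  counts <- if (inherits(profile, "expression_profile")) profile$counts
            else data.table::as.data.table(profile)
  lib <- sum(counts$count)
  if (lib == 0L) stop("zero library size: no mapped tags to normalise")
  out <- data.table::copy(counts)
  out[, per_million := count * 1e6 / lib]
  out[]
}

#' Distribution of mapped tags across 3'-end CATG site ranks
#'
#' Diagnostic for transcript 3'-end annotation quality: in a well-annotated
#' transcript set most tags map to the 3'-most CATG site (rank 1).
#'
#' @param profile An `expression_profile` from [map_tags()].
#' @return `data.table` with `rank3p`, `n_tags`, `frac_tags`,
#'   `n_genes` (genes supported by tags at that rank).
#' @export
tag_position_distribution <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  m <- profile$mapped
  if (nrow(m) == 0L)
    return(data.table::data.table(rank3p = integer(), n_tags = integer(),
                                  frac_tags = numeric(), n_genes = integer()))
  out <- m[, .(n_tags = sum(count), n_genes = data.table::uniqueN(gene)),
           by = rank3p]
  out[, frac_tags := n_tags / sum(n_tags)]
  data.table::setorder(out, rank3p)
  out[]
}
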