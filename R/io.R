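#' Read a pair of FASTQ files into a read-pair tibble
#'
#' Mates are matched by file order (the usual demultiplexed Illumina layout).
#' A mismatch in read counts between the two files is a hard error.
#'
#' @param fastq_fwd,fastq_rev Paths to the forward and reverse FASTQ files
#'   (Phred+33).
#' @param site Site label attached to every pair.
#' @return A tibble with columns `id`, `site`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`; qualities are Phred+33 strings.
#' @export
read_fastq_pairs <- function(fastq_fwd, fastq_rev, site = "S1") {
  fwd <- Biostrings::readQualityScaledDNAStringSet(fastq_fwd)
  rev <- Biostrings::readQualityScaledDNAStringSet(fastq_rev)
  if (length(fwd) != length(rev))
    abort(sprintf(
      "Mate count mismatch: %d reads in '%s' but %d in '%s'",
      length(fwd), fastq_fwd, length(rev), fastq_rev))
  ids <- sub("[/ ].*$", "", names(fwd))
  tibble::tibble(
    id = ids,
    site = site,
    fwd_seq = unname(as.character(fwd)),
    fwd_qual = unname(as.character(Biostrings::quality(fwd))),
    rev_seq = unname(as.character(rev)),
    rev_qual = unname(as.character(Biostrings::quality(rev)))
  )
}

#' Write a read-pair tibble as two FASTQ files
#'
#' @param pairs Read-pair tibble (see [read_fastq_pairs()]).
#' @param fastq_fwd,fastq_rev Output paths.
#' @return The input, invisibly.
#' @export
write_fastq_pairs <- function(pairs, fastq_fwd, fastq_rev) {
  assert_cols(pairs, c("id", "fwd_seq", "fwd_qual", "rev_seq", "rev_qual"))
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- ids
    # advisory "metadata columns dropped" warning is expected here
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  }
  wr(pairs$fwd_seq, pairs$fwd_qual, pairs$id, fastq_fwd)
  wr(pairs$rev_seq, pairs$rev_qual, pairs$id, fastq_rev)
  invisible(pairs)
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub(" .*$", "", names(x)))
}

#' Read or write the VT reference catalogue
#'
#' The catalogue travels as a FASTA of type sequences plus a TSV sidecar with
#' columns `vt_id`, `cultured`, `biome_records`, `continents`, `realms`
#' (semicolon-separated lists).
#'
#' @param fasta,tsv Paths to the type-sequence FASTA and the sidecar TSV.
#' @return A reference tibble with list-columns `biome_records`, `continents`
#'   and `realms`.
#' @export
read_vt_reference <- function(fasta, tsv) {
  seqs <- read_fasta(fasta)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  assert_cols(meta, c("vt_id", "cultured", "biome_records", "continents", "realms"),
              "reference sidecar")
  if (!all(meta$vt_id %in% names(seqs)))
    abort("Reference sidecar lists vt_id values absent from the FASTA")
  split_semi <- function(x) {
    out <- strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  tibble::tibble(
    vt_id = meta$vt_id,
    type_seq = unname(seqs[meta$vt_id]),
    cultured = as.logical(meta$cultured),
    biome_records = split_semi(meta$biome_records),
    continents = split_semi(meta$continents),
    realms = split_semi(meta$realms)
  )
}

#' @rdname read_vt_reference
#' @param refs Reference tibble.
#' @export
write_vt_reference <- function(refs, fasta, tsv) {
  assert_cols(refs, c("vt_id", "type_seq", "cultured", "biome_records",
                      "continents", "realms"))
  write_fasta(stats::setNames(refs$type_seq, refs$vt_id), fasta)
  join_semi <- function(col) vapply(col, paste, character(1), collapse = ";")
  meta <- data.frame(
    vt_id = refs$vt_id,
    cultured = refs$cultured,
    biome_records = join_semi(refs$biome_records),
    continents = join_semi(refs$continents),
    realms = join_semi(refs$realms)
  )
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(refs)
}

#' Convert a long community tibble to a site x VT count matrix
#'
#' @param comm Community tibble with columns `site`, `vt_id`, `reads`.
#' @return An integer matrix, sites as rows, VT as columns (both sorted).
#' @export
community_matrix <- function(comm) {
  assert_cols(comm, c("site", "vt_id", "reads"))
  sites <- sort(unique(comm$site))
  vts <- sort(unique(comm$vt_id))
  m <- matrix(0L, length(sites), length(vts), dimnames = list(sites, vts))
  if (nrow(comm) > 0)
    m[cbind(match(comm$site, sites), match(comm$vt_id, vts))] <- as.integer(comm$reads)
  m
}

#' Convert a site x VT count matrix to a long community tibble
#' @param m Count matrix with site rownames and VT colnames.
#' @param keep_zeros Keep zero cells? Default drops them.
#' @export
community_tibble <- function(m, keep_zeros = FALSE) {
  out <- tibble::tibble(
    site = rep(rownames(m), times = ncol(m)),
    vt_id = rep(colnames(m), each = nrow(m)),
    reads = as.integer(m)
  )
  if (!keep_zeros) out <- dplyr::filter(out, .data$reads > 0)
  dplyr::arrange(out, .data$site, .data$vt_id)
}

#' Read or write a community table TSV (sites as rows, VT as columns)
#' @param path TSV path.
#' @export
read_community <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  community_tibble(m)
}

#' @rdname read_community
#' @param comm Community tibble.
#' @export
write_community <- function(comm, path) {
  m <- community_matrix(comm)
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(comm)
}

#' Presence sets per site
#' @param comm Community tibble.
#' @return Named list of character vectors of VT present at each site.
#' @export
community_sets <- function(comm) {
  assert_cols(comm, c("site", "vt_id"))
  lapply(split(comm$vt_id, comm$site), unique)
}
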