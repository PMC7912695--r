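#' Match and trim amplicon primers from read pairs
#'
#' Primers are anchored at the 5' terminus of each mate (amplicon primers are
#' terminal by construction).  IUPAC degeneracy codes in the primer match any
#' of their expansions; an N in the read matches nothing.  A pair is rejected
#' when either mate has more than `max_mismatch` mismatches against its primer
#' in the primer-length 5' window, or when a mate is shorter than its primer.
#'
#' @param pairs Read-pair tibble (see [read_fastq_pairs()]).
#' @param fwd_primer,rev_primer Primer sequences (may contain IUPAC codes).
#' @param max_mismatch Maximum mismatches tolerated per mate (default 1).
#' @return The input tibble with primers removed from passing pairs and a
#'   logical column `primer_ok`; sequences/qualities of failing pairs are left
#'   untrimmed.
#' @export
match_and_trim_primers <- function(pairs, fwd_primer, rev_primer,
                                   max_mismatch = 1L) {
  assert_cols(pairs, c("fwd_seq", "fwd_qual", "rev_seq", "rev_qual"))
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer), max_mismatch >= 0)
  mm_f <- cpp_primer_mismatch(pairs$fwd_seq, fwd_primer)
  mm_r <- cpp_primer_mismatch(pairs$rev_seq, rev_primer)
  ok <- mm_f <= max_mismatch & mm_r <= max_mismatch
  lf <- nchar(fwd_primer); lr <- nchar(rev_primer)
  dplyr::mutate(
    pairs,
    fwd_seq = ifelse(ok, substring(.data$fwd_seq, lf + 1L), .data$fwd_seq),
    fwd_qual = ifelse(ok, substring(.data$fwd_qual, lf + 1L), .data$fwd_qual),
    rev_seq = ifelse(ok, substring(.data$rev_seq, lr + 1L), .data$rev_seq),
    rev_qual = ifelse(ok, substring(.data$rev_qual, lr + 1L), .data$rev_qual),
    primer_ok = ok
  )
}

#' Filter read pairs on mean Phred quality
#'
#' A pair is kept iff the arithmetic mean Phred score of *both* mates is at
#' least `min_mean_q` (inclusive).  Pairs with an empty mate are dropped.
#'
#' @param pairs Read-pair tibble.
#' @param min_mean_q Minimum mean Phred score per mate (default 30).
#' @return The input tibble with a logical column `quality_ok`.
#' @export
quality_filter <- function(pairs, min_mean_q = 30) {
  assert_cols(pairs, c("fwd_qual", "rev_qual"))
  mf <- cpp_mean_phred(pairs$fwd_qual)
  mr <- cpp_mean_phred(pairs$rev_qual)
  ok <- !is.na(mf) & !is.na(mr) & mf >= min_mean_q & mr >= min_mean_q
  dplyr::mutate(pairs, quality_ok = ok)
}

#' Merge read pairs by overlap
#'
#' The reverse mate is reverse-complemented, then candidate overlap lengths in
#' `[min_overlap, max_overlap]` are scanned.  The overlap with the highest
#' identity (matching bases / overlap length; N matches nothing) of at least
#' `min_identity` is accepted, ties broken towards the longest overlap.
#' Consensus bases in the overlap take the mate with the higher Phred score,
#' ties going to the forward mate.
#'
#' @param pairs Read-pair tibble.
#' @param min_overlap,max_overlap Overlap window in bp (defaults 10 and 300).
#' @param min_identity Minimum overlap identity (default 0.75).
#' @return A tibble with columns `id`, `site`, `seq`, `overlap_len`,
#'   `merge_ok`; `seq`/`overlap_len` are NA for failed merges.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_overlap = 300L,
                        min_identity = 0.75) {
  assert_cols(pairs, c("id", "fwd_seq", "fwd_qual", "rev_seq", "rev_qual"))
  res <- cpp_merge_pairs(pairs$fwd_seq, pairs$fwd_qual,
                         pairs$rev_seq, pairs$rev_qual,
                         as.integer(min_overlap), as.integer(max_overlap),
                         min_identity)
  tibble::tibble(
    id = pairs$id,
    site = if ("site" %in% names(pairs)) pairs$site else NA_character_,
    seq = res$seq,
    overlap_len = res$overlap,
    merge_ok = res$ok
  )
}

#' Process the read pairs of one site: trim, filter, merge
#'
#' Applies [match_and_trim_primers()], [quality_filter()] and [merge_pairs()]
#' in order; a pair is counted in exactly one category (primer failure takes
#' precedence over quality failure, which takes precedence over merge
#' failure), so the per-site counts always sum to the input count.
#'
#' @param pairs Read-pair tibble for one or more sites.
#' @param config Pipeline configuration (see [pipeline_config()]); only the
#'   read-stage fields are used.
#' @return An object of class `amf_processed_reads`: a list with `merged`
#'   (tibble `id`, `site`, `seq`, `overlap_len`) and `stats` (per-site tibble
#'   `site`, `n_input`, `n_primer_fail`, `n_quality_fail`, `n_merge_fail`,
#'   `n_merged`).
#' @export
process_reads <- function(pairs, config = pipeline_config()) {
  assert_cols(pairs, c("id", "site", "fwd_seq", "fwd_qual", "rev_seq", "rev_qual"))
  sites <- unique(pairs$site)
  if (nrow(pairs) == 0) {
    out <- list(
      merged = tibble::tibble(id = character(), site = character(),
                              seq = character(), overlap_len = integer()),
      stats = empty_stats(sites)
    )
    class(out) <- c("amf_processed_reads", class(out))
    return(out)
  }
  trimmed <- match_and_trim_primers(pairs, config$fwd_primer, config$rev_primer,
                                    config$max_mismatch)
  qual <- quality_filter(trimmed, config$min_mean_q)
  stage2 <- dplyr::filter(qual, .data$primer_ok)
  stage3 <- dplyr::filter(stage2, .data$quality_ok)
  merged <- merge_pairs(stage3, config$min_overlap, config$max_overlap,
                        config$min_identity)
  per_site <- function(s) {
    q <- qual[qual$site == s, ]
    m <- merged[merged$site == s, ]
    n_input <- nrow(q)
    n_primer <- sum(!q$primer_ok)
    n_quality <- sum(q$primer_ok & !q$quality_ok)
    n_merge <- sum(!m$merge_ok)
    tibble::tibble(site = s, n_input = n_input, n_primer_fail = n_primer,
                   n_quality_fail = n_quality, n_merge_fail = n_merge,
                   n_merged = n_input - n_primer - n_quality - n_merge)
  }
  stats <- dplyr::bind_rows(lapply(sort(sites), per_site))
  ok <- dplyr::filter(merged, .data$merge_ok)
  out <- list(
    merged = dplyr::select(ok, "id", "site", "seq", "overlap_len"),
    stats = stats
  )
  class(out) <- c("amf_processed_reads", class(out))
  for (i in seq_len(nrow(stats)))
    message(sprintf(
      "[reads] site %s: %d input, %d primer-fail, %d quality-fail, %d merge-fail, %d merged",
      stats$site[i], stats$n_input[i], stats$n_primer_fail[i],
      stats$n_quality_fail[i], stats$n_merge_fail[i], stats$n_merged[i]))
  out
}

empty_stats <- function(sites) {
  tibble::tibble(site = sort(unique(as.character(sites))),
                 n_input = 0L, n_primer_fail = 0L, n_quality_fail = 0L,
                 n_merge_fail = 0L, n_merged = 0L)
}

#' @describeIn process_reads Read one site's FASTQ pair from disk and process it.
#' @param fastq_fwd,fastq_rev FASTQ paths for the site.
#' @param site Site label.
#' @export
process_site <- function(fastq_fwd, fastq_rev, site = "S1",
                         config = pipeline_config()) {
  pairs <- read_fastq_pairs(fastq_fwd, fastq_rev, site = site)
  process_reads(pairs, config)
}

#' Drop reads flagged by an external chimera screen
#'
#' Chimera detection itself is delegated to external tools; this hook removes
#' merged reads whose ids are listed (one per line) in `id_file`.
#'
#' @param merged Merged-read tibble.
#' @param id_file Path to a plain-text file of read ids to drop.
#' @export
drop_chimeras <- function(merged, id_file) {
  ids <- readLines(id_file, warn = FALSE)
  dplyr::filter(merged, !(.data$id %in% ids))
}

#' @export
print.amf_processed_reads <- function(x, ...) {
  cat("Processed amplicon reads:", nrow(x$merged), "merged reads across",
      nrow(x$stats), "site(s)\n")
  print(x$stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.amf_processed_reads <- function(x, ...) x$merged

#' @importFrom generics glance
#' @export
glance.amf_processed_reads <- function(x, ...) x$stats
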