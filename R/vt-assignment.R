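#' Local alignment of reads against one reference sequence
#'
#' Smith-Waterman local alignment with affine gaps (match +1, mismatch -1,
#' gap of length L costs L+1).  Identity is matching bases over alignment
#' columns (gap columns included in the denominator); coverage is the number
#' of read positions inside the local alignment over the read length.  Reads
#' with no positive-scoring local alignment get identity 0 and coverage 0.
#'
#' @param reads Character vector of read sequences.
#' @param ref A single reference sequence.
#' @return A tibble with columns `score`, `identity`, `coverage`.
#' @export
align_reads <- function(reads, ref) {
  stopifnot(length(ref) == 1, nzchar(ref))
  m <- cpp_sw_batch(reads, ref, 1, -1, 2, 1)
  tibble::as_tibble(m)
}

#' @describeIn align_reads Single-read convenience wrapper returning a named
#'   numeric vector `c(identity, coverage)`.
#' @param read A single read sequence.
#' @export
align_to_reference <- function(read, ref) {
  stopifnot(length(read) == 1, nzchar(read))
  a <- align_reads(read, ref)
  c(identity = a$identity[1], coverage = a$coverage[1])
}

#' Assign merged reads to virtual taxa by best hit
#'
#' Closed-reference assignment: each read is aligned against VT type
#' sequences and assigned to the highest-identity reference among those
#' passing both the identity and the coverage threshold (ties broken by
#' higher coverage, then lexicographically smallest `vt_id`).  Reads with no
#' passing hit stay unassigned (`vt_id` NA).
#'
#' Both the read and its reverse complement are considered.  By default a
#' shared 6-mer prescreen ranks the references and only the best
#' `prescreen_top` candidates are aligned (the prescreen also picks the
#' strand); set `prescreen_top = Inf` to align every read against every
#' reference on both strands.
#'
#' @param merged Merged-read tibble (columns `id`, `site`, `seq`).
#' @param refs Reference tibble (see [read_vt_reference()]).
#' @param id_threshold Minimum identity (default 0.97).
#' @param cov_threshold Minimum coverage of the read (default 0.95).
#' @param prescreen_top Number of prescreen candidates per read (default 2).
#' @param both_strands Consider the reverse complement? Default TRUE.
#' @return A tibble `read_id`, `site`, `vt_id`, `identity`, `coverage`.
#' @export
assign_vt <- function(merged, refs, id_threshold = 0.97, cov_threshold = 0.95,
                      prescreen_top = 2, both_strands = TRUE) {
  assert_cols(merged, c("id", "site", "seq"))
  assert_cols(refs, c("vt_id", "type_seq"))
  if (nrow(refs) == 0) abort("Empty reference set")
  nr <- nrow(merged)
  if (nr == 0)
    return(tibble::tibble(read_id = character(), site = character(),
                          vt_id = character(), identity = double(),
                          coverage = double()))
  # deterministic reference order regardless of input ordering
  refs <- dplyr::arrange(refs, .data$vt_id)
  reads <- merged$seq
  exhaustive <- is.infinite(prescreen_top) || prescreen_top >= nrow(refs)

  if (exhaustive) {
    strands <- if (both_strands) c("fwd", "rc") else "fwd"
    cand <- expand.grid(read_idx = seq_len(nr), ref_idx = seq_len(nrow(refs)),
                        strand = strands, stringsAsFactors = FALSE)
  } else {
    kf <- cpp_kmer_screen(reads, refs$type_seq, 6L)
    kr <- if (both_strands) cpp_kmer_screen(revcomp(reads), refs$type_seq, 6L)
          else matrix(-1L, nr, nrow(refs))
    best <- pmax(kf, kr)
    k <- as.integer(prescreen_top)
    # top-k candidate references per read; ties resolved towards the
    # lexicographically smallest vt_id (refs are sorted by vt_id)
    work <- best
    read_idx <- rep(seq_len(nr), k)
    ref_idx <- integer(nr * k)
    for (j in seq_len(k)) {
      top <- max.col(work, ties.method = "first")
      ref_idx[(j - 1) * nr + seq_len(nr)] <- top
      work[cbind(seq_len(nr), top)] <- -1L
    }
    cell <- cbind(read_idx, ref_idx)
    strand <- ifelse(kr[cell] > kf[cell], "rc", "fwd")
    cand <- data.frame(read_idx = read_idx, ref_idx = ref_idx,
                       strand = strand, stringsAsFactors = FALSE)
    # when forward and reverse prescreen scores tie (strand defaulted to
    # "fwd"), align the reverse strand as well
    if (both_strands) {
      tied <- cand[kf[cell] == kr[cell], , drop = FALSE]
      if (nrow(tied) > 0) {
        tied$strand <- "rc"
        cand <- rbind(cand, tied)
      }
    }
  }

  rc_reads <- NULL
  hits <- vector("list", 0)
  for (ri in unique(cand$ref_idx)) {
    for (st in unique(cand$strand[cand$ref_idx == ri])) {
      idx <- cand$read_idx[cand$ref_idx == ri & cand$strand == st]
      if (st != "fwd" && is.null(rc_reads)) rc_reads <- revcomp(reads)
      qs <- if (st == "fwd") reads[idx] else rc_reads[idx]
      a <- cpp_sw_batch(qs, refs$type_seq[ri], 1, -1, 2, 1)
      hits[[length(hits) + 1]] <- tibble::tibble(
        read_idx = idx, vt_id = refs$vt_id[ri],
        identity = a[, "identity"], coverage = a[, "coverage"])
    }
  }
  all_hits <- dplyr::bind_rows(hits) |>
    dplyr::filter(.data$identity >= id_threshold,
                  .data$coverage >= cov_threshold) |>
    dplyr::group_by(.data$read_idx) |>
    dplyr::arrange(dplyr::desc(.data$identity), dplyr::desc(.data$coverage),
                   .data$vt_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  out <- tibble::tibble(read_id = merged$id, site = merged$site,
                        vt_id = NA_character_, identity = NA_real_,
                        coverage = NA_real_)
  out$vt_id[all_hits$read_idx] <- all_hits$vt_id
  out$identity[all_hits$read_idx] <- all_hits$identity
  out$coverage[all_hits$read_idx] <- all_hits$coverage
  out
}

#' Build the site x VT community table from assignments
#'
#' @param assignments Assignment tibble from [assign_vt()]; unassigned reads
#'   (NA `vt_id`) are excluded.
#' @return A long community tibble `site`, `vt_id`, `reads`, sorted.
#' @export
build_community_table <- function(assignments) {
  assert_cols(assignments, c("site", "vt_id"))
  assignments |>
    dplyr::filter(!is.na(.data$vt_id)) |>
    dplyr::count(.data$site, .data$vt_id, name = "reads") |>
    dplyr::arrange(.data$site, .data$vt_id)
}

#' Remove dataset-level singleton VT
#'
#' Drops every VT whose total read count across all sites equals one; all
#' other counts are unchanged.  Idempotent.
#'
#' @param comm Community tibble.
#' @export
remove_singletons <- function(comm) {
  assert_cols(comm, c("site", "vt_id", "reads"))
  totals <- comm |>
    dplyr::group_by(.data$vt_id) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
  keep <- totals$vt_id[totals$total > 1]
  dplyr::filter(comm, .data$vt_id %in% keep)
}

#' Fraction of retained VT that are cultured taxa
#'
#' Cultured taxa are VT containing sequences of known morphospecies identity
#' (flagged in the reference catalogue).
#'
#' @param comm Community tibble (after singleton removal).
#' @param refs Reference tibble with a `cultured` flag.
#' @return A fraction in `[0, 1]`.
#' @export
cultured_fraction <- function(comm, refs) {
  assert_cols(comm, "vt_id")
  assert_cols(refs, c("vt_id", "cultured"))
  vts <- unique(comm$vt_id)
  if (length(vts) == 0) return(NaN)
  unknown <- setdiff(vts, refs$vt_id)
  if (length(unknown) > 0)
    abort(paste("VT absent from reference catalogue:",
                paste(unknown, collapse = ", ")))
  mean(refs$cultured[match(vts, refs$vt_id)])
}
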