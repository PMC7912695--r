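#' Per-VT aridity index from reference biome records
#'
#' The aridity index of a VT is the fraction of its database records labelled
#' with a desert biome (by default exactly "deserts and xeric shrublands").
#' A VT with zero records has an undefined index (`NA`, flagged) and is
#' excluded from downstream community means.
#'
#' @param refs Reference tibble with list-column `biome_records`.
#' @param desert_labels Character set of biome labels counted as desert.
#' @return A tibble `vt_id`, `aridity`, `n_records`.
#' @export
aridity_index <- function(refs,
                          desert_labels = "deserts and xeric shrublands") {
  assert_cols(refs, c("vt_id", "biome_records"))
  stopifnot(length(desert_labels) >= 1)
  tibble::tibble(
    vt_id = refs$vt_id,
    n_records = vapply(refs$biome_records, length, integer(1)),
    aridity = vapply(refs$biome_records, function(recs) {
      if (length(recs) == 0) return(NA_real_)
      mean(recs %in% desert_labels)
    }, double(1))
  )[, c("vt_id", "aridity", "n_records")]
}

#' Community-level aridity index
#'
#' Unweighted mean of the (defined) per-VT aridity indices of the member VT.
#'
#' @param taxa Character vector of member VT ids (non-empty).
#' @param indices Aridity-index tibble from [aridity_index()].
#' @return A named list `value`, `n_vt` (number of members with a defined
#'   index).
#' @export
community_aridity <- function(taxa, indices) {
  assert_cols(indices, c("vt_id", "aridity"))
  taxa <- unique(taxa)
  if (length(taxa) == 0) abort("Empty sample")
  unknown <- setdiff(taxa, indices$vt_id)
  if (length(unknown) > 0)
    abort(paste("VT without aridity index:", paste(unknown, collapse = ", ")))
  vals <- indices$aridity[match(taxa, indices$vt_id)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    abort("No member VT has a defined aridity index")
  list(value = mean(vals), n_vt = length(vals))
}

#' Randomization test of community aridity against a taxon pool
#'
#' Null communities are uniform random subsets of the pool, of the same size
#' as the observed sample, drawn without replacement; each null value is the
#' mean aridity of the drawn VT.  `Z = (observed - null mean) / null SD`
#' (SD over the `n_reps` null values, denominator `n_reps - 1`; the observed
#' value is not included in the null distribution).  The call is two-sided
#' at `|Z| > z_crit`.  Member VT absent from the pool still contribute to
#' the observed mean; the pool only shapes the null.
#'
#' @param taxa Observed sample (character vector of VT ids).
#' @param indices Aridity-index tibble.
#' @param pool Character vector of pool VT ids (at least as many as the
#'   sample has members).
#' @param n_reps Number of null draws (default 999).
#' @param seed Optional RNG seed.
#' @param z_crit Two-sided significance threshold (default 1.96).
#' @param sample_name,pool_scale Labels carried into the result.
#' @return A one-row `amf_null_tests` tibble (see [ses_mpd()]).
#' @export
aridity_null_test <- function(taxa, indices, pool, n_reps = 999L, seed = NULL,
                              z_crit = 1.96, sample_name = "sample",
                              pool_scale = "global") {
  taxa <- unique(taxa); pool <- unique(pool)
  n <- length(taxa)
  if (length(pool) < n) abort("Pool smaller than the observed sample")
  observed <- community_aridity(taxa, indices)$value
  pool_vals <- indices$aridity[match(pool, indices$vt_id)]
  if (anyNA(pool_vals))
    abort("Pool contains VT without a defined aridity index")
  nulls <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) mean(sample(pool_vals, n)), double(1))
  })
  null_test_row(sample_name, "aridity", observed, nulls, n_reps, pool_scale,
                z_crit)
}

#' Multi-scale aridity randomization tests for every site
#'
#' Runs [aridity_null_test()] for each site against each pool scale
#' (typically global, continent and biogeographic realm), mirroring a
#' scales x sites Z-value table.
#'
#' @param comm Community tibble.
#' @param indices Aridity-index tibble.
#' @param pools Pool tibble (`scale`, `vt_id`, optional `site`; NA site =
#'   pool shared by every site).
#' @inheritParams aridity_null_test
#' @return An `amf_null_tests` tibble, one row per site x scale.
#' @export
multi_scale_test <- function(comm, indices, pools, n_reps = 999L, seed = NULL,
                             z_crit = 1.96) {
  sets <- community_sets(comm)
  rows <- purrr::imap(pool_list(pools, names(sets)), function(site_pools, sc) {
    purrr::imap(site_pools, function(pl, s) {
      if (!s %in% names(sets)) return(NULL)
      aridity_null_test(sets[[s]], indices, pl, n_reps = n_reps,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, paste("aridity", sc, s)),
                        z_crit = z_crit, sample_name = s, pool_scale = sc)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("amf_null_tests", class(out))
  out
}

#' Count sites with significant over-representation at one scale
#'
#' Counts Z values strictly greater than `z_crit` (one-sided count of
#' over-represented sites; the two-sided flag lives in the `significant`
#' column of the results).
#'
#' @param results An `amf_null_tests` tibble (or any tibble with `pool_scale`
#'   and `z` columns).
#' @param scale Pool scale to count at.
#' @param z_crit Threshold (default 1.96); the boundary value itself is not
#'   counted.
#' @return An integer count.
#' @export
count_significant <- function(results, scale, z_crit = 1.96) {
  assert_cols(results, c("pool_scale", "z"))
  if (!scale %in% results$pool_scale)
    abort(sprintf("No results at scale '%s'", scale))
  z <- results$z[results$pool_scale == scale]
  sum(!is.na(z) & z > z_crit)
}

#' Cross-tabulate null-test results as a scales x sites Z table
#'
#' @param results An `amf_null_tests` tibble.
#' @param z_crit Threshold used to mark significant cells with an asterisk.
#' @return A tibble, one row per scale, one column per site; cells are
#'   formatted Z values with `*` marking `|Z| > z_crit`.
#' @export
z_table <- function(results, z_crit = 1.96) {
  assert_cols(results, c("sample", "pool_scale", "z"))
  results |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$z), "NA",
      sprintf("%.3f%s", .data$z, ifelse(abs(.data$z) > z_crit, "*", "")))) |>
    dplyr::select("pool_scale", "sample", "cell") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "cell")
}

#' @export
glance.amf_null_tests <- function(x, ...) {
  x |>
    dplyr::group_by(.data$statistic, .data$pool_scale) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_significant = sum(.data$significant, na.rm = TRUE),
      n_over = sum(!is.na(.data$z) & .data$z > 1.96),
      n_under = sum(!is.na(.data$z) & .data$z < -1.96),
      .groups = "drop")
}

#' @export
tidy.amf_null_tests <- function(x, ...) tibble::as_tibble(x)
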