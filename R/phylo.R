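#' Jukes-Cantor distance matrix from aligned sequences
#'
#' Pairwise JC69 distances `-(3/4) log(1 - (4/3) p)` over ungapped column
#' pairs (pairwise deletion of gap/N columns).  Saturated pairs
#' (`p >= 0.75`) are capped at `cap` rather than returned infinite.
#'
#' @param seqs Named character vector of equal-length aligned DNA sequences.
#' @param cap Finite stand-in for saturated distances (default 5).
#' @return A square symmetric matrix with `names(seqs)` as dimnames.
#' @export
jc_distance_matrix <- function(seqs, cap = 5) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1)
    abort("Aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  # raw p-distances first: NaN there means no comparable (ungapped) columns,
  # while p >= 0.75 is JC saturation and is capped, not an error
  p <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                               pairwise.deletion = TRUE))
  if (any(is.nan(p)))
    abort("Sequence pair with zero comparable columns")
  m <- -0.75 * log(1 - 4 / 3 * pmin(p, 0.749999))
  m[p >= 0.75 | m > cap] <- cap
  diag(m) <- 0
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining.  Negative branch lengths, which NJ can
#' produce on non-additive matrices, are clamped to zero with the deficit
#' transferred to the adjacent (sister) edge so root-to-tip distances change
#' as little as possible.
#'
#' @param d Square symmetric distance matrix (or `dist`) over at least 2 taxa.
#' @return An unrooted `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) abort("Neighbor joining needs at least 2 taxa")
  if (nrow(m) == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = c(m[1, 2] / 2, m[1, 2] / 2),
               tip.label = rownames(m), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(m))
  clamp_negative_branches(tr)
}

# Clamp negative branch lengths to zero, adding each deficit to the sister
# edge at the same parent node (standard post-processing; only non-additive
# inputs are affected).
clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters) > 0)
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
  }
  tr
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of leaves.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A square symmetric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  m <- stats::cophenetic(tree)
  m[sort(rownames(m)), sort(colnames(m))]
}

#' Mean pairwise phylogenetic distance within a sample
#'
#' Unweighted (presence-absence) mean of the patristic distance over all
#' unordered pairs of taxa in the sample.  Samples with fewer than two taxa
#' have no pairs: `NA` is returned, not zero.
#'
#' @param taxa Character vector of taxon labels present in the sample.
#' @param d Patristic distance matrix.
#' @return The mean pairwise distance, or `NA_real_`.
#' @export
mpd_obs <- function(taxa, d) {
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, rownames(d))
  if (length(unknown) > 0)
    abort(paste("Taxa absent from distance matrix:", paste(unknown, collapse = ", ")))
  if (length(taxa) < 2) return(NA_real_)
  sub <- d[taxa, taxa]
  mean(sub[lower.tri(sub)])
}

#' Mean phylogenetic distance between two samples
#'
#' Presence-absence mean of `d(i, j)` over all cross pairs with `i` in one
#' sample and `j` in the other; symmetric in its arguments.
#'
#' @param a,b Character vectors of taxon labels (both non-empty).
#' @param d Patristic distance matrix.
#' @export
comdist_pair <- function(a, b, d) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) abort("Empty sample in comdist")
  unknown <- setdiff(c(a, b), rownames(d))
  if (length(unknown) > 0)
    abort(paste("Taxa absent from distance matrix:", paste(unknown, collapse = ", ")))
  mean(d[a, b, drop = FALSE])
}

#' Between-sample phylogenetic distance matrix of a community table
#'
#' @param comm Community tibble.
#' @param d Patristic distance matrix covering all VT in `comm`.
#' @return A `dist` object of pairwise [comdist_pair()] values between sites.
#' @export
comdist_matrix <- function(comm, d) {
  sets <- community_sets(comm)
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i < j)
        m[i, j] <- m[j, i] <- comdist_pair(sets[[i]], sets[[j]], d)
  stats::as.dist(m)
}

#' Standardized effect size of mean pairwise distance against a taxon pool
#'
#' Null communities are uniform random subsets of `pool`, of the same size
#' as the observed sample, drawn without replacement.  The Z value is
#' `(observed - null mean) / null SD` (null SD with denominator
#' `n_reps - 1`); negative Z indicates phylogenetic clustering.  A null SD
#' of zero (e.g. sample == pool) flags the result degenerate with no Z.
#'
#' @param taxa Observed sample (character vector of taxon labels).
#' @param d Patristic distance matrix.
#' @param pool Taxon pool to draw null samples from (must be at least as
#'   large as the sample).
#' @param n_reps Number of null draws (default 999).
#' @param seed Optional RNG seed.
#' @param z_crit Two-sided significance threshold (default 1.96).
#' @param sample_name,pool_scale Labels carried into the result.
#' @return A one-row `amf_null_test` tibble: `sample`, `statistic`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `n_reps`, `pool_scale`,
#'   `significant`, `degenerate`.
#' @export
ses_mpd <- function(taxa, d, pool, n_reps = 999L, seed = NULL, z_crit = 1.96,
                    sample_name = "sample", pool_scale = "global") {
  taxa <- unique(taxa); pool <- unique(pool)
  if (length(pool) < length(taxa))
    abort("Pool smaller than the observed sample")
  observed <- mpd_obs(taxa, d)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      mpd_obs(sample(pool, length(taxa)), d)
    }, double(1))
  })
  null_test_row(sample_name, "mpd", observed, nulls, n_reps, pool_scale, z_crit)
}

# Shared assembly of a NullTestResult row from observed value + null draws.
null_test_row <- function(sample_name, statistic, observed, nulls, n_reps,
                          pool_scale, z_crit) {
  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd
  out <- tibble::tibble(
    sample = sample_name, statistic = statistic, observed = observed,
    null_mean = null_mean, null_sd = null_sd, z = z,
    n_reps = as.integer(n_reps), pool_scale = pool_scale,
    significant = !degenerate && is.finite(z) && abs(z) > z_crit,
    degenerate = degenerate)
  class(out) <- c("amf_null_tests", class(out))
  out
}

#' Per-site ses.mpd against one or more pools
#'
#' @param comm Community tibble.
#' @param d Patristic distance matrix.
#' @param pools Pool tibble with columns `scale`, `vt_id` and optionally
#'   `site` (NA or absent = pool applies to every site).
#' @inheritParams ses_mpd
#' @return An `amf_null_tests` tibble, one row per site x scale.
#' @export
ses_mpd_sites <- function(comm, d, pools, n_reps = 999L, seed = NULL,
                          z_crit = 1.96) {
  sets <- community_sets(comm)
  rows <- purrr::imap(pool_list(pools, names(sets)), function(site_pools, sc) {
    purrr::imap(site_pools, function(pl, s) {
      if (!s %in% names(sets)) return(NULL)
      ses_mpd(sets[[s]], d, pl, n_reps = n_reps,
              seed = if (is.null(seed)) NULL
                     else derive_seed(seed, paste("sesmpd", sc, s)),
              z_crit = z_crit, sample_name = s, pool_scale = sc)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("amf_null_tests", class(out))
  out
}

# Normalize a pools tibble into list[scale][site] -> character vector.
pool_list <- function(pools, sites) {
  assert_cols(pools, c("scale", "vt_id"), "pools")
  if (!"site" %in% names(pools)) pools$site <- NA_character_
  out <- list()
  for (sc in unique(pools$scale)) {
    p <- pools[pools$scale == sc, ]
    shared <- unique(p$vt_id[is.na(p$site)])
    out[[sc]] <- stats::setNames(lapply(sites, function(s) {
      unique(c(shared, p$vt_id[!is.na(p$site) & p$site == s]))
    }), sites)
  }
  out
}
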