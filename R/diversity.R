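#' Analytic rarefaction curve
#'
#' Expected VT richness in a uniform random subsample of `m` reads, computed
#' hypergeometrically (without replacement):
#' `E[S_m] = sum_i 1 - choose(n - n_i, m) / choose(n, m)`.
#'
#' @param comm Community tibble (`site`, `vt_id`, `reads`).
#' @param depths Integer subsample sizes; defaults to 20 depths evenly spaced
#'   from 1 to each site's total read count.  A depth larger than a site's
#'   total count is an error.
#' @return A tibble `site`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(comm, depths = NULL) {
  assert_cols(comm, c("site", "vt_id", "reads"))
  m <- community_matrix(comm)
  out <- lapply(rownames(m), function(s) {
    counts <- m[s, m[s, ] > 0]
    n <- sum(counts)
    d <- depths %||% unique(pmax(1L, round(seq(1, n, length.out = 20))))
    if (any(d > n))
      abort(sprintf("Rarefaction depth %d exceeds total count %d at site %s",
                    max(d), n, s))
    # rarefy's advisory about minimum counts > 1 is expected for floored
    # synthetic tables
    er <- as.numeric(suppressWarnings(vegan::rarefy(counts, sample = d)))
    tibble::tibble(site = s, depth = as.integer(d), expected_richness = er)
  })
  dplyr::bind_rows(out)
}

#' Observed Hill diversity of one abundance vector
#'
#' Hill numbers (effective numbers of species): order 0 is richness, order 1
#' is the exponential of Shannon entropy, order 2 is inverse Simpson
#' concentration.
#'
#' @param counts Positive integer abundances.
#' @param q Diversity order, one of 0, 1, 2.
#' @return The observed Hill number.
#' @export
hill_observed <- function(counts, q) {
  stopifnot(q %in% 0:2, all(counts >= 1))
  p <- counts / sum(counts)
  switch(as.character(q),
    "0" = length(p),
    "1" = exp(-sum(p * log(p))),
    "2" = 1 / sum(p^2))
}

#' Asymptotic Hill diversity of one abundance vector
#'
#' Order 0 uses Chao1: `S_obs + f1^2 / (2 f2)` (bias-corrected
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when there are no doubletons), with
#' `f1`/`f2` the singleton/doubleton counts.  Orders 1 and 2 use the
#' Chao-Jost asymptotic estimators of the Shannon and Simpson effective
#' numbers (the estimators behind sample-completeness extrapolation).
#'
#' @inheritParams hill_observed
#' @return The asymptotic Hill number estimate (never below the observed
#'   value for q = 0).
#' @export
hill_asymptotic <- function(counts, q) {
  stopifnot(q %in% 0:2, all(counts >= 1))
  n <- sum(counts)
  if (n < 2) abort("Asymptotic estimation requires at least 2 reads")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (q == 0) {
    s_obs <- length(counts)
    return(if (f2 > 0) s_obs + f1^2 / (2 * f2)
           else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  if (q == 1) {
    # Chao-Jost entropy estimator, exponentiated to an effective number
    x <- counts[counts >= 1 & counts <= n - 1]
    h_known <- sum(vapply(x, function(xi) {
      (xi / n) * sum(1 / seq(xi, n - 1))
    }, double(1)))
    a <- if (f1 == 0) 1
         else if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
         else 2 / ((n - 1) * (f1 - 1) + 2)
    h_rare <- 0
    if (f1 > 0 && a < 1) {
      r <- seq_len(n - 1)
      h_rare <- (f1 / n) * (1 - a)^(1 - n) *
        (-log(a) - sum((1 - a)^r / r))
    }
    return(exp(h_known + h_rare))
  }
  # q = 2: minimum-variance unbiased estimator of sum(p_i^2)
  s2 <- sum(counts * (counts - 1)) / (n * (n - 1))
  if (s2 <= 0) return(hill_observed(counts, 2))
  1 / s2
}

#' Multinomial bootstrap uncertainty for a Hill diversity estimate
#'
#' Resamples the abundance vector from its multinomial estimate `B` times,
#' re-estimates the asymptotic Hill number, and reports the bootstrap
#' standard error with 95% normal-approximation confidence limits.  For
#' q = 0 the lower limit is floored at the observed richness.
#'
#' @inheritParams hill_observed
#' @param B Number of bootstrap resamples (minimum 50, default 200).
#' @param seed Optional RNG seed for reproducibility.
#' @return A named list `se`, `lcl`, `ucl`.
#' @export
bootstrap_ci <- function(counts, q, B = 200L, seed = NULL) {
  stopifnot(B >= 50)
  n <- sum(counts)
  est <- hill_asymptotic(counts, q)
  boots <- with_seed(seed, {
    draws <- stats::rmultinom(B, n, counts / n)
    apply(draws, 2, function(cv) {
      cv <- cv[cv > 0]
      if (length(cv) == 0 || sum(cv) < 2) return(NA_real_)
      hill_asymptotic(cv, q)
    })
  })
  se <- stats::sd(boots, na.rm = TRUE)
  lcl <- est - 1.96 * se
  ucl <- est + 1.96 * se
  if (q == 0) lcl <- max(lcl, hill_observed(counts, 0))
  list(se = se, lcl = lcl, ucl = ucl)
}

#' Per-site diversity table (observed and asymptotic Hill numbers)
#'
#' @param comm Community tibble.
#' @param q Diversity orders to report (default 0, 1, 2).
#' @param B Bootstrap resamples for the uncertainty (default 200).
#' @param seed RNG seed (per-site seeds are derived deterministically).
#' @return A tibble `site`, `q`, `observed`, `estimated`, `se`, `lcl`, `ucl`.
#' @export
site_diversity <- function(comm, q = 0:2, B = 200L, seed = NULL) {
  m <- community_matrix(comm)
  rows <- list()
  for (s in rownames(m)) {
    counts <- m[s, m[s, ] > 0]
    for (qi in q) {
      obs <- hill_observed(counts, qi)
      if (sum(counts) < 2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          site = s, q = qi, observed = obs, estimated = obs,
          se = NA_real_, lcl = NA_real_, ucl = NA_real_)
        next
      }
      est <- hill_asymptotic(counts, qi)
      ci <- bootstrap_ci(counts, qi, B = B,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, paste0(s, "_q", qi)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        site = s, q = qi, observed = obs, estimated = est,
        se = ci$se, lcl = ci$lcl, ucl = ci$ucl)
    }
  }
  dplyr::bind_rows(rows)
}
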