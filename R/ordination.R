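#' Jaccard dissimilarity matrix of a community table
#'
#' `d(a, b) = 1 - |A intersect B| / |A union B|` on presence-absence sets;
#' two empty samples are at distance 0 by convention.
#'
#' @param comm Community tibble (at least 2 sites).
#' @return A `dist` object with site labels.
#' @export
jaccard_matrix <- function(comm) {
  m <- community_matrix(comm)
  if (nrow(m) < 2) abort("Jaccard matrix needs at least 2 samples")
  pa <- (m > 0) * 1
  d <- as.matrix(vegan::vegdist(pa, method = "jaccard", binary = TRUE))
  empty <- rowSums(pa) == 0
  d[empty, empty] <- 0
  stats::as.dist(d)
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical PCoA: Gower double-centring followed by eigendecomposition;
#' scores on each axis are scaled by the square root of its eigenvalue.
#' Negative eigenvalues are reported, not corrected.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param k Number of axes (default 2; must be < number of samples).
#' @return An `amf_ordination` object: list with `scores` (samples x axes),
#'   `method = "pcoa"`, `eigenvalues`.
#' @export
pcoa_ord <- function(d, k = 2L) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of samples")
  if (all(m == 0)) {
    scores <- matrix(0, n, k, dimnames = list(rownames(m), paste0("axis", 1:k)))
    out <- list(scores = scores, method = "pcoa", eigenvalues = rep(0, n - 1),
                stress = NA_real_)
    class(out) <- "amf_ordination"
    return(out)
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  scores <- fit$points
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  out <- list(scores = scores, method = "pcoa", eigenvalues = fit$eig,
              stress = NA_real_)
  class(out) <- "amf_ordination"
  out
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1 with monotone regression of configuration
#' distances on the input dissimilarities, taking the best of `n_starts`
#' random starts (plus a metric start).  Stress is reported as a fraction
#' in `[0, 1]`.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param k Number of axes (default 2).
#' @param n_starts Number of random starts (default 20).
#' @param seed Optional RNG seed; a fixed seed makes the configuration
#'   reproducible.
#' @return An `amf_ordination` object with `stress` and a `converged` flag.
#' @export
nmds_ord <- function(d, k = 2L, n_starts = 20L, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(k >= 1, n_starts >= 1)
  if (n == 2) {
    half <- m[1, 2] / 2
    scores <- matrix(0, 2, k, dimnames = list(rownames(m), paste0("axis", 1:k)))
    scores[, 1] <- c(-half, half)
    out <- list(scores = scores, method = "nmds", eigenvalues = NULL,
                stress = 0, converged = TRUE)
    class(out) <- "amf_ordination"
    return(out)
  }
  fit <- with_seed(seed, {
    suppressWarnings(suppressMessages(
      vegan::metaMDS(stats::as.dist(m), k = k, try = n_starts,
                     trymax = n_starts, trace = 0, autotransform = FALSE,
                     wascores = FALSE)))
  })
  scores <- vegan::scores(fit, display = "sites")
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  if (!fit$converged)
    warning("NMDS did not converge; returning the best configuration found")
  out <- list(scores = scores, method = "nmds", eigenvalues = NULL,
              stress = fit$stress, converged = isTRUE(fit$converged))
  class(out) <- "amf_ordination"
  out
}

#' Permutation-tested environmental vector fitting
#'
#' Least-squares projection of each (numeric) environmental variable onto
#' the ordination axes; `r2` is the fraction of the variable's variance
#' explained and the p-value uses the add-one permutation convention
#' `(1 + #permuted r2 >= observed) / (n_perm + 1)`.  Constant variables get
#' `r2 = 0`, `p = 1`.
#'
#' @param ord An `amf_ordination` object.
#' @param env Data frame of numeric variables; rows must align with the
#'   ordination samples (matched by rownames when present, by position
#'   otherwise).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return A tibble `variable`, one direction-cosine column per axis
#'   (`axis1`, ...), `r2`, `p`.
#' @export
fit_environment <- function(ord, env, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(ord, "amf_ordination"))
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[, num, drop = FALSE]
  if (nrow(env) != nrow(ord$scores))
    abort("env rows must align with ordination samples")
  if (!is.null(rownames(env)) &&
      all(rownames(ord$scores) %in% rownames(env)))
    env <- env[rownames(ord$scores), , drop = FALSE]
  constant <- vapply(env, function(v) stats::sd(v) == 0, logical(1))
  fitted_env <- env[, !constant, drop = FALSE]
  rows <- list()
  if (ncol(fitted_env) > 0) {
    fit <- with_seed(seed, {
      vegan::envfit(ord$scores, fitted_env, permutations = n_perm)
    })
    arr <- fit$vectors$arrows
    for (vi in seq_len(nrow(arr))) {
      row <- tibble::tibble(variable = rownames(arr)[vi])
      for (j in seq_len(ncol(arr))) row[[paste0("axis", j)]] <- arr[vi, j]
      row$r2 <- unname(fit$vectors$r[vi])
      row$p <- unname(fit$vectors$pvals[vi])
      rows[[length(rows) + 1]] <- row
    }
  }
  for (v in names(env)[constant]) {
    row <- tibble::tibble(variable = v)
    for (j in seq_len(ncol(ord$scores))) row[[paste0("axis", j)]] <- NA_real_
    row$r2 <- 0
    row$p <- 1
    rows[[length(rows) + 1]] <- row
  }
  dplyr::bind_rows(rows)
}

#' @export
print.amf_ordination <- function(x, ...) {
  cat(toupper(x$method), "ordination:", nrow(x$scores), "samples,",
      ncol(x$scores), "axes")
  if (x$method == "nmds") cat(sprintf(", stress %.4f", x$stress))
  cat("\n")
  invisible(x)
}

#' @export
tidy.amf_ordination <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample")
}

#' @export
glance.amf_ordination <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = nrow(x$scores),
    n_axes = ncol(x$scores),
    stress = x$stress,
    first_eigenvalue = if (is.null(x$eigenvalues)) NA_real_ else x$eigenvalues[1]
  )
}
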