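BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

q_string <- function(q, n) strrep(intToUtf8(q + 33L), n)

# read-pair tibble builder; default qualities Q40 everywhere
make_pairs <- function(fwd, rev, fq = NULL, rq = NULL, site = "A",
                       id = sprintf("r%03d", seq_along(fwd))) {
  tibble::tibble(
    id = id, site = site,
    fwd_seq = fwd,
    fwd_qual = fq %||% q_string(40L, nchar(fwd)),
    rev_seq = rev,
    rev_qual = rq %||% q_string(40L, nchar(rev)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substitute bases at 1-based positions, guaranteeing a mismatch
mutate_at_pos <- function(seq, positions) {
  for (p in positions) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(BASES, old)[1]
  }
  seq
}

# all concrete expansions of an IUPAC primer (for primers <= 12 bp)
iupac_expansions <- function(primer) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  sets <- tab[strsplit(primer, "")[[1]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# independent all-offsets merging oracle mirroring the documented rules
brute_merge <- function(fwd, fq, rev, rq, min_o = 10, max_o = 300,
                        min_ident = 0.75) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  rcq <- paste(rev(strsplit(rq, "")[[1]]), collapse = "")
  lf <- nchar(fwd); lr <- nchar(rc)
  best <- NULL
  for (o in seq(min_o, min(lf, lr, max_o))) {
    a <- strsplit(substring(fwd, lf - o + 1), "")[[1]]
    b <- strsplit(substring(rc, 1, o), "")[[1]]
    matches <- sum(a == b & a %in% BASES)
    ident <- matches / o
    if (ident >= min_ident && (is.null(best) || ident >= best$ident))
      best <- list(o = o, ident = ident)
  }
  if (is.null(best)) return(list(ok = FALSE))
  o <- best$o
  a <- strsplit(substring(fwd, lf - o + 1), "")[[1]]
  b <- strsplit(substring(rc, 1, o), "")[[1]]
  qa <- utf8ToInt(substring(fq, lf - o + 1)) - 33L
  qb <- utf8ToInt(substring(rcq, 1, o)) - 33L
  cons <- ifelse(qb > qa, b, a)
  list(ok = TRUE, o = o,
       seq = paste0(substring(fwd, 1, lf - o), paste(cons, collapse = ""),
                    substring(rc, o + 1)))
}

# brute-force patristic distances by walking explicit root paths
brute_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(tip) {
    edges <- numeric(0); node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  })
  m <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    shared <- intersect(paths[[i]], paths[[j]])
    d <- sum(tree$edge.length[setdiff(c(paths[[i]], paths[[j]]), shared)])
    m[i, j] <- m[j, i] <- d
  }
  m
}

# small simulation config used across tests
small_cfg <- function(...) {
  args <- list(
    n_vt = 12L, site_names = c("A", "B"),
    site_continents = c("Asia", "Asia"),
    site_realms = c("Palearctic", "Palearctic"),
    site_richness = c(4L, 6L), reads_per_site = 150L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# fraction of site x VT presence cells (over the union of planted and
# observed VT) on which two community tables agree
presence_agreement <- function(observed, planted) {
  mo <- community_matrix(observed); mp <- community_matrix(planted)
  sites <- union(rownames(mo), rownames(mp))
  vts <- union(colnames(mo), colnames(mp))
  full <- function(m) {
    out <- matrix(FALSE, length(sites), length(vts),
                  dimnames = list(sites, vts))
    out[rownames(m), colnames(m)] <- m > 0
    out
  }
  mean(full(mo) == full(mp))
}

# reference tibble built directly (no simulation) for assignment tests
make_refs <- function(seqs, cultured = rep(FALSE, length(seqs)),
                      biomes = rep(list(character()), length(seqs))) {
  tibble::tibble(
    vt_id = sprintf("VT%03d", seq_along(seqs)),
    type_seq = seqs, cultured = cultured,
    biome_records = biomes,
    continents = rep(list("Asia"), length(seqs)),
    realms = rep(list("Palearctic"), length(seqs)))
}
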