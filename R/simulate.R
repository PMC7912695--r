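#' Simulation configuration for synthetic desert-survey data
#'
#' Defines the conditions the generator emulates: a MaarjAM-like VT
#' reference catalogue (type sequences evolved along a Yule tree under JC69,
#' biome/continent/realm records, cultured flags), six desert site
#' communities assembled with a tunable habitat-filtering effect, and raw
#' paired amplicon reads.  The defaults mirror the desert soil survey:
#' six sites with observed richness 13, 17, 36, 13, 3 and 4 VT, a
#' 50-VT catalogue, roughly 5,000 reads per site and a 1% per-base read
#' error rate.
#'
#' @param n_vt Number of virtual taxa in the catalogue (>= 4).
#' @param birth_rate Yule birth rate for the reference phylogeny.
#' @param seq_length Type-sequence length in bp (sequences are emitted
#'   pre-aligned; evolution is substitution-only, no indels).
#' @param mutation_scale Root-to-tip tree height in expected substitutions
#'   per site.
#' @param min_pendant Minimum terminal-branch length added to every tip
#'   (substitutions/site); guarantees a floor on pairwise reference
#'   divergence so closed-reference assignment is identifiable.
#' @param site_names,site_continents,site_realms,site_richness Per-site
#'   labels, geography and number of member VT.
#' @param reads_per_site Approximate read pairs emitted per site.
#' @param read_length Read length in bp for both mates.
#' @param read_error_rate Per-base substitution error rate in reads.
#' @param quality_mean,quality_sd Per-base Phred score distribution.
#' @param affiliation_beta Habitat-filtering strength: community members are
#'   drawn without replacement with weight `exp(beta * aridity)`; 0 = neutral.
#' @param clustering_mode `"none"` or `"clade"` (members restricted to one
#'   root clade of the reference tree, planting phylogenetic clustering).
#' @param desert_fraction_range Range the per-VT desert record fraction is
#'   drawn from (uniform).
#' @param records_per_vt_mean Mean number of database records per VT.
#' @param cultured_prob Probability a VT is flagged cultured.
#' @param continent_prob,realm_prob Probability a VT occurs in any given
#'   continent/realm.
#' @param fwd_primer,rev_primer Amplicon primer sequences prepended to the
#'   template (defaults are the published WANDA and AML2 SSU primers).
#' @param primer_fail_rate,quality_fail_rate,merge_fail_rate Fractions of
#'   reads planted with a specific processing defect (bad primer, low mean
#'   quality, unmergeable mate); recorded in the ground truth.
#' @param seed Integer seed; every stage derives its own sub-seed from it.
#' @return An `amf_sim_config` list.
#' @export
simulation_config <- function(
    n_vt = 50L,
    birth_rate = 1,
    seq_length = 250L,
    mutation_scale = 0.15,
    min_pendant = 0.03,
    site_names = c("ARG", "AUS", "ISR", "KAZ", "SAU", "USA"),
    site_continents = c("South America", "Australia", "Asia", "Asia",
                        "Asia", "North America"),
    site_realms = c("Neotropic", "Australasia", "Palearctic", "Palearctic",
                    "Palearctic", "Nearctic"),
    site_richness = c(13L, 17L, 36L, 13L, 3L, 4L),
    reads_per_site = 5000L,
    read_length = 170L,
    read_error_rate = 0.01,
    quality_mean = 35,
    quality_sd = 3,
    affiliation_beta = 8,
    clustering_mode = c("none", "clade"),
    desert_fraction_range = c(0, 0.6),
    records_per_vt_mean = 10,
    cultured_prob = 0.42,
    continent_prob = 0.6,
    realm_prob = 0.6,
    fwd_primer = "CAGCCGCGGTAATTCCAGCT",
    rev_primer = "GAACCCAAACACTTTGGTTTCC",
    primer_fail_rate = 0,
    quality_fail_rate = 0,
    merge_fail_rate = 0,
    seed = 1L) {
  clustering_mode <- match.arg(clustering_mode)
  stopifnot(
    n_vt >= 4, birth_rate > 0, seq_length > 50, mutation_scale >= 0,
    min_pendant >= 0, length(site_names) == length(site_richness),
    length(site_names) == length(site_continents),
    length(site_names) == length(site_realms),
    all(site_richness >= 1), all(site_richness <= n_vt),
    reads_per_site >= 1, read_length > nchar(fwd_primer) + 10,
    read_error_rate >= 0, read_error_rate < 1,
    diff(range(desert_fraction_range)) >= 0,
    all(desert_fraction_range >= 0), all(desert_fraction_range <= 1),
    primer_fail_rate >= 0, quality_fail_rate >= 0, merge_fail_rate >= 0,
    primer_fail_rate + quality_fail_rate + merge_fail_rate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "amf_sim_config"
  cfg
}

#' @export
print.amf_sim_config <- function(x, ...) {
  cat("Synthetic desert-survey configuration:\n")
  cat(sprintf("  %d VT, %d sites (%s), ~%d reads/site, error %.3g/bp\n",
              x$n_vt, length(x$site_names),
              paste(x$site_names, collapse = ", "),
              x$reads_per_site, x$read_error_rate))
  cat(sprintf("  affiliation beta %.2g, clustering %s, seed %d\n",
              x$affiliation_beta, x$clustering_mode, x$seed))
  invisible(x)
}

biome_labels <- function() {
  c("temperate grasslands", "tropical moist forest",
    "mediterranean woodland", "temperate broadleaf forest",
    "montane grasslands")
}

#' Simulate the VT reference catalogue, phylogeny and aligned type sequences
#'
#' A Yule tree over `n_vt` leaves is rescaled so the root-to-tip height
#' equals `mutation_scale` substitutions/site and every terminal branch is
#' extended by `min_pendant`; type sequences evolve along it under JC69
#' (substitutions only, so the sequences stay aligned).  Each VT receives
#' biome records with a desert fraction drawn from
#' `desert_fraction_range`, continent/realm occurrences, and a cultured
#' flag.  Per-site continent/realm pools are guaranteed to hold at least
#' `site_richness + 2` VT.
#'
#' @param cfg An `amf_sim_config`.
#' @param seed Seed override (defaults to a sub-seed of `cfg$seed`).
#' @return A list: `refs` (reference tibble), `tree` (`phylo`),
#'   `alignment` (named character vector of aligned type sequences).
#' @export
simulate_reference <- function(cfg = simulation_config(), seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, "simulate_reference")
  with_seed(seed, {
    tree <- ape::rphylo(cfg$n_vt, birth = cfg$birth_rate, death = 0)
    tree$tip.label <- sprintf("VT%03d", seq_len(cfg$n_vt))
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth > 0)
      tree$edge.length <- tree$edge.length * (cfg$mutation_scale / depth)
    tips <- tree$edge[, 2] <= ape::Ntip(tree)
    tree$edge.length[tips] <- tree$edge.length[tips] + cfg$min_pendant

    aln <- phangorn::simSeq(tree, l = cfg$seq_length, type = "DNA")
    mat <- toupper(as.character(aln))
    seqs <- stats::setNames(apply(mat, 1, paste, collapse = ""),
                            rownames(mat))[tree$tip.label]

    n_rec <- 1L + stats::rpois(cfg$n_vt, max(cfg$records_per_vt_mean - 1, 0))
    frac <- stats::runif(cfg$n_vt, cfg$desert_fraction_range[1],
                         cfg$desert_fraction_range[2])
    records <- lapply(seq_len(cfg$n_vt), function(i) {
      nd <- stats::rbinom(1, n_rec[i], frac[i])
      sample(c(rep("deserts and xeric shrublands", nd),
               sample(biome_labels(), n_rec[i] - nd, replace = TRUE)))
    })
    all_conts <- unique(cfg$site_continents)
    all_realms <- unique(cfg$site_realms)
    draw_sets <- function(universe, p) {
      lapply(seq_len(cfg$n_vt), function(i) {
        s <- universe[stats::runif(length(universe)) < p]
        if (length(s) == 0) s <- sample(universe, 1)
        s
      })
    }
    conts <- draw_sets(all_conts, cfg$continent_prob)
    realms <- draw_sets(all_realms, cfg$realm_prob)
    # top up per-site pools so every null test has enough taxa to draw from
    top_up <- function(sets, labels, need) {
      for (i in seq_along(labels)) {
        members <- which(vapply(sets, function(s) labels[i] %in% s, logical(1)))
        short <- need[i] + 2L - length(members)
        if (short > 0) {
          add <- sample(setdiff(seq_len(cfg$n_vt), members), short)
          for (j in add) sets[[j]] <- c(sets[[j]], labels[i])
        }
      }
      sets
    }
    conts <- top_up(conts, cfg$site_continents, cfg$site_richness)
    realms <- top_up(realms, cfg$site_realms, cfg$site_richness)

    refs <- tibble::tibble(
      vt_id = tree$tip.label,
      type_seq = unname(seqs),
      cultured = stats::runif(cfg$n_vt) < cfg$cultured_prob,
      biome_records = records,
      continents = conts,
      realms = realms)
    list(refs = refs, tree = tree, alignment = seqs)
  })
}

#' Simulate site communities with habitat filtering
#'
#' Each site draws its configured number of member VT without replacement
#' with weight proportional to `exp(affiliation_beta * aridity)`; in
#' `"clade"` mode the candidate pool is restricted to the largest root
#' clade of the reference tree.  Member read counts are log-normal,
#' scaled to `reads_per_site` and floored at 2 reads so that every planted
#' member survives dataset-level singleton removal.
#'
#' @param ref A list from [simulate_reference()].
#' @param cfg An `amf_sim_config`.
#' @param seed Seed override.
#' @return A list: `membership` (tibble `site`, `vt_id`) and `comm`
#'   (community tibble `site`, `vt_id`, `reads`).
#' @export
simulate_communities <- function(ref, cfg = simulation_config(), seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, "simulate_communities")
  idx <- aridity_index(ref$refs)
  arid <- stats::setNames(idx$aridity, idx$vt_id)
  site_pool <- rep(list(ref$refs$vt_id), length(cfg$site_names))
  if (cfg$clustering_mode == "clade") {
    # each site draws from the smallest clade able to host it: the tightest
    # monophyletic restriction, planting phylogenetic clustering at every site
    ntip <- ape::Ntip(ref$tree)
    clade_tips <- c(as.list(ref$tree$tip.label),
                    lapply(ntip + seq_len(ref$tree$Nnode), function(nd)
                      ape::extract.clade(ref$tree, nd)$tip.label))
    sizes <- lengths(clade_tips)
    site_pool <- lapply(cfg$site_richness, function(n) {
      ok <- which(sizes >= min(n + 2L, ape::Ntip(ref$tree)))
      clade_tips[[ok[which.min(sizes[ok])]]]
    })
  }
  with_seed(seed, {
    rows <- lapply(seq_along(cfg$site_names), function(i) {
      n <- cfg$site_richness[i]
      candidates <- site_pool[[i]]
      w <- exp(cfg$affiliation_beta * arid[candidates])
      members <- sample(candidates, n, prob = w)
      lognorm <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
      reads <- pmax(2L, as.integer(round(
        lognorm / sum(lognorm) * cfg$reads_per_site)))
      tibble::tibble(site = cfg$site_names[i], vt_id = sort(members),
                     reads = reads[order(members)])
    })
    comm <- dplyr::bind_rows(rows)
    list(membership = dplyr::select(comm, "site", "vt_id"), comm = comm)
  })
}

#' Simulate paired amplicon reads from site communities
#'
#' For every community member, `reads` read pairs are cut from the amplicon
#' `fwd_primer + type_seq + revcomp(rev_primer)`: the forward mate is the
#' first `read_length` bases, the reverse mate the reverse complement of the
#' last `read_length` bases.  Substitution errors are injected at
#' `read_error_rate` per base and Phred strings drawn from the configured
#' quality profile.  Configured fractions of reads are planted with a
#' defect — a corrupted primer, a low-quality mate, or an unmergeable
#' reverse mate — and all ground truth (source VT, defect) is recorded.
#'
#' @param comm Community tibble with planted read counts
#'   (from [simulate_communities()]).
#' @param ref A list from [simulate_reference()].
#' @param cfg An `amf_sim_config`.
#' @param seed Seed override.
#' @return A list: `pairs` (read-pair tibble) and `truth`
#'   (tibble `id`, `site`, `vt_id`, `defect`).
#' @export
simulate_reads <- function(comm, ref, cfg = simulation_config(), seed = NULL) {
  seed <- seed %||% derive_seed(cfg$seed, "simulate_reads")
  assert_cols(comm, c("site", "vt_id", "reads"))
  seqs <- stats::setNames(ref$refs$type_seq, ref$refs$vt_id)
  amplicon <- paste0(cfg$fwd_primer, seqs, revcomp(cfg$rev_primer))
  names(amplicon) <- names(seqs)
  la <- nchar(amplicon)
  if (any(cfg$read_length > la))
    abort("read_length exceeds amplicon length")
  with_seed(seed, {
    site_v <- rep(comm$site, comm$reads)
    vt_v <- rep(comm$vt_id, comm$reads)
    n <- length(site_v)
    ord <- order(site_v)
    site_v <- site_v[ord]; vt_v <- vt_v[ord]
    id_v <- unlist(lapply(split(seq_len(n), site_v), function(ii)
      sprintf("%s_r%06d", site_v[ii][1], seq_along(ii))), use.names = FALSE)

    amp <- amplicon[vt_v]
    fwd <- substr(amp, 1, cfg$read_length)
    rev <- revcomp(substring(amp, nchar(amp) - cfg$read_length + 1))

    # per-base independent substitution errors at `rate`
    inject <- function(reads, rate) {
      if (rate <= 0) return(reads)
      len <- cfg$read_length
      bases <- c("A", "C", "G", "T")
      hits <- which(matrix(stats::runif(length(reads) * len) < rate,
                           length(reads), len), arr.ind = TRUE)
      while (nrow(hits) > 0) {
        first <- !duplicated(hits[, 1])
        rows <- hits[first, 1]; cols <- hits[first, 2]
        old <- substr(reads[rows], cols, cols)
        shift <- sample.int(3, length(rows), replace = TRUE)
        new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
        tmp <- reads[rows]
        substr(tmp, cols, cols) <- new
        reads[rows] <- tmp
        hits <- hits[!first, , drop = FALSE]
      }
      reads
    }
    fwd <- inject(fwd, cfg$read_error_rate)
    rev <- inject(rev, cfg$read_error_rate)

    qual_string <- function(n_reads) {
      len <- cfg$read_length
      q <- pmin(41L, pmax(2L, as.integer(round(
        stats::rnorm(n_reads * len, cfg$quality_mean, cfg$quality_sd)))))
      s <- rawToChar(as.raw(q + 33L))
      substring(s, (seq_len(n_reads) - 1L) * len + 1L, seq_len(n_reads) * len)
    }
    fq <- qual_string(n)
    rq <- qual_string(n)

    defect <- rep("none", n)
    p_def <- c(primer = cfg$primer_fail_rate, quality = cfg$quality_fail_rate,
               merge = cfg$merge_fail_rate)
    if (sum(p_def) > 0) {
      u <- stats::runif(n)
      defect[u < p_def[1]] <- "primer"
      defect[u >= p_def[1] & u < sum(p_def[1:2])] <- "quality"
      defect[u >= sum(p_def[1:2]) & u < sum(p_def)] <- "merge"
      for (i in which(defect == "primer")) {
        # three guaranteed mismatches at the primer 5' end
        for (p in 1:3) {
          old <- substr(fwd[i], p, p)
          substr(fwd[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
      low_q <- which(defect == "quality")
      if (length(low_q) > 0)
        fq[low_q] <- strrep(intToUtf8(20L + 33L), cfg$read_length)
      bad_m <- which(defect == "merge")
      if (length(bad_m) > 0) {
        # keep the reverse primer intact so the pair fails only at merging
        tail_len <- cfg$read_length - nchar(cfg$rev_primer)
        rev[bad_m] <- vapply(bad_m, function(i) paste0(
          cfg$rev_primer,
          paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE),
                collapse = "")), character(1))
      }
    }

    pairs <- tibble::tibble(id = id_v, site = site_v, fwd_seq = fwd,
                            fwd_qual = fq, rev_seq = rev, rev_qual = rq)
    truth <- tibble::tibble(id = id_v, site = site_v, vt_id = vt_v,
                            defect = defect)
    list(pairs = pairs, truth = truth)
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_reference()], [simulate_communities()] and
#' [simulate_reads()] and writes every file the pipeline consumes:
#' reference FASTA + sidecar TSV, aligned type sequences, Newick tree, pool
#' definition TSV (global/continent/realm), a site environment table, paired
#' FASTQ files per site, and plain-text ground truth (true community table
#' and per-read source/defect labels).
#'
#' @param cfg An `amf_sim_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`ref`, `comm`,
#'   `pairs`, `truth`, `pools`, `env`) and `files` (named vector of paths).
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = tempfile("amfsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "fastq"), showWarnings = FALSE)
  ref <- simulate_reference(cfg)
  cm <- simulate_communities(ref, cfg)
  rd <- simulate_reads(cm$comm, ref, cfg)

  files <- c(
    reference_fasta = file.path(dir, "reference.fasta"),
    reference_tsv = file.path(dir, "reference.tsv"),
    alignment_fasta = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    pools = file.path(dir, "pools.tsv"),
    env = file.path(dir, "env.tsv"),
    true_community = file.path(dir, "true_community.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"))

  write_vt_reference(ref$refs, files["reference_fasta"], files["reference_tsv"])
  write_fasta(ref$alignment, files["alignment_fasta"])
  ape::write.tree(ref$tree, files["tree"])

  pools <- reference_pools(ref$refs, cfg)
  utils::write.table(pools, files["pools"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  env <- with_seed(derive_seed(cfg$seed, "simulate_env"), {
    tibble::tibble(
      site = cfg$site_names,
      mat = round(stats::runif(length(cfg$site_names), 10, 26), 1),
      map = round(stats::runif(length(cfg$site_names), 100, 330)),
      ph = round(stats::runif(length(cfg$site_names), 4.9, 8.5), 2),
      p = round(stats::runif(length(cfg$site_names), 0.4, 61), 2),
      n = round(stats::runif(length(cfg$site_names), 0.03, 0.1), 2),
      c = round(stats::runif(length(cfg$site_names), 0.29, 0.62), 2))
  })
  utils::write.table(env, files["env"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_community(cm$comm, files["true_community"])
  utils::write.table(rd$truth, files["ground_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in cfg$site_names) {
    p <- rd$pairs[rd$pairs$site == s, ]
    f1 <- file.path(dir, "fastq", paste0(s, "_R1.fastq"))
    f2 <- file.path(dir, "fastq", paste0(s, "_R2.fastq"))
    write_fastq_pairs(p, f1, f2)
    files[paste0("fastq_", s, "_R1")] <- f1
    files[paste0("fastq_", s, "_R2")] <- f2
  }
  invisible(list(ref = ref, comm = cm$comm, membership = cm$membership,
                 pairs = rd$pairs, truth = rd$truth, pools = pools, env = env,
                 files = files, dir = dir))
}

#' Pool definitions (global / continent / realm) from a reference catalogue
#'
#' @param refs Reference tibble.
#' @param cfg An `amf_sim_config` carrying the per-site geography.
#' @return A tibble `site`, `scale`, `vt_id` (global rows have NA site).
#' @export
reference_pools <- function(refs, cfg) {
  rows <- list(tibble::tibble(site = NA_character_, scale = "global",
                              vt_id = refs$vt_id))
  for (i in seq_along(cfg$site_names)) {
    in_cont <- vapply(refs$continents, function(s)
      cfg$site_continents[i] %in% s, logical(1))
    in_realm <- vapply(refs$realms, function(s)
      cfg$site_realms[i] %in% s, logical(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      site = cfg$site_names[i], scale = "continent",
      vt_id = refs$vt_id[in_cont])
    rows[[length(rows) + 1]] <- tibble::tibble(
      site = cfg$site_names[i], scale = "realm",
      vt_id = refs$vt_id[in_realm])
  }
  dplyr::bind_rows(rows)
}
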