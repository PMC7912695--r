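#' Pipeline configuration
#'
#' All stage parameters with their survey defaults: primer matching with at
#' most 1 mismatch, mean Phred >= 30 per mate, merging over a 10-300 bp
#' overlap at >= 75% identity, closed-reference assignment at 97% identity
#' and 95% read coverage, 999 randomization replicates, a 1.96 two-sided Z
#' threshold, and 200 bootstrap resamples for diversity uncertainty.
#' Round-trips losslessly through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param fwd_primer,rev_primer Amplicon primers (defaults: WANDA and AML2).
#' @param max_mismatch Primer mismatches tolerated per mate.
#' @param min_mean_q Minimum mean Phred score per mate.
#' @param min_overlap,max_overlap,min_identity Merge parameters.
#' @param id_threshold,cov_threshold Assignment thresholds.
#' @param prescreen_top References aligned per read after the k-mer
#'   prescreen (`Inf` = exhaustive).
#' @param n_reps Randomization replicates for null tests.
#' @param z_crit Two-sided Z significance threshold.
#' @param B Bootstrap resamples for diversity confidence limits.
#' @param seed Global seed; stages derive their own sub-seeds.
#' @return A named list of class `amf_config`.
#' @export
pipeline_config <- function(fwd_primer = "CAGCCGCGGTAATTCCAGCT",
                            rev_primer = "GAACCCAAACACTTTGGTTTCC",
                            max_mismatch = 1L, min_mean_q = 30,
                            min_overlap = 10L, max_overlap = 300L,
                            min_identity = 0.75, id_threshold = 0.97,
                            cov_threshold = 0.95, prescreen_top = 2,
                            n_reps = 999L, z_crit = 1.96, B = 200L,
                            seed = 1L) {
  stopifnot(max_mismatch >= 0, min_mean_q >= 0, min_overlap >= 1,
            max_overlap >= min_overlap, min_identity >= 0, min_identity <= 1,
            id_threshold >= 0, id_threshold <= 1,
            cov_threshold >= 0, cov_threshold <= 1,
            n_reps >= 1, z_crit > 0, B >= 50)
  cfg <- as.list(environment())
  class(cfg) <- "amf_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config An `amf_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Executes read processing, VT assignment, singleton removal, diversity
#' estimation, phylogenetic community structure, ordination and the
#' multi-scale habitat-affiliation tests, writing every output as plain TSV /
#' FASTA / Newick into `output_dir` together with a checksummed manifest.
#' The input directory layout is the one [simulate_dataset()] emits
#' (`fastq/<site>_R1.fastq` + `_R2.fastq`, `reference.fasta`,
#' `reference.tsv`, `alignment.fasta`, `pools.tsv`, `env.tsv`).
#'
#' @param input_dir Dataset directory.
#' @param output_dir Output directory (created if missing).
#' @param config An `amf_config` (see [pipeline_config()]).
#' @param skip_reads Skip stages 1-2 and start from a provided community
#'   table (`community_file`).
#' @param community_file Community TSV used when `skip_reads = TRUE`
#'   (defaults to `<input_dir>/true_community.tsv`).
#' @return Invisibly, a list with the stage results and `manifest`
#'   (tibble `file`, `md5`).
#' @export
run_pipeline <- function(input_dir, output_dir, config = pipeline_config(),
                         skip_reads = FALSE, community_file = NULL) {
  if (!dir.exists(input_dir)) abort(paste("Input directory not found:", input_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  refs <- stage("reference", read_vt_reference(
    file.path(input_dir, "reference.fasta"),
    file.path(input_dir, "reference.tsv")))
  pools <- stage("reference", {
    p <- utils::read.delim(file.path(input_dir, "pools.tsv"),
                           stringsAsFactors = FALSE)
    p$site <- as.character(p$site)
    tibble::as_tibble(p)
  })

  outputs <- character()
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(output_dir, name)
    if (is.null(writer)) {
      utils::write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  if (skip_reads) {
    community_file <- community_file %||% file.path(input_dir, "true_community.tsv")
    comm_raw <- stage("assign", read_community(community_file))
    processed <- NULL
    assignments <- NULL
  } else {
    fq <- list.files(file.path(input_dir, "fastq"), "_R1\\.fastq$",
                     full.names = TRUE)
    if (length(fq) == 0) abort("No FASTQ files found under input_dir/fastq")
    sites <- sub("_R1\\.fastq$", "", basename(fq))
    pairs <- stage("reads", dplyr::bind_rows(lapply(sites, function(s)
      read_fastq_pairs(file.path(input_dir, "fastq", paste0(s, "_R1.fastq")),
                       file.path(input_dir, "fastq", paste0(s, "_R2.fastq")),
                       site = s))))
    processed <- stage("reads", process_reads(pairs, config))
    emit(processed$stats, "processing_stats.tsv")
    emit(stats::setNames(processed$merged$seq, processed$merged$id),
         "merged.fasta", write_fasta)
    assignments <- stage("assign", assign_vt(
      processed$merged, refs, id_threshold = config$id_threshold,
      cov_threshold = config$cov_threshold,
      prescreen_top = config$prescreen_top))
    emit(assignments, "assignments.tsv")
    comm_raw <- stage("assign", build_community_table(assignments))
  }

  comm <- stage("assign", remove_singletons(comm_raw))
  emit(comm, "community.tsv", write_community)

  div <- stage("diversity", site_diversity(
    comm, B = config$B, seed = derive_seed(config$seed, "diversity")))
  emit(div, "diversity.tsv")
  rar <- stage("diversity", rarefaction_curve(comm))
  emit(rar, "rarefaction.tsv")

  aln <- stage("phylo", read_fasta(file.path(input_dir, "alignment.fasta")))
  jc <- stage("phylo", jc_distance_matrix(aln))
  tree <- stage("phylo", nj_tree(jc))
  emit(tree, "nj_tree.nwk", function(obj, path) ape::write.tree(obj, path))
  pd <- stage("phylo", patristic_distances(tree))
  emit(data.frame(vt_id = rownames(pd), pd, check.names = FALSE),
       "patristic.tsv")
  ses <- stage("phylo", ses_mpd_sites(
    comm, pd, pools, n_reps = config$n_reps,
    seed = derive_seed(config$seed, "phylo"), z_crit = config$z_crit))
  emit(ses, "ses_mpd.tsv")

  jac <- stage("ordination", jaccard_matrix(comm))
  k_ord <- max(1L, min(2L, length(unique(comm$site)) - 1L))
  pcoa <- stage("ordination", pcoa_ord(jac, k = k_ord))
  emit(tidy(pcoa), "pcoa_scores.tsv")
  cd <- stage("ordination", comdist_matrix(comm, pd))
  nmds <- stage("ordination", nmds_ord(
    cd, k = k_ord, seed = derive_seed(config$seed, "ordination")))
  emit(tidy(nmds), "nmds_scores.tsv")
  env_path <- file.path(input_dir, "env.tsv")
  envfit_res <- NULL
  if (file.exists(env_path)) {
    env <- utils::read.delim(env_path, stringsAsFactors = FALSE)
    rownames(env) <- env$site
    env <- env[rownames(nmds$scores), , drop = FALSE]
    envfit_res <- stage("ordination", fit_environment(
      nmds, env[, setdiff(names(env), "site"), drop = FALSE],
      n_perm = config$n_reps,
      seed = derive_seed(config$seed, "envfit")))
    emit(envfit_res, "envfit.tsv")
  }

  indices <- stage("habitat", aridity_index(refs))
  emit(indices, "aridity_index.tsv")
  habitat <- stage("habitat", multi_scale_test(
    comm, indices, pools, n_reps = config$n_reps,
    seed = derive_seed(config$seed, "habitat"), z_crit = config$z_crit))
  emit(habitat, "aridity_tests.tsv")
  emit(z_table(habitat, config$z_crit), "aridity_z_table.tsv")

  manifest <- tibble::tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)))
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(processed = processed, assignments = assignments,
                 community = comm, diversity = div, rarefaction = rar,
                 tree = tree, ses_mpd = ses, pcoa = pcoa, nmds = nmds,
                 envfit = envfit_res, aridity = indices, habitat = habitat,
                 manifest = manifest))
}
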