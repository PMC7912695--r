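test_that("alignment of identical and lightly mutated reads is exact", {
  set.seed(21)
  ref <- rand_dna(100)
  a <- align_to_reference(ref, ref)
  expect_equal(unname(a["identity"]), 1.0)
  expect_equal(unname(a["coverage"]), 1.0)
  # 3 substitutions in 100 bp, full-length alignment
  mut <- mutate_at_pos(ref, c(20, 50, 80))
  a3 <- align_to_reference(mut, ref)
  expect_equal(unname(a3["identity"]), 0.97)
  expect_equal(unname(a3["coverage"]), 1.0)
})

test_that("unrelated random sequences never reach assignment coverage", {
  set.seed(22)
  reads <- replicate(300, rand_dna(200))
  refs <- replicate(300, rand_dna(200))
  cov_at_id <- vapply(seq_along(reads), function(i) {
    a <- align_to_reference(reads[i], refs[i])
    if (a["identity"] >= 0.97) a["coverage"] else 0
  }, double(1))
  expect_lt(max(cov_at_id), 0.95)
})

test_that("local alignment scores match Biostrings pairwiseAlignment", {
  set.seed(23)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:20) {
    # related pairs (mutated copies) and unrelated pairs
    ref <- rand_dna(80)
    read <- if (i %% 2 == 0) mutate_at_pos(ref, sample(80, sample(1:10, 1)))
            else rand_dna(80)
    ours <- align_reads(read, ref)$score
    theirs <- Biostrings::pairwiseAlignment(
      read, ref, type = "local", substitutionMatrix = submat,
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, max(theirs, 0))
  }
})

test_that("best-hit assignment recovers the source reference", {
  set.seed(24)
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  refs <- ref$refs
  # reads = type sequences with 1% substitution noise
  reads <- vapply(refs$type_seq, function(s)
    mutate_at_pos(s, sample(nchar(s), ceiling(0.01 * nchar(s)))), character(1))
  merged <- tibble::tibble(id = refs$vt_id, site = "A", seq = unname(reads))
  out <- assign_vt(merged, refs, prescreen_top = Inf)
  expect_equal(out$vt_id, refs$vt_id)
  expect_true(all(out$identity >= 0.97))
  # prescreen gives the same answer as the exhaustive scan
  out_ps <- assign_vt(merged, refs, prescreen_top = 2)
  expect_equal(out_ps, out)
})

test_that("reverse-complemented reads are still assigned", {
  set.seed(25)
  cfg <- small_cfg()
  refs <- simulate_reference(cfg)$refs
  merged <- tibble::tibble(id = "r1", site = "A",
                           seq = revcomp_chr(refs$type_seq[3]))
  out <- assign_vt(merged, refs)
  expect_equal(out$vt_id, refs$vt_id[3])
})

test_that("reads below identity or coverage threshold stay unassigned", {
  set.seed(26)
  ref <- rand_dna(200)
  refs <- make_refs(ref)
  # ~4% divergence: below the 97% identity threshold
  bad <- mutate_at_pos(ref, sample(200, 8))
  out <- assign_vt(tibble::tibble(id = "r1", site = "A", seq = bad), refs,
                   prescreen_top = Inf)
  expect_true(is.na(out$vt_id))
  # only half the read aligns: coverage below 95%
  half <- paste0(substr(ref, 1, 100), rand_dna(100))
  out2 <- assign_vt(tibble::tibble(id = "r2", site = "A", seq = half), refs,
                    prescreen_top = Inf)
  expect_true(is.na(out2$vt_id))
})

test_that("assignment is deterministic under reference reordering and monotone in thresholds", {
  set.seed(27)
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  reads <- vapply(ref$refs$type_seq[1:8], function(s)
    mutate_at_pos(s, sample(nchar(s), 3)), character(1))
  merged <- tibble::tibble(id = sprintf("r%d", 1:8), site = "A",
                           seq = unname(reads))
  a1 <- assign_vt(merged, ref$refs, prescreen_top = Inf)
  a2 <- assign_vt(merged, ref$refs[sample(nrow(ref$refs)), ],
                  prescreen_top = Inf)
  expect_equal(a1, a2)
  for (thr in list(c(0.90, 0.95), c(0.99, 0.95), c(0.97, 0.99))) {
    ax <- assign_vt(merged, ref$refs, id_threshold = thr[1],
                    cov_threshold = thr[2], prescreen_top = Inf)
    if (thr[1] >= 0.97 && thr[2] >= 0.95)
      expect_lte(sum(!is.na(ax$vt_id)), sum(!is.na(a1$vt_id)))
    else
      expect_gte(sum(!is.na(ax$vt_id)), sum(!is.na(a1$vt_id)))
  }
})

test_that("empty reference set errors", {
  expect_error(assign_vt(tibble::tibble(id = "r", site = "A", seq = "ACGT"),
                         make_refs(character())),
               "Empty reference")
})

test_that("community table counts assigned reads and ignores order", {
  asg <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    site = c("A", "A", "A", "B", "A"),
    vt_id = c("VT1", "VT1", "VT1", "VT1", NA),
    identity = 1, coverage = 1)
  tab <- build_community_table(asg)
  expect_equal(tab$reads[tab$site == "A"], 3L)
  expect_equal(tab$reads[tab$site == "B"], 1L)
  expect_equal(build_community_table(asg[sample(5), ]), tab)
  none <- build_community_table(asg[integer(0), ])
  expect_equal(nrow(none), 0)
})

test_that("singleton removal drops total-count-1 VT only, idempotently", {
  comm <- tibble::tibble(
    site = c("A", "A", "B", "B"),
    vt_id = c("VT1", "VT2", "VT2", "VT3"),
    reads = c(1L, 1L, 1L, 5L))
  out <- remove_singletons(comm)
  expect_false("VT1" %in% out$vt_id)        # dataset singleton
  expect_true("VT2" %in% out$vt_id)         # 1 + 1 across sites = retained
  expect_equal(remove_singletons(out), out) # idempotent
  all_singles <- tibble::tibble(site = "A", vt_id = c("x", "y"),
                                reads = c(1L, 1L))
  expect_equal(nrow(remove_singletons(all_singles)), 0)
})

test_that("cultured fraction counts flagged VT among retained taxa", {
  refs <- make_refs(replicate(50, rand_dna(30)),
                    cultured = c(rep(TRUE, 21), rep(FALSE, 29)))
  comm <- tibble::tibble(site = "A", vt_id = refs$vt_id, reads = 2L)
  expect_equal(cultured_fraction(comm, refs), 0.42)
  refs_none <- make_refs(replicate(4, rand_dna(30)))
  comm4 <- tibble::tibble(site = "A", vt_id = refs_none$vt_id, reads = 2L)
  expect_equal(cultured_fraction(comm4, refs_none), 0)
  refs_all <- make_refs(replicate(4, rand_dna(30)), cultured = rep(TRUE, 4))
  comm_all <- tibble::tibble(site = "A", vt_id = refs_all$vt_id, reads = 2L)
  expect_equal(cultured_fraction(comm_all, refs_all), 1)
  expect_error(cultured_fraction(
    tibble::tibble(site = "A", vt_id = "nope", reads = 2L), refs),
    "absent")
})

test_that("reference catalogue round-trips through FASTA + sidecar", {
  set.seed(28)
  refs <- make_refs(replicate(4, rand_dna(60)),
                    cultured = c(TRUE, FALSE, TRUE, FALSE),
                    biomes = list(c("deserts and xeric shrublands", "temperate grasslands"),
                                  character(), "temperate grasslands",
                                  rep("deserts and xeric shrublands", 3)))
  d <- withr::local_tempdir()
  write_vt_reference(refs, file.path(d, "ref.fasta"), file.path(d, "ref.tsv"))
  back <- read_vt_reference(file.path(d, "ref.fasta"), file.path(d, "ref.tsv"))
  expect_equal(back, refs)
})
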