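test_that("primer matching trims exact and 1-mismatch hits and rejects worse", {
  primer <- "ACGTACGTAC"
  insert <- "GGGGGCCCCCTTTTTAAAAA"
  exact <- paste0(primer, insert)
  one_mm <- paste0(mutate_at_pos(primer, 3), insert)
  two_mm <- paste0(mutate_at_pos(primer, c(3, 7)), insert)
  pairs <- make_pairs(fwd = c(exact, one_mm, two_mm),
                      rev = rep(exact, 3))
  out <- match_and_trim_primers(pairs, primer, primer, max_mismatch = 1)
  expect_equal(out$primer_ok, c(TRUE, TRUE, FALSE))
  expect_equal(out$fwd_seq[1], insert)
  expect_equal(out$fwd_qual[1], q_string(40L, nchar(insert)))
  # failing pair left untrimmed
  expect_equal(nchar(out$fwd_seq[3]), nchar(two_mm))
})

test_that("IUPAC codes in the primer match their expansions; N in read does not", {
  # R matches A: one other mismatch is still within max_mismatch = 1
  primer <- "RCGT"
  read <- paste0("ACGA", "GGGGGGGGGG")   # R~A match, T/A mismatch at pos 4
  pairs <- make_pairs(fwd = read, rev = "GGGGGGGGGG")
  out <- match_and_trim_primers(pairs, primer, "GGGG", max_mismatch = 1)
  expect_true(out$primer_ok[1])
  # read N counts as a mismatch even against primer N
  pairs_n <- make_pairs(fwd = paste0("NNGT", "GGGGGGGGGG"), rev = "GGGGGGGGGG")
  out_n <- match_and_trim_primers(pairs_n, "NCGT", "GGGG", max_mismatch = 1)
  expect_false(out_n$primer_ok[1])
})

test_that("primer mismatch counting equals brute-force IUPAC expansion", {
  set.seed(101)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (rep in 1:25) {
    primer <- paste(sample(codes, 8, replace = TRUE), collapse = "")
    read <- rand_dna(30)
    mm_cpp <- desertam:::cpp_primer_mismatch(read, primer)
    mm_brute <- min(vapply(iupac_expansions(primer), function(e)
      hamming(e, substr(read, 1, 8)), double(1)))
    expect_equal(mm_cpp, mm_brute)
  }
})

test_that("reads shorter than the primer are rejected, not an error", {
  pairs <- make_pairs(fwd = "ACG", rev = "ACGTACGTACGT")
  out <- match_and_trim_primers(pairs, "ACGTACGTAC", "ACGT")
  expect_false(out$primer_ok[1])
})

test_that("quality filter keeps pairs with both mates at mean Q >= threshold", {
  n <- 20L
  pairs <- make_pairs(
    fwd = replicate(3, rand_dna(n)), rev = replicate(3, rand_dna(n)),
    fq = c(q_string(30L, n), q_string(35L, n), q_string(2L, n)),
    rq = c(q_string(30L, n),
           paste0(q_string(30L, n - 1L), intToUtf8(10L + 33L)),  # mean 29.x
           q_string(2L, n)))
  out <- quality_filter(pairs, min_mean_q = 30)
  expect_equal(out$quality_ok, c(TRUE, FALSE, FALSE))
})

test_that("empty mate is dropped by the quality filter", {
  pairs <- make_pairs(fwd = "ACGT", rev = "", fq = q_string(40L, 4), rq = "")
  expect_false(quality_filter(pairs)$quality_ok[1])
})

test_that("merging finds an exact overlap and respects the window", {
  set.seed(7)
  left <- rand_dna(130)
  ovl <- rand_dna(20)
  right <- rand_dna(130)
  fwd <- paste0(left, ovl)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(ovl, right))))
  out <- merge_pairs(make_pairs(fwd = fwd, rev = rev))
  expect_true(out$merge_ok[1])
  expect_equal(out$overlap_len[1], 20L)
  expect_equal(out$seq[1], paste0(left, ovl, right))
  expect_equal(nchar(out$seq[1]), 150 + 150 - 20)
  # overlap below the minimum window is rejected
  ovl8 <- rand_dna(8)
  fwd8 <- paste0(rand_dna(100), ovl8)
  rev8 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(ovl8, rand_dna(100)))))
  out8 <- merge_pairs(make_pairs(fwd = fwd8, rev = rev8))
  expect_false(out8$merge_ok[1])
})

test_that("merge identity boundary sits exactly at 75%", {
  set.seed(8)
  # same 20 bp overlap; plant 5 then 6 mismatches on the forward copy
  for (n_mm in c(5L, 6L)) {
    ovl <- rand_dna(20)
    left <- rand_dna(120)
    right <- rand_dna(120)
    ovl_mut <- mutate_at_pos(ovl, sample(20, n_mm))
    fwd <- paste0(left, ovl_mut)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste0(ovl, right))))
    out <- merge_pairs(make_pairs(fwd = fwd, rev = rev))
    if (n_mm == 5L) {
      expect_true(out$merge_ok[1])
      expect_equal(out$overlap_len[1], 20L)
    } else {
      # 6/20 mismatches = identity 0.70 < 0.75; only spurious overlaps remain
      expect_true(!out$merge_ok[1] || out$overlap_len[1] != 20L)
    }
  }
})

test_that("merging agrees with an exhaustive all-offsets oracle", {
  set.seed(9)
  for (i in 1:40) {
    # random template with a planted overlap of random length, plus noise
    o <- sample(10:40, 1)
    templ <- rand_dna(80 + o)
    fwd <- substr(templ, 1, 60 + o)
    revpart <- substring(templ, 61)
    # sprinkle mismatches on the reverse copy
    n_mm <- sample(0:6, 1)
    if (n_mm > 0) revpart <- mutate_at_pos(revpart, sample(nchar(revpart), n_mm))
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(revpart)))
    fq <- q_string(sample(20:40, 1), nchar(fwd))
    rq <- q_string(sample(20:40, 1), nchar(rev))
    got <- merge_pairs(make_pairs(fwd = fwd, rev = rev, fq = fq, rq = rq))
    want <- brute_merge(fwd, fq, rev, rq)
    expect_equal(got$merge_ok[1], want$ok)
    if (want$ok) {
      expect_equal(got$overlap_len[1], want$o)
      expect_equal(got$seq[1], want$seq)
    }
  }
})

test_that("consensus takes the higher-Phred base, ties to forward", {
  ovl_f <- "AAAAAAAAAAAA"           # forward says A
  ovl_r <- "AAAAACAAAAAA"           # reverse says C at position 6
  fwd <- paste0(rand_dna(20), ovl_f)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(ovl_r, rand_dna(20)))))
  # reverse qualities higher -> C wins
  out_hi <- merge_pairs(make_pairs(
    fwd = fwd, rev = rev,
    fq = q_string(20L, nchar(fwd)), rq = q_string(40L, nchar(rev))))
  expect_equal(substr(out_hi$seq[1], 26, 26), "C")
  # equal qualities -> forward base wins
  out_tie <- merge_pairs(make_pairs(
    fwd = fwd, rev = rev,
    fq = q_string(30L, nchar(fwd)), rq = q_string(30L, nchar(rev))))
  expect_equal(substr(out_tie$seq[1], 26, 26), "A")
})

test_that("process_reads conserves counts and matches planted defects", {
  cfg <- small_cfg(read_error_rate = 0, primer_fail_rate = 0.1,
                   quality_fail_rate = 0.1, merge_fail_rate = 0.1)
  ref <- simulate_reference(cfg)
  cm <- simulate_communities(ref, cfg)
  rd <- simulate_reads(cm$comm, ref, cfg)
  pr <- suppressMessages(process_reads(rd$pairs, pipeline_config()))
  st <- pr$stats
  expect_equal(st$n_input,
               st$n_primer_fail + st$n_quality_fail + st$n_merge_fail +
                 st$n_merged)
  planted <- table(rd$truth$site, rd$truth$defect)
  for (s in rownames(planted)) {
    row <- st[st$site == s, ]
    expect_equal(row$n_primer_fail, unname(planted[s, "primer"]))
    expect_equal(row$n_quality_fail, unname(planted[s, "quality"]))
    expect_equal(row$n_merge_fail, unname(planted[s, "merge"]))
  }
  # order insensitivity
  shuffled <- rd$pairs[sample(nrow(rd$pairs)), ]
  pr2 <- suppressMessages(process_reads(shuffled, pipeline_config()))
  expect_equal(pr2$stats, st)
})

test_that("empty input yields an empty result with zeroed stats", {
  pairs <- make_pairs(fwd = character(), rev = character(),
                      id = character(), site = character())
  pr <- process_reads(pairs, pipeline_config())
  expect_equal(nrow(pr$merged), 0)
  expect_true(all(pr$stats$n_input == 0))
})

test_that("FASTQ round trip preserves pairs and mismatched files error", {
  set.seed(11)
  pairs <- make_pairs(fwd = replicate(5, rand_dna(40)),
                      rev = replicate(5, rand_dna(40)),
                      fq = replicate(5, q_string(33L, 40)),
                      rq = replicate(5, q_string(35L, 40)))
  d <- withr::local_tempdir()
  write_fastq_pairs(pairs, file.path(d, "a_R1.fastq"), file.path(d, "a_R2.fastq"))
  back <- read_fastq_pairs(file.path(d, "a_R1.fastq"), file.path(d, "a_R2.fastq"),
                           site = "A")
  expect_equal(back, pairs)
  # truncate the reverse file -> mate count mismatch names both files
  writeLines(readLines(file.path(d, "a_R2.fastq"))[1:4],
             file.path(d, "b_R2.fastq"))
  expect_error(
    read_fastq_pairs(file.path(d, "a_R1.fastq"), file.path(d, "b_R2.fastq")),
    "a_R1.*b_R2|Mate count")
})

test_that("chimera hook drops listed ids", {
  merged <- tibble::tibble(id = c("r1", "r2", "r3"), site = "A",
                           seq = replicate(3, rand_dna(30)), overlap_len = 12L)
  f <- withr::local_tempfile(lines = c("r2"))
  expect_equal(drop_chimeras(merged, f)$id, c("r1", "r3"))
})
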