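test_that("Jukes-Cantor distances match the closed form and cap saturation", {
  a <- paste(rep("A", 100), collapse = "")
  seqs <- c(x = a, y = a)
  expect_equal(unname(jc_distance_matrix(seqs)["x", "y"]), 0)
  # 10 differences in 100 sites: p = 0.1
  b <- mutate_at_pos(a, 1:10)
  d <- jc_distance_matrix(c(x = a, y = b))
  expect_equal(unname(d["x", "y"]), -0.75 * log(1 - 4 / 3 * 0.1),
               tolerance = 1e-9)
  expect_equal(unname(d["x", "y"]), 0.10732, tolerance = 1e-4)
  # saturated pair capped at a finite value
  far <- paste(rep("C", 100), collapse = "")
  dc <- jc_distance_matrix(c(x = a, y = far), cap = 5)
  expect_equal(unname(dc["x", "y"]), 5)
  expect_error(jc_distance_matrix(c(x = "AC", y = "ACG")), "equal length")
})

test_that("neighbor joining handles 2 taxa and reproduces additive matrices", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(unname(patristic_distances(t2)["a", "b"]), 0.4)
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    rebuilt <- nj_tree(dm)
    expect_true(all(rebuilt$edge.length >= 0))
    pd <- patristic_distances(rebuilt)
    expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  }
})

test_that("patristic distances equal brute-force path walks", {
  set.seed(42)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:10, 1))
    want <- brute_patristic(tr)
    got <- patristic_distances(tr)
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-12)
  }
  # star tree with unit pendant edges: all distances 2
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, 5)
  ps <- patristic_distances(star)
  expect_true(all(ps[lower.tri(ps)] == 2))
  expect_true(all(diag(ps) == 0))
})

test_that("mpd and comdist match brute-force pair enumeration", {
  set.seed(43)
  tr <- ape::rtree(12)
  d <- patristic_distances(tr)
  expect_equal(mpd_obs(c("t1", "t2"), d), d["t1", "t2"])
  expect_true(is.na(mpd_obs("t1", d)))
  expect_error(mpd_obs("nope", d), "absent")
  taxa <- sample(rownames(d), 6)
  pairs <- utils::combn(taxa, 2)
  expect_equal(mpd_obs(taxa, d),
               mean(d[cbind(pairs[1, ], pairs[2, ])]))
  a <- sample(rownames(d), 3); b <- sample(rownames(d), 4)
  cross <- expand.grid(a, b, stringsAsFactors = FALSE)
  expect_equal(comdist_pair(a, b, d),
               mean(d[cbind(cross[[1]], cross[[2]])]))
  expect_equal(comdist_pair(a, b, d), comdist_pair(b, a, d))
  expect_equal(comdist_pair("t1", "t1", d), 0)
  expect_error(comdist_pair(character(), a, d), "Empty")
  # order permutation invariance
  expect_equal(mpd_obs(rev(taxa), d), mpd_obs(taxa, d))
})

test_that("mpd and comdist agree with picante", {
  set.seed(44)
  tr <- ape::rtree(10)
  d <- patristic_distances(tr)
  comm <- tibble::tibble(
    site = rep(c("A", "B"), c(4, 5)),
    vt_id = c(sample(tr$tip.label, 4), sample(tr$tip.label, 5)),
    reads = 2L)
  m <- (community_matrix(comm) > 0) * 1
  pic_mpd <- picante::mpd(m, d[colnames(m), colnames(m)])
  ours <- vapply(community_sets(comm), mpd_obs, double(1), d = d)
  expect_equal(unname(ours[rownames(m)]), pic_mpd)
  pic_cd <- as.matrix(picante::comdist(m, d[colnames(m), colnames(m)],
                                       abundance.weighted = FALSE))
  expect_equal(as.matrix(comdist_matrix(comm, d))["A", "B"], pic_cd["A", "B"])
})

test_that("ses_mpd matches exhaustive enumeration for small pools", {
  set.seed(45)
  tr <- ape::rtree(4)
  d <- patristic_distances(tr)
  pool <- rownames(d)
  taxa <- pool[1:2]
  all_subsets <- utils::combn(pool, 2)
  exact <- apply(all_subsets, 2, mpd_obs, d = d)
  res <- ses_mpd(taxa, d, pool, n_reps = 3000, seed = 9)
  pop_mean <- mean(exact)
  pop_sd <- sqrt(mean((exact - pop_mean)^2))
  expect_lt(abs(res$null_mean - pop_mean), 3 * pop_sd / sqrt(res$n_reps))
  expect_lt(abs(res$null_sd - pop_sd), 3 * pop_sd / sqrt(2 * (res$n_reps - 1)))
  expect_equal(res$z, (res$observed - res$null_mean) / res$null_sd)
})

test_that("ses_mpd flags a degenerate null when sample equals pool", {
  tr <- ape::rtree(5)
  d <- patristic_distances(tr)
  res <- ses_mpd(rownames(d), d, rownames(d), n_reps = 99, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
  expect_false(res$significant)
})

test_that("ses_mpd is reproducible under a fixed seed and rejects small pools", {
  tr <- ape::rtree(8)
  d <- patristic_distances(tr)
  r1 <- ses_mpd(rownames(d)[1:3], d, rownames(d), n_reps = 199, seed = 7)
  r2 <- ses_mpd(rownames(d)[1:3], d, rownames(d), n_reps = 199, seed = 7)
  expect_identical(r1, r2)
  expect_error(ses_mpd(rownames(d)[1:5], d, rownames(d)[1:3]), "Pool smaller")
})

test_that("clade-restricted samples are detected as phylogenetically clustered", {
  set.seed(46)
  cfg <- small_cfg(clustering_mode = "clade", n_vt = 40L,
                   site_richness = c(5L, 12L))
  ref <- simulate_reference(cfg)
  d <- patristic_distances(ref$tree)
  hits <- 0L; n_rep <- 30L
  for (r in seq_len(n_rep)) {
    cm <- simulate_communities(ref, cfg, seed = r)
    taxa <- cm$comm$vt_id[cm$comm$site == "B"]
    res <- ses_mpd(taxa, d, ref$refs$vt_id, n_reps = 199, seed = r + 1000)
    if (!is.na(res$z) && res$z < -1.96) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
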