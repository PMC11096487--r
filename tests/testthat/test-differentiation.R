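test_that("distance matrix counts differing characters with pairwise deletion", {
  expect_equal(unname(sequence_distance_matrix(c(a = "ACGT", b = "ACGT"))[1, 2]), 0)
  expect_equal(unname(sequence_distance_matrix(c(a = "ACGT", b = "ACTT"))[1, 2]), 1)
  seqs <- rand_seqs(10, 50, seed = 31)
  substr(seqs[3], 10, 12) <- "N-N"
  d <- sequence_distance_matrix(new_alignment(seqs), include_indel_chars = FALSE)
  expect_equal(unname(d), oracle_dist(seqs))
  expect_equal(diag(d), setNames(rep(0, 10), names(seqs)))
  expect_true(isSymmetric(d))
  # indel characters add steps: one shared 2-site gap event = 1 step
  d2 <- sequence_distance_matrix(c(a = "AC--T", b = "ACGGT"))
  expect_equal(unname(d2[1, 2]), 1)
})

test_that("pairwise Phi_ST is 1 for fixed differences and ~0 under panmixia", {
  s1 <- paste0(rep("A", 40), collapse = "")
  s2 <- paste0(c(rep("G", 5), rep("A", 35)), collapse = "")
  r <- pairwise_phist(rep(s1, 5), rep(s2, 5), n_perm = 99, seed = 1)
  expect_equal(r$phi_st, 1)
  expect_lt(r$p, 0.05)
  # two samples from one panmictic pool
  set.seed(42)
  phis <- replicate(20, {
    pool <- rand_seqs(16, 40, seed = sample.int(1e6, 1))
    pairwise_phist(pool[1:8], pool[9:16])$phi_st
  })
  expect_lt(median(abs(phis)), 0.1)
})

test_that("pairwise Phi_ST equals the Phi_ST matrix entry (full AMOVA route)", {
  seqs <- rand_seqs(12, 30, seed = 7)
  map <- toy_map(names(seqs), rep(c("P1", "P2"), each = 6), "tx")
  pm <- phist_matrix(new_alignment(seqs), map)
  pp <- pairwise_phist(seqs[1:6], seqs[7:12])
  expect_equal(unname(pm["P1", "P2"]), pp$phi_st, tolerance = 1e-12)
})

test_that("AMOVA recovers forced partitions and percent sums to 100", {
  s1 <- paste0(rep("A", 50), collapse = "")
  s2 <- paste0(c(rep("C", 10), rep("A", 40)), collapse = "")
  seqs <- setNames(c(rep(s1, 6), rep(s2, 6)), paste0("i", 1:12))
  map <- toy_map(names(seqs), rep(c("p1", "p2", "p3", "p4"), each = 3),
                 rep(c("t1", "t2"), each = 6))
  am <- amova(new_alignment(seqs), map, n_perm = 0)
  expect_equal(unname(am$phi["Phi_CT"]), 1)
  expect_equal(am$table$pct[1], 100)
  expect_equal(sum(am$table$pct), 100, tolerance = 1e-9)
  # all sequences identical: all components zero
  seqs0 <- setNames(rep(s1, 12), names(seqs))
  am0 <- amova(new_alignment(seqs0), map, n_perm = 0)
  expect_equal(am0$table$sigma2, rep(0, 3))
})

test_that("haploid AMOVA components equal the brute-force three-level oracle", {
  for (i in 1:5) {
    seqs <- rand_seqs(12, 25, seed = 40 + i)
    taxon <- rep(c("t1", "t2"), each = 6)
    pop <- c(rep(c("p1", "p2"), each = 3), rep(c("p3", "p4", "p5"), each = 2))
    map <- toy_map(names(seqs), pop, taxon)
    am <- amova(new_alignment(seqs), map, n_perm = 0,
                include_indel_chars = FALSE)
    d2 <- sequence_distance_matrix(new_alignment(seqs),
                                   include_indel_chars = FALSE)
    oc <- oracle_amova3(d2, taxon, pop)
    expect_equal(am$table$sigma2, unname(oc), tolerance = 1e-10)
    expect_equal(sum(am$table$pct), 100, tolerance = 1e-9)
  }
})

test_that("diploid four-level AMOVA yields Phi_IS and consistent percentages", {
  fx <- make_fixture(fixture_recipe("taiwan_its"), seed = 5)
  # subset two populations per taxon to keep the instance small
  keep_pops <- c("T", "N", "HSH", "LA")
  keep <- fx$map$population %in% keep_pops
  map <- as_sample_map(as.data.frame(fx$map[keep, ]))
  recs <- individual_stems(names(fx$alignment$seq)) %in% map$sample_id
  aln <- new_alignment(fx$alignment$seq[recs], "diploid_phased")
  am <- amova(aln, map, n_perm = 50, seed = 3)
  expect_equal(nrow(am$table), 4L)
  expect_true("Phi_IS" %in% names(am$phi))
  expect_equal(sum(am$table$pct), 100, tolerance = 1e-9)
  expect_gt(am$table$pct[1], am$table$pct[2])  # taxa dominate the variance
  expect_true(all(am$p[c("Phi_CT", "Phi_SC", "Phi_ST")] <= 1))
})

test_that("three-taxon coalescent data put more variance among taxa than among populations", {
  cfg <- sim_config(N = c(MA = 150, TW = 150, PH = 150), T1 = 3000, T2 = 6000,
                    M2N = c(MA_TW = 0, TW_PH = 0))
  sm <- simulate_marker(cfg, "cp", c(MA = 8, TW = 8, PH = 8), seed = 11)
  # split each deme sample into two populations
  map <- as.data.frame(sm$map)
  map$population <- paste0(map$population,
                           rep(c("a", "b"), length.out = nrow(map)))
  am <- amova(sm$alignment, as_sample_map(map), n_perm = 0)
  expect_gt(am$table$pct[1], am$table$pct[2])
})

test_that("permutation p-values are valid under the null", {
  reps <- 200
  set.seed(9)
  pvals <- replicate(reps, {
    pool <- rand_seqs(16, 30, seed = sample.int(1e6, 1))
    pairwise_phist(pool[1:8], pool[9:16], n_perm = 99,
                   seed = sample.int(1e6, 1))$p
  })
  rate <- mean(pvals <= 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  # p-values spread over (0, 1] rather than piling near 0
  expect_gt(mean(pvals), 0.3)
})

test_that("neighbour joining recovers additive trees and permutes cleanly", {
  set.seed(13)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length + 0.1
  d <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)
  # label permutation only permutes leaves
  perm <- sample(nrow(d))
  rec2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(rec, rec2)), 0)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  # negative inputs tolerated, branch lengths clamped at zero
  d2 <- d; d2[1, 2] <- d2[2, 1] <- -0.05
  expect_true(all(nj_tree(d2)$edge.length >= 0))
})
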