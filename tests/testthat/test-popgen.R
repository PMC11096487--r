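test_that("haplotype diversity matches closed forms and is count-order invariant", {
  expect_equal(haplotype_diversity(c(5)), 0)
  expect_equal(haplotype_diversity(c(2, 2)), 4 / 3 * 0.5)
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_equal(haplotype_diversity(c(3, 7, 2)), haplotype_diversity(c(7, 2, 3)))
  expect_error(haplotype_diversity(c(1)), "at least 2")
})

test_that("nucleotide diversity matches definition and brute force", {
  s1 <- paste0(rep("A", 100), collapse = "")
  s2 <- paste0(c("C", "C", rep("A", 98)), collapse = "")
  expect_equal(nucleotide_diversity(c(a = s1, b = s2)), 0.02)
  expect_equal(nucleotide_diversity(c(a = s1, b = s1, c = s1)), 0)
  seqs <- rand_seqs(4, 60, seed = 21)
  substr(seqs[1], 5, 7) <- "--N"  # exercise pairwise deletion
  expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs))
  expect_equal(nucleotide_diversity(seqs), nucleotide_diversity(rev(seqs)))
})

test_that("Watterson's theta uses harmonic-number scaling", {
  # n = 5 sequences, 3 segregating sites, L = 100
  base <- paste0(rep("A", 100), collapse = "")
  v <- function(pos) {
    s <- strsplit(base, "")[[1]]; s[pos] <- "G"; paste0(s, collapse = "")
  }
  seqs <- c(a = v(1), b = v(2), c = v(3), d = base, e = base)
  a4 <- sum(1 / 1:4)
  expect_equal(watterson_theta(seqs), 3 / (a4 * 100))
  expect_equal(watterson_theta(c(x = base, y = base)), 0)
  # n = 2: theta_W equals pi exactly on complete data
  two <- rand_seqs(2, 80, seed = 3)
  expect_equal(watterson_theta(two), nucleotide_diversity(two))
})

test_that("F_IS has the right sign, null value and oracle agreement", {
  all_het <- matrix(rep(c("A", "B"), 10), ncol = 2, byrow = TRUE)
  expect_lt(fis(all_het), 0)
  # genotype counts at exact HWE proportions: f close to 0
  hwe_g <- rbind(matrix(rep(c("A", "A"), 50), ncol = 2, byrow = TRUE),
                 matrix(rep(c("A", "B"), 100), ncol = 2, byrow = TRUE),
                 matrix(rep(c("B", "B"), 50), ncol = 2, byrow = TRUE))
  expect_lt(abs(fis(hwe_g)), 1e-2)
  expect_true(is.na(fis(matrix("A", 10, 2))))
  for (i in 1:20) {
    set.seed(100 + i)
    k <- sample(2:4, 1)
    g <- matrix(sample(LETTERS[1:k], 2 * sample(5:30, 1), replace = TRUE),
                ncol = 2)
    if (length(unique(as.vector(g))) < 2) next
    expect_equal(fis(g), oracle_fis(g), tolerance = 1e-12)
  }
})

test_that("HWE exact enumeration reproduces the two-heterozygote case", {
  g <- matrix(c("A", "B", "A", "B"), nrow = 2, byrow = TRUE)
  r <- hwe_exact_test(g)
  expect_equal(r$method, "enumeration")
  expect_equal(r$p, 1)
  # monomorphic: degenerate, p = 1
  r2 <- hwe_exact_test(matrix("A", 5, 2))
  expect_equal(r2$p, 1)
  expect_equal(r2$method, "degenerate")
})

test_that("switch chain agrees with enumeration on all small tables", {
  # all allele-count configurations with n <= 6 individuals, 2-3 alleles;
  # observed tables built by seeded random pairing of the gene copies
  for (n in 3:6) {
    for (k in 2:3) {
      parts <- utils::combn(2 * n - 1, k - 1)
      for (ci in seq_len(ncol(parts))) {
        cuts <- c(0, parts[, ci], 2 * n)
        m <- diff(cuts)
        if (any(m < 1)) next
        copies <- rep(LETTERS[1:k], m)
        set.seed(n * 100 + k * 10 + ci)
        g <- matrix(sample(copies), ncol = 2)
        e <- hwe_exact_test(g)
        expect_equal(e$method, "enumeration")
        ch <- hwe_exact_test(g, enum_limit = 1, chain_steps = 2e4,
                             burn_in = 2e3, seed = 77)
        expect_lt(abs(ch$p - e$p), max(3 * ch$se, 0.02))
      }
    }
  }
})

test_that("exact test holds its nominal size on Hardy-Weinberg fixtures", {
  gr <- data.frame(taxon = "t", population = "P", haplogroup = "hg",
                   n_seqs = 50L)
  rec <- new_fixture_recipe(gr, "diploid_phased", n_haplotypes = 2,
                            pairing = "random")
  reps <- 500
  rej <- 0
  for (i in seq_len(reps)) {
    fx <- make_fixture(rec, seed = i)
    hap <- collapse_haplotypes(fx$alignment, fx$map)
    p <- hwe_exact_test(its_genotypes(hap))$p
    if (p < 0.05) rej <- rej + 1
  }
  # conditional exact tests are valid (often conservative)
  expect_lte(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("heterozygote-excess fixtures are flagged after Bonferroni", {
  gr <- data.frame(taxon = "philippine", population = "AP",
                   haplogroup = "hg", n_seqs = 40L)
  rec <- new_fixture_recipe(gr, "diploid_phased", n_haplotypes = 2,
                            centre_share = 0.5, pairing = "het_excess")
  fx <- make_fixture(rec, seed = 1)
  hap <- collapse_haplotypes(fx$alignment, fx$map)
  g <- its_genotypes(hap)
  expect_lt(fis(g), -0.5)
  res <- hwe_exact_test(g)
  # significant even against a table-wide correction across 11 populations
  bc <- bonferroni(c(res$p, rep(0.5, 10)))
  expect_true(bc$significant[1])
})

test_that("Bonferroni thresholds and adjustment follow alpha/k", {
  b <- bonferroni(rep(0.01, 19), alpha = 0.05)
  expect_equal(b$threshold, 0.05 / 19)
  expect_equal(bonferroni(0.03)$p_adjusted, 0.03)
  expect_true(bonferroni(c(0, 0.9), alpha = 0.05)$significant[1])
  expect_equal(bonferroni(c(0.2, 0.01), alpha = 0.05)$p_adjusted,
               c(0.4, 0.02))
})

test_that("diversity table summarises per population with x1000 scaling", {
  fx <- make_fixture(fixture_recipe("taiwan_cp"), seed = 2)
  tab <- diversity_table(fx$alignment, fx$map)
  expect_equal(sum(tab$n), 246)
  expect_true(all(tab$Hd >= 0 & tab$Hd <= 1))
  tab1000 <- diversity_table(fx$alignment, fx$map, scale_1000 = TRUE)
  expect_equal(tab1000$pi, tab$pi * 1000)
})
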