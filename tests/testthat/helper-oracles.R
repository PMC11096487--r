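# Independent oracle implementations used to cross-check the package's
# estimators on small instances. These deliberately use naive formulations
# (double loops, textbook formulas) distinct from the package code paths.

rand_seqs <- function(n, L, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  s <- vapply(seq_len(n), function(i)
    paste0(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(s) <- paste0("s", seq_len(n))
  s
}

# brute-force mean pairwise difference per comparable site
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  m[!(m %in% c("A", "C", "G", "T"))] <- NA
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  mean(vals)
}

# naive pairwise difference count with pairwise deletion (substitutions only)
oracle_dist <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  m[!(m %in% c("A", "C", "G", "T"))] <- NA
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    d[i, j] <- sum(m[i, ok] != m[j, ok])
  }
  d
}

# Weir-Cockerham single-population f via explicit within/between-individual
# mean squares on allele indicators (textbook ANOVA route)
oracle_fis <- function(genotypes) {
  n <- nrow(genotypes)
  alleles <- sort(unique(as.vector(genotypes)))
  if (length(alleles) < 2) return(NA_real_)
  MSG <- 0; MSI <- 0
  for (a in alleles) {
    x <- (genotypes == a) * 1
    xbar <- rowMeans(x)
    p <- mean(x)
    MSG <- MSG + sum((x - xbar)^2) / n
    MSI <- MSI + 2 * sum((xbar - p)^2) / (n - 1)
  }
  1 - 2 * MSG / (MSI + MSG)
}

# three-level AMOVA components via the closed-form Excoffier coefficient
# formulas, computed with definitional double-loop sums of squares
oracle_amova3 <- function(d2, taxon, pop) {
  N <- nrow(d2)
  ss_set <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  pops <- unique(pop); taxa <- unique(taxon)
  pop_taxon <- sapply(pops, function(p) taxon[pop == p][1])
  ss_tot <- ss_set(1:N)
  ss_wp <- sum(sapply(pops, function(p) ss_set(which(pop == p))))
  ss_wg <- sum(sapply(taxa, function(g) ss_set(which(taxon == g))))
  SSD_ag <- ss_tot - ss_wg
  SSD_ap <- ss_wg - ss_wp
  SSD_wp <- ss_wp
  G <- length(taxa); P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  N_g <- sapply(taxa, function(g) sum(taxon == g))
  sum_np2_over_Ng <- sum(sapply(taxa, function(g)
    sum(n_p[pop_taxon == g]^2) / N_g[g]))
  n_c <- (N - sum_np2_over_Ng) / (P - G)
  n_c2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  n_c3 <- (N - sum(N_g^2) / N) / (G - 1)
  s2_c <- SSD_wp / (N - P)
  s2_b <- (SSD_ap / (P - G) - s2_c) / n_c
  s2_a <- (SSD_ag / (G - 1) - s2_c - n_c2 * s2_b) / n_c3
  c(among_taxa = s2_a, among_pops = s2_b, within = s2_c)
}

# minimum spanning tree weight by naive Prim's algorithm
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  in_tree <- c(1)
  w <- 0
  while (length(in_tree) < n) {
    best <- Inf; bj <- NA
    for (i in in_tree) for (j in setdiff(1:n, in_tree)) {
      if (d[i, j] < best) { best <- d[i, j]; bj <- j }
    }
    w <- w + best
    in_tree <- c(in_tree, bj)
  }
  w
}

# deterministic small sample map for ad-hoc alignments
toy_map <- function(ids, population, taxon, ploidy = 1L) {
  as_sample_map(data.frame(sample_id = ids, population = population,
                           taxon = taxon, ploidy = ploidy,
                           stringsAsFactors = FALSE))
}
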