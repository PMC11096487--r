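#' Weir-Cockerham inbreeding coefficient (single population)
#'
#' Multi-allelic Weir & Cockerham f-hat for one population, combined across
#' alleles by summing variance components: for allele a with frequency p and
#' observed heterozygote proportion h (individuals carrying exactly one copy
#' of a), the between-individual component is
#' `b = n/(n-1) * (p(1-p) - (2n-1)/(4n) * h)` and the within-individual
#' component is `c = h/2`; `f = 1 - sum(c) / sum(b + c)`. Zero indicates
#' Hardy-Weinberg proportions, negative values heterozygote excess.
#'
#' @param genotypes n x 2 matrix of allele labels (one row per individual,
#'   unordered).
#' @return f-hat, or `NA` if the sample is monomorphic (undefined).
#' @export
fis <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != 2L) stop("genotypes must be an n x 2 matrix")
  n <- nrow(genotypes)
  if (n < 2L) stop("need at least 2 individuals")
  alleles <- sort(unique(as.vector(genotypes)))
  if (length(alleles) < 2L) return(NA_real_)
  bsum <- 0; csum <- 0
  het <- genotypes[, 1L] != genotypes[, 2L]
  for (a in alleles) {
    p <- mean(genotypes == a)
    h <- mean(het & (genotypes[, 1L] == a | genotypes[, 2L] == a))
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    bsum <- bsum + b
    csum <- csum + h / 2
  }
  1 - csum / (bsum + csum)
}

# Conditional log-probability of a genotype count table given allele counts:
# log[ n! 2^h prod(m_a!) / ((2n)! prod(n_ij!)) ].
hwe_table_logprob <- function(G) {
  n <- sum(G)
  # allele counts from the upper-triangular representation:
  # rowSums + colSums gives 2*G[a,a] + sum of heterozygote cells touching a
  m <- rowSums(G) + colSums(G)
  h <- n - sum(diag(G))
  lfactorial(n) + h * log(2) + sum(lfactorial(m)) -
    lfactorial(2 * n) - sum(lfactorial(G[upper.tri(G, diag = TRUE)]))
}

# Genotype count matrix (upper triangular, i <= j) from an n x 2 matrix of
# allele indices 1..k.
genotype_counts <- function(al, k) {
  G <- matrix(0L, k, k)
  i <- pmin(al[, 1L], al[, 2L])
  j <- pmax(al[, 1L], al[, 2L])
  for (r in seq_along(i)) G[i[r], j[r]] <- G[i[r], j[r]] + 1L
  G
}

# Enumerate all genotype tables compatible with allele counts m
# (vector of length k, sum 2n). Returns a numeric vector of table
# log-probabilities, or NULL if more than max_tables tables exist.
enumerate_hwe_tables <- function(m, max_tables = 1e5) {
  k <- length(m)
  logps <- numeric(0)
  count <- 0L
  overflow <- FALSE
  G <- matrix(0L, k, k)
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  rec <- function(ci, rem) {
    if (overflow) return()
    if (ci > nrow(cells)) {
      if (all(rem == 0L)) {
        count <<- count + 1L
        if (count > max_tables) { overflow <<- TRUE; return() }
        logps[count] <<- hwe_table_logprob(G)
      }
      return()
    }
    i <- cells[ci, 1L]; j <- cells[ci, 2L]
    last_for_i <- (j == k)
    maxv <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:maxv) {
      G[i, j] <<- v
      rem2 <- rem
      rem2[i] <- rem2[i] - v * (if (i == j) 2L else 1L)
      if (i != j) rem2[j] <- rem2[j] - v
      if (last_for_i && rem2[i] != 0L) next
      rec(ci + 1L, rem2)
      if (overflow) break
    }
    G[i, j] <<- 0L
  }
  rec(1L, as.integer(m))
  if (overflow) NULL else logps[seq_len(count)]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: the p-value is the total probability, under the
#' distribution of genotype tables conditioned on the observed allele counts,
#' of tables no more probable than the observed one. When the table universe
#' is small (at most `enum_limit` tables) it is computed by full enumeration;
#' otherwise it is estimated with a Guo-Thompson-style switch Markov chain:
#' a random walk that swaps single allele copies between random individuals,
#' whose stationary law on pairings induces the conditional table
#' distribution.
#'
#' @param genotypes n x 2 matrix of allele labels.
#' @param chain_steps Markov chain length after burn-in (default 1e6).
#' @param burn_in discarded initial steps (default 1e4).
#' @param seed integer seed for the chain (required when the chain is used).
#' @param enum_limit maximum table universe for exact enumeration.
#' @return object of class `hwe_result`: list with `p` (p-value), `se`
#'   (batch-means Monte-Carlo standard error; 0 for enumeration), `method`
#'   (`"enumeration"`, `"chain"` or `"degenerate"`), `F_IS`,
#'   `n_individuals`, `n_alleles` and the chain settings.
#' @export
hwe_exact_test <- function(genotypes, chain_steps = 1e6, burn_in = 1e4,
                           seed = NULL, enum_limit = 1e5) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  alleles <- sort(unique(as.vector(genotypes)))
  k <- length(alleles)
  f <- fis(genotypes)
  base <- list(F_IS = f, n_individuals = n, n_alleles = k,
               chain_steps = chain_steps, burn_in = burn_in, seed = seed)
  if (k < 2L) {
    out <- c(list(p = 1, se = 0, method = "degenerate"), base)
    class(out) <- "hwe_result"
    return(out)
  }
  al <- matrix(match(genotypes, alleles), ncol = 2L)
  G_obs <- genotype_counts(al, k)
  lp_obs <- hwe_table_logprob(G_obs)
  m <- rowSums(G_obs) + colSums(G_obs)
  tol <- 1e-9
  logps <- enumerate_hwe_tables(m, max_tables = enum_limit)
  if (!is.null(logps)) {
    p <- sum(exp(logps[logps <= lp_obs + tol]))
    p <- min(1, p)
    out <- c(list(p = p, se = 0, method = "enumeration"), base)
    class(out) <- "hwe_result"
    return(out)
  }
  if (is.null(seed)) stop("seed is required for the Markov chain estimate")
  set.seed(seed)
  p <- hwe_switch_chain(al, k, lp_obs, chain_steps, burn_in, tol)
  out <- c(list(p = p$p, se = p$se, method = "chain"), base)
  class(out) <- "hwe_result"
  out
}

# Allele-switch Markov chain over genotype tables with fixed allele counts.
# A state is a pairing of the 2n gene copies into individuals; swapping one
# allele copy between two random individuals is a symmetric random walk on
# pairings, whose uniform stationary law induces exactly the conditional
# distribution of tables given allele counts (every swap is accepted; only
# the table log-probability is tracked for the p-value indicator).
hwe_switch_chain <- function(al, k, lp_obs, chain_steps, burn_in, tol) {
  n <- nrow(al)
  G <- genotype_counts(al, k)
  cur_lp <- hwe_table_logprob(G)
  total <- burn_in + chain_steps
  hits <- logical(chain_steps)
  us <- sample.int(n, total, replace = TRUE)
  vs <- sample.int(n, total, replace = TRUE)
  pus <- sample.int(2L, total, replace = TRUE)
  pvs <- sample.int(2L, total, replace = TRUE)
  for (s in seq_len(total)) {
    u <- us[s]; v <- vs[s]
    if (u != v) {
      pu <- pus[s]; pv <- pvs[s]
      a <- al[u, pu]; b <- al[v, pv]
      if (a != b) {
        gu_i <- min(al[u, ]); gu_j <- max(al[u, ])
        gv_i <- min(al[v, ]); gv_j <- max(al[v, ])
        # genotypes after swapping allele copies a and b
        nu <- al[u, ]; nu[pu] <- b
        nv <- al[v, ]; nv[pv] <- a
        nu_i <- min(nu); nu_j <- max(nu)
        nv_i <- min(nv); nv_j <- max(nv)
        dlp <- 0
        dlp <- dlp + log(G[gu_i, gu_j]); G[gu_i, gu_j] <- G[gu_i, gu_j] - 1L
        dlp <- dlp + log(G[gv_i, gv_j]); G[gv_i, gv_j] <- G[gv_i, gv_j] - 1L
        G[nu_i, nu_j] <- G[nu_i, nu_j] + 1L; dlp <- dlp - log(G[nu_i, nu_j])
        G[nv_i, nv_j] <- G[nv_i, nv_j] + 1L; dlp <- dlp - log(G[nv_i, nv_j])
        dh <- (nu_i != nu_j) + (nv_i != nv_j) - (gu_i != gu_j) - (gv_i != gv_j)
        dlp <- dlp + dh * log(2)
        al[u, ] <- nu; al[v, ] <- nv
        cur_lp <- cur_lp + dlp
      }
    }
    if (s > burn_in) hits[s - burn_in] <- (cur_lp <= lp_obs + tol)
  }
  nb <- 50L
  bsize <- chain_steps %/% nb
  bm <- vapply(seq_len(nb), function(b)
    mean(hits[seq.int((b - 1L) * bsize + 1L, b * bsize)]), numeric(1))
  list(p = mean(hits), se = stats::sd(bm) / sqrt(nb))
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("HWE exact test (", x$method, "): p = ", format(x$p, digits = 4),
      if (x$method == "chain") paste0(" (MC se ", format(x$se, digits = 2), ")"),
      ", F_IS = ", format(x$F_IS, digits = 3),
      ", n = ", x$n_individuals, ", alleles = ", x$n_alleles, "\n", sep = "")
  invisible(x)
}

#' Bonferroni correction
#'
#' Table-wide control at level `alpha` across `k` tests: the per-test
#' threshold is `alpha/k` and the adjusted p-value is `min(1, k*p)`.
#'
#' @param p_values numeric vector of raw p-values.
#' @param alpha table-wide error rate (default 0.05).
#' @return list with `threshold`, `p_adjusted` and logical `significant`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  k <- length(p_values)
  if (k < 1L) stop("need at least one p-value")
  p_adj <- stats::p.adjust(p_values, method = "bonferroni")
  list(threshold = alpha / k, p_adjusted = p_adj,
       significant = p_values < alpha / k)
}

#' Per-individual genotypes from a phased-diploid haplotype table
#'
#' Treats the two ITS haplotypes of each individual as the two alleles of a
#' single biparentally inherited locus.
#'
#' @param haptable a `haplotype_table` built from a `diploid_phased`
#'   alignment.
#' @param population optional population code to subset to.
#' @return n x 2 character matrix of haplotype ids, rownames = individuals.
#' @export
its_genotypes <- function(haptable, population = NULL) {
  if (haptable$ploidy_mode != "diploid_phased")
    stop("genotypes require a diploid_phased haplotype table")
  a <- haptable$assignment
  if (!is.null(population)) a <- a[a$population == population, , drop = FALSE]
  inds <- unique(a$individual)
  g <- t(vapply(inds, function(ind)
    sort(a$haplotype_id[a$individual == ind]), character(2)))
  rownames(g) <- inds
  g
}

#' Per-population HWE summary for a phased-diploid marker
#'
#' Runs [fis()] and [hwe_exact_test()] for every population and applies a
#' Bonferroni correction across populations.
#'
#' @param haptable a `haplotype_table` from a phased diploid alignment.
#' @param alpha table-wide error rate.
#' @param seed integer seed forwarded to the exact-test chain.
#' @param ... further arguments passed to [hwe_exact_test()].
#' @return data.frame with one row per population: `population`, `n`,
#'   `n_alleles`, `F_IS`, `p_raw`, `p_bonferroni`, `significant`, `method`.
#' @export
hwe_table <- function(haptable, alpha = 0.05, seed = 1L, ...) {
  pops <- colnames(haptable$counts)
  rows <- lapply(pops, function(p) {
    g <- its_genotypes(haptable, p)
    res <- hwe_exact_test(g, seed = seed, ...)
    data.frame(population = p, n = nrow(g), n_alleles = res$n_alleles,
               F_IS = res$F_IS, p_raw = res$p, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bc <- bonferroni(out$p_raw, alpha = alpha)
  out$p_bonferroni <- bc$p_adjusted
  out$significant <- bc$significant
  out
}
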