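#' Pairwise character-difference distance matrix
#'
#' Counts differing characters between every pair of sequences
#' (substitutions plus, optionally, simple-indel-coded gap characters), with
#' pairwise deletion of missing data: a site contributes only when both
#' sequences carry an unambiguous state there. Gap and N nucleotide positions
#' are missing for the substitution characters; an `NA` indel state is
#' missing for that indel character.
#'
#' @param x a `yew_alignment`, a `haplotype_table` (distances between its
#'   haplotype sequences) or a character vector of equal-length sequences.
#' @param include_indel_chars add one character per coded gap event
#'   (default `TRUE`).
#' @return symmetric numeric matrix of difference counts, zero diagonal,
#'   labelled by record (or haplotype) ids.
#' @export
sequence_distance_matrix <- function(x, include_indel_chars = TRUE) {
  if (inherits(x, "haplotype_table")) {
    aln <- new_alignment(stats::setNames(x$haplotypes$sequence,
                                         x$haplotypes$haplotype_id))
    return(sequence_distance_matrix(aln, include_indel_chars))
  }
  if (!inherits(x, "yew_alignment")) x <- new_alignment(x)
  m <- seq_char_matrix(x)
  states <- list(m)
  if (include_indel_chars) {
    ind <- code_indels_simple(x)
    if (ncol(ind$states) > 0L)
      states <- c(states, list(matrix(as.character(ind$states),
                                      nrow = nrow(ind$states))))
  }
  M <- do.call(cbind, states)
  n <- nrow(M)
  lab <- names(x$seq)
  # matches[i,j] = number of sites where i and j share the same non-missing
  # state; comparable[i,j] = number of sites non-missing in both.
  B <- (!is.na(M)) * 1
  comparable <- B %*% t(B)
  vals <- unique(as.vector(M))
  vals <- vals[!is.na(vals)]
  matches <- matrix(0, n, n)
  for (v in vals) {
    Iv <- (M == v & !is.na(M)) * 1
    matches <- matches + Iv %*% t(Iv)
  }
  d <- comparable - matches
  diag(d) <- 0
  dimnames(d) <- list(lab, lab)
  d
}

# Sum over cells of a grouping factor of (within-cell pairwise d2 sums
# divided by cell size): SS(f) = sum_g [ sum_{i<j in g} d2_ij / n_g ].
ss_within <- function(d2, fac) {
  fac <- as.character(fac)
  A <- rowsum(d2, fac)                 # groups x N
  B <- rowsum(t(A), fac)               # groups x groups (cell pair sums)
  ng <- as.vector(table(fac)[rownames(B)])
  sum(diag(as.matrix(B)) / (2 * ng))
}

# Variance components of a fully nested design on squared distances.
# strata: data.frame of factors, one column per level, ordered from the top
# (e.g. taxon) down (e.g. individual); rows = units (sequences/gene copies).
# Returns df, SSD, MS, sigma2 per stratum (top .. within).
amova_components <- function(d2, strata) {
  N <- nrow(d2)
  K <- ncol(strata)
  # nest lower levels inside upper ones so labels are unique per cell
  nested <- strata
  for (k in seq_len(K)) {
    nested[[k]] <- if (k == 1L) as.character(strata[[1L]]) else
      paste(nested[[k - 1L]], as.character(strata[[k]]), sep = "\r")
  }
  ss_total <- sum(d2) / (2 * N)
  ss_lvl <- vapply(seq_len(K), function(k) ss_within(d2, nested[[k]]),
                   numeric(1))
  a <- vapply(seq_len(K), function(k) length(unique(nested[[k]])), integer(1))
  SSD <- numeric(K + 1L)
  df <- numeric(K + 1L)
  SSD[1L] <- ss_total - ss_lvl[1L]
  df[1L] <- a[1L] - 1L
  if (K >= 2L) for (k in 2:K) {
    SSD[k] <- ss_lvl[k - 1L] - ss_lvl[k]
    df[k] <- a[k] - a[k - 1L]
  }
  SSD[K + 1L] <- ss_lvl[K]
  df[K + 1L] <- N - a[K]
  # EMS coefficients: coef[k, m] multiplies sigma2 of level m in E[SSD_k];
  # S_m(w) = sum over level-m cells inside w of n_cell^2.
  sizes <- lapply(seq_len(K), function(m) table(nested[[m]]))
  S_in <- function(m, fac_above) {
    # sum of level-m cell sizes squared within each cell of fac_above
    nm <- nested[[m]]
    if (is.null(fac_above)) {
      return(stats::setNames(sum(as.numeric(sizes[[m]])^2), "all"))
    }
    first <- !duplicated(nm)
    cell_above <- fac_above[first]
    cell_n <- as.numeric(sizes[[m]][nm[first]])
    tapply(cell_n^2, cell_above, sum)
  }
  n_of <- function(fac) table(fac)
  coef <- matrix(0, nrow = K, ncol = K)
  for (k in seq_len(K)) {
    fac_k <- nested[[k]]
    fac_up <- if (k == 1L) NULL else nested[[k - 1L]]
    n_k <- n_of(fac_k)
    n_up <- if (is.null(fac_up)) stats::setNames(N, "all") else n_of(fac_up)
    for (m in k:K) {
      Sm_k <- S_in(m, fac_k)
      Sm_up <- S_in(m, fac_up)
      coef[k, m] <- sum(as.numeric(Sm_k) / as.numeric(n_k[names(Sm_k)])) -
        sum(as.numeric(Sm_up) / as.numeric(n_up[names(Sm_up)]))
    }
  }
  sigma2 <- numeric(K + 1L)
  sigma2[K + 1L] <- if (df[K + 1L] > 0) SSD[K + 1L] / df[K + 1L] else 0
  for (k in K:1) {
    resid <- SSD[k] - df[k] * sigma2[K + 1L]
    if (k < K) for (m in (k + 1L):K) resid <- resid - coef[k, m] * sigma2[m]
    sigma2[k] <- if (coef[k, k] > 0) resid / coef[k, k] else NA_real_
  }
  list(df = df, SSD = SSD, MS = ifelse(df > 0, SSD / df, NA), sigma2 = sigma2)
}

# Phi indices from nested variance components (top .. within).
phi_from_sigma <- function(sigma2) {
  K <- length(sigma2) - 1L
  tot <- sum(sigma2)
  if (K == 1L) {
    return(c(Phi_ST = sigma2[1L] / tot))
  }
  if (K == 2L) {
    return(c(Phi_CT = sigma2[1L] / tot,
             Phi_SC = sigma2[2L] / sum(sigma2[2:3]),
             Phi_ST = sum(sigma2[1:2]) / tot))
  }
  if (K == 3L) {
    return(c(Phi_CT = sigma2[1L] / tot,
             Phi_SC = sigma2[2L] / sum(sigma2[2:4]),
             Phi_ST = sum(sigma2[1:3]) / tot,
             Phi_IS = sigma2[3L] / sum(sigma2[3:4])))
  }
  stop("unsupported number of levels")
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Excoffier-style AMOVA on squared inter-haplotype distances (difference
#' counts are used directly as squared Euclidean distances). For a haploid
#' marker the hierarchy is taxon / population / within populations
#' (indices Phi_CT, Phi_SC, Phi_ST); for a phased diploid marker a
#' within-individual level is added (plus Phi_IS). Significance of each index
#' is assessed by permutation: populations among taxa for Phi_CT, units among
#' populations within taxa for Phi_SC, units among all populations for
#' Phi_ST, and gene copies among individuals within populations for Phi_IS
#' (units are individuals for diploid data, sequences for haploid data).
#' Permutation p-values use `(count(perm >= obs) + 1) / (n_perm + 1)`.
#' Negative variance components are retained and reported.
#'
#' @param alignment a `yew_alignment`.
#' @param map a `sample_map`.
#' @param n_perm number of permutations per index (0 to skip tests).
#' @param seed integer seed for the permutations.
#' @param include_indel_chars passed to [sequence_distance_matrix()].
#' @return object of class `yew_amova`: list with `table` (source of
#'   variation, df, SSD, variance component `sigma2`, percent of variation),
#'   `phi` (named vector), `p` (permutation p-values), `n_perm`, `seed`.
#' @export
amova <- function(alignment, map, n_perm = 2000, seed = 1L,
                  include_indel_chars = TRUE) {
  check_alignment_map(alignment, map)
  diploid <- alignment$ploidy_mode == "diploid_phased"
  ids <- names(alignment$seq)
  inds <- individual_stems(ids)
  mrow <- match(inds, map$sample_id)
  taxon <- map$taxon[mrow]
  pop <- map$population[mrow]
  if (length(unique(taxon)) < 2L)
    stop("AMOVA requires at least 2 groups (taxa)")
  d2 <- sequence_distance_matrix(alignment, include_indel_chars)
  strata <- if (diploid)
    data.frame(taxon = taxon, population = pop, individual = inds,
               stringsAsFactors = FALSE)
  else data.frame(taxon = taxon, population = pop, stringsAsFactors = FALSE)
  comp <- amova_components(d2, strata)
  phi <- phi_from_sigma(comp$sigma2)
  # degenerate design guard: a taxon with a single population makes the
  # among-population permutation scheme for Phi_CT ill-defined
  pops_per_taxon <- tapply(pop, taxon, function(x) length(unique(x)))
  if (any(pops_per_taxon < 2L))
    warning("group(s) with a single population: ",
            paste(names(pops_per_taxon)[pops_per_taxon < 2L], collapse = ", "),
            "; Phi_CT permutation test may be weak")
  p <- rep(NA_real_, length(phi))
  names(p) <- names(phi)
  if (n_perm > 0L) {
    set.seed(seed)
    obs <- phi
    count <- stats::setNames(numeric(length(phi)), names(phi))
    # unit = individual (diploid) or sequence (haploid); copies of one
    # individual move together except for the Phi_IS scheme
    unit <- if (diploid) inds else ids
    u_first <- !duplicated(unit)
    u_pop <- pop[u_first]; u_taxon <- taxon[u_first]
    u_id <- unit[u_first]
    pop_taxon <- tapply(taxon, pop, function(x) x[1L])
    for (b in seq_len(n_perm)) {
      # Phi_CT: permute whole populations among taxa
      pt <- sample(as.vector(pop_taxon))
      names(pt) <- names(pop_taxon)
      st1 <- strata; st1$taxon <- pt[pop]
      s1 <- amova_components(d2, st1)$sigma2
      ph1 <- phi_from_sigma(s1)
      if (!is.na(ph1["Phi_CT"]) && ph1["Phi_CT"] >= obs["Phi_CT"] - 1e-12)
        count["Phi_CT"] <- count["Phi_CT"] + 1
      # Phi_SC: permute units among populations within taxa
      new_pop_sc <- u_pop
      for (tx in unique(u_taxon)) {
        sel <- u_taxon == tx
        new_pop_sc[sel] <- sample(u_pop[sel])
      }
      st2 <- strata
      st2$population <- new_pop_sc[match(unit, u_id)]
      s2 <- amova_components(d2, st2)$sigma2
      ph2 <- phi_from_sigma(s2)
      if (!is.na(ph2["Phi_SC"]) && ph2["Phi_SC"] >= obs["Phi_SC"] - 1e-12)
        count["Phi_SC"] <- count["Phi_SC"] + 1
      # Phi_ST: permute units among all populations (taxon follows pop)
      new_pop_st <- sample(u_pop)
      st3 <- strata
      st3$population <- new_pop_st[match(unit, u_id)]
      st3$taxon <- pop_taxon[st3$population]
      s3 <- amova_components(d2, st3)$sigma2
      ph3 <- phi_from_sigma(s3)
      if (!is.na(ph3["Phi_ST"]) && ph3["Phi_ST"] >= obs["Phi_ST"] - 1e-12)
        count["Phi_ST"] <- count["Phi_ST"] + 1
      # Phi_IS: permute gene copies among individuals within populations
      if (diploid) {
        st4 <- strata
        for (pp in unique(pop)) {
          sel <- which(pop == pp)
          st4$individual[sel] <- sample(strata$individual[sel])
        }
        s4 <- amova_components(d2, st4)$sigma2
        ph4 <- phi_from_sigma(s4)
        if (!is.na(ph4["Phi_IS"]) && ph4["Phi_IS"] >= obs["Phi_IS"] - 1e-12)
          count["Phi_IS"] <- count["Phi_IS"] + 1
      }
    }
    p <- (count + 1) / (n_perm + 1)
    if (!diploid) p <- p[names(phi)]
  }
  src <- if (diploid)
    c("Among taxa", "Among populations within taxa",
      "Among individuals within populations", "Within individuals")
  else c("Among taxa", "Among populations within taxa", "Within populations")
  tab <- data.frame(source = src, df = comp$df, SSD = comp$SSD,
                    sigma2 = comp$sigma2,
                    pct = 100 * comp$sigma2 / sum(comp$sigma2),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, phi = phi, p = p[names(phi)], n_perm = n_perm,
              seed = seed)
  class(out) <- "yew_amova"
  out
}

#' @export
print.yew_amova <- function(x, ...) {
  cat("Analysis of molecular variance (", x$n_perm, " permutations)\n", sep = "")
  tab <- x$table
  tab$pct <- round(tab$pct, 1)
  tab$sigma2 <- signif(tab$sigma2, 4)
  tab$SSD <- signif(tab$SSD, 5)
  print(tab, row.names = FALSE)
  cat("\nFixation indices:\n")
  for (nm in names(x$phi))
    cat(sprintf("  %s = %.3f  (p = %s)\n", nm, x$phi[nm],
                ifelse(is.na(x$p[nm]), "NA", format(x$p[nm], digits = 3))))
  invisible(x)
}

#' Pairwise Phi_ST between two populations
#'
#' Two-level AMOVA (population / within) on squared difference counts, with a
#' permutation test shuffling sequences between the two populations.
#'
#' @param seqs_a,seqs_b character vectors (or `yew_alignment`s) of sequences
#'   for the two populations; each must have at least 2 sequences.
#' @param n_perm permutations for the test (0 to skip).
#' @param seed integer seed.
#' @param include_indel_chars passed to [sequence_distance_matrix()].
#' @return list with `phi_st`, `p`, `sigma2` (among, within) and `n_perm`.
#' @export
pairwise_phist <- function(seqs_a, seqs_b, n_perm = 0, seed = 1L,
                           include_indel_chars = TRUE) {
  sa <- if (inherits(seqs_a, "yew_alignment")) unname(seqs_a$seq) else unname(seqs_a)
  sb <- if (inherits(seqs_b, "yew_alignment")) unname(seqs_b$seq) else unname(seqs_b)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("each population needs at least 2 sequences")
  all_seqs <- stats::setNames(c(sa, sb),
                              paste0("s", seq_len(length(sa) + length(sb))))
  d2 <- sequence_distance_matrix(new_alignment(all_seqs), include_indel_chars)
  grp <- rep(c("A", "B"), c(length(sa), length(sb)))
  comp <- amova_components(d2, data.frame(pop = grp))
  phi <- comp$sigma2[1L] / sum(comp$sigma2)
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    cnt <- 0
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      s <- amova_components(d2, data.frame(pop = pg))$sigma2
      if (s[1L] / sum(s) >= phi - 1e-12) cnt <- cnt + 1
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  list(phi_st = unname(phi), p = p,
       sigma2 = c(among = unname(comp$sigma2[1L]),
                  within = unname(comp$sigma2[2L])),
       n_perm = n_perm)
}

#' Matrix of pairwise Phi_ST between all populations
#'
#' @param alignment a `yew_alignment`.
#' @param map a `sample_map`.
#' @param include_indel_chars passed to [sequence_distance_matrix()].
#' @return symmetric matrix of Phi_ST values (negative estimates retained),
#'   labelled by population code.
#' @export
phist_matrix <- function(alignment, map, include_indel_chars = TRUE) {
  check_alignment_map(alignment, map)
  ids <- names(alignment$seq)
  pop <- map$population[match(individual_stems(ids), map$sample_id)]
  pops <- unique(pop)
  P <- length(pops)
  if (P < 2L) stop("need at least 2 populations")
  d2 <- sequence_distance_matrix(alignment, include_indel_chars)
  M <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) {
    for (j in seq.int(i + 1L, P)) {
      sel <- pop %in% c(pops[i], pops[j])
      comp <- amova_components(d2[sel, sel, drop = FALSE],
                               data.frame(pop = pop[sel]))
      phi <- comp$sigma2[1L] / sum(comp$sigma2)
      M[i, j] <- M[j, i] <- phi
    }
  }
  M
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining on a symmetric distance matrix (e.g. pairwise
#' Phi_ST between populations). Labels are sorted lexicographically before
#' clustering so exact ties resolve deterministically; negative branch
#' lengths are clamped to zero in the output only.
#'
#' @param d symmetric matrix or `dist` with at least 3 labels.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (nrow(m) < 3L) stop("neighbour joining requires at least 3 labels")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
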