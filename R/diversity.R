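#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity, `Hd = n/(n-1) * (1 - sum(p_i^2))`, from a
#' vector of haplotype counts.
#'
#' @param counts non-negative integer vector of haplotype counts.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires at least 2 sequences")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# Character matrix of an alignment (or a character vector of sequences),
# with gaps and N converted to NA.
seq_char_matrix <- function(x) {
  seqs <- if (inherits(x, "yew_alignment")) x$seq else x
  m <- do.call(rbind, strsplit(unname(toupper(seqs)), "", fixed = TRUE))
  m[!(m %in% c("A", "C", "G", "T"))] <- NA_character_
  rownames(m) <- names(seqs)
  m
}

#' Nucleotide diversity per site
#'
#' Mean pairwise difference per comparable site, with pairwise deletion of
#' missing data: for each sequence pair only sites where both sequences carry
#' an unambiguous nucleotide are compared, and the per-pair per-site
#' proportions of differences are averaged over all `C(n,2)` pairs. On
#' complete (gap/N-free) data this equals
#' `sum(d_ij) / C(n,2) / L`.
#'
#' @param x a `yew_alignment` or character vector of equal-length sequences.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(x) {
  m <- seq_char_matrix(x)
  n <- nrow(m)
  if (n < 2) stop("nucleotide diversity requires at least 2 sequences")
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      L <- sum(ok)
      if (L == 0L) stop("no comparable sites between records ", i, " and ", j)
      tot <- tot + sum(m[i, ok] != m[j, ok]) / L
      npairs <- npairs + 1L
    }
  }
  tot / npairs
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a_{n-1} * L_valid)` where `S` is the number of segregating
#' sites and `a_{n-1} = sum_{k=1}^{n-1} 1/k`. Sites containing any gap or N
#' are removed before counting (complete-column deletion), and `L_valid` is
#' the number of retained sites.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_W per site.
#' @export
watterson_theta <- function(x) {
  m <- seq_char_matrix(x)
  n <- nrow(m)
  if (n < 2) stop("watterson_theta requires at least 2 sequences")
  complete <- !apply(is.na(m), 2L, any)
  L <- sum(complete)
  if (L == 0L) stop("no complete columns to analyse")
  mm <- m[, complete, drop = FALSE]
  S <- sum(apply(mm, 2L, function(col) length(unique(col)) > 1L))
  a <- sum(1 / seq_len(n - 1L))
  S / (a * L)
}

#' Number of segregating sites
#'
#' Counts polymorphic columns after complete-column deletion of gap/N sites.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `S` (segregating sites) and `L_valid` (analysed sites).
#' @export
segregating_sites <- function(x) {
  m <- seq_char_matrix(x)
  complete <- !apply(is.na(m), 2L, any)
  mm <- m[, complete, drop = FALSE]
  S <- if (ncol(mm) == 0L) 0L else
    sum(apply(mm, 2L, function(col) length(unique(col)) > 1L))
  list(S = as.integer(S), L_valid = as.integer(sum(complete)))
}

#' Per-population diversity summary
#'
#' Computes, for each population in the sample map, the sample size, number
#' of segregating sites, haplotype diversity, nucleotide diversity and
#' Watterson's theta, from a haplotype table and its source alignment. For
#' phased diploid data each individual contributes two sequences (`n` is the
#' number of gene copies analysed; the `individuals` column gives the
#' individual count). `pi` and `theta_W` are reported per site; set
#' `scale_1000 = TRUE` to multiply them by 1,000 for reporting.
#'
#' @param alignment a `yew_alignment`.
#' @param map a `sample_map`.
#' @param scale_1000 multiply pi and theta_W by 1000 in the output.
#' @return data.frame with one row per population.
#' @export
diversity_table <- function(alignment, map, scale_1000 = FALSE) {
  check_alignment_map(alignment, map)
  hap <- collapse_haplotypes(alignment, map, use_indel_chars = FALSE,
                             gap_as_missing = TRUE)
  assign <- hap$assignment
  pops <- unique(assign$population)
  rows <- lapply(pops, function(p) {
    recs <- assign$record_id[assign$population == p]
    sub <- alignment$seq[recs]
    hd <- if (length(recs) >= 2)
      haplotype_diversity(as.vector(table(assign$haplotype_id[assign$population == p])))
    else NA_real_
    pi <- if (length(recs) >= 2) nucleotide_diversity(sub) else NA_real_
    th <- if (length(recs) >= 2) watterson_theta(sub) else NA_real_
    ss <- segregating_sites(sub)
    data.frame(population = p,
               taxon = assign$taxon[assign$population == p][1L],
               individuals = length(unique(assign$individual[assign$population == p])),
               n = length(recs), S = ss$S, L_valid = ss$L_valid,
               Hd = hd, pi = pi, theta_W = th,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (scale_1000) {
    out$pi <- out$pi * 1000
    out$theta_W <- out$theta_W * 1000
  }
  out
}
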