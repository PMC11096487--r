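#' Construct a fixture recipe
#'
#' A fixture recipe fully determines the haplogroup membership of every
#' sequence in a synthetic data set, so downstream classify-and-count results
#' are exact by construction. Haplogroup centre sequences are placed
#' `2 * min_between` substitutions apart (so haplogroups fall into separate
#' networks whenever the connection limit is below that distance), and each
#' haplogroup carries `n_haplotypes` haplotypes at most two steps apart.
#'
#' @param groups data.frame with columns `taxon`, `population`, `haplogroup`
#'   and `n_seqs` (gene copies; for diploid markers copies per population
#'   must sum to an even number).
#' @param ploidy_mode `"haploid"` or `"diploid_phased"`.
#' @param L alignment length (sites).
#' @param min_between minimum substitution distance between a haplogroup
#'   centre and any other haplogroup's sites (centres end up `2*min_between`
#'   steps apart).
#' @param n_haplotypes haplotypes per haplogroup (single integer or named by
#'   haplogroup).
#' @param centre_share fraction of each group's copies assigned to the
#'   haplogroup's centre haplotype (the remainder cycles through the variant
#'   haplotypes); controls the allele-frequency skew of fixtures.
#' @param pairing how diploid gene copies are paired into individuals:
#'   `"random"` (Hardy-Weinberg by construction), `"sequential"`, or
#'   `"het_excess"` (unlike haplotypes paired preferentially, emulating a
#'   strong heterozygote excess).
#' @param name optional recipe name.
#' @return list of class `fixture_recipe`.
#' @export
new_fixture_recipe <- function(groups, ploidy_mode = c("haploid", "diploid_phased"),
                               L = 600, min_between = 12, n_haplotypes = 3,
                               centre_share = 0.6,
                               pairing = c("random", "sequential", "het_excess"),
                               name = "custom") {
  ploidy_mode <- match.arg(ploidy_mode)
  pairing <- match.arg(pairing)
  need <- c("taxon", "population", "haplogroup", "n_seqs")
  if (nrow(groups) > 0 && !all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (nrow(groups) > 0 && ploidy_mode == "diploid_phased") {
    per_pop <- tapply(groups$n_seqs, groups$population, sum)
    if (any(per_pop %% 2L != 0L))
      stop("diploid recipes need an even number of gene copies per population")
  }
  stopifnot(centre_share >= 0, centre_share <= 1)
  out <- list(groups = groups, ploidy_mode = ploidy_mode, L = L,
              min_between = min_between, n_haplotypes = n_haplotypes,
              centre_share = centre_share, pairing = pairing, name = name)
  class(out) <- "fixture_recipe"
  out
}

#' Packaged fixture recipes
#'
#' Named recipes replicating the published haplogroup-membership counts of
#' the insular yew study system:
#' \describe{
#'   \item{`taiwan_cp`}{141 Taiwanese chloroplast sequences (2 in the
#'     continental `mairei` haplogroup) plus 105 continental sequences.}
#'   \item{`taiwan_its`}{282 Taiwanese ITS gene copies (16 in the `mairei`
#'     haplogroup) plus 210 continental copies.}
#'   \item{`philippines_cp`}{38 Philippine chloroplast sequences (2 in the
#'     Taiwan-derived incursion haplogroup, at Mt. Apo) plus 141 Taiwanese
#'     sequences.}
#'   \item{`philippines_its`}{76 Philippine ITS gene copies (19 in the
#'     Taiwan-derived incursion haplogroup) plus 282 Taiwanese copies.}
#'   \item{`insular_cp`}{the 141 + 38 = 179 insular individuals only
#'     (haploid), one haplogroup per island taxon.}
#' }
#' Population codes and sample sizes follow the study design (nine Taiwanese
#' sites, two Philippine sites, seven continental sites). Which populations
#' carry the introgressed copies is not fixed by the counts; recipes place
#' the Taiwanese introgressed copies in the largest site (T) and the
#' Philippine incursion copies at Mt. Apo (AP).
#'
#' @param name one of the recipe names above.
#' @return a `fixture_recipe`.
#' @export
fixture_recipe <- function(name = c("taiwan_cp", "taiwan_its",
                                    "philippines_cp", "philippines_its",
                                    "insular_cp")) {
  name <- match.arg(name)
  tw_pops <- data.frame(
    population = c("T", "N", "M", "S", "H", "Z", "C", "D", "B"),
    n = c(28L, 16L, 16L, 18L, 15L, 14L, 15L, 15L, 4L))
  ma_pops <- data.frame(
    population = c("HSH", "LA", "JY", "TSH", "JX", "WP", "FQ"),
    n = c(12L, 15L, 15L, 15L, 15L, 15L, 18L))
  ph_pops <- data.frame(population = c("BH", "AP"), n = c(18L, 20L))
  g <- function(taxon, pops, haplogroup, mult = 1L) {
    data.frame(taxon = taxon, population = pops$population,
               haplogroup = haplogroup, n_seqs = pops$n * mult,
               stringsAsFactors = FALSE)
  }
  move_seqs <- function(groups, population, from, to, k) {
    # reallocate k gene copies of one population to another haplogroup
    i <- which(groups$population == population & groups$haplogroup == from)
    groups$n_seqs[i] <- groups$n_seqs[i] - k
    rbind(groups, data.frame(taxon = groups$taxon[i], population = population,
                             haplogroup = to, n_seqs = k,
                             stringsAsFactors = FALSE))
  }
  switch(name,
    taiwan_cp = {
      gr <- rbind(g("taiwanese", tw_pops, "insular"),
                  g("mairei", ma_pops, "mairei"))
      gr <- move_seqs(gr, "T", "insular", "mairei", 2L)
      new_fixture_recipe(gr, "haploid", name = name)
    },
    taiwan_its = {
      gr <- rbind(g("taiwanese", tw_pops, "insular", 2L),
                  g("mairei", ma_pops, "mairei", 2L))
      gr <- move_seqs(gr, "T", "insular", "mairei", 16L)
      new_fixture_recipe(gr, "diploid_phased", name = name)
    },
    philippines_cp = {
      gr <- rbind(g("taiwanese", tw_pops, "taiwan_shared"),
                  g("philippine", ph_pops, "philippine"))
      gr <- move_seqs(gr, "AP", "philippine", "taiwan_shared", 2L)
      new_fixture_recipe(gr, "haploid", name = name)
    },
    philippines_its = {
      gr <- rbind(g("taiwanese", tw_pops, "taiwan_shared", 2L),
                  g("philippine", ph_pops, "philippine", 2L))
      gr <- move_seqs(gr, "AP", "philippine", "taiwan_shared", 19L)
      new_fixture_recipe(gr, "diploid_phased", name = name)
    },
    insular_cp = {
      gr <- rbind(g("taiwanese", tw_pops, "taiwanese"),
                  g("philippine", ph_pops, "philippine"))
      new_fixture_recipe(gr, "haploid", name = name)
    })
}

#' Build a deterministic fixture data set from a recipe
#'
#' Generates an alignment, sample map and per-record truth table in which
#' every sequence's haplogroup is known by construction. Haplogroup centres
#' are separated by `2 * min_between` substitutions; within a haplogroup,
#' haplotypes are the centre plus one private substitution each (pairwise at
#' most 2 steps). Sequence-to-haplotype allocation cycles deterministically
#' through the haplogroup's haplotypes; only the pairing of diploid copies
#' into individuals uses the seeded random stream (recipe membership counts
#' are never sampled).
#'
#' @param recipe a `fixture_recipe`.
#' @param seed integer seed.
#' @return list with `alignment` (a `yew_alignment`), `map` (a
#'   `sample_map`) and `truth` (data.frame `record_id`, `individual`,
#'   `population`, `taxon`, `haplogroup`).
#' @export
make_fixture <- function(recipe, seed = 1L) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  set.seed(seed)
  gr <- recipe$groups
  L <- recipe$L
  if (is.null(gr) || nrow(gr) == 0L) {
    aln <- new_alignment(character(0), recipe$ploidy_mode)
    map <- as_sample_map(data.frame(sample_id = character(0),
                                    population = character(0),
                                    taxon = character(0),
                                    ploidy = integer(0)))
    return(list(alignment = aln, map = map,
                truth = data.frame(record_id = character(0),
                                   individual = character(0),
                                   population = character(0),
                                   taxon = character(0),
                                   haplogroup = character(0))))
  }
  hgs <- unique(gr$haplogroup)
  n_hap <- recipe$n_haplotypes
  if (length(n_hap) == 1L && is.null(names(n_hap)))
    n_hap <- stats::setNames(rep(n_hap, length(hgs)), hgs)
  need_sites <- length(hgs) * recipe$min_between + sum(n_hap[hgs] - 1L)
  if (need_sites > L)
    stop("infeasible distance constraints: need ", need_sites,
         " marked sites but L = ", L)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  site <- 0L
  hap_seqs <- list()
  for (hg in hgs) {
    centre <- base
    block <- seq.int(site + 1L, site + recipe$min_between)
    site <- site + recipe$min_between
    centre[block] <- vapply(centre[block], flip, character(1))
    haps <- list(centre)
    k <- n_hap[[hg]]
    if (k > 1L) for (v in seq_len(k - 1L)) {
      site <- site + 1L
      hv <- centre
      hv[site] <- flip(hv[site])
      haps[[v + 1L]] <- hv
    }
    hap_seqs[[hg]] <- vapply(haps, paste0, character(1), collapse = "")
  }
  # allocate copies: cycle through the haplogroup's haplotypes, keeping the
  # centre haplotype predominant (first ~60% of copies)
  recs <- list()
  for (r in seq_len(nrow(gr))) {
    n <- gr$n_seqs[r]
    if (n == 0L) next
    haps <- hap_seqs[[gr$haplogroup[r]]]
    k <- length(haps)
    n_centre <- if (k == 1L) n else ceiling((recipe$centre_share %||% 0.6) * n)
    idx <- c(rep(1L, n_centre),
             rep(seq.int(2L, max(2L, k)), length.out = n - n_centre))
    recs[[r]] <- data.frame(population = gr$population[r],
                            taxon = gr$taxon[r],
                            haplogroup = gr$haplogroup[r],
                            sequence = haps[idx],
                            stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  seqs <- character(0)
  truth <- list()
  if (recipe$ploidy_mode == "haploid") {
    i_by_pop <- stats::setNames(rep(0L, length(unique(recs$population))),
                                unique(recs$population))
    ids <- character(nrow(recs))
    for (r in seq_len(nrow(recs))) {
      p <- recs$population[r]
      i_by_pop[p] <- i_by_pop[p] + 1L
      ids[r] <- sprintf("%s_%03d", p, i_by_pop[p])
    }
    seqs <- stats::setNames(recs$sequence, ids)
    aln <- new_alignment(seqs, "haploid")
    map <- data.frame(sample_id = ids, population = recs$population,
                      taxon = recs$taxon, ploidy = 1L,
                      stringsAsFactors = FALSE)
    truth <- data.frame(record_id = ids, individual = ids,
                        population = recs$population, taxon = recs$taxon,
                        haplogroup = recs$haplogroup,
                        stringsAsFactors = FALSE)
  } else {
    ids <- character(nrow(recs))
    inds <- character(0)
    map_rows <- list()
    truth_rows <- list()
    for (p in unique(recs$population)) {
      sel <- which(recs$population == p)
      ord <- switch(recipe$pairing,
                    sequential = sel,
                    random = sel[sample.int(length(sel))],
                    het_excess = {
                      # pair copies from opposite ends of the haplotype-sorted
                      # order so most pairs are unlike
                      o <- sel[order(recs$sequence[sel])]
                      n2 <- length(o) %/% 2L
                      as.vector(rbind(o[seq_len(n2)],
                                      rev(o[seq.int(n2 + 1L, length(o))])))
                    })
      for (i in seq_len(length(ord) %/% 2L)) {
        ind <- sprintf("%s_%03d", p, i)
        inds <- c(inds, ind)
        ids[ord[2L * i - 1L]] <- paste0(ind, "_h1")
        ids[ord[2L * i]] <- paste0(ind, "_h2")
        map_rows[[length(map_rows) + 1L]] <-
          data.frame(sample_id = ind, population = p,
                     taxon = recs$taxon[ord[1L]], ploidy = 2L,
                     stringsAsFactors = FALSE)
      }
    }
    seqs <- stats::setNames(recs$sequence, ids)
    aln <- new_alignment(seqs, "diploid_phased")
    map <- do.call(rbind, map_rows)
    truth <- data.frame(record_id = ids, individual = individual_stems(ids),
                        population = recs$population, taxon = recs$taxon,
                        haplogroup = recs$haplogroup,
                        stringsAsFactors = FALSE)
  }
  list(alignment = aln, map = as_sample_map(map), truth = truth)
}
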