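#' Simulation configuration for the three-taxon island history
#'
#' Describes a three-deme isolation-with-migration history
#' `[(TW, PH), MA]`: Taiwanese and Philippine island populations split at
#' `T1` generations ago from an insular ancestor, which split from the
#' continental deme at `T2`. Defaults follow the modal demographic estimates
#' for the yew system: effective sizes 16,400 (MA), 6,900 (TW) and 2,700
#' (PH) individuals; `T1 = 1.56` My and `T2 = 4.16` My converted at a
#' 25-year generation time; rare post-split migration expressed as population
#' migration rates `2*Ne*M` of 0.40 (MA to TW) and 0.16 (TW to PH).
#'
#' Two loci are predefined: a concatenated chloroplast locus (haploid,
#' paternal, inheritance scalar 0.25) and the nuclear ITS locus (diploid,
#' biparental, scalar 1). Per-generation per-site mutation rates derive from
#' locus-wide yearly rates of 1.67e-6 (cp) and 1.24e-6 (ITS).
#'
#' @param N named vector of effective deme sizes in individuals
#'   (`MA`, `TW`, `PH`).
#' @param N_anc_insular effective size of the TW/PH ancestor.
#' @param N_anc_root effective size of the root ancestor.
#' @param T1,T2 split times in generations (`T2 > T1 > 0`).
#' @param M2N named vector of population migration rates `2*Ne*M`
#'   (`MA_TW`: MA into TW; `TW_PH`: TW into PH), forward in time.
#' @param generation_time years per generation (used only for reporting).
#' @param loci list of locus specifications: each a list with `name`, `L`
#'   (sites), `mu` (per site per generation), `ploidy` (1 or 2) and `scalar`
#'   (inheritance scalar).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = c(MA = 16400, TW = 6900, PH = 2700),
                       N_anc_insular = 6900,
                       N_anc_root = 16400,
                       T1 = round(1.56e6 / 25),
                       T2 = round(4.16e6 / 25),
                       M2N = c(MA_TW = 0.40, TW_PH = 0.16),
                       generation_time = 25,
                       loci = list(
                         cp = list(name = "cp", L = 2000,
                                   mu = 1.67e-6 * 25 / 2000,
                                   ploidy = 1L, scalar = 0.25),
                         its = list(name = "its", L = 600,
                                    mu = 1.24e-6 * 25 / 600,
                                    ploidy = 2L, scalar = 1))) {
  stopifnot(all(c("MA", "TW", "PH") %in% names(N)), all(N > 0),
            T2 >= T1, T1 > 0, all(M2N >= 0),
            N_anc_insular > 0, N_anc_root > 0)
  out <- list(N = N, N_anc_insular = N_anc_insular, N_anc_root = N_anc_root,
              T1 = T1, T2 = T2, M2N = M2N,
              generation_time = generation_time, loci = loci)
  class(out) <- "sim_config"
  out
}

#' Simulate a genealogy under the structured coalescent
#'
#' Backward-time structured coalescent with exponential waiting times for a
#' three-deme isolation-with-migration history. Gene-copy counts per deme are
#' `2 * N * scalar` (the inheritance scalar accounts for ploidy and
#' transmitting sex, e.g. 0.25 for paternal haploid chloroplast).
#' Between `T1` and `T2` the island demes are merged into the insular
#' ancestor; beyond `T2` all lineages coalesce in the root deme, so
#' coalescence is guaranteed. Backward per-lineage migration rates are the
#' forward migrant fractions implied by the configured `2*Ne*M` values.
#'
#' @param config a [sim_config()].
#' @param locus locus name in `config$loci` (e.g. `"cp"`, `"its"`).
#' @param n named vector of sampled gene-copy counts per deme
#'   (`MA`, `TW`, `PH`; missing demes sample 0).
#' @param seed integer seed.
#' @return object of class `genealogy`: list with `parent` (parent index per
#'   node, NA at root), `time` (node times in generations, tips at 0),
#'   `tip_label`, `tip_deme`, `n_tips` and `locus`.
#' @export
simulate_genealogy <- function(config, locus, n, seed) {
  loc <- config$loci[[locus]]
  if (is.null(loc)) stop("unknown locus: ", locus)
  set.seed(seed)
  demes0 <- c("MA", "TW", "PH")
  nn <- stats::setNames(rep(0L, 3L), demes0)
  nn[names(n)] <- as.integer(n)
  n_tot <- sum(nn)
  if (n_tot < 1L) stop("no lineages sampled")
  copies <- function(Nind) 2 * Nind * loc$scalar
  # backward migration: rate at which a lineage in the recipient deme traces
  # back to the source = forward migrant fraction M = (2NeM)/(2 Ne scalar ...)
  m_back <- function(M2N, N_recip) M2N / copies(N_recip)
  tip_deme <- rep(demes0, nn)
  tip_label <- unlist(lapply(demes0, function(d)
    if (nn[d] > 0L) paste0(d, "_", seq_len(nn[d])) else character(0)))
  max_nodes <- 2L * n_tot - 1L
  parent <- rep(NA_integer_, max_nodes)
  time <- numeric(max_nodes)
  active <- seq_len(n_tot)
  deme <- tip_deme
  t <- 0
  next_node <- n_tot
  epoch_ends <- c(config$T1, config$T2, Inf)
  epoch <- if (config$T1 > 0) 1L else 2L
  deme_size <- function(d) {
    switch(d,
           MA = config$N[["MA"]], TW = config$N[["TW"]], PH = config$N[["PH"]],
           INS = config$N_anc_insular, ANC = config$N_anc_root)
  }
  mig_rates <- function(ep) {
    if (ep == 1L) {
      list(TW = c(MA = m_back(config$M2N[["MA_TW"]], config$N[["TW"]])),
           PH = c(TW = m_back(config$M2N[["TW_PH"]], config$N[["PH"]])))
    } else if (ep == 2L) {
      list(INS = c(MA = m_back(config$M2N[["MA_TW"]], config$N_anc_insular)))
    } else list()
  }
  while (length(active) > 1L) {
    mr <- mig_rates(epoch)
    repeat {
      ds <- unique(deme)
      k <- table(factor(deme, levels = ds))
      coal_rate <- vapply(ds, function(d)
        as.numeric(k[d]) * (as.numeric(k[d]) - 1) / 2 / copies(deme_size(d)),
        numeric(1))
      mig_rate <- vapply(ds, function(d)
        if (!is.null(mr[[d]])) as.numeric(k[d]) * sum(mr[[d]]) else 0,
        numeric(1))
      R <- sum(coal_rate) + sum(mig_rate)
      t_ev <- if (R > 0) t + stats::rexp(1, R) else Inf
      if (t_ev >= epoch_ends[epoch]) {
        t <- epoch_ends[epoch]
        epoch <- epoch + 1L
        if (epoch == 2L) deme[deme %in% c("TW", "PH")] <- "INS"
        if (epoch == 3L) deme[] <- "ANC"
        break
      }
      t <- t_ev
      pr <- c(coal_rate, mig_rate)
      ev <- sample.int(length(pr), 1L, prob = pr)
      if (ev <= length(ds)) {
        d <- ds[ev]
        pair <- sample(which(deme == d), 2L)
        next_node <- next_node + 1L
        time[next_node] <- t
        parent[active[pair]] <- next_node
        keep <- setdiff(seq_along(active), pair)
        new_active <- c(active[keep], next_node)
        new_deme <- c(deme[keep], d)
        active <- new_active
        deme <- new_deme
      } else {
        d <- ds[ev - length(ds)]
        i <- if (sum(deme == d) == 1L) which(deme == d) else
          sample(which(deme == d), 1L)
        dest <- names(mr[[d]])
        deme[i] <- if (length(dest) == 1L) dest else
          dest[sample.int(length(dest), 1L, prob = mr[[d]])]
      }
      if (length(active) == 1L) break
    }
  }
  out <- list(parent = parent[seq_len(next_node)],
              time = time[seq_len(next_node)],
              tip_label = tip_label, tip_deme = tip_deme,
              n_tips = n_tot, locus = locus)
  class(out) <- "genealogy"
  out
}

# tips descending from each node, as a list of integer vectors
genealogy_descendants <- function(gen) {
  n_nodes <- length(gen$parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(gen$n_tips)) desc[[i]] <- i
  ord <- order(gen$time[seq_len(n_nodes)])
  for (i in ord) {
    p <- gen$parent[i]
    if (!is.na(p)) desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  desc
}

#' Drop mutations (and indels) on a genealogy
#'
#' Infinite-sites substitutions: each branch receives
#' `Poisson(branch length * mu * L)` mutations, every mutation occupies a
#' fresh site (an error suggests increasing `L` if sites are exhausted), and
#' derived states propagate to all descendant tips. Optional indel events
#' (rate per sequence per generation) create short gap runs (1-3 sites)
#' inherited by the descendants.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param L sequence length.
#' @param mu per-site per-generation mutation rate.
#' @param indel_rate per-sequence per-generation indel rate (default 0).
#' @param seed integer seed.
#' @return a haploid `yew_alignment` of the tip sequences.
#' @export
sprinkle_mutations <- function(genealogy, L, mu, indel_rate = 0, seed) {
  set.seed(seed)
  n_nodes <- length(genealogy$parent)
  blen <- ifelse(is.na(genealogy$parent), 0,
                 genealogy$time[genealogy$parent] - genealogy$time)
  n_mut <- stats::rpois(n_nodes, blen * mu * L)
  total <- sum(n_mut)
  if (total > L)
    stop("site exhaustion: ", total, " mutations for ", L,
         " sites; increase L or lower mu")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  tips <- matrix(rep(anc, genealogy$n_tips), nrow = genealogy$n_tips,
                 byrow = TRUE)
  desc <- genealogy_descendants(genealogy)
  if (total > 0L) {
    sites <- sample.int(L, total)
    si <- 0L
    for (nd in which(n_mut > 0L)) {
      for (m in seq_len(n_mut[nd])) {
        si <- si + 1L
        s <- sites[si]
        derived <- sample(setdiff(bases, anc[s]), 1L)
        tips[desc[[nd]], s] <- derived
      }
    }
  }
  if (indel_rate > 0) {
    n_ind <- stats::rpois(n_nodes, blen * indel_rate)
    for (nd in which(n_ind > 0L)) {
      for (m in seq_len(n_ind[nd])) {
        w <- sample.int(3L, 1L)
        start <- sample.int(L - w + 1L, 1L)
        tips[desc[[nd]], start:(start + w - 1L)] <- "-"
      }
    }
  }
  seqs <- apply(tips, 1L, paste0, collapse = "")
  names(seqs) <- genealogy$tip_label
  new_alignment(seqs, "haploid")
}

#' Simulate a marker data set under the island history
#'
#' Convenience wrapper: genealogy plus mutations for one locus, with phased
#' pairing of gene copies into individuals for diploid loci, and a matching
#' sample map (one population per deme).
#'
#' @param config a [sim_config()].
#' @param locus locus name.
#' @param n_individuals named vector of sampled individuals per deme.
#' @param seed integer seed.
#' @param indel_rate per-sequence per-generation indel rate.
#' @return list with `alignment` (haploid or diploid_phased) and `map`.
#' @export
simulate_marker <- function(config, locus, n_individuals, seed,
                            indel_rate = 0) {
  loc <- config$loci[[locus]]
  if (is.null(loc)) stop("unknown locus: ", locus)
  n_copies <- n_individuals * loc$ploidy
  gen <- simulate_genealogy(config, locus, n_copies, seed)
  aln <- sprinkle_mutations(gen, loc$L, loc$mu, indel_rate, seed + 1L)
  demes <- names(n_individuals)[n_individuals > 0]
  taxon_of <- c(MA = "mairei", TW = "taiwanese", PH = "philippine")
  if (loc$ploidy == 2L) {
    seqs <- aln$seq
    ids <- character(length(seqs))
    inds <- character(0)
    k <- 0L
    for (d in demes) {
      sel <- which(gen$tip_deme == d)
      for (i in seq_len(length(sel) %/% 2L)) {
        ind <- sprintf("%s_%03d", d, i)
        inds <- c(inds, ind)
        k <- k + 1L; ids[sel[2L * i - 1L]] <- paste0(ind, "_h1")
        ids[sel[2L * i]] <- paste0(ind, "_h2")
      }
    }
    names(seqs) <- ids
    aln <- new_alignment(seqs, "diploid_phased")
    map <- data.frame(sample_id = inds,
                      population = sub("_[0-9]+$", "", inds),
                      taxon = taxon_of[sub("_[0-9]+$", "", inds)],
                      ploidy = 2L, stringsAsFactors = FALSE)
  } else {
    map <- data.frame(sample_id = gen$tip_label,
                      population = gen$tip_deme,
                      taxon = taxon_of[gen$tip_deme],
                      ploidy = 1L, stringsAsFactors = FALSE)
  }
  list(alignment = aln, map = as_sample_map(map))
}
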