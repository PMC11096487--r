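#' Statistical-parsimony connection limit
#'
#' Maximum number of mutational steps at which two haplotypes may be joined
#' so that the probability that the connecting path is free of superimposed
#' mutations stays above `p_threshold`. The parsimony probability for `j`
#' observed differences over `L` sites is computed as
#' `P(j; L) = ((L - j) / L)^j`: under a two-sequence coalescent argument the
#' probability that an observed difference is due to a single mutation is
#' `1/(1 + theta)` with the per-site mutation parameter estimated from the
#' pair as `theta = j/(L - j)`, giving `(L - j)/L` per difference. The limit
#' is the largest `j` with `P(j; L) >= p_threshold` (0 when even a single
#' step fails the threshold, e.g. `p_threshold = 1`).
#'
#' A user-supplied fixed limit (`override`) short-circuits the computation;
#' published analyses often fix the limit explicitly, and all packaged
#' fixtures do so.
#'
#' @param L alignment length (sites), >= 1.
#' @param p_threshold probability-of-parsimony threshold (default 0.95).
#' @param override optional fixed limit returned as-is.
#' @return integer connection limit in mutational steps.
#' @export
connection_limit <- function(L, p_threshold = 0.95, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (L < 1) stop("L must be >= 1")
  j <- 0L
  while (j + 1L < L && parsimony_probability(j + 1L, L) >= p_threshold)
    j <- j + 1L
  j
}

#' @rdname connection_limit
#' @param j number of mutational steps.
#' @export
parsimony_probability <- function(j, L) ((L - j) / L)^j

#' Build a statistical-parsimony haplotype network
#'
#' Joins haplotype pairs in order of increasing mutational distance
#' (substitutions plus indel-coded characters, one step per gap event), never
#' beyond the connection limit. All pairs at a given distance whose endpoints
#' lie in different components at the start of that distance round are
#' connected, so alternative equal-length connections are retained as
#' reticulations. A connection of d > 1 steps is realised through d - 1
#' inferred intermediate nodes, each edge spanning exactly one step.
#' Haplotypes farther than the limit from every connected haplotype remain in
#' separate components (separate networks).
#'
#' @param haptable a `haplotype_table`.
#' @param limit connection limit in steps; if `NULL`, computed with
#'   [connection_limit()] from the haplotype sequence length and
#'   `p_threshold`.
#' @param p_threshold threshold used when `limit` is `NULL`.
#' @return object of class `parsimony_network`: list with `graph` (igraph;
#'   vertex attributes `inferred`, `size` = sampled sequence count), `limit`,
#'   `membership` (component id per sampled haplotype), `n_components`,
#'   `distances` (haplotype step-distance matrix) and `haptable`.
#' @export
build_parsimony_network <- function(haptable, limit = NULL, p_threshold = 0.95) {
  hap_ids <- haptable$haplotypes$haplotype_id
  H <- length(hap_ids)
  L <- nchar(haptable$haplotypes$sequence[1L])
  if (is.null(limit)) limit <- connection_limit(L, p_threshold)
  d <- if (H > 1L)
    sequence_distance_matrix(new_alignment(
      stats::setNames(haptable$haplotypes$sequence, hap_ids)),
      include_indel_chars = !is.null(haptable$indels))
  else matrix(0, 1, 1, dimnames = list(hap_ids, hap_ids))
  comp <- seq_len(H)  # union-find by relabelling
  links <- list()
  if (H > 1L) {
    dvals <- sort(unique(d[upper.tri(d)]))
    dvals <- dvals[dvals > 0 & dvals <= limit]
    for (dv in dvals) {
      comp_at_start <- comp
      idx <- which(d == dv & upper.tri(d), arr.ind = TRUE)
      # deterministic order: by row then column index (first-occurrence ids)
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        if (comp_at_start[i] != comp_at_start[j]) {
          links[[length(links) + 1L]] <- c(i, j, dv)
          ci <- comp[i]; cj <- comp[j]
          if (ci != cj) comp[comp == cj] <- ci
        }
      }
    }
  }
  # expand links into one-step edges through inferred intermediates
  edges <- character(0)
  inferred <- character(0)
  k_int <- 0L
  for (ln in links) {
    i <- ln[1L]; j <- ln[2L]; dv <- ln[3L]
    if (dv == 1) {
      edges <- c(edges, hap_ids[i], hap_ids[j])
    } else {
      path <- character(dv - 1L)
      for (s in seq_len(dv - 1L)) {
        k_int <- k_int + 1L
        path[s] <- paste0("int", k_int)
      }
      inferred <- c(inferred, path)
      chain <- c(hap_ids[i], path, hap_ids[j])
      for (s in seq_len(length(chain) - 1L))
        edges <- c(edges, chain[s], chain[s + 1L])
    }
  }
  sizes <- rowSums(haptable$counts)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, H, name = hap_ids, inferred = FALSE,
                            size = as.numeric(sizes[hap_ids]))
  if (length(inferred) > 0L)
    g <- igraph::add_vertices(g, length(inferred), name = inferred,
                              inferred = TRUE, size = 0)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, edges)
  memb_all <- igraph::components(g)$membership
  membership <- memb_all[hap_ids]
  out <- list(graph = g, limit = as.integer(limit), membership = membership,
              n_components = length(unique(membership)),
              distances = d, haptable = haptable)
  class(out) <- "parsimony_network"
  out
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat("<parsimony_network> ", length(x$membership), " haplotypes, ",
      x$n_components, " network(s), connection limit ", x$limit, " steps\n",
      sep = "")
  invisible(x)
}

#' Classify sequences into haplogroups from a parsimony network
#'
#' Haplogroups are the connected components of the network (separate
#' networks), labelled by the majority taxon over the sampled sequence counts
#' of their member haplotypes; an exact tie is broken by taxon label order
#' with a warning. When several components share a majority taxon the labels
#' are disambiguated with a numeric suffix in decreasing component-size
#' order. Alternatively, `reference` can pre-assign labels to selected
#' haplotypes; each component containing a reference haplotype takes that
#' label (used when haplogroups of interest are subgraphs known a priori).
#'
#' @param network a `parsimony_network`.
#' @param reference optional named character vector: names are haplotype ids,
#'   values are haplogroup labels.
#' @return object of class `haplogroup_assignment`: data.frame with one row
#'   per sequence record (`record_id`, `individual`, `population`, `taxon`,
#'   `haplotype_id`, `haplogroup`, `haplogroup_taxon`).
#' @export
classify_haplogroups <- function(network, reference = NULL) {
  haptable <- network$haptable
  memb <- network$membership
  comps <- sort(unique(memb))
  tc <- haptable$taxon_counts
  lab <- character(length(comps))
  maj <- character(length(comps))
  sizes <- numeric(length(comps))
  for (ci in seq_along(comps)) {
    haps <- names(memb)[memb == comps[ci]]
    tot <- colSums(tc[haps, , drop = FALSE])
    sizes[ci] <- sum(tot)
    top <- names(tot)[tot == max(tot)]
    if (length(top) > 1L) {
      top <- sort(top)
      warning("majority-taxon tie in component ", comps[ci], " (",
              paste(top, collapse = ", "), "); using ", top[1L])
    }
    maj[ci] <- top[1L]
  }
  lab <- maj
  dup_taxa <- unique(maj[duplicated(maj)])
  for (tx in dup_taxa) {
    sel <- which(maj == tx)
    sel <- sel[order(-sizes[sel])]
    lab[sel] <- paste0(tx, ".", seq_along(sel))
  }
  if (!is.null(reference)) {
    for (h in names(reference)) {
      if (!h %in% names(memb)) stop("reference haplotype not in network: ", h)
      lab[match(memb[h], comps)] <- reference[[h]]
    }
  }
  comp_label <- stats::setNames(lab, comps)
  comp_taxon <- stats::setNames(maj, comps)
  a <- haptable$assignment
  a$haplogroup <- unname(comp_label[as.character(memb[a$haplotype_id])])
  a$haplogroup_taxon <- unname(comp_taxon[as.character(memb[a$haplotype_id])])
  class(a) <- c("haplogroup_assignment", "data.frame")
  a
}

#' Count introgressed sequences
#'
#' Number and percentage of sequences of a focal taxon that fall in a donor
#' haplogroup (foreign-haplogroup sequences within a taxon).
#'
#' @param assignment a `haplogroup_assignment`.
#' @param focal_taxon taxon whose sequences are screened.
#' @param donor_haplogroup haplogroup label (or its majority taxon) marking
#'   introgressed origin.
#' @return list with `count`, `total` and `percent` (100 * count / total).
#' @export
count_introgressed <- function(assignment, focal_taxon, donor_haplogroup) {
  if (!focal_taxon %in% assignment$taxon)
    stop("unknown focal taxon: ", focal_taxon)
  if (!(donor_haplogroup %in% assignment$haplogroup ||
        donor_haplogroup %in% assignment$haplogroup_taxon))
    stop("unknown donor haplogroup: ", donor_haplogroup)
  foc <- assignment[assignment$taxon == focal_taxon, , drop = FALSE]
  hit <- foc$haplogroup == donor_haplogroup |
    foc$haplogroup_taxon == donor_haplogroup
  list(count = sum(hit), total = nrow(foc),
       percent = 100 * sum(hit) / nrow(foc))
}

#' Export a parsimony network
#'
#' Writes the network as GraphML and/or a one-step edge list TSV with columns
#' `from`, `to`, `steps` (always 1) and `inferred` (whether either endpoint
#' is an inferred intermediate).
#'
#' @param network a `parsimony_network`.
#' @param graphml_path optional GraphML output path.
#' @param edgelist_path optional TSV output path.
#' @return invisibly, the list of written paths.
#' @export
write_network <- function(network, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(network$graph)
    inf <- igraph::V(network$graph)$inferred
    names(inf) <- igraph::V(network$graph)$name
    df <- data.frame(from = el[, 1L], to = el[, 2L], steps = 1L,
                     inferred = inf[el[, 1L]] | inf[el[, 2L]])
    utils::write.table(df, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(graphml = graphml_path, edgelist = edgelist_path))
}
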