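test_that("connection limit respects overrides, thresholds and monotonicity", {
  expect_equal(connection_limit(600, override = 14), 14L)
  expect_equal(connection_limit(600, p_threshold = 1.0), 0L)
  lims <- vapply(c(50, 100, 200, 400, 800, 1600, 3200), connection_limit,
                 numeric(1))
  expect_true(all(diff(lims) >= 0))
  js <- 1:20
  probs <- parsimony_probability(js, 600)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(diff(probs) < 0))
})

chain_haptable <- function(seqs, taxa = NULL) {
  ids <- paste0("i", seq_along(seqs))
  if (is.null(taxa)) taxa <- rep("tx", length(seqs))
  map <- toy_map(ids, rep("P1", length(seqs)), taxa)
  collapse_haplotypes(new_alignment(setNames(seqs, ids)), map, prefix = "h")
}

test_that("a one-step chain yields a path with no inferred nodes", {
  h <- chain_haptable(c("AAAA", "AAAT", "AATT"))
  net <- build_parsimony_network(h, limit = 5)
  expect_equal(net$n_components, 1L)
  expect_equal(igraph::vcount(net$graph), 3L)  # no intermediates
  expect_equal(igraph::ecount(net$graph), 2L)
  expect_false(any(igraph::V(net$graph)$inferred))
})

test_that("multi-step connections pass through inferred intermediates", {
  h <- chain_haptable(c("AAAAAA", "AATTTA"))  # 3 steps apart
  net <- build_parsimony_network(h, limit = 5)
  expect_equal(net$n_components, 1L)
  expect_equal(igraph::vcount(net$graph), 4L)  # 2 sampled + 2 inferred
  expect_equal(igraph::ecount(net$graph), 3L)  # every edge one step
  expect_equal(sum(igraph::V(net$graph)$inferred), 2L)
})

test_that("haplotypes beyond the limit split into separate networks", {
  # third haplotype 6 steps from both others; limit 5
  h <- chain_haptable(c("AAAAAAAA", "AAAAAAAT", "TTTTTTAA"))
  net <- build_parsimony_network(h, limit = 5)
  expect_equal(net$n_components, 2L)
  # raising the limit rejoins them
  net2 <- build_parsimony_network(h, limit = 7)
  expect_equal(net2$n_components, 1L)
})

test_that("network size matches the brute-force minimum spanning construction", {
  # search deterministically for a tie-free instance (distinct pairwise
  # distances make the minimum spanning construction unique)
  found <- FALSE
  for (s in 1:300) {
    seqs <- rand_seqs(5, 60, seed = s)
    d <- oracle_dist(seqs)
    off <- d[upper.tri(d)]
    if (anyDuplicated(off) == 0 && all(off >= 1)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  h <- chain_haptable(unname(seqs))
  net <- build_parsimony_network(h, limit = max(off) + 1)
  w <- oracle_mst_weight(d)
  expect_equal(igraph::ecount(net$graph), w)          # total steps = MST weight
  expect_equal(sum(igraph::V(net$graph)$inferred), w - 4)  # intermediates
  expect_equal(net$n_components, 1L)
})

test_that("construction is invariant under haplotype input order", {
  seqs <- c("AAAAAA", "AAAAAT", "AAAATT", "TTTAAA")
  h1 <- chain_haptable(seqs)
  h2 <- chain_haptable(rev(seqs))
  n1 <- build_parsimony_network(h1, limit = 2)
  n2 <- build_parsimony_network(h2, limit = 2)
  expect_equal(n1$n_components, n2$n_components)
  expect_equal(igraph::ecount(n1$graph), igraph::ecount(n2$graph))
  expect_equal(sum(igraph::V(n1$graph)$inferred),
               sum(igraph::V(n2$graph)$inferred))
})

test_that("haplogroup classification follows the majority taxon with tie warnings", {
  h <- chain_haptable(c(rep("AAAAAAAA", 3), "AAAAAAAT", rep("TTTTTTTT", 2)),
                      taxa = c("mairei", "mairei", "mairei", "taiwanese",
                               "taiwanese", "taiwanese"))
  net <- build_parsimony_network(h, limit = 3)
  expect_equal(net$n_components, 2L)
  cls <- classify_haplogroups(net)
  # component 1: 3 mairei + 1 taiwanese sequences -> mairei
  expect_equal(unique(cls$haplogroup[cls$record_id %in% paste0("i", 1:4)]),
               "mairei")
  ci <- count_introgressed(cls, "taiwanese", "mairei")
  expect_equal(ci$count, 1L)
  expect_equal(ci$total, 3L)
  # exact tie: one sequence of each taxon in one component
  h2 <- chain_haptable(c("AAAA", "AAAT"), taxa = c("b_tax", "a_tax"))
  net2 <- build_parsimony_network(h2, limit = 3)
  expect_warning(cls2 <- classify_haplogroups(net2), "tie")
  expect_equal(unique(cls2$haplogroup), "a_tax")
})

test_that("reference haplotypes can seed haplogroup labels", {
  h <- chain_haptable(c("AAAA", "AAAT", "TTTT"))
  net <- build_parsimony_network(h, limit = 2)
  cls <- classify_haplogroups(net, reference = c(h1 = "insular", h3 = "mairei"))
  expect_setequal(unique(cls$haplogroup), c("insular", "mairei"))
  expect_error(classify_haplogroups(net, reference = c(zz = "x")),
               "not in network")
})

test_that("fixture haplogroup memberships are recovered exactly end to end", {
  fx <- make_fixture(fixture_recipe("philippines_its"), seed = 3)
  hap <- collapse_haplotypes(fx$alignment, fx$map, prefix = "its")
  net <- build_parsimony_network(hap, limit = 10)
  cls <- classify_haplogroups(net)
  # every record's classified haplogroup matches the recipe truth up to the
  # majority-taxon labelling (taiwan_shared -> taiwanese)
  truth_label <- ifelse(fx$truth$haplogroup == "taiwan_shared",
                        "taiwanese", "philippine")
  expect_equal(cls$haplogroup[match(fx$truth$record_id, cls$record_id)],
               truth_label)
  ci <- count_introgressed(cls, "philippine", "taiwanese")
  expect_equal(c(ci$count, ci$total), c(19L, 76L))
  # donor absent from focal taxon: zero percent
  ci0 <- count_introgressed(cls, "taiwanese", "philippine")
  expect_equal(ci0$count, 0L)
  expect_error(count_introgressed(cls, "nope", "philippine"), "unknown focal")
  expect_error(count_introgressed(cls, "taiwanese", "nope"), "unknown donor")
})

test_that("network edges never span more than one mutational step", {
  fx <- make_fixture(fixture_recipe("taiwan_cp"), seed = 4)
  hap <- collapse_haplotypes(fx$alignment, fx$map, prefix = "cp")
  net <- build_parsimony_network(hap, limit = 10)
  # sampled-haplotype pairwise path lengths are at least the raw distances
  g <- net$graph
  sampled <- igraph::V(g)$name[!igraph::V(g)$inferred]
  sp <- igraph::distances(g, v = sampled, to = sampled)
  d <- net$distances[sampled, sampled]
  reach <- is.finite(sp)
  expect_true(all(sp[reach] >= d[reach] - 1e-9))
  # exports are written
  gml <- tempfile(fileext = ".graphml"); el <- tempfile(fileext = ".tsv")
  write_network(net, gml, el)
  expect_true(file.exists(gml) && file.exists(el))
  edges <- read.delim(el)
  expect_true(all(edges$steps == 1))
})
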