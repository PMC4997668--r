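make_profiles <- function(vectors) {
  codons <- sense_codons()$codon_rna
  m <- do.call(rbind, lapply(vectors, function(v) {
    full <- rep(1, length(codons))
    full[seq_along(v)] <- v
    full
  }))
  dimnames(m) <- list(names(vectors), codons)
  m
}

test_that("RSCU distances are Euclidean with the expected identities", {
  m <- make_profiles(list(a = c(2, 0), b = c(2, 0), c = c(0, 2)))
  d <- as.matrix(rscu_distance(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], sqrt(8), tolerance = 1e-12)

  # triangle inequality on random triples
  set.seed(3)
  for (i in 1:20) {
    m3 <- matrix(stats::runif(3 * 59, 0, 2), nrow = 3,
                 dimnames = list(c("x", "y", "z"), sense_codons()$codon_rna))
    dd <- as.matrix(rscu_distance(m3))
    expect_lte(dd["x", "z"], dd["x", "y"] + dd["y", "z"] + 1e-12)
  }
})

test_that("average-linkage heights match the exhaustive oracle on small n", {
  set.seed(9)
  for (n in c(4, 5, 6)) {
    m <- matrix(stats::runif(n * 8), nrow = n,
                dimnames = list(paste0("g", seq_len(n)), NULL))
    d <- stats::dist(m)
    cl <- usage_cluster(d, linkage = "average", k = 2)
    expect_equal(sort(cl$hclust$height), oracle_average_link_heights(d),
                 tolerance = 1e-12)
    # merge heights are monotone non-decreasing (ultrametric)
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
  }
})

test_that("two leaves merge once at their distance; k must not exceed n", {
  d <- stats::dist(c(a = 0, b = 1))
  cl <- usage_cluster(d, k = 2)
  expect_equal(cl$hclust$height, 1)
  expect_equal(sort(cl$partition$cluster), c(1L, 2L))
  expect_error(usage_cluster(d, k = 3), "exceeds")
})

test_that("the k=2 cut recovers planted clusters and ignores label order", {
  set.seed(4)
  base1 <- stats::runif(59, 0, 2)
  base2 <- stats::runif(59, 0, 2)
  m <- rbind(
    t(replicate(4, base1 + stats::rnorm(59, 0, 0.05))),
    t(replicate(4, base2 + stats::rnorm(59, 0, 0.05)))
  )
  rownames(m) <- sprintf("g%d", 1:8)
  truth <- rep(c(1L, 2L), each = 4)
  cl <- usage_cluster(stats::dist(m), k = 2)
  expect_equal(two_group_agreement(cl$partition$cluster, truth), 1)

  # permuting the input leaves the partition (as sets) unchanged
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  cl_p <- usage_cluster(stats::dist(m[perm, ]), k = 2)
  joined <- merge(cl$partition, cl_p$partition, by = "gene_id")
  expect_equal(two_group_agreement(joined$cluster.x, joined$cluster.y), 1)
})

test_that("neighbor joining reconstructs an additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):5,C:3,D:4) gives these pairwise path lengths
  labs <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 3, 9, 10,
                 3, 0, 10, 11,
                 9, 10, 0, 7,
                 10, 11, 7, 0), 4, dimnames = list(labs, labs))
  tree <- neighbor_joining(stats::as.dist(dm))
  expect_setequal(tree$tip.label, labs)
  # path distances between leaves reproduce the input matrix exactly
  path <- ape::cophenetic.phylo(tree)[labs, labs]
  expect_equal(path, dm, tolerance = 1e-9)
  # topology identical to the generating tree
  truth <- ape::read.tree(text = "((A:1,B:2):5,C:3,D:4);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(truth)), 0)
  # and the five branch lengths are recovered
  expect_equal(sort(tree$edge.length), c(1, 2, 3, 4, 5), tolerance = 1e-9)
})

test_that("three equidistant taxa get three equal half-length branches", {
  labs <- c("x", "y", "z")
  dm <- matrix(2, 3, 3, dimnames = list(labs, labs))
  diag(dm) <- 0
  tree <- neighbor_joining(stats::as.dist(dm))
  expect_equal(unname(tree$edge.length), rep(1, 3), tolerance = 1e-12)
  expect_error(neighbor_joining(stats::dist(c(a = 0, b = 1))), "at least 3")
})

test_that("negative NJ branches are clamped without losing path length", {
  labs <- c("A", "B", "C", "D")
  # slightly non-additive matrix that induces a negative internal branch
  dm <- matrix(c(0, 0.1, 1, 1,
                 0.1, 0, 1, 1.2,
                 1, 1, 0, 0.1,
                 1, 1.2, 0.1, 0), 4, dimnames = list(labs, labs))
  raw <- ape::nj(stats::as.dist(dm))
  tree <- neighbor_joining(stats::as.dist(dm))
  expect_true(all(tree$edge.length >= 0))
  expect_equal(attr(tree, "raw_edge_length"), raw$edge.length)
  # the deficit is transferred, not invented: total length stays between the
  # raw total and the total with negatives merely zeroed
  expect_gte(sum(tree$edge.length), sum(raw$edge.length) - 1e-12)
  expect_lte(sum(tree$edge.length), sum(pmax(raw$edge.length, 0)) + 1e-12)
  # topology is untouched by clamping
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(raw)), 0)
})

test_that("Newick output is deterministic, quoted, and round-trips", {
  d <- stats::dist(c(a = 0, b = 1))
  expect_equal(write_newick(usage_cluster(d, k = 1)), "(a:0.5,b:0.5);")

  # deterministic ordering by smallest descendant label
  set.seed(6)
  m <- matrix(stats::runif(5 * 10), nrow = 5,
              dimnames = list(c("e", "c", "a", "d", "b"), NULL))
  tr <- neighbor_joining(stats::dist(m))
  nwk1 <- write_newick(tr)
  # same tree with reordered input yields the same string
  tr2 <- neighbor_joining(stats::dist(m[c(3, 5, 2, 4, 1), ]))
  expect_equal(write_newick(tr2), nwk1)

  # round-trip through a standard parser preserves topology and lengths
  parsed <- ape::read.tree(text = nwk1)
  expect_equal(phangorn::RF.dist(ape::unroot(parsed), ape::unroot(tr)), 0)
  expect_equal(sort(parsed$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)

  # labels with spaces are quoted
  d2 <- stats::dist(c(`sp one` = 0, `sp two` = 1))
  nwk2 <- write_newick(usage_cluster(d2, k = 1))
  expect_equal(nwk2, "('sp one':0.5,'sp two':0.5);")
})

test_that("NJ and clustering both recover the default planted cohort", {
  co <- generate_cohort(cohort_spec(), seed = 1)
  r <- rscu(count_codons(co$sequences))
  d <- rscu_distance(r)
  truth <- co$manifest$group

  cl <- usage_cluster(d, k = 2)
  expect_equal(two_group_agreement(
    cl$partition$cluster[match(co$manifest$gene_id, cl$partition$gene_id)],
    truth), 1)

  njp <- nj_partition(neighbor_joining(d))
  expect_equal(two_group_agreement(
    njp$cluster[match(co$manifest$gene_id, njp$gene_id)], truth), 1)
})
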