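#' Euclidean distances between RSCU profiles
#'
#' Pairwise Euclidean distance between genes in the 59-dimensional RSCU
#' space. Undefined RSCU entries (unused families) are imputed as 0, so all
#' profiles live in the same codon universe.
#'
#' @param rscu_tbl Long RSCU tibble from [rscu()], or a genes-by-codon
#'   matrix as from [rscu_wide()].
#' @return A [stats::dist] object with gene labels.
#' @export
rscu_distance <- function(rscu_tbl) {
  m <- if (is.data.frame(rscu_tbl)) rscu_wide(rscu_tbl) else rscu_tbl
  stats::dist(m, method = "euclidean")
}

#' Hierarchical clustering of codon-usage profiles
#'
#' Agglomerative clustering of a gene distance matrix (default: average
#' linkage, the convention for RSCU dendrograms), with a flat partition cut
#' at `k` groups.
#'
#' @param d A [stats::dist] object, e.g. from [rscu_distance()].
#' @param linkage One of `"average"`, `"complete"`, `"single"`,
#'   `"ward.D2"`.
#' @param k Number of flat groups to extract (default 2).
#' @return An object of class `usage_cluster`: list with `hclust` (the
#'   [stats::hclust] tree), `partition` (tibble `gene_id`, `cluster`),
#'   `linkage`, `k`.
#' @export
usage_cluster <- function(d, linkage = c("average", "complete", "single",
                                         "ward.D2"), k = 2) {
  linkage <- match.arg(linkage)
  n <- attr(d, "Size")
  if (k > n) stop("k = ", k, " exceeds the number of genes (", n, ")",
                  call. = FALSE)
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, k = k)
  structure(list(
    hclust = hc,
    partition = tibble::tibble(gene_id = names(cut),
                               cluster = unname(cut)),
    linkage = linkage,
    k = k
  ), class = "usage_cluster")
}

#' @export
print.usage_cluster <- function(x, ...) {
  cat("Codon-usage cluster tree (", x$linkage, " linkage, ",
      length(x$hclust$order), " genes, k = ", x$k, ")\n", sep = "")
  print(table(x$partition$cluster))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the Saitou-Nei neighbor-joining tree (unrooted) for any distance
#' matrix, by default the Euclidean RSCU distance. NJ can return small
#' negative branch lengths on noisy data; these are clamped to zero with
#' the deficit transferred to the adjacent branches so that path lengths
#' through the node are preserved where possible. The raw (unclamped)
#' lengths are kept in `attr(, "raw_edge_length")`.
#'
#' @param d A [stats::dist] object over at least 3 taxa.
#' @param clamp_negative Clamp negative branch lengths (default `TRUE`).
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) {
    stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  }
  tree <- ape::nj(d)
  raw <- tree$edge.length
  if (clamp_negative && any(tree$edge.length < 0)) {
    tree <- .clamp_negative_edges(tree)
  }
  attr(tree, "raw_edge_length") <- raw
  tree
}

# set negative edges to zero, pushing the deficit onto the edges emanating
# from the child node (iterate; bounded by the edge count)
.clamp_negative_edges <- function(tree) {
  for (pass in seq_len(length(tree$edge.length) + 1L)) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2L]
    below <- which(tree$edge[, 1L] == child)
    if (length(below) > 0L) {
      tree$edge.length[below] <- tree$edge.length[below] + deficit
    }
    # leaf edge with nothing below: deficit is simply dropped
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Two-group partition from a neighbor-joining tree
#'
#' Midpoint-roots the (intrinsically unrooted) NJ tree and splits the
#' leaves by the two subtrees of the root.
#'
#' @param tree An [ape::phylo] tree from [neighbor_joining()].
#' @return Tibble `gene_id`, `cluster` (1/2).
#' @export
nj_partition <- function(tree) {
  rooted <- phangorn::midpoint(tree)
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1L] == root, 2L]
  side1 <- if (kids[1L] <= length(rooted$tip.label)) {
    rooted$tip.label[kids[1L]]
  } else {
    ape::extract.clade(rooted, kids[1L])$tip.label
  }
  tibble::tibble(
    gene_id = rooted$tip.label,
    cluster = ifelse(rooted$tip.label %in% side1, 1L, 2L)
  )
}

#' Write a tree as a Newick string
#'
#' Deterministic Newick serialisation with branch lengths: children of each
#' node are ordered lexicographically by their smallest descendant leaf
#' label, and labels needing it are quoted per Newick rules. Accepts
#' cluster trees ([usage_cluster()] results, serialised as ultrametric
#' dendrograms whose leaf-to-merge path lengths equal half the merge
#' height) and [ape::phylo] trees.
#'
#' @param tree A `usage_cluster` object, [stats::hclust] tree, or
#'   [ape::phylo] tree.
#' @param path Optional file to write to.
#' @param digits Significant digits for branch lengths (default 10).
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (inherits(tree, "usage_cluster")) tree <- tree$hclust
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) {
    stop("unsupported tree object", call. = FALSE)
  }
  nwk <- paste0(.newick_node(tree, .root_node(tree), NA, digits), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

.root_node <- function(tree) {
  setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
}

.newick_quote <- function(label) {
  # ] first so the bracket expression stays literal
  if (grepl("[][ \t():;,']", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

# smallest leaf label under each node, for deterministic child ordering
.min_leaf <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  min(vapply(kids, function(k) .min_leaf(tree, k), character(1)))
}

.newick_node <- function(tree, node, edge_len, digits) {
  ntip <- length(tree$tip.label)
  suffix <- if (is.na(edge_len)) "" else
    paste0(":", format(edge_len, digits = digits, scientific = FALSE,
                       trim = TRUE))
  if (node <= ntip) {
    return(paste0(.newick_quote(tree$tip.label[node]), suffix))
  }
  kid_edges <- which(tree$edge[, 1L] == node)
  kids <- tree$edge[kid_edges, 2L]
  ord <- order(vapply(kids, function(k) .min_leaf(tree, k), character(1)))
  parts <- vapply(ord, function(i) {
    len <- if (is.null(tree$edge.length)) NA_real_ else
      tree$edge.length[kid_edges[i]]
    .newick_node(tree, kids[i], len, digits)
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")", suffix)
}
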