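#' Classical (Torgerson) multidimensional scaling
#'
#' Projects a distance matrix into k dimensions by double-centering of
#' -d^2/2 and eigendecomposition (via [stats::cmdscale()]); axes are ordered
#' by descending eigenvalue and scaled by the square root of the eigenvalue,
#' so Euclidean-realisable distances are reproduced exactly. The embedding is
#' deterministic up to the sign of each axis; for reproducible plots an
#' orientation label can be supplied whose coordinate is made negative on
#' every axis.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of dimensions (default 2).
#' @param orient_negative Optional label whose coordinates are flipped to be
#'   negative (<= 0) on each axis.
#' @return List of class `polyte_mds`: `points` (labels x k), `eig` (all
#'   eigenvalues, descending), `k`.
#' @export
classical_mds <- function(d, k = 2, orient_negative = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (!is.null(orient_negative)) {
    i <- match(orient_negative, rownames(pts))
    if (is.na(i)) stop("orientation label not found: ", orient_negative)
    for (j in seq_len(ncol(pts))) {
      if (pts[i, j] > 0) pts[, j] <- -pts[, j]
    }
  }
  structure(list(points = pts, eig = fit$eig, k = k), class = "polyte_mds")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) over population-averaged
#' allele-sharing distances. Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with the deficit transferred to
#' the adjacent edge (the usual post-processing), so all branch lengths are
#' nonnegative; on additive input the tree is exact and untouched.
#'
#' @param d Symmetric distance matrix (>= 3 labels).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 labels")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

# Move each negative edge's deficit onto its sibling/parent edge and clamp
# to zero; preserves path lengths through the affected node for all pairs
# on opposite sides.
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  repeat {
    i <- which(el < 0)
    if (length(i) == 0) break
    i <- i[1]
    child <- tree$edge[i, 2]
    # edges adjacent through the child node (internal) or the parent node (tip)
    node <- if (child > ape::Ntip(tree)) child else tree$edge[i, 1]
    adj <- setdiff(which(tree$edge[, 1] == node | tree$edge[, 2] == node), i)
    el[adj] <- el[adj] + el[i]
    el[i] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Newick serialisation of a tree
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree) else ape::write.tree(tree, file = path)
}

#' Locate the hypothetical ancestor in embedding and tree
#'
#' Reports where the insertion-free ancestral pseudo-genome falls: its
#' nearest neighbour(s) by distance (ties are all reported, not silently
#' broken), and the bipartition of the remaining taxa induced by its
#' attachment point in the neighbor-joining tree. On serial-founder-structured
#' data the attachment separates the African-like clade from the rest.
#'
#' @param d Distance matrix including the ancestor row/column.
#' @param label Ancestor label (default `"ANCESTOR"`).
#' @return List: `nearest` (character vector, all tied nearest neighbours),
#'   `nearest_distance`, `split` (list of two character vectors: the taxon
#'   sets on either side of the attachment edge).
#' @export
attach_ancestor_and_report <- function(d, label = "ANCESTOR") {
  d <- as.matrix(d)
  if (!label %in% rownames(d)) stop("ancestor label absent: ", label)
  dv <- d[label, setdiff(rownames(d), label)]
  nearest <- names(dv)[dv <= min(dv) + 1e-12]

  tree <- neighbor_joining(d)
  tip <- which(tree$tip.label == label)
  parent <- tree$edge[tree$edge[, 2] == tip, 1]
  # the two subtrees hanging off the attachment node, away from the ancestor
  adj <- tree$edge[tree$edge[, 1] == parent & tree$edge[, 2] != tip, 2]
  if (length(adj) < 2) {  # attachment node also the ape root trifurcation
    adj <- c(adj, tree$edge[tree$edge[, 2] == parent, 1])
  }
  sides <- lapply(adj, function(v) tips_away(tree, parent, v))
  list(nearest = nearest, nearest_distance = unname(min(dv)),
       split = lapply(sides, function(s) setdiff(s, label)))
}

# tip labels reachable from `from` when entering node/tip `v`, not crossing
# back through `from` (treats the phylo edge list as an undirected tree)
tips_away <- function(tree, from, v) {
  ntip <- ape::Ntip(tree)
  out <- character(0)
  stack <- list(c(from, v))
  while (length(stack) > 0) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    prev <- e[1]; cur <- e[2]
    if (cur <= ntip) {
      out <- c(out, tree$tip.label[cur])
      next
    }
    nb <- c(tree$edge[tree$edge[, 1] == cur, 2],
            tree$edge[tree$edge[, 2] == cur, 1])
    for (w in setdiff(nb, prev)) stack[[length(stack) + 1]] <- c(cur, w)
  }
  out
}

#' Write an MDS embedding as TSV
#' @param mds A `polyte_mds` object.
#' @param path Output path.
#' @export
write_embedding <- function(mds, path) {
  out <- data.frame(label = rownames(mds$points), mds$points)
  names(out)[-1] <- paste0("axis", seq_len(ncol(mds$points)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
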