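#' Minimum-spanning-tree network topology
#'
#' Functional network organisation is summarised on the spanning tree over
#' the strongest connections (the standard MEG-network "MST" backbone,
#' equivalently the minimum spanning tree of `1 - PLV`): its diameter (the
#' longest shortest path, in hops — an inverse proxy for integration) and its
#' leaf fraction (fraction of degree-1 nodes — a proxy for segregation).
#'
#' @name mst_metrics
#' @keywords internal
NULL

#' Maximum spanning tree of a connectivity matrix
#'
#' Kruskal's algorithm on edges sorted by decreasing weight, with exact ties
#' broken lexicographically by (row, column) index so results are fully
#' deterministic. Disconnected input is rejected with the component
#' partition in the error message.
#'
#' @param w Symmetric non-negative weight matrix (e.g. a PLV matrix); the
#'   diagonal is ignored. Entries equal to zero are treated as absent edges.
#' @return Integer matrix of `n - 1` rows, columns `i`, `j` (i < j), the tree
#'   edges in the order added.
#' @examples
#' w <- matrix(0, 4, 4)
#' w[upper.tri(w)] <- c(0.9, 0.8, 0.2, 0.1, 0.7, 0.3)
#' w <- w + t(w)
#' maximum_spanning_tree(w)
#' @export
maximum_spanning_tree <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  n <- nrow(w)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12))) stop("weight matrix must be symmetric")
  if (any(w[upper.tri(w)] < 0)) stop("weights must be non-negative")
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  comp_check <- igraph::components(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  )
  if (comp_check$no > 1) {
    stop(
      "input graph is disconnected; component sizes: ",
      paste(comp_check$csize, collapse = ", "),
      "; membership: ", paste(comp_check$membership, collapse = " ")
    )
  }
  ord <- order(-w[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(0L, n - 1, 2, dimnames = list(NULL, c("i", "j")))
  k <- 0L
  for (e in seq_len(nrow(idx))) {
    a <- find(idx[e, 1])
    b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      edges[k, ] <- c(idx[e, 1], idx[e, 2])
      if (k == n - 1L) break
    }
  }
  edges
}

tree_graph <- function(edges, n) {
  stopifnot(is.matrix(edges), ncol(edges) == 2)
  if (nrow(edges) != n - 1) stop("not a tree: expected ", n - 1, " edges, got ", nrow(edges))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (!igraph::is_connected(g) || igraph::ecount(g) != n - 1) {
    stop("not a tree: graph is disconnected or cyclic")
  }
  g
}

#' Tree diameter in hops
#'
#' The longest shortest path of a spanning tree, counted in edges.
#'
#' @param edges Two-column edge matrix (from [maximum_spanning_tree()]).
#' @param n Number of nodes.
#' @param normalized If TRUE, divide by `n - 1` (the path-graph maximum).
#' @return Diameter (integer hops, or a fraction if normalised).
#' @export
tree_diameter <- function(edges, n, normalized = FALSE) {
  g <- tree_graph(edges, n)
  d <- igraph::diameter(g, weights = NA)
  if (normalized) d / (n - 1) else as.integer(d)
}

#' Leaf fraction of a tree
#'
#' Fraction of nodes with exactly one connection.
#'
#' @inheritParams tree_diameter
#' @return Real in (0, 1].
#' @export
leaf_fraction <- function(edges, n) {
  g <- tree_graph(edges, n)
  sum(igraph::degree(g) == 1) / n
}

#' Spanning-tree summary of a functional network
#'
#' Convenience wrapper: extracts the maximum spanning tree of the PLV matrix
#' and computes both topology measures.
#'
#' @param fn A `functional_network` (or a bare symmetric matrix).
#' @return A `spanning_tree_summary`: `edges`, `diameter`, `leaf_fraction`,
#'   `n_regions`.
#' @export
mst_summary <- function(fn) {
  w <- if (inherits(fn, "functional_network")) fn$plv else fn
  w <- w - diag(diag(w)) # self-weights never enter a spanning tree
  n <- nrow(w)
  edges <- maximum_spanning_tree(w)
  structure(
    list(
      edges = edges,
      diameter = tree_diameter(edges, n),
      leaf_fraction = leaf_fraction(edges, n),
      n_regions = n
    ),
    class = "spanning_tree_summary"
  )
}

#' @export
print.spanning_tree_summary <- function(x, ...) {
  cat(sprintf(
    "<spanning_tree_summary> %d regions: diameter %d hops, leaf fraction %.3f\n",
    x$n_regions, x$diameter, x$leaf_fraction
  ))
  invisible(x)
}

#' Write a spanning tree as an edge-list TSV
#'
#' Columns `region_i`, `region_j`, `weight`.
#'
#' @param tree A `spanning_tree_summary`.
#' @param w The weight matrix the tree was computed from.
#' @param path Output file path.
#' @export
write_tree <- function(tree, w, path) {
  utils::write.table(
    data.frame(
      region_i = tree$edges[, 1], region_j = tree$edges[, 2],
      weight = w[tree$edges]
    ),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
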