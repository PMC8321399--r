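#' Minimum spanning forest by Kruskal's algorithm
#'
#' Consumes a weight-sorted edge stream and grows a forest with a
#' disjoint-set structure (union by rank, path halving): an edge is accepted
#' exactly when it connects two different trees. Nodes untouched by any edge
#' remain singleton roots. Within each tree the node with the smallest index
#' is chosen as root and the edges are oriented away from it.
#'
#' @param num_nodes number of distinct reads (graph nodes).
#' @param edges edge data frame sorted by nondecreasing `weight` (see
#'   [collect_rounds()]).
#' @return an object of class `has_forest` with fields `parent_of` (`NA` at
#'   roots), `edge_of` (row index into `edges` of the edge to the parent),
#'   `edges` (the accepted edges), `roots`, `total_weight`, `num_nodes`.
#' @export
kruskal_msf <- function(num_nodes, edges) {
  num_nodes <- as.integer(num_nodes)
  edges$u <- as.integer(edges$u)
  edges$v <- as.integer(edges$v)
  if (nrow(edges) && is.unsorted(edges$weight)) {
    stop("edge stream is not sorted by nondecreasing weight", call. = FALSE)
  }
  parent <- seq_len(num_nodes)
  rnk <- integer(num_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    ru <- find(edges$u[i]); rv <- find(edges$v[i])
    if (ru != rv) {
      keep[i] <- TRUE
      if (rnk[ru] < rnk[rv]) { parent[ru] <- rv }
      else if (rnk[ru] > rnk[rv]) { parent[rv] <- ru }
      else { parent[rv] <- ru; rnk[ru] <- rnk[ru] + 1L }
    }
  }
  sel <- edges[keep, , drop = FALSE]
  rownames(sel) <- NULL
  # orient each tree away from its smallest-index node
  adj_from <- c(sel$u, sel$v)
  adj_to <- c(sel$v, sel$u)
  adj_edge <- c(seq_len(nrow(sel)), seq_len(nrow(sel)))
  ord <- order(adj_from, adj_to)
  adj_from <- adj_from[ord]; adj_to <- adj_to[ord]; adj_edge <- adj_edge[ord]
  bounds <- findInterval(0:num_nodes + 0.5, adj_from)
  parent_of <- rep(NA_integer_, num_nodes)
  edge_of <- rep(NA_integer_, num_nodes)
  comp <- vapply(seq_len(num_nodes), find, 0L)
  roots <- as.integer(tapply(seq_len(num_nodes), comp, min))
  roots <- sort(roots)
  visited <- logical(num_nodes)
  for (r in roots) {
    queue <- r
    visited[r] <- TRUE
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      lo <- bounds[x]; hi <- bounds[x + 1L]
      if (hi > lo) {
        nb <- adj_to[(lo + 1L):hi]
        ed <- adj_edge[(lo + 1L):hi]
        new <- !visited[nb]
        if (any(new)) {
          nb <- nb[new]; ed <- ed[new]
          visited[nb] <- TRUE
          parent_of[nb] <- x
          edge_of[nb] <- ed
          queue <- c(queue, nb)
        }
      }
    }
  }
  structure(list(parent_of = parent_of, edge_of = edge_of, edges = sel,
                 roots = roots, total_weight = sum(sel$weight),
                 num_nodes = num_nodes),
            class = "has_forest")
}

#' @export
print.has_forest <- function(x, ...) {
  cat(sprintf("<has_forest> %d nodes, %d trees, %d edges, total weight %d\n",
              x$num_nodes, length(x$roots), nrow(x$edges), x$total_weight))
  invisible(x)
}
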