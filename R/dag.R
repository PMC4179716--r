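#' Directed acyclic graph over named nodes
#'
#' A `dag` is the structure `G` of a Bayesian network: an ordered node set and
#' a set of directed edges, constrained to be acyclic. Nodes are ROI names;
#' an edge `parent -> child` states that the child's conditional mean is
#' linear in the parent.
#'
#' @param nodes character vector of unique node names (order is kept and used
#'   for deterministic tie-breaking elsewhere).
#' @param edges two-column character matrix or data.frame (`parent`, `child`),
#'   or `NULL` for the empty graph.
#' @return An object of class `dag` with elements `nodes` and `edges`
#'   (a two-column character matrix).
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' dag_parents(g, "C")
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("dag needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node names: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns (parent, child)")
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("parent", "child")
  rownames(edges) <- NULL
  bad <- setdiff(c(edges), nodes)
  if (length(bad)) stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
  if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicated edges")
  g <- structure(list(nodes = nodes, edges = edges), class = "dag")
  if (is.null(topological_order(g))) stop("edge set contains a directed cycle")
  g
}

#' @export
print.dag <- function(x, ...) {
  cat("dag with", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parent set of a node
#'
#' @param g a [dag()].
#' @param node node name.
#' @return Character vector of parents (in-neighbours), possibly empty.
#' @export
dag_parents <- function(g, node) {
  stopifnot(inherits(g, "dag"))
  if (!node %in% g$nodes) stop("unknown node: ", node)
  unname(g$edges[g$edges[, 2L] == node, 1L])
}

#' Adjacency matrix of a dag
#'
#' @param g a [dag()].
#' @return Logical `p x p` matrix `A` with `A[i, j]` true iff edge
#'   `nodes[i] -> nodes[j]` is present; dimnames are the node names.
#' @export
dag_adjacency <- function(g) {
  stopifnot(inherits(g, "dag"))
  p <- length(g$nodes)
  a <- matrix(FALSE, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    a[cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes))] <- TRUE
  }
  a
}

# Kahn's algorithm on the adjacency; NULL when a cycle remains.
topological_order <- function(g) {
  a <- if (inherits(g, "dag")) dag_adjacency(g) else g
  p <- nrow(a)
  indeg <- colSums(a)
  order <- integer(0)
  active <- rep(TRUE, p)
  repeat {
    ready <- which(active & indeg == 0)
    if (!length(ready)) break
    i <- ready[1L]
    order <- c(order, i)
    active[i] <- FALSE
    indeg <- indeg - a[i, ]
    a[i, ] <- FALSE
  }
  if (any(active)) return(NULL)
  if (!is.null(rownames(a))) rownames(a)[order] else order
}

# Directed reachability from -> to on a logical adjacency matrix (BFS).
adj_has_path <- function(a, from, to) {
  if (from == to) return(TRUE)
  seen <- rep(FALSE, nrow(a))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(a[frontier[1L], ] & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- c(frontier[-1L], nxt)
  }
  FALSE
}

adj_to_dag <- function(a, nodes = rownames(a)) {
  idx <- which(a, arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    dag(nodes, cbind(nodes[idx[, 1L]], nodes[idx[, 2L]]))
  } else {
    dag(nodes)
  }
}

# Canonical sorted edge string, used for tie-breaks and set comparisons.
edge_key <- function(edges) {
  if (NROW(edges) == 0L) return(character(0))
  sort(paste(edges[, 1L], edges[, 2L], sep = "->"))
}
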