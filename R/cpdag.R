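# Markov equivalence utilities. BIC cannot distinguish DAGs with the same
# skeleton and v-structures, so structure-recovery claims are stated on the
# CPDAG (completed partially directed acyclic graph) of the learned model.

#' CPDAG of a DAG (Markov equivalence class representative)
#'
#' Keeps the skeleton, orients the v-structure (unshielded collider) edges,
#' and closes under the Meek orientation rules R1-R3; the remaining edges are
#' reversible within the equivalence class and stay undirected. (Rule R4
#' only applies when external background-knowledge orientations are present,
#' which never happens here.)
#'
#' @param g a [dag()].
#' @return Object of class `pdag`: list with `nodes`, `directed` (compelled
#'   edges, two-column matrix) and `undirected` (reversible edges, canonical
#'   two-column matrix with the lexicographically smaller endpoint first).
#' @export
cpdag <- function(g) {
  stopifnot(inherits(g, "dag"))
  a <- dag_adjacency(g)
  p <- nrow(a)
  nodes <- g$nodes
  skel <- a | t(a)
  dir <- matrix(FALSE, p, p, dimnames = dimnames(a))   # compelled u -> v
  # v-structures: a -> c <- b with a, b non-adjacent
  for (cc in seq_len(p)) {
    pa <- which(a[, cc])
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in seq((i + 1L), length(pa))) {
      u <- pa[i]; v <- pa[j]
      if (!skel[u, v]) {
        dir[u, cc] <- TRUE
        dir[v, cc] <- TRUE
      }
    }
  }
  und <- skel & !(dir | t(dir))
  repeat {
    changed <- FALSE
    orient <- function(u, v) {
      dir[u, v] <<- TRUE
      und[u, v] <<- FALSE
      und[v, u] <<- FALSE
      changed <<- TRUE
    }
    for (u in seq_len(p)) for (v in seq_len(p)) {
      if (!und[u, v] || u == v) next
      # R1: w -> u, u - v, w and v non-adjacent  =>  u -> v
      ws <- which(dir[, u])
      if (any(!skel[ws, v])) { orient(u, v); next }
      # R2: u -> w -> v with u - v  =>  u -> v
      if (any(dir[u, ] & dir[, v])) { orient(u, v); next }
      # R3: u - w1, u - w2, w1 -> v, w2 -> v, w1 and w2 non-adjacent => u -> v
      ws <- which(und[u, ] & dir[, v])
      if (length(ws) >= 2L) {
        hit <- FALSE
        for (i in seq_len(length(ws) - 1L)) for (j in seq((i + 1L), length(ws))) {
          if (!skel[ws[i], ws[j]]) hit <- TRUE
        }
        if (hit) { orient(u, v); next }
      }
    }
    if (!changed) break
  }
  didx <- which(dir, arr.ind = TRUE)
  uidx <- which(und & upper.tri(und), arr.ind = TRUE)
  directed <- if (nrow(didx)) {
    e <- cbind(nodes[didx[, 1L]], nodes[didx[, 2L]])
    e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  } else matrix(character(0), ncol = 2L)
  undirected <- if (nrow(uidx)) {
    e <- cbind(pmin(nodes[uidx[, 1L]], nodes[uidx[, 2L]]),
               pmax(nodes[uidx[, 1L]], nodes[uidx[, 2L]]))
    unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
  } else matrix(character(0), ncol = 2L)
  colnames(directed) <- colnames(undirected) <- c("a", "b")
  structure(list(nodes = nodes, directed = directed, undirected = undirected),
            class = "pdag")
}

#' @export
print.pdag <- function(x, ...) {
  cat("pdag on", length(x$nodes), "nodes:",
      nrow(x$directed), "compelled,", nrow(x$undirected), "reversible edges\n")
  if (nrow(x$directed))
    cat("  ", paste(x$directed[, 1L], "->", x$directed[, 2L], collapse = ", "), "\n")
  if (nrow(x$undirected))
    cat("  ", paste(x$undirected[, 1L], "--", x$undirected[, 2L], collapse = ", "), "\n")
  invisible(x)
}

#' Skeleton of a dag or pdag as canonical unordered pairs
#'
#' @param g a [dag()] or `pdag`.
#' @return Character vector of `"a--b"` keys (a < b), sorted.
#' @export
skeleton <- function(g) {
  e <- if (inherits(g, "dag")) g$edges else rbind(g$directed, g$undirected)
  if (!NROW(e)) return(character(0))
  sort(unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "--")))
}

#' Are two DAGs Markov equivalent (same skeleton and v-structures)?
#'
#' @param g1,g2 two [dag()]s on the same node set.
#' @return `TRUE` when their CPDAGs coincide.
#' @export
markov_equivalent <- function(g1, g2) {
  p1 <- cpdag(g1); p2 <- cpdag(g2)
  setequal(p1$nodes, p2$nodes) &&
    identical(edge_key(p1$directed), edge_key(p2$directed)) &&
    identical(edge_key(p1$undirected), edge_key(p2$undirected))
}
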