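# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: moments are built by recursion over the
# topological order (not the matrix-inverse identity the package uses), and
# the MVN log-pdf goes through base determinant/solve.

# Joint mean and covariance of a linear Gaussian network, built node by node:
# cov(X_j, X_k) = sum_p beta_pj cov(X_p, X_k) for k earlier in the order,
# var(X_j) = sum over parent pairs + residual variance.
oracle_mvn <- function(bn) {
  nodes <- bn$dag$nodes
  ord <- topological_order(bn$dag)
  p <- length(nodes)
  cv <- matrix(0, p, p, dimnames = list(nodes, nodes))
  mu <- stats::setNames(numeric(p), nodes)
  for (nd in ord) {
    pr <- bn$params[[nd]]
    mu[nd] <- pr$mean
    pa <- names(pr$coefficients)
    b <- pr$coefficients
    for (other in ord) {
      if (other == nd) break
      cv[nd, other] <- cv[other, nd] <- sum(b * cv[pa, other])
    }
    cv[nd, nd] <- pr$residual_sd^2 +
      if (length(pa)) drop(t(b) %*% cv[pa, pa, drop = FALSE] %*% b) else 0
  }
  list(mean = mu, cov = cv)
}

oracle_mvn_logpdf <- function(mvn, x) {
  # x: matrix with columns in names(mvn$mean)
  x <- as.matrix(x)[, names(mvn$mean), drop = FALSE]
  p <- length(mvn$mean)
  ld <- determinant(mvn$cov, logarithm = TRUE)$modulus
  cn <- sweep(x, 2L, mvn$mean)
  maha <- rowSums((cn %*% solve(mvn$cov)) * cn)
  as.numeric(-0.5 * (p * log(2 * pi) + ld + maha))
}

# Random linear Gaussian network on p nodes: random topological order,
# Bernoulli(edge_p) edges, weights in the magnitude range the studied
# networks exhibit, optionally sign-mixed.
random_gbn <- function(p = 4, edge_p = 0.4, beta_range = c(0.3, 0.9),
                       sd_range = c(0.5, 1.5), mean_range = c(-1, 8),
                       mixed_signs = FALSE) {
  nodes <- paste0("V", seq_len(p))
  perm <- sample(nodes)
  edges <- NULL
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    if (stats::runif(1) < edge_p) edges <- rbind(edges, c(perm[i], perm[j]))
  }
  g <- dag(nodes, edges)
  params <- lapply(nodes, function(nd) {
    pa <- dag_parents(g, nd)
    sg <- if (mixed_signs) sample(c(-1, 1), length(pa), TRUE) else rep(1, length(pa))
    list(mean = stats::runif(1, mean_range[1], mean_range[2]),
         coefficients = stats::setNames(
           sg * stats::runif(length(pa), beta_range[1], beta_range[2]), pa),
         residual_sd = stats::runif(1, sd_range[1], sd_range[2]))
  })
  names(params) <- nodes
  gbn(g, params)
}

# A random 4-node dataset drawn from a random network (the instance family
# for the search-oracle comparisons).
random_instance <- function(p = 4, n = 300, ...) {
  roi_matrix(sample_gbn(random_gbn(p = p, ...), n))
}

# Two-group table from two (possibly identical) networks, no spec object.
two_group_table <- function(bn_a, bn_b, n_a, n_b) {
  ta <- sample_gbn(bn_a, n_a, group = "A", subject_prefix = "A")
  tb <- sample_gbn(bn_b, n_b, group = "B", subject_prefix = "B")
  roi_table(rbind(roi_matrix(ta), roi_matrix(tb)),
            c(ta$subject_id, tb$subject_id), c(ta$group, tb$group))
}

# Equivalence-class oracle: all DAGs on the node set sharing skeleton and
# v-structures with g; an edge is compelled iff it has the same direction in
# every class member. Independent of the package's Meek-rule closure.
oracle_equivalence_class <- function(g) {
  nodes <- g$nodes
  p <- length(nodes)
  vstructs <- function(d) {
    a <- dag_adjacency(d)
    sk <- a | t(a)
    out <- character(0)
    for (cc in seq_len(p)) {
      pa <- which(a[, cc])
      if (length(pa) < 2) next
      for (i in seq_len(length(pa) - 1)) for (j in seq((i + 1), length(pa))) {
        if (!sk[pa[i], pa[j]]) {
          out <- c(out, paste(sort(nodes[c(pa[i], pa[j])])[1],
                              sort(nodes[c(pa[i], pa[j])])[2], nodes[cc]))
        }
      }
    }
    sort(out)
  }
  target_skel <- skeleton(g)
  target_v <- vstructs(g)
  # enumerate all orientations of the skeleton edges, keep acyclic + matching
  pairs <- strsplit(target_skel, "--", fixed = TRUE)
  m <- length(pairs)
  members <- list()
  for (code in 0:(2^m - 1)) {
    edges <- t(vapply(seq_len(m), function(k) {
      pr <- pairs[[k]]
      if (bitwAnd(code, bitwShiftL(1L, k - 1L)) > 0L) rev(pr) else pr
    }, character(2)))
    d <- tryCatch(dag(nodes, edges), error = function(e) NULL)
    if (!is.null(d) && identical(vstructs(d), target_v)) {
      members[[length(members) + 1L]] <- d
    }
  }
  members
}
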