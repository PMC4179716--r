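#' Linear Gaussian Bayesian network
#'
#' The pair `(G, theta)`: a [dag()] plus, for every node `j`, an unconditional
#' mean `u_j`, one linear weight `beta_p` per parent, and a residual standard
#' deviation `sigma_j > 0`. The conditional density of node `j` is normal with
#' mean `u_j + sum_p beta_p * (x_p - u_p)` and sd `sigma_j`; the implied joint
#' is multivariate normal.
#'
#' @param dag a [dag()].
#' @param params named list (one entry per node) of lists with elements
#'   `mean`, `coefficients` (named numeric, names exactly the node's parents;
#'   may be empty), and `residual_sd` (> 0).
#' @param n_fit number of subjects used in fitting; 0 for hand-specified models.
#' @return An object of class `gbn`.
#' @examples
#' g <- dag(c("X1", "X2"), rbind(c("X1", "X2")))
#' bn <- gbn(g, list(
#'   X1 = list(mean = 0, coefficients = numeric(0), residual_sd = 1),
#'   X2 = list(mean = 0, coefficients = c(X1 = 0.786), residual_sd = 0.5)))
#' log_density(bn, c(X1 = 0, X2 = 0))
#' @export
gbn <- function(dag, params, n_fit = 0L) {
  stopifnot(inherits(dag, "dag"))
  if (!setequal(names(params), dag$nodes) || length(params) != length(dag$nodes)) {
    stop("params must have exactly one entry per dag node")
  }
  params <- params[dag$nodes]
  for (nd in dag$nodes) {
    pr <- params[[nd]]
    if (!all(c("mean", "coefficients", "residual_sd") %in% names(pr))) {
      stop("node '", nd, "': params need mean, coefficients, residual_sd")
    }
    if (!is.finite(pr$residual_sd) || pr$residual_sd <= 0) {
      stop("node '", nd, "': residual_sd must be strictly positive")
    }
    pa <- dag_parents(dag, nd)
    cf <- pr$coefficients
    if (length(pa) == 0L && length(cf) == 0L) next
    if (!setequal(names(cf), pa) || length(cf) != length(pa)) {
      stop("node '", nd, "': coefficient names must equal the parent set {",
           paste(pa, collapse = ", "), "}")
    }
    params[[nd]]$coefficients <- cf[pa]
  }
  structure(list(dag = dag, params = params, n_fit = as.integer(n_fit)),
            class = "gbn")
}

#' @export
print.gbn <- function(x, ...) {
  cat("Gaussian Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges", if (x$n_fit > 0) paste0("(fitted on n=", x$n_fit, ")"), "\n")
  for (nd in x$dag$nodes) {
    pr <- x$params[[nd]]
    rhs <- if (length(pr$coefficients)) {
      paste(sprintf("%+.3f*(%s - u)", pr$coefficients, names(pr$coefficients)),
            collapse = " ")
    } else ""
    cat(sprintf("  %s ~ N(%.3f %s, sd %.3f)\n", nd, pr$mean, rhs, pr$residual_sd))
  }
  invisible(x)
}

# Shared least-squares engine: column means plus centered cross-products of a
# group's ROI matrix. All family fits and search scores are computed from this.
prep_fit_data <- function(x, nodes = colnames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  missing <- setdiff(nodes, colnames(x))
  if (length(missing)) stop("data is missing ROI columns: ", paste(missing, collapse = ", "))
  x <- x[, nodes, drop = FALSE]
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in ROI data")
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  s <- crossprod(xc)
  zero <- nodes[diag(s) <= 0]
  if (length(zero)) stop("zero-variance ROI column(s): ", paste(zero, collapse = ", "))
  list(n = n, means = mu, s = s, nodes = nodes)
}

# OLS of centered child on centered parents from cross-products; MLE
# (divide-by-N) residual variance. p_idx may be empty.
family_ols <- function(fd, c_idx, p_idx) {
  if (length(p_idx) == 0L) {
    return(list(beta = numeric(0), sigma2 = fd$s[c_idx, c_idx] / fd$n))
  }
  spp <- fd$s[p_idx, p_idx, drop = FALSE]
  if (qr(spp)$rank < length(p_idx)) {
    stop("singular parent design for node '", fd$nodes[c_idx], "' (collinear parents: ",
         paste(fd$nodes[p_idx], collapse = ", "), ")")
  }
  spc <- fd$s[p_idx, c_idx]
  beta <- drop(solve(spp, spc))
  rss <- fd$s[c_idx, c_idx] - sum(spc * beta)
  list(beta = beta, sigma2 = max(rss, 0) / fd$n)
}

resolve_fit_matrix <- function(data, nodes = NULL) {
  if (inherits(data, "roi_table")) data <- roi_matrix(data)
  data <- as.matrix(data)
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, colnames(data))
    if (length(missing)) stop("data is missing ROI columns: ", paste(missing, collapse = ", "))
    data <- data[, nodes, drop = FALSE]
  }
  data
}

#' Maximum-likelihood parameters for a fixed structure
#'
#' For each node, the unconditional mean is the sample column mean, the
#' connection weights are the ordinary-least-squares solution of the
#' mean-centered node on its mean-centered parents, and the residual variance
#' is the divide-by-N (maximum-likelihood) residual variance — the form the
#' BIC's maximized log-likelihood requires.
#'
#' @param dag a [dag()] whose nodes are columns of `data`.
#' @param data a [roi_table()] (typically one group's rows) or numeric matrix.
#' @param standardize if `TRUE`, z-score each column before fitting (off by
#'   default; volumes are modelled on their raw scale).
#' @return A fitted [gbn()] with `n_fit` set to the row count.
#' @export
fit_mle <- function(dag, data, standardize = FALSE) {
  stopifnot(inherits(dag, "dag"))
  x <- resolve_fit_matrix(data, dag$nodes)
  if (standardize) x <- scale(x)
  max_pa <- if (nrow(dag$edges)) max(table(factor(dag$edges[, 2L], levels = dag$nodes))) else 0L
  if (nrow(x) < max_pa + 2L) {
    stop("need at least ", max_pa + 2L, " subjects to fit (have ", nrow(x), ")")
  }
  fd <- prep_fit_data(x, dag$nodes)
  params <- lapply(seq_along(dag$nodes), function(j) {
    pa <- dag_parents(dag, dag$nodes[j])
    fit <- family_ols(fd, j, match(pa, dag$nodes))
    if (fit$sigma2 <= 0) {
      stop("zero residual variance for node '", dag$nodes[j], "' (deterministic family)")
    }
    list(mean = unname(fd$means[j]),
         coefficients = stats::setNames(as.numeric(fit$beta), pa),
         residual_sd = sqrt(fit$sigma2))
  })
  names(params) <- dag$nodes
  gbn(dag, params, n_fit = fd$n)
}

#' Joint log-density of subjects under a Gaussian BN
#'
#' Sum over nodes of the univariate normal log-density of each node given its
#' parents — the factorized joint density of the network.
#'
#' @param bn a [gbn()].
#' @param x named numeric vector covering all nodes, or a matrix / roi_table
#'   with one row per subject.
#' @return Numeric vector of log-densities, one per subject.
#' @export
log_density <- function(bn, x) {
  stopifnot(inherits(bn, "gbn"))
  nodes <- bn$dag$nodes
  if (is.null(dim(x)) && !inherits(x, "roi_table")) x <- t(as.matrix(x))
  xm <- resolve_fit_matrix(x, nodes)
  if (anyNA(xm) || any(!is.finite(xm))) stop("non-finite values in subject data")
  ll <- numeric(nrow(xm))
  for (nd in nodes) {
    pr <- bn$params[[nd]]
    mu <- pr$mean
    if (length(pr$coefficients)) {
      pa <- names(pr$coefficients)
      upar <- vapply(bn$params[pa], `[[`, numeric(1), "mean")
      mu <- mu + drop(sweep(xm[, pa, drop = FALSE], 2L, upar) %*% pr$coefficients)
    }
    ll <- ll + stats::dnorm(xm[, nd], mean = mu, sd = pr$residual_sd, log = TRUE)
  }
  unname(ll)
}

#' Bayesian Information Criterion of a network on group data
#'
#' Maximized log-likelihood minus `(d/2) * log(N)` where `d` counts one mean,
#' one residual variance and one weight per parent for every node
#' (`d = sum_j (|parents_j| + 2)`). When `bn` was fitted by [fit_mle()] on the
#' same rows this is the BIC; for other parameters it is the same penalized
#' log-likelihood. The score decomposes as a sum of per-family terms, which
#' the structure search exploits for caching.
#'
#' @param bn a [gbn()].
#' @param data a [roi_table()] or numeric matrix with at least 2 rows.
#' @return Scalar score (natural logarithms; larger is better).
#' @export
bic_score <- function(bn, data) {
  stopifnot(inherits(bn, "gbn"))
  xm <- resolve_fit_matrix(data, bn$dag$nodes)
  n <- nrow(xm)
  if (n < 2L) stop("BIC needs at least 2 subjects")
  d <- sum(vapply(bn$params, function(p) length(p$coefficients) + 2L, integer(1)))
  sum(log_density(bn, xm)) - d / 2 * log(n)
}

#' Draw subjects from a Gaussian BN (ancestral sampling)
#'
#' Samples nodes in topological order, each from its conditional normal given
#' already-sampled parents. Deterministic under a fixed seed.
#'
#' @param bn a [gbn()].
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed (local to this call when supplied).
#' @param group group label for the returned table.
#' @param subject_prefix prefix for generated subject ids.
#' @return A single-group [roi_table()] with `n` rows.
#' @export
sample_gbn <- function(bn, n, seed = NULL, group = "A", subject_prefix = "S") {
  stopifnot(inherits(bn, "gbn"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- bn$dag$nodes
  ord <- topological_order(bn$dag)
  x <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  for (nd in ord) {
    pr <- bn$params[[nd]]
    mu <- pr$mean
    if (length(pr$coefficients)) {
      pa <- names(pr$coefficients)
      upar <- vapply(bn$params[pa], `[[`, numeric(1), "mean")
      mu <- mu + drop(sweep(x[, pa, drop = FALSE], 2L, upar) %*% pr$coefficients)
    }
    x[, nd] <- stats::rnorm(n, mean = mu, sd = pr$residual_sd)
  }
  roi_table(x, sprintf("%s%04d", subject_prefix, seq_len(n)), rep(group, n))
}

#' Implied multivariate normal of a Gaussian BN
#'
#' Solving the linear structural equations gives the joint distribution in
#' closed form: mean `u` and covariance `(I - W)^-1 D (I - W)^-T`, where
#' `W[j, p]` holds the weight of parent `p` in child `j`'s equation and `D`
#' is the diagonal of residual variances.
#'
#' @param bn a [gbn()].
#' @return List with `mean` (named vector) and `cov` (matrix).
#' @export
implied_mvn <- function(bn) {
  stopifnot(inherits(bn, "gbn"))
  nodes <- bn$dag$nodes
  p <- length(nodes)
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  d <- numeric(p)
  u <- numeric(p)
  for (j in seq_len(p)) {
    pr <- bn$params[[nodes[j]]]
    u[j] <- pr$mean
    d[j] <- pr$residual_sd^2
    if (length(pr$coefficients)) w[j, names(pr$coefficients)] <- pr$coefficients
  }
  inv <- solve(diag(p) - w)
  cov <- inv %*% diag(d, p) %*% t(inv)
  dimnames(cov) <- list(nodes, nodes)
  list(mean = stats::setNames(u, nodes), cov = cov)
}
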