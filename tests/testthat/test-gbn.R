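test_that("fit_mle on an edgeless graph returns column means and divide-by-N variances", {
  set.seed(1)
  x <- matrix(rnorm(60, mean = 7, sd = 0.5), 20, 3,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  bn <- fit_mle(dag(colnames(x)), x)
  for (j in colnames(x)) {
    expect_equal(bn$params[[j]]$mean, mean(x[, j]))
    expect_equal(bn$params[[j]]$residual_sd^2,
                 mean((x[, j] - mean(x[, j]))^2))   # MLE, not N-1
    expect_length(bn$params[[j]]$coefficients, 0)
  }
  expect_identical(bn$n_fit, 20L)
})

test_that("fitted single-parent weight matches the closed-form OLS oracle and the truth", {
  g <- dag(c("lSTG", "lHES"), rbind(c("lSTG", "lHES")))
  bn_true <- gbn(g, list(
    lSTG = list(mean = 0, coefficients = numeric(0), residual_sd = 1),
    lHES = list(mean = 0, coefficients = c(lSTG = 0.786), residual_sd = 0.5)))
  x <- roi_matrix(sample_gbn(bn_true, 1e5, seed = 42))
  fit <- fit_mle(g, x)
  beta_hat <- fit$params$lHES$coefficients[["lSTG"]]
  # closed-form OLS from raw moments, independently of the fitting code
  oracle <- stats::cov(x[, "lSTG"], x[, "lHES"]) / stats::var(x[, "lSTG"])
  expect_equal(beta_hat, unname(oracle), tolerance = 1e-10)
  expect_lt(abs(beta_hat - 0.786), 0.02)
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(3)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  x <- cbind(x, c = x[, "a"], d = x[, "a"] + x[, "b"] + rnorm(30))
  g <- dag(colnames(x), rbind(c("a", "d"), c("c", "d")))  # a and c identical
  expect_error(fit_mle(g, x), "singular|collinear")
  xz <- cbind(a = rnorm(30), z = rep(2, 30))
  expect_error(fit_mle(dag(colnames(xz)), xz), "zero-variance.*z")
  expect_error(fit_mle(dag("a"), matrix(c(1, NA), 2, 1, dimnames = list(NULL, "a"))),
               "non-finite|missing")
})

test_that("log_density factorizes correctly for a standard normal node", {
  bn <- gbn(dag("x"), list(x = list(mean = 0, coefficients = numeric(0),
                                    residual_sd = 1)))
  expect_equal(log_density(bn, c(x = 0)), -0.5 * log(2 * pi))
  expect_lt(log_density(bn, c(x = 5)), log_density(bn, c(x = 0)))
  expect_error(log_density(bn, c(x = NaN)), "non-finite")
})

test_that("log_density equals the implied multivariate normal log-pdf", {
  set.seed(7)
  for (i in 1:5) {
    bn <- random_gbn(p = sample(3:6, 1), edge_p = 0.5, mixed_signs = TRUE)
    mvn <- oracle_mvn(bn)
    x <- matrix(rnorm(200 * length(bn$dag$nodes)), 200) %*%
      chol(mvn$cov) + rep(mvn$mean, each = 200)
    colnames(x) <- bn$dag$nodes
    expect_lt(max(abs(log_density(bn, x) - oracle_mvn_logpdf(mvn, x))), 1e-8)
  }
})

test_that("bic_score penalizes (|parents| + 2)/2 log N per node and decomposes", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("V", 1:4)))
  # empty graph: penalty exactly (2k/2) log N
  bn0 <- fit_mle(dag(colnames(x)), x)
  expect_equal(sum(log_density(bn0, x)) - bic_score(bn0, x), 4 * log(50))
  # disjoint sub-networks: score adds up
  g12 <- dag(c("V1", "V2"), rbind(c("V1", "V2")))
  g34 <- dag(c("V3", "V4"), rbind(c("V3", "V4")))
  gall <- dag(colnames(x), rbind(c("V1", "V2"), c("V3", "V4")))
  expect_equal(bic_score(fit_mle(gall, x), x),
               bic_score(fit_mle(g12, x[, 1:2]), x[, 1:2]) +
                 bic_score(fit_mle(g34, x[, 3:4]), x[, 3:4]),
               tolerance = 1e-9)
  expect_error(bic_score(bn0, x[1, , drop = FALSE]), "at least 2")
})

test_that("Markov-equivalent structures score identically; true chain beats empty", {
  set.seed(9)
  g_chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  bn <- gbn(g_chain, list(
    A = list(mean = 0, coefficients = numeric(0), residual_sd = 1),
    B = list(mean = 0, coefficients = c(A = 0.8), residual_sd = 0.6),
    C = list(mean = 0, coefficients = c(B = 0.8), residual_sd = 0.6)))
  x <- roi_matrix(sample_gbn(bn, 500))
  fwd <- dag(c("A", "B"), rbind(c("A", "B")))
  rev <- dag(c("A", "B"), rbind(c("B", "A")))
  expect_equal(bic_score(fit_mle(fwd, x[, 1:2]), x[, 1:2]),
               bic_score(fit_mle(rev, x[, 1:2]), x[, 1:2]), tolerance = 1e-8)
  expect_gt(bic_score(fit_mle(g_chain, x), x),
            bic_score(fit_mle(dag(c("A", "B", "C")), x), x))
})

test_that("ancestral sampling reproduces the implied moments and is seed-deterministic", {
  bn1 <- gbn(dag("v"), list(v = list(mean = 5, coefficients = numeric(0),
                                     residual_sd = 2)))
  s <- roi_matrix(sample_gbn(bn1, 50000, seed = 10))
  expect_lt(abs(mean(s) - 5), 0.05)
  expect_lt(abs(sd(s) - 2), 0.05)

  g <- dag(c("X1", "X2"), rbind(c("X1", "X2")))
  bn2 <- gbn(g, list(
    X1 = list(mean = 0, coefficients = numeric(0), residual_sd = 1),
    X2 = list(mean = 0, coefficients = c(X1 = 0.9), residual_sd = 0.5)))
  x <- roi_matrix(sample_gbn(bn2, 50000, seed = 11))
  mvn <- oracle_mvn(bn2)
  rho <- mvn$cov["X1", "X2"] / sqrt(mvn$cov["X1", "X1"] * mvn$cov["X2", "X2"])
  expect_lt(abs(cor(x[, "X1"], x[, "X2"]) - rho), 0.02)

  expect_identical(sample_gbn(bn2, 100, seed = 3), sample_gbn(bn2, 100, seed = 3))
  expect_error(sample_gbn(bn2, 0), "positive")
})

test_that("fitting samples from a known network recovers its parameters", {
  spec <- builtin_spec("auditory")
  x <- roi_matrix(sample_gbn(spec$bn_a, 1e5, seed = 21))
  fit <- fit_mle(spec$bn_a$dag, x)
  for (nd in spec$bn_a$dag$nodes) {
    tru <- spec$bn_a$params[[nd]]
    est <- fit$params[[nd]]
    if (length(tru$coefficients)) {
      expect_lt(max(abs(est$coefficients - tru$coefficients)), 0.03)
    }
    expect_lt(abs(est$residual_sd / tru$residual_sd - 1), 0.03)
  }
})

test_that("gbn validation catches inconsistent parameters", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  ok <- list(A = list(mean = 0, coefficients = numeric(0), residual_sd = 1),
             B = list(mean = 0, coefficients = c(A = 0.5), residual_sd = 1))
  expect_s3_class(gbn(g, ok), "gbn")
  bad_sd <- ok; bad_sd$B$residual_sd <- 0
  expect_error(gbn(g, bad_sd), "strictly positive")
  bad_cf <- ok; bad_cf$B$coefficients <- c(Z = 0.5)
  expect_error(gbn(g, bad_cf), "parent set")
  expect_error(gbn(g, ok["A"]), "one entry per dag node")
})

test_that("JSON serialization round-trips a fitted network exactly", {
  set.seed(13)
  bn <- fit_mle(random_gbn(p = 4, edge_p = 0.6)$dag, random_instance(p = 4, n = 80))
  path <- withr::local_tempfile(fileext = ".json")
  write_gbn(bn, path)
  back <- read_gbn(path)
  expect_identical(back$dag$nodes, bn$dag$nodes)
  expect_identical(edge_key(back$dag$edges), edge_key(bn$dag$edges))
  expect_identical(back$n_fit, bn$n_fit)
  for (nd in bn$dag$nodes) {
    expect_identical(back$params[[nd]]$mean, bn$params[[nd]]$mean)
    expect_identical(back$params[[nd]]$residual_sd, bn$params[[nd]]$residual_sd)
    expect_identical(back$params[[nd]]$coefficients, bn$params[[nd]]$coefficients)
  }
})
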