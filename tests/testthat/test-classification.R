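test_that("a subject at model A's mean is assigned to A when only means differ", {
  g <- dag(c("r1", "r2"))
  mk <- function(m) gbn(g, list(
    r1 = list(mean = m, coefficients = numeric(0), residual_sd = 1),
    r2 = list(mean = m, coefficients = numeric(0), residual_sd = 1)))
  bn_a <- mk(5); bn_b <- mk(8)
  tbl <- roi_table(matrix(c(5, 5), 1, 2, dimnames = list(NULL, c("r1", "r2"))),
                   "s1", "A")
  rep <- classify(bn_a, bn_b, tbl, label_a = "A", label_b = "B")
  expect_identical(rep$subjects$assigned, "A")
})

test_that("decisions and ROC equal an independent MVN likelihood-ratio classifier", {
  spec <- builtin_spec("motor", n_a = 100, n_b = 100, residual_sd = 0.3, seed = 61)
  tbl <- generate_cohort(spec)
  bn_a <- greedy_search(roi_group(tbl, "A"))$bn
  bn_b <- greedy_search(roi_group(tbl, "B"))$bn
  rep <- classify(bn_a, bn_b, tbl)

  mvn_a <- oracle_mvn(bn_a); mvn_b <- oracle_mvn(bn_b)
  x <- roi_matrix(tbl, bn_a$dag$nodes)
  llr <- oracle_mvn_logpdf(mvn_a, x) - oracle_mvn_logpdf(mvn_b, x)
  # the decision statistic IS the MVN log-likelihood ratio
  expect_lt(max(abs(rep$subjects$diff - llr)), 1e-8)
  oracle_assign <- ifelse(llr > 0, "A", "B")
  expect_identical(rep$subjects$assigned, oracle_assign)
  oracle_acc <- mean(oracle_assign == tbl$group)
  expect_identical(rep$summary$accuracy, oracle_acc)
  expect_gt(rep$summary$accuracy, 0.5)   # above chance; groups differ in weights only

  # ROC equality against an oracle sweep over the same statistic
  thr <- c(Inf, sort(unique(llr), decreasing = TRUE))
  otpr <- vapply(thr, function(t) mean(llr[tbl$group == "A"] >= t), numeric(1))
  ofpr <- vapply(thr, function(t) mean(llr[tbl$group == "B"] >= t), numeric(1))
  expect_equal(rep$roc$tpr, otpr, tolerance = 1e-12)
  expect_equal(rep$roc$fpr, ofpr, tolerance = 1e-12)
})

test_that("ROC is monotone with (0,0) and (1,1) endpoints and pROC agrees on AUC", {
  spec <- builtin_spec("auditory", n_a = 80, n_b = 80, seed = 62)
  tbl <- generate_cohort(spec)
  rep <- evaluate_protocol(tbl)
  roc <- rep$roc
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  ref <- pROC::roc(response = tbl$group == "A", predictor = rep$subjects$diff,
                   quiet = TRUE, direction = "<")
  expect_equal(rep$summary$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("identical models tie to the default class; swapping positive swaps rates", {
  spec <- builtin_spec("motor", n_a = 20, n_b = 20, seed = 63)
  tbl <- generate_cohort(spec)
  bn <- greedy_search(roi_matrix(tbl))$bn
  rep <- classify(bn, bn, tbl)
  expect_true(all(rep$subjects$diff == 0))
  expect_true(all(rep$subjects$assigned == "A"))
  expect_equal(rep$summary$accuracy, mean(tbl$group == "A"))

  spec2 <- builtin_spec("motor", n_a = 30, n_b = 25, seed = 64)
  tbl2 <- generate_cohort(spec2)
  bn_a <- greedy_search(roi_group(tbl2, "A"))$bn
  bn_b <- greedy_search(roi_group(tbl2, "B"))$bn
  r1 <- classify(bn_a, bn_b, tbl2, positive = "A")
  r2 <- classify(bn_a, bn_b, tbl2, positive = "B")
  expect_equal(r1$summary$sensitivity, r2$summary$specificity)
  expect_equal(r1$summary$specificity, r2$summary$sensitivity)
  # summary recomputes from the per-subject rows
  rows <- r1$subjects
  expect_equal(r1$summary$accuracy, mean(rows$assigned == rows$group))
  expect_equal(r1$summary$sensitivity,
               mean(rows$assigned[rows$group == "A"] == "A"))
})

test_that("well-separated groups classify perfectly under resubstitution", {
  g <- dag(c("r1", "r2"))
  mk <- function(m) gbn(g, list(
    r1 = list(mean = m, coefficients = numeric(0), residual_sd = 0.3),
    r2 = list(mean = m, coefficients = numeric(0), residual_sd = 0.3)))
  set.seed(65)
  tbl <- two_group_table(mk(5), mk(9), 25, 25)
  rep <- evaluate_protocol(tbl)
  expect_equal(rep$summary$accuracy, 1.0)
})

test_that("leave-one-out is no more optimistic than resubstitution on average", {
  accs <- vapply(1:6, function(s) {
    spec <- builtin_spec("motor", n_a = 15, n_b = 15, residual_sd = 0.4, seed = 70 + s)
    tbl <- generate_cohort(spec)
    resub <- evaluate_protocol(tbl, "resubstitution", restarts = 5)
    loo <- evaluate_protocol(tbl, "leave-one-out", restarts = 5)
    c(resub$summary$accuracy, loo$summary$accuracy)
  }, numeric(2))
  expect_lte(mean(accs[2, ]), mean(accs[1, ]))
  # determinism of the protocol runner
  spec <- builtin_spec("motor", n_a = 12, n_b = 12, seed = 77)
  tbl <- generate_cohort(spec)
  expect_identical(evaluate_protocol(tbl, "leave-one-out", restarts = 2)$subjects,
                   evaluate_protocol(tbl, "leave-one-out", restarts = 2)$subjects)
})

test_that("ROI mismatches are reported by name", {
  spec <- builtin_spec("motor", n_a = 10, n_b = 10, seed = 66)
  tbl <- generate_cohort(spec)
  bn <- greedy_search(roi_matrix(tbl))$bn
  tbl_small <- tbl[, setdiff(names(tbl), "SMA")]
  class(tbl_small) <- c("roi_table", "data.frame")
  expect_error(classify(bn, bn, tbl_small), "SMA")
})
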