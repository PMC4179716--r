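test_that("one-sided permutation probabilities are complementary and reproducible", {
  spec <- builtin_spec("motor", n_a = 40, n_b = 40, seed = 51)
  tbl <- generate_cohort(spec)
  cmp1 <- compare_groups(tbl, n_permutations = 60, seed = 52)
  cmp2 <- compare_groups(tbl, n_permutations = 60, seed = 52)
  expect_identical(as.data.frame(cmp1), as.data.frame(cmp2))
  expect_true(all(cmp1$p_a_gt_b + cmp1$p_b_gt_a == 1))
  expect_true(all(cmp1$p_a_gt_b >= 0 & cmp1$p_a_gt_b <= 1))
  # tested edges come from the union of the two learned models
  models <- attr(cmp1, "models")
  union_keys <- union(edge_key(models$a$dag$edges), edge_key(models$b$dag$edges))
  expect_setequal(paste0(cmp1$parent, "->", cmp1$child), union_keys)
})

test_that("a planted single-edge weight difference is detected with high power", {
  # the homotopic-pair motif with one connection whose weight differs
  # between groups (0.65 vs 0.35); n = 200 per group
  mk <- function(beta) {
    gbn(dag(c("lSTG", "rSTG"), rbind(c("lSTG", "rSTG"))), list(
      lSTG = list(mean = 7, coefficients = numeric(0), residual_sd = 0.5),
      rSTG = list(mean = 7, coefficients = c(lSTG = beta), residual_sd = 0.5)))
  }
  bn_hi <- mk(0.65); bn_lo <- mk(0.35)
  hits <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    tbl <- two_group_table(bn_hi, bn_lo, 200, 200)
    cmp <- compare_groups(tbl, n_permutations = 200, seed = 700 + s)
    row <- cmp[cmp$parent == "lSTG" & cmp$child == "rSTG", ]
    if (nrow(row) == 1 && row$p_a_gt_b <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("input validation and reporting options behave", {
  spec <- builtin_spec("motor", n_a = 30, n_b = 30, seed = 55)
  tbl <- generate_cohort(spec)
  one <- roi_group(tbl, "A")
  expect_error(compare_groups(one, n_permutations = 10), "two group labels")
  expect_error(compare_groups(tbl, n_permutations = 0), ">= 1")
  expect_error(compare_groups(tbl, n_permutations = 10, alpha = 1.2), "alpha")

  cmp <- compare_groups(tbl, n_permutations = 40, seed = 56,
                        adjust = "BH", corrected = TRUE)
  expect_true(all(c("q_a_gt_b", "q_b_gt_a",
                    "p_a_gt_b_corrected", "p_b_gt_a_corrected") %in% names(cmp)))
  expect_true(all(cmp$q_a_gt_b >= cmp$p_a_gt_b))
  expect_true(all(cmp$p_a_gt_b_corrected > 0 & cmp$p_a_gt_b_corrected < 1))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_edge_report(cmp, tsv = tsv, json = js)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), nrow(cmp))
  doc <- jsonlite::read_json(js)
  expect_identical(doc$n_permutations, 40L)
  expect_length(doc$edges, nrow(cmp))
})

test_that("the permutation p of a fixed, stably present edge is exchangeable-uniform", {
  # single strong edge, null cohort: its one-sided p over replicates should
  # spread over [0, 1] rather than pile near 0
  bn <- gbn(dag(c("lSTG", "rSTG"), rbind(c("lSTG", "rSTG"))), list(
    lSTG = list(mean = 7, coefficients = numeric(0), residual_sd = 0.5),
    rSTG = list(mean = 7, coefficients = c(lSTG = 0.7), residual_sd = 0.5)))
  ps <- numeric(0)
  for (s in 1:12) {
    set.seed(800 + s)
    tbl <- two_group_table(bn, bn, 50, 50)
    cmp <- compare_groups(tbl, n_permutations = 80, seed = 900 + s)
    row <- cmp[cmp$parent == "lSTG" & cmp$child == "rSTG", ]
    if (nrow(row) == 1) ps <- c(ps, row$p_a_gt_b)
  }
  expect_gte(length(ps), 10)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_gt(max(ps) - min(ps), 0.3)
})
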