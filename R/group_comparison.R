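#' Permutation test of between-group connection weight differences
#'
#' Learns one network per group (structure and parameters, via
#' [greedy_search()]), takes the union of directed edges over the two models
#' as the tested edge set, and builds the null distribution of each edge's
#' weight difference by relabelling: every permutation reassigns subjects to
#' two pseudo-groups of the original sizes, relearns BOTH structure and
#' parameters per pseudo-group, and records the per-edge weight difference
#' (0 when the edge is absent from a learned model). One-sided tail
#' probabilities are counted complementarily, so `p_a_gt_b + p_b_gt_a = 1`
#' for every edge.
#'
#' @param data a [roi_table()] with exactly two group labels.
#' @param n_permutations number of label permutations (default 5000).
#' @param alpha per-edge significance level for the `significant` flag
#'   (default 0.05; no multiple-testing correction by default).
#' @param seed integer seed driving the permutation stream.
#' @param standardize z-score columns within each (pseudo-)group before
#'   learning.
#' @param max_parents optional parent cap passed to the search.
#' @param restarts random-restart climbs per relearn (default 0: the single
#'   deterministic empty-start climb). Whatever the setting, the identical
#'   search procedure is applied to the observed and to every permuted
#'   labelling, so the permutation null is exchangeable by construction;
#'   restarts improve the learned structures but multiply runtime by
#'   `restarts + 1` across all `n_permutations`.
#' @param adjust `"none"` (default) or `"BH"`: with `"BH"`, adds
#'   Benjamini-Hochberg adjusted columns `q_a_gt_b`/`q_b_gt_a` and bases the
#'   significance flag on them.
#' @param corrected if `TRUE`, also report the add-one corrected one-sided
#'   p-values `(r + 1) / (B + 1)` (inference-grade; these do not sum to 1).
#' @return A data.frame of class `edge_comparison` with one row per tested
#'   directed edge: `parent`, `child`, `weight_a`, `weight_b`,
#'   `observed_diff`, `p_a_gt_b`, `p_b_gt_a`, `significant`. Attributes:
#'   `groups`, `models` (the two fitted [gbn()]s), `n_permutations`, `alpha`,
#'   `seed`, `n_redraws`.
#' @export
compare_groups <- function(data, n_permutations = 5000L, alpha = 0.05,
                           seed = NULL, standardize = FALSE, max_parents = Inf,
                           restarts = 0L, adjust = c("none", "BH"),
                           corrected = FALSE) {
  stopifnot(inherits(data, "roi_table"))
  adjust <- match.arg(adjust)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  labels <- group_labels(data)
  if (length(labels) != 2L) {
    stop("need exactly two group labels, found: ", paste(labels, collapse = ", "))
  }
  x <- roi_matrix(data)
  is_a <- data$group == labels[1L]
  n_a <- sum(is_a)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)   # initialize the RNG state so it can be saved/restored
  }

  learn_weights <- function(rows) {
    xg <- x[rows, , drop = FALSE]
    if (standardize) xg <- scale(xg)
    eng <- new_score_engine(xg)
    p <- eng$p
    empty <- matrix(FALSE, p, p, dimnames = list(eng$fd$nodes, eng$fd$nodes))
    res <- climb_adj(eng, empty, max_parents = max_parents)
    if (restarts > 0L) {
      # restart draws must not disturb the permutation stream
      old_seed <- get(".Random.seed", envir = globalenv())
      set.seed(1L)
      for (r in seq_len(restarts)) {
        cand <- climb_adj(eng, random_start_adj(p, eng$fd$nodes),
                          max_parents = max_parents)
        if (cand$score > res$score + 1e-6) res <- cand
      }
      assign(".Random.seed", old_seed, envir = globalenv())
    }
    list(adj = res$adj, w = weights_from_adj(eng$fd, res$adj))
  }

  fit_a <- learn_weights(is_a)
  fit_b <- learn_weights(!is_a)
  union_adj <- fit_a$adj | fit_b$adj
  idx <- which(union_adj, arr.ind = TRUE)
  if (!nrow(idx)) stop("no edges learned in either group; nothing to test")
  nodes <- colnames(x)
  ord <- order(nodes[idx[, 1L]], nodes[idx[, 2L]])
  idx <- idx[ord, , drop = FALSE]
  obs <- fit_a$w[idx] - fit_b$w[idx]

  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(x)
  ge_count <- integer(nrow(idx))
  redraws <- 0L
  done <- 0L
  max_redraws <- ceiling(0.1 * n_permutations)
  while (done < n_permutations) {
    perm <- sample.int(n)
    rows_a <- logical(n)
    rows_a[perm[seq_len(n_a)]] <- TRUE
    pd <- tryCatch({
      pa <- learn_weights(rows_a)
      pb <- learn_weights(!rows_a)
      pa$w[idx] - pb$w[idx]
    }, error = function(e) NULL)
    if (is.null(pd)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("more than 10% of permutations failed to fit (", redraws, " redraws)")
      }
      next
    }
    ge_count <- ge_count + (pd >= obs)
    done <- done + 1L
  }

  p_a <- ge_count / n_permutations
  p_b <- 1 - p_a
  out <- data.frame(parent = nodes[idx[, 1L]], child = nodes[idx[, 2L]],
                    weight_a = fit_a$w[idx], weight_b = fit_b$w[idx],
                    observed_diff = obs, p_a_gt_b = p_a, p_b_gt_a = p_b,
                    stringsAsFactors = FALSE)
  if (corrected) {
    out$p_a_gt_b_corrected <- (ge_count + 1L) / (n_permutations + 1L)
    out$p_b_gt_a_corrected <- (n_permutations - ge_count + 1L) / (n_permutations + 1L)
  }
  if (adjust == "BH") {
    out$q_a_gt_b <- stats::p.adjust(out$p_a_gt_b, method = "BH")
    out$q_b_gt_a <- stats::p.adjust(out$p_b_gt_a, method = "BH")
    out$significant <- pmin(out$q_a_gt_b, out$q_b_gt_a) <= alpha
  } else {
    out$significant <- pmin(out$p_a_gt_b, out$p_b_gt_a) <= alpha
  }
  attr(out, "groups") <- labels
  attr(out, "models") <- list(a = fit_mle(adj_to_dag(fit_a$adj), x[is_a, , drop = FALSE]),
                              b = fit_mle(adj_to_dag(fit_b$adj), x[!is_a, , drop = FALSE]))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "n_redraws") <- redraws
  class(out) <- c("edge_comparison", "data.frame")
  out
}

#' Write an edge-comparison report to TSV and/or JSON
#'
#' @param comp an `edge_comparison` from [compare_groups()].
#' @param tsv,json output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_edge_report <- function(comp, tsv = NULL, json = NULL) {
  stopifnot(inherits(comp, "edge_comparison"))
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(comp), tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json)) {
    doc <- list(groups = attr(comp, "groups"),
                n_permutations = attr(comp, "n_permutations"),
                alpha = attr(comp, "alpha"),
                seed = attr(comp, "seed"),
                n_redraws = attr(comp, "n_redraws"),
                edges = as.data.frame(comp))
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv = tsv, json = json))
}
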