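# Group assignment by joint-density comparison: a subject is attributed to
# the group model under which its ROI vector has the larger joint
# log-density, i.e. a likelihood-ratio rule with equal class priors.

classification_summary <- function(truth, assigned, score, positive, negative) {
  tp <- sum(truth == positive & assigned == positive)
  fn <- sum(truth == positive & assigned != positive)
  tn <- sum(truth == negative & assigned == negative)
  fp <- sum(truth == negative & assigned != negative)
  roc <- roc_points(truth == positive, score)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(truth), auc = roc_auc(roc),
       positive = positive, negative = negative)
}

# ROC by sweeping the decision threshold over the observed scores: at
# threshold t the subject is called positive when score >= t. Thresholds run
# from +Inf (nobody positive, point (0,0)) down through every observed score
# (all positive at the minimum, point (1,1)).
roc_points <- function(is_positive, score) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  np <- sum(is_positive)
  nn <- sum(!is_positive)
  tpr <- vapply(thr, function(t) sum(is_positive & score >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(!is_positive & score >= t) / nn, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  f <- roc$fpr[o]; t <- roc$tpr[o]
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

#' Classify subjects by comparing joint densities under two group models
#'
#' Each subject is assigned to the model giving the larger joint log-density
#' of its ROI vector (threshold 0 on the log-density difference, equal class
#' priors). The ROC sweeps that threshold over all observed differences.
#'
#' @param bn_a,bn_b fitted [gbn()]s for the two groups, sharing one node set.
#' @param subjects a [roi_table()] whose ROI columns cover the models' nodes.
#' @param label_a,label_b group labels attached to assignments under model A
#'   and B; default to the first/second group label present in `subjects`.
#' @param positive which label is the "positive" class for
#'   sensitivity/specificity and the ROC (default `label_a`).
#' @param tie label assigned when the two log-densities are exactly equal
#'   (default `label_a`, the group listed first).
#' @return Object of class `gbn_classification`: list with `subjects`
#'   (per-subject data.frame: id, true group, both log-densities, difference,
#'   assignment), `summary` (sensitivity, specificity, accuracy, auc) and
#'   `roc` (threshold, fpr, tpr).
#' @export
classify <- function(bn_a, bn_b, subjects, label_a = NULL, label_b = NULL,
                     positive = NULL, tie = NULL) {
  stopifnot(inherits(bn_a, "gbn"), inherits(bn_b, "gbn"),
            inherits(subjects, "roi_table"))
  if (!setequal(bn_a$dag$nodes, bn_b$dag$nodes)) {
    stop("the two models must share one ROI set")
  }
  missing <- setdiff(bn_a$dag$nodes, roi_names(subjects))
  if (length(missing)) {
    stop("subjects table lacks model ROI(s): ", paste(missing, collapse = ", "))
  }
  labels <- group_labels(subjects)
  if (is.null(label_a)) label_a <- labels[1L]
  if (is.null(label_b)) label_b <- if (length(labels) > 1L) labels[2L] else "B"
  if (is.null(positive)) positive <- label_a
  if (is.null(tie)) tie <- label_a
  ld_a <- log_density(bn_a, subjects)
  ld_b <- log_density(bn_b, subjects)
  diff <- ld_a - ld_b
  assigned <- ifelse(diff > 0, label_a, ifelse(diff < 0, label_b, tie))
  rows <- data.frame(subject_id = subjects$subject_id, group = subjects$group,
                     logdens_a = ld_a, logdens_b = ld_b, diff = diff,
                     assigned = assigned, stringsAsFactors = FALSE)
  negative <- if (positive == label_a) label_b else label_a
  score <- if (positive == label_a) diff else -diff
  summ <- classification_summary(rows$group, rows$assigned, score,
                                 positive, negative)
  structure(list(subjects = rows, summary = summ,
                 roc = roc_points(rows$group == positive, score)),
            class = "gbn_classification")
}

#' @export
print.gbn_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("gbn_classification: %d subjects | sensitivity %.4f, ",
                     "specificity %.4f, accuracy %.4f, AUC %.4f (positive: %s)\n"),
              nrow(x$subjects), s$sensitivity, s$specificity, s$accuracy,
              s$auc, s$positive))
  invisible(x)
}

#' Fit-and-classify under a stated evaluation protocol
#'
#' `"resubstitution"` learns both group networks on the full table and then
#' classifies every subject with them (the default; optimistic, but the
#' protocol matched by the reported in-sample accuracies of this kind of
#' analysis). `"leave-one-out"` refits the held-out subject's group model
#' without that subject before classifying it (the other group's model is
#' unaffected by the holdout and is fitted once).
#'
#' @param data a [roi_table()] with exactly two groups.
#' @param protocol `"resubstitution"` or `"leave-one-out"`.
#' @param standardize,max_parents,restarts passed to [greedy_search()].
#' @param positive positive-class label (default: first group).
#' @return A `gbn_classification` (see [classify()]); for resubstitution the
#'   fitted models are attached as attribute `models`.
#' @export
evaluate_protocol <- function(data, protocol = c("resubstitution", "leave-one-out"),
                              standardize = FALSE, max_parents = Inf,
                              restarts = 30L, positive = NULL) {
  stopifnot(inherits(data, "roi_table"))
  protocol <- match.arg(protocol)
  labels <- group_labels(data)
  if (length(labels) != 2L) stop("need exactly two groups")
  fit_group <- function(tbl) {
    greedy_search(tbl, standardize = standardize, max_parents = max_parents,
                  restarts = restarts)$bn
  }
  if (protocol == "resubstitution") {
    bn_a <- fit_group(roi_group(data, labels[1L]))
    bn_b <- fit_group(roi_group(data, labels[2L]))
    out <- classify(bn_a, bn_b, data, label_a = labels[1L], label_b = labels[2L],
                    positive = positive)
    attr(out, "models") <- list(a = bn_a, b = bn_b)
    return(out)
  }
  # leave-one-out
  if (min(table(data$group)) < 4L) {
    stop("leave-one-out needs at least 4 subjects per group")
  }
  full <- list()
  full[[labels[1L]]] <- fit_group(roi_group(data, labels[1L]))
  full[[labels[2L]]] <- fit_group(roi_group(data, labels[2L]))
  n <- nrow(data)
  ld_a <- ld_b <- numeric(n)
  for (i in seq_len(n)) {
    gi <- data$group[i]
    rest <- data[-i, , drop = FALSE]
    class(rest) <- c("roi_table", "data.frame")
    refit <- fit_group(roi_group(rest, gi))
    bn_a <- if (gi == labels[1L]) refit else full[[labels[1L]]]
    bn_b <- if (gi == labels[2L]) refit else full[[labels[2L]]]
    row <- data[i, , drop = FALSE]
    class(row) <- c("roi_table", "data.frame")
    ld_a[i] <- log_density(bn_a, row)
    ld_b[i] <- log_density(bn_b, row)
  }
  if (is.null(positive)) positive <- labels[1L]
  negative <- setdiff(labels, positive)
  diff <- ld_a - ld_b
  assigned <- ifelse(diff > 0, labels[1L], ifelse(diff < 0, labels[2L], labels[1L]))
  rows <- data.frame(subject_id = data$subject_id, group = data$group,
                     logdens_a = ld_a, logdens_b = ld_b, diff = diff,
                     assigned = assigned, stringsAsFactors = FALSE)
  score <- if (positive == labels[1L]) diff else -diff
  summ <- classification_summary(rows$group, rows$assigned, score,
                                 positive, negative)
  structure(list(subjects = rows, summary = summ,
                 roc = roc_points(rows$group == positive, score)),
            class = "gbn_classification")
}
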