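#' Pearson chi-square test of independence for a 2x2 cohort table
#'
#' Cohort balance check (e.g. sex by group). Continuity correction is off by
#' default, matching the uncorrected Pearson statistic convention of the
#' demographic tables this mirrors.
#'
#' @param counts 2x2 matrix of nonnegative counts (rows: groups, columns:
#'   categories).
#' @param correction apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `dof`, and `p_value`.
#' @examples
#' chi_square_independence(matrix(c(65, 44, 60, 22), 2, 2, byrow = TRUE))
#' @export
chi_square_independence <- function(counts, correction = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("table total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal total; expected counts undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correction))
  list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value)
}
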