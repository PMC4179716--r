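#' Subjects-by-ROIs volume table
#'
#' The observed data `D`: one row per subject, a group label, and one column
#' of average gray-matter volume per ROI. Stored as a plain data.frame with
#' leading columns `subject_id` and `group`, class `roi_table`.
#'
#' @param values numeric subjects x ROIs matrix (column names are ROI names,
#'   or supply `roi_names`).
#' @param subject_ids character vector, one per row, unique.
#' @param groups character vector of group labels, one per row.
#' @param roi_names optional ROI column names overriding `colnames(values)`.
#' @return A `roi_table` data.frame.
#' @export
roi_table <- function(values, subject_ids, groups, roi_names = NULL) {
  values <- as.matrix(values)
  if (!is.null(roi_names)) colnames(values) <- roi_names
  if (is.null(colnames(values))) stop("ROI columns must be named")
  if (anyDuplicated(colnames(values))) stop("duplicate ROI names")
  n <- nrow(values)
  subject_ids <- as.character(subject_ids)
  groups <- as.character(groups)
  if (length(subject_ids) != n || length(groups) != n) {
    stop("subject_ids and groups must match the row count (", n, ")")
  }
  if (anyDuplicated(subject_ids)) {
    stop("duplicated subject_id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) stop("ROI values must be finite, no missing values")
  out <- data.frame(subject_id = subject_ids, group = groups,
                    values, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' @export
print.roi_table <- function(x, ...) {
  cat("roi_table:", nrow(x), "subjects x", length(roi_names(x)), "ROIs; groups:",
      paste(sprintf("%s (n=%d)", names(table(x$group)), as.integer(table(x$group))),
            collapse = ", "), "\n")
  NextMethod()
}

#' ROI column names of a table
#' @param tbl a [roi_table()].
#' @return Character vector of ROI names.
#' @export
roi_names <- function(tbl) setdiff(names(tbl), c("subject_id", "group"))

#' Numeric ROI matrix of a table
#' @param tbl a [roi_table()].
#' @param rois optional subset/ordering of ROI columns.
#' @return Numeric matrix with subject_ids as rownames.
#' @export
roi_matrix <- function(tbl, rois = roi_names(tbl)) {
  m <- as.matrix(as.data.frame(tbl)[, rois, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$subject_id
  m
}

#' Rows of one group
#' @param tbl a [roi_table()].
#' @param group group label to keep.
#' @return A `roi_table` restricted to that group.
#' @export
roi_group <- function(tbl, group) {
  out <- tbl[tbl$group == group, , drop = FALSE]
  if (!nrow(out)) stop("no subjects with group label '", group, "'")
  class(out) <- c("roi_table", "data.frame")
  out
}

group_labels <- function(tbl) unique(tbl$group)

#' Read / write the delimited-text form of a volume table
#'
#' Comma-separated by default, header row, leading columns `subject_id` and
#' `group` followed by one column per ROI.
#'
#' @param path file path.
#' @param tbl a [roi_table()].
#' @param sep field separator.
#' @return `read_roi_table` returns a `roi_table`; `write_roi_table` returns
#'   `path` invisibly.
#' @export
read_roi_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df))) stop("missing required columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  rois <- setdiff(names(df), need)
  roi_table(as.matrix(df[, rois, drop = FALSE]), df$subject_id, df$group)
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(tbl, path, sep = ",") {
  stopifnot(inherits(tbl, "roi_table"))
  utils::write.table(as.data.frame(tbl), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
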