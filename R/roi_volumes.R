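# ROI mean-volume extraction from modulated gray-matter images and an
# integer-labelled atlas mask. Upstream VBM preprocessing (segmentation,
# normalization, modulation, smoothing) is assumed done by external
# neuroimaging software; this module only averages.

#' ROI definitions for a labelled mask
#'
#' @param roi_name unique ROI names.
#' @param label_value positive integer label codes in the mask image.
#' @param network network membership (e.g. `"auditory"`), recycled.
#' @return data.frame of class `roi_definition`.
#' @export
roi_definitions <- function(roi_name, label_value, network = "custom") {
  roi_name <- as.character(roi_name)
  label_value <- as.integer(label_value)
  if (length(roi_name) != length(label_value)) stop("name/label length mismatch")
  if (anyDuplicated(roi_name)) stop("duplicate roi_name")
  if (anyDuplicated(label_value)) stop("duplicate label_value")
  if (any(is.na(label_value)) || any(label_value < 1L)) {
    stop("label_value must be integers >= 1")
  }
  out <- data.frame(roi_name = roi_name, label_value = label_value,
                    network = rep_len(as.character(network), length(roi_name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_definition", "data.frame")
  out
}

load_volume <- function(x, what) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read ", what, ": file not found: ", x)
    x <- RNifti::readNifti(x)
  }
  x
}

#' Mean gray-matter volume per ROI from an image and a labelled mask
#'
#' For each ROI, averages the image voxels carrying that ROI's mask label
#' whose intensity is strictly above the cut-off (default 0.15, excluding
#' probable non-gray-matter voxels; a voxel exactly at the cut-off is
#' excluded).
#'
#' @param gm_image 3-D numeric array, `RNifti` image, or NIfTI file path
#'   (modulated gray-matter volumes).
#' @param mask same-shape integer-labelled volume (array, image, or path).
#' @param rois a [roi_definitions()] table.
#' @param threshold intensity cut-off (strict `>`), default 0.15.
#' @return data.frame with one row per ROI: `roi_name`, `label_value`,
#'   `mean`, `n_voxels`.
#' @export
extract_roi_means <- function(gm_image, mask, rois, threshold = 0.15) {
  stopifnot(inherits(rois, "roi_definition"))
  gm_image <- load_volume(gm_image, "gm_image")
  mask <- load_volume(mask, "mask")
  if (!identical(dim(gm_image), dim(mask))) {
    stop("image and mask shapes differ: ", paste(dim(gm_image), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  }
  if (inherits(gm_image, "niftiImage") && inherits(mask, "niftiImage")) {
    if (!isTRUE(all.equal(RNifti::xform(gm_image), RNifti::xform(mask),
                          tolerance = 1e-4, check.attributes = FALSE))) {
      stop("image and mask affines (xforms) differ")
    }
  }
  gm <- as.numeric(gm_image)
  mk <- as.integer(mask)
  res <- lapply(seq_len(nrow(rois)), function(i) {
    vox <- gm[mk == rois$label_value[i]]
    keep <- vox[vox > threshold]
    if (!length(keep)) {
      stop("ROI '", rois$roi_name[i], "' (label ", rois$label_value[i],
           ") has no voxels above threshold ", threshold)
    }
    c(mean = mean(keep), n_voxels = length(keep))
  })
  res <- do.call(rbind, res)
  data.frame(roi_name = rois$roi_name, label_value = rois$label_value,
             mean = res[, "mean"], n_voxels = as.integer(res[, "n_voxels"]),
             stringsAsFactors = FALSE)
}

#' Build a subjects-by-ROIs volume table from per-subject images
#'
#' @param metadata data.frame with columns `subject_id`, `group`, `path`
#'   (NIfTI file per subject).
#' @param mask labelled mask volume (array, image, or path), shared by all
#'   subjects.
#' @param rois a [roi_definitions()] table; column order of the result.
#' @param threshold intensity cut-off, default 0.15.
#' @return A [roi_table()] with provenance (`threshold`, `mask_md5` when the
#'   mask came from a file) in attribute `provenance`.
#' @export
build_table <- function(metadata, mask, rois, threshold = 0.15) {
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(metadata)) stop("empty subject list")
  if (anyDuplicated(metadata$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(metadata$subject_id[duplicated(metadata$subject_id)]),
               collapse = ", "))
  }
  mask_md5 <- if (is.character(mask) && file.exists(mask)) {
    unname(tools::md5sum(mask))
  } else NA_character_
  mask <- load_volume(mask, "mask")
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- tryCatch(
      extract_roi_means(metadata$path[i], mask, rois, threshold = threshold),
      error = function(e) stop("subject '", metadata$subject_id[i], "': ",
                               conditionMessage(e), call. = FALSE))
    stats::setNames(m$mean, m$roi_name)
  })
  values <- do.call(rbind, rows)
  tbl <- roi_table(values, metadata$subject_id, metadata$group,
                   roi_names = rois$roi_name)
  attr(tbl, "provenance") <- list(threshold = threshold, mask_md5 = mask_md5,
                                  n_subjects = nrow(tbl))
  tbl
}
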