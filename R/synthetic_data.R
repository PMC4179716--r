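# Synthetic two-group cohorts. The built-in ground truths transcribe the
# published young/old connection lists for the auditory, visual and motor
# structural networks (weight coefficients as printed); unconditional means
# and residual sds are not published and are configurable scaffolding.

builtin_networks <- function() {
  ed <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(parent = m[, 1L], child = m[, 2L],
               weight = as.numeric(m[, 3L]), stringsAsFactors = FALSE)
  }
  list(
    auditory = list(
      nodes = c("lHES", "rHES", "lSMG", "rSMG", "lSTG", "rSTG"),
      young = ed("lHES", "rHES", 0.502,
                 "lSTG", "rSTG", 0.665,
                 "lSTG", "lHES", 0.786,
                 "rSTG", "rHES", 0.328,
                 "lSTG", "lSMG", 0.654,
                 "rSTG", "rSMG", 0.338,
                 "lSMG", "rSMG", 0.443),
      old = ed("lHES", "rHES", 0.493,
               "lSTG", "rSTG", 0.634,
               "lSTG", "lHES", 0.811,
               "rSTG", "rHES", 0.346,
               "lSTG", "lSMG", 0.494,
               "rSTG", "rSMG", 0.691,
               "rSMG", "lSMG", 0.351)),
    visual = list(
      nodes = c("lCAL", "rCAL", "lLING", "rLING", "lMOG", "rMOG"),
      young = ed("rLING", "lLING", 0.533,
                 "rMOG", "lMOG", 0.438,
                 "lCAL", "rCAL", 0.897,
                 "rLING", "rMOG", 0.537,
                 "rCAL", "rLING", 0.758,
                 "lCAL", "lMOG", 0.321,
                 "lCAL", "lLING", 0.369),
      old = ed("rLING", "lLING", 0.841,
               "rMOG", "lMOG", 0.786,
               "lCAL", "rCAL", 0.914,
               "rLING", "rMOG", 0.563,
               "lLING", "lCAL", 0.714)),
    motor = list(
      nodes = c("lPoCG", "rPoCG", "lPreCG", "rPreCG", "SMA"),
      young = ed("lPreCG", "rPreCG", 0.483,
                 "lPoCG", "rPoCG", 0.698,
                 "lPoCG", "lPreCG", 0.396,
                 "rPoCG", "rPreCG", 0.344,
                 "lPreCG", "SMA", 0.487),
      old = ed("lPreCG", "rPreCG", 0.621,
               "lPoCG", "rPoCG", 0.657,
               "lPoCG", "lPreCG", 0.633,
               "rPoCG", "rPreCG", 0.326,
               "lPreCG", "SMA", 0.671)))
}

gbn_from_edges <- function(nodes, edges, base_mean, residual_sd) {
  g <- dag(nodes, as.matrix(edges[, c("parent", "child")]))
  params <- lapply(nodes, function(nd) {
    rows <- edges$child == nd
    list(mean = base_mean,
         coefficients = stats::setNames(edges$weight[rows], edges$parent[rows]),
         residual_sd = residual_sd)
  })
  names(params) <- nodes
  gbn(g, params, n_fit = 0L)
}

#' Two-group cohort specification
#'
#' @param bn_a,bn_b ground-truth [gbn()]s sharing one node set.
#' @param n_a,n_b group sizes (>= 3).
#' @param seed integer seed used by [generate_cohort()].
#' @param network_name descriptive name.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(bn_a, bn_b, n_a, n_b, seed = 1L,
                        network_name = "custom") {
  stopifnot(inherits(bn_a, "gbn"), inherits(bn_b, "gbn"))
  if (!setequal(bn_a$dag$nodes, bn_b$dag$nodes)) {
    stop("the two networks must share one node set")
  }
  if (n_a < 3L || n_b < 3L) stop("group sizes must be >= 3")
  structure(list(network_name = network_name, bn_a = bn_a, bn_b = bn_b,
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Built-in two-group network templates
#'
#' Ground-truth young/old network pairs for the auditory, visual and motor
#' structural networks, with the published connection lists and weight
#' coefficients. The unpublished unconditional means and residual sds default
#' to 7.0 and 0.5 (synthetic scaffolding, configurable); default group sizes
#' follow the studied cohort (109 young, 82 old).
#'
#' @param network_name one of `"auditory"`, `"visual"`, `"motor"`.
#' @param n_a,n_b group sizes (defaults 109 and 82).
#' @param residual_sd residual standard deviation for every node (default 0.5).
#' @param base_mean unconditional mean for every node (default 7.0).
#' @param seed seed stored in the spec.
#' @return A [cohort_spec()] with `bn_a` the young-group network and `bn_b`
#'   the old-group network.
#' @export
builtin_spec <- function(network_name, n_a = 109L, n_b = 82L,
                         residual_sd = 0.5, base_mean = 7.0, seed = 1L) {
  nets <- builtin_networks()
  if (!network_name %in% names(nets)) {
    stop("unknown network '", network_name, "'; options: ",
         paste(names(nets), collapse = ", "))
  }
  net <- nets[[network_name]]
  cohort_spec(gbn_from_edges(net$nodes, net$young, base_mean, residual_sd),
              gbn_from_edges(net$nodes, net$old, base_mean, residual_sd),
              n_a = n_a, n_b = n_b, seed = seed, network_name = network_name)
}

#' Generate a two-group cohort table from a spec
#'
#' Ancestral-samples `n_a` subjects from `bn_a` and `n_b` from `bn_b` under
#' the spec's seed and concatenates them; deterministic for a given spec.
#'
#' @param spec a [cohort_spec()].
#' @param labels two group labels (default `c("A", "B")`).
#' @return A [roi_table()] with `n_a + n_b` rows.
#' @export
generate_cohort <- function(spec, labels = c("A", "B")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(labels) != 2L || labels[1L] == labels[2L]) {
    stop("labels must be two distinct group names")
  }
  set.seed(spec$seed)
  ta <- sample_gbn(spec$bn_a, spec$n_a, group = labels[1L], subject_prefix = "A")
  tb <- sample_gbn(spec$bn_b, spec$n_b, group = labels[2L], subject_prefix = "B")
  out <- rbind(as.data.frame(ta), as.data.frame(tb))
  roi_table(as.matrix(out[, roi_names(ta), drop = FALSE]),
            out$subject_id, out$group)
}

#' Write a toy NIfTI image set realizing a cohort table
#'
#' Emits one small gray-matter image per subject plus a shared labelled mask
#' such that [build_table()] on the written files reproduces the cohort table
#' exactly: every ROI gets a block of voxels set to that subject's table
#' value (constant within the ROI, so thresholded averaging returns it), and
#' all other voxels are 0 (below any positive threshold). Used to exercise
#' the extraction path end-to-end without real imaging data.
#'
#' @param spec a [cohort_spec()] (the table is generated from it) or a
#'   [roi_table()] directly.
#' @param out_dir output directory (created if needed).
#' @param dim_xyz image dimensions, default `c(12, 12, 12)`.
#' @param threshold cut-off the images must survive; every table value must
#'   exceed it (error otherwise).
#' @return List with `metadata` (subject_id, group, path), `mask_path`,
#'   `rois` (a [roi_definitions()]), and `table` (the realized cohort table).
#' @export
write_toy_images <- function(spec, out_dir, dim_xyz = c(12L, 12L, 12L),
                             threshold = 0.15) {
  tbl <- if (inherits(spec, "cohort_spec")) generate_cohort(spec) else spec
  stopifnot(inherits(tbl, "roi_table"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  rois <- roi_names(tbl)
  values <- roi_matrix(tbl)
  if (any(values <= threshold)) {
    stop("cohort values must exceed the threshold (", threshold,
         ") for an exact image round trip")
  }
  nvox <- prod(dim_xyz)
  vox_per_roi <- 8L
  if (nvox < length(rois) * vox_per_roi) stop("image too small for ", length(rois), " ROIs")
  mask <- array(0L, dim = dim_xyz)
  for (r in seq_along(rois)) {
    mask[seq.int((r - 1L) * vox_per_roi + 1L, r * vox_per_roi)] <- r
  }
  mask_path <- file.path(out_dir, "mask.nii")
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  paths <- character(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    img <- array(0, dim = dim_xyz)
    for (r in seq_along(rois)) {
      img[mask == r] <- values[i, r]
    }
    paths[i] <- file.path(out_dir, paste0(tbl$subject_id[i], ".nii"))
    RNifti::writeNifti(RNifti::asNifti(img), paths[i])
  }
  metadata <- data.frame(subject_id = tbl$subject_id, group = tbl$group,
                         path = paths, stringsAsFactors = FALSE)
  utils::write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  list(metadata = metadata, mask_path = mask_path,
       rois = roi_definitions(rois, seq_along(rois)), table = tbl)
}
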