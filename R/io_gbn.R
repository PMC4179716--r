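#' Serialize a Gaussian BN to JSON
#'
#' The document stores `nodes`, `edges` as an array of `[parent, child]`
#' pairs, one `{mean, coefficients, residual_sd}` record per node, and
#' `n_fit`. Numbers are written at full double precision so a round trip is
#' exact.
#'
#' @param bn a [gbn()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gbn <- function(bn, path) {
  stopifnot(inherits(bn, "gbn"))
  doc <- list(
    nodes = bn$dag$nodes,
    edges = unname(apply(bn$dag$edges, 1L, function(e) as.list(e), simplify = FALSE)),
    params = lapply(bn$params, function(p) list(
      mean = p$mean,
      coefficients = as.list(p$coefficients),
      residual_sd = p$residual_sd)),
    n_fit = bn$n_fit)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a Gaussian BN from its JSON serialization
#'
#' @param path file written by [write_gbn()].
#' @return A [gbn()].
#' @export
read_gbn <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- unlist(doc$nodes)
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) c(e[[1]], e[[2]])))
  } else NULL
  params <- lapply(doc$params, function(p) list(
    mean = as.numeric(p$mean),
    coefficients = stats::setNames(as.numeric(unlist(p$coefficients)),
                                   names(p$coefficients)),
    residual_sd = as.numeric(p$residual_sd)))
  gbn(dag(nodes, edges), params, n_fit = as.integer(doc$n_fit))
}
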