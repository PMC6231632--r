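#' Concatenation fusion of QDCP and LBP histograms
#'
#' Joins the orientation-texture histogram and the brightness-texture
#' histogram end to end (QDCP block first), giving a `2 P` feature vector
#' (72 for 8 neighbors). Cheap, at the cost of discarding co-occurrence
#' information between the two codes.
#'
#' @param h_qdcp,h_lbp `texton_histogram`s with the same label count and
#'   normalization state.
#' @return a `fused_feature` with fields `vector`, `scheme = "concat"`,
#'   `n_labels`.
#' @export
fuse_concat <- function(h_qdcp, h_lbp) {
  stopifnot(inherits(h_qdcp, "texton_histogram"),
            inherits(h_lbp, "texton_histogram"))
  if (h_qdcp$n_labels != h_lbp$n_labels) {
    abort("Histograms have different label counts.",
          class = "qdcp_invalid_input")
  }
  if (!identical(h_qdcp$normalized, h_lbp$normalized)) {
    abort("Histograms have different normalization states.",
          class = "qdcp_invalid_input")
  }
  structure(
    list(vector = c(h_qdcp$bins, h_lbp$bins), scheme = "concat",
         n_labels = h_qdcp$n_labels, normalized = h_qdcp$normalized),
    class = "fused_feature"
  )
}

#' Joint co-occurrence fusion of QDCP and LBP index images
#'
#' Builds the P x P co-occurrence table of (QDCP label, LBP label) pairs over
#' the shared valid pixels and flattens it row-major with the QDCP label as
#' the major index, giving a `P^2` vector (1296 for 8 neighbors). Row sums of
#' the table reproduce the QDCP histogram and column sums the LBP histogram.
#'
#' @param qdcp_idx,lbp_idx `texton_index` images computed from the same
#'   source image with the same neighborhood (identical valid masks).
#' @param normalize L1-normalize the flattened table?
#' @return a `fused_feature` with `scheme = "joint"`.
#' @export
fuse_joint <- function(qdcp_idx, lbp_idx, normalize = TRUE) {
  stopifnot(inherits(qdcp_idx, "texton_index"),
            inherits(lbp_idx, "texton_index"))
  if (!identical(qdcp_idx$valid_mask, lbp_idx$valid_mask)) {
    abort("Index images have different valid masks.",
          class = "qdcp_invalid_input")
  }
  if (qdcp_idx$n_labels != lbp_idx$n_labels) {
    abort("Index images have different label counts.",
          class = "qdcp_invalid_input")
  }
  p <- qdcp_idx$n_labels
  a <- qdcp_idx$labels[qdcp_idx$valid_mask]
  b <- lbp_idx$labels[lbp_idx$valid_mask]
  n_valid <- length(a)
  if (n_valid == 0L) {
    abort("No valid pixels to histogram.", class = "qdcp_empty_region")
  }
  # row-major (QDCP-major) flattening: cell (a, b) -> position a * P + b
  joint <- as.numeric(tabulate(a * p + b + 1L, nbins = p * p))
  if (normalize) joint <- joint / n_valid
  structure(
    list(vector = joint, scheme = "joint", n_labels = p,
         normalized = normalize, n_valid = n_valid),
    class = "fused_feature"
  )
}

#' @export
print.fused_feature <- function(x, ...) {
  cat(sprintf("<fused_feature: scheme = %s, length %d>\n",
              x$scheme, length(x$vector)))
  invisible(x)
}
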