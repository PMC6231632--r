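#' Texton label histogram
#'
#' Empirical distribution of texton labels over the valid pixels of an index
#' image: bin `j` counts the valid pixels carrying dense label `j`. With
#' `normalize = TRUE` (the default used for classifier features) the counts
#' are L1-normalized to frequencies.
#'
#' @param idx a `texton_index` (from [qdcp_index_image()] or
#'   [lbp_index_image()]).
#' @param normalize L1-normalize to frequencies?
#' @return a `texton_histogram` with fields `bins`, `n_labels`, `normalized`,
#'   `n_valid`.
#' @export
texton_histogram <- function(idx, normalize = TRUE) {
  stopifnot(inherits(idx, "texton_index"))
  vals <- idx$labels[idx$valid_mask]
  n_valid <- length(vals)
  if (n_valid == 0L) {
    abort("No valid pixels to histogram.", class = "qdcp_empty_region")
  }
  bins <- tabulate(vals + 1L, nbins = idx$n_labels)
  bins <- as.numeric(bins)
  if (normalize) bins <- bins / n_valid
  structure(
    list(bins = bins, n_labels = idx$n_labels, normalized = normalize,
         n_valid = n_valid),
    class = "texton_histogram"
  )
}

#' @export
print.texton_histogram <- function(x, ...) {
  cat(sprintf("<texton_histogram: %d bins, %s, %d pixels>\n", x$n_labels,
              if (x$normalized) "frequencies" else "counts", x$n_valid))
  invisible(x)
}

#' QDCP feature histogram of an RGB image
#'
#' The full counter-color descriptor pipeline: convert to the working color
#' space (default the luma/chroma space, whose signed chroma axes spread
#' stain orientations over most of the unit sphere), decompose into
#' magnitude and orientation, index counter-color textons on the orientation
#' field, and summarize them in a rotation-invariant label histogram.
#'
#' @param img RGB `color_image` (or `H x W x 3` array in `[0, 1]`).
#' @param spec a [neighborhood_spec()]; default 8 samples at radius 1.
#' @param t_o similarity threshold; the 0.75-0.85 band (30-40 degrees of
#'   color separation) is a good default for stained tissue.
#' @param color_space working space for the decomposition.
#' @param normalize L1-normalize the histogram?
#' @param table optional precomputed rotation code table.
#' @return a `texton_histogram`.
#' @export
qdcp_feature <- function(img, spec = neighborhood_spec(), t_o = 0.8,
                         color_space = "ycbcr", normalize = TRUE,
                         table = NULL) {
  conv <- to_color_space(img, color_space)
  md <- md_decompose(conv)
  idx <- qdcp_index_image(md$orientation, spec, t_o, table)
  texton_histogram(idx, normalize)
}

#' LBP feature histogram of an RGB image
#'
#' Rotation-invariant LBP summarizing brightness texture. With
#' `source = "magnitude"` it runs on the color-vector magnitude of the
#' luma/chroma image (the fusion ingredient that complements the
#' orientation-based descriptor); with `source = "luma"` it runs on the Y
#' channel alone, the grayscale baseline.
#'
#' @inheritParams qdcp_feature
#' @param source scalar image to describe: `"magnitude"` or `"luma"`.
#' @return a `texton_histogram`.
#' @export
lbp_feature <- function(img, source = c("magnitude", "luma"),
                        spec = neighborhood_spec(), normalize = TRUE,
                        table = NULL) {
  source <- match.arg(source)
  conv <- rgb_to_ycbcr(img)
  scalar <- if (source == "magnitude") {
    md_decompose(conv)$magnitude
  } else {
    unclass(conv)[, , 1]
  }
  idx <- lbp_index_image(scalar, spec, table)
  texton_histogram(idx, normalize)
}
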