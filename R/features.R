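descriptor_names <- c("qdcp", "lbp", "qdcp_lbp", "qdcp_joint_lbp")

# Per-image descriptor rows for a whole vector of thresholds, reusing one
# color decomposition and one neighbor-similarity stack across the grid.
.image_descriptor_rows <- function(img, descriptor, t_o_grid, spec,
                                   color_space, source, normalize, table) {
  conv <- to_color_space(img, color_space)
  md <- md_decompose(conv)
  p <- table$n_labels

  lbp_hist <- NULL
  lbp_idx_core <- NULL
  if (descriptor %in% c("lbp", "qdcp_lbp", "qdcp_joint_lbp")) {
    scalar <- if (descriptor == "lbp" && source == "luma") {
      unclass(conv)[, , 1]
    } else {
      md$magnitude
    }
    st <- .scalar_stack(scalar, spec)
    rows <- (st$band + 1):(nrow(scalar) - st$band)
    cols <- (st$band + 1):(ncol(scalar) - st$band)
    center <- scalar[rows, cols, drop = FALSE]
    code <- .code_from_bits(st$vals >= as.vector(center))
    lbp_idx_core <- table$label_of_raw[code + 1L]
    counts <- as.numeric(tabulate(lbp_idx_core + 1L, nbins = p))
    lbp_hist <- if (normalize) counts / length(lbp_idx_core) else counts
  }
  if (descriptor == "lbp") {
    return(matrix(lbp_hist, nrow = 1))
  }

  st <- .similarity_stack(md$orientation, spec)
  out <- matrix(0, length(t_o_grid),
                switch(descriptor, qdcp = p, qdcp_lbp = 2L * p,
                       qdcp_joint_lbp = p * p))
  for (i in seq_along(t_o_grid)) {
    code <- .code_from_bits(st$sim < t_o_grid[i])
    q_labels <- table$label_of_raw[code + 1L]
    n_valid <- length(q_labels)
    row <- switch(descriptor,
      qdcp = {
        counts <- as.numeric(tabulate(q_labels + 1L, nbins = p))
        if (normalize) counts / n_valid else counts
      },
      qdcp_lbp = {
        counts <- as.numeric(tabulate(q_labels + 1L, nbins = p))
        c(if (normalize) counts / n_valid else counts, lbp_hist)
      },
      qdcp_joint_lbp = {
        joint <- as.numeric(tabulate(q_labels * p + lbp_idx_core + 1L,
                                     nbins = p * p))
        if (normalize) joint / n_valid else joint
      }
    )
    out[i, ] <- row
  }
  out
}

#' Feature matrices over a threshold grid
#'
#' Extracts one feature matrix per candidate similarity threshold, reusing a
#' single color decomposition and neighbor-similarity stack per image across
#' the whole grid. The returned named list is the unit [nested_cv()] selects
#' over in its inner loop. Plain LBP has no threshold, so it yields a single
#' set.
#'
#' @param images list of RGB `color_image`s or `H x W x 3` arrays.
#' @param descriptor `"qdcp"`, `"lbp"`, `"qdcp_lbp"`, or `"qdcp_joint_lbp"`.
#' @param t_o_grid numeric vector of thresholds (ignored for `"lbp"`).
#' @param spec,color_space,source,normalize see [extract_features()].
#' @return named list of numeric matrices (rows = images).
#' @export
feature_set_grid <- function(images, descriptor, t_o_grid = 0.8,
                             spec = neighborhood_spec(),
                             color_space = "ycbcr",
                             source = "magnitude", normalize = TRUE) {
  descriptor <- match.arg(descriptor, descriptor_names)
  table <- build_rotation_code_table(spec$n_samples)
  rows <- lapply(images, .image_descriptor_rows, descriptor = descriptor,
                 t_o_grid = t_o_grid, spec = spec, color_space = color_space,
                 source = source, normalize = normalize, table = table)
  if (descriptor == "lbp") {
    return(list(lbp = do.call(rbind, rows)))
  }
  sets <- lapply(seq_along(t_o_grid), function(i) {
    do.call(rbind, lapply(rows, function(r) r[i, , drop = FALSE]))
  })
  names(sets) <- sprintf("t_o=%.2f", t_o_grid)
  sets
}

#' Extract descriptor features as a tibble
#'
#' Data-frame-first feature extraction: takes either a dataset manifest (a
#' data frame with `image_path` and `class_label` columns, see
#' [load_dataset()]) or a list of in-memory RGB images, and returns one row
#' per image with `path`, `label`, and `bin_*` feature columns suitable for
#' [write_features()] and [nested_cv()].
#'
#' @param x a manifest data frame, or a list of `color_image`s /
#'   `H x W x 3` arrays.
#' @param labels class labels when `x` is a list of images (optional).
#' @param descriptor `"qdcp"`, `"lbp"`, `"qdcp_lbp"` (histogram
#'   concatenation), or `"qdcp_joint_lbp"` (joint co-occurrence histogram).
#' @param t_o similarity threshold for the counter-color code.
#' @param spec a [neighborhood_spec()].
#' @param color_space working color space for the decomposition.
#' @param source scalar source for plain LBP: `"magnitude"` or `"luma"`.
#' @param normalize L1-normalize histograms?
#' @return a tibble: `path`, `label`, `bin_000` ... `bin_<D-1>`.
#' @export
extract_features <- function(x, labels = NULL,
                             descriptor = c("qdcp", "lbp", "qdcp_lbp",
                                            "qdcp_joint_lbp"),
                             t_o = 0.8, spec = neighborhood_spec(),
                             color_space = "ycbcr",
                             source = c("magnitude", "luma"),
                             normalize = TRUE) {
  descriptor <- match.arg(descriptor)
  source <- match.arg(source)
  if (is.data.frame(x)) {
    if (!all(c("image_path", "class_label") %in% names(x))) {
      abort("Manifest must have `image_path` and `class_label` columns.",
            class = "qdcp_invalid_input")
    }
    paths <- x$image_path
    labels <- x$class_label
    images <- lapply(paths, read_image)
  } else {
    images <- x
    paths <- names(images) %||% sprintf("image_%03d", seq_along(images))
    if (is.null(labels)) labels <- rep(NA_character_, length(images))
  }
  sets <- feature_set_grid(images, descriptor, t_o_grid = t_o, spec = spec,
                           color_space = color_space, source = source,
                           normalize = normalize)
  mat <- sets[[1]]
  colnames(mat) <- sprintf("bin_%03d", seq_len(ncol(mat)) - 1L)
  dplyr::bind_cols(
    tibble(path = as.character(paths), label = as.character(labels)),
    as_tibble(mat)
  )
}

# numeric feature matrix from a feature tibble
feature_matrix <- function(features) {
  bins <- grep("^bin_", names(features), value = TRUE)
  as.matrix(features[, bins, drop = FALSE])
}
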