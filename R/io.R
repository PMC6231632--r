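#' Read an image file as an RGB color image
#'
#' PNG and TIFF are decoded to floating point in `[0, 1]`. Alpha channels
#' are dropped; single-channel images are replicated to three channels.
#'
#' @param path image file path.
#' @return an RGB `color_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Image not found: %s", path), class = "qdcp_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format '%s' (%s).", ext, path),
          class = "qdcp_io_error")
  )
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3), c(dim(px), 3L))
  } else if (dim(px)[3] >= 3L) {
    px <- px[, , 1:3, drop = FALSE]
  } else {
    abort(sprintf("Cannot interpret %d-channel image: %s", dim(px)[3], path),
          class = "qdcp_io_error")
  }
  color_image(px, "rgb")
}

#' Write an RGB color image to a PNG file
#'
#' @param img RGB `color_image` or array; values clamped to `[0, 1]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- pmin(pmax(unclass(img), 0), 1)
  png::writePNG(px, path)
  invisible(path)
}

#' Load a dataset manifest
#'
#' Either enumerates a directory whose class-named subdirectories contain
#' the images (lexicographically sorted, so re-runs give identical
#' ordering), or reads a CSV manifest with `image_path` and `class_label`
#' columns (relative paths resolved against the CSV's directory).
#'
#' @param root dataset directory or manifest CSV path.
#' @return a tibble with `image_path` and `class_label`.
#' @export
load_dataset <- function(root) {
  if (dir.exists(root)) {
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    rows <- lapply(classes, function(cl) {
      files <- sort(list.files(file.path(root, cl),
                               pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) == 0L) return(NULL)
      tibble(image_path = files, class_label = cl)
    })
    manifest <- dplyr::bind_rows(rows)
  } else if (file.exists(root)) {
    manifest <- readr::read_csv(root, show_col_types = FALSE)
    if (!all(c("image_path", "class_label") %in% names(manifest))) {
      abort("Manifest CSV must have `image_path` and `class_label` columns.",
            class = "qdcp_invalid_input")
    }
    base <- dirname(root)
    rel <- !grepl("^(/|[A-Za-z]:)", manifest$image_path)
    manifest$image_path[rel] <- file.path(base, manifest$image_path[rel])
    manifest <- as_tibble(manifest[, c("image_path", "class_label")])
  } else {
    abort(sprintf("Dataset root not found: %s", root), class = "qdcp_io_error")
  }
  if (is.null(manifest) || nrow(manifest) == 0L) {
    abort("Dataset is empty.", class = "qdcp_invalid_input")
  }
  if (length(unique(manifest$class_label)) < 2L) {
    abort("Dataset must contain at least two classes.",
          class = "qdcp_invalid_input")
  }
  missing <- manifest$image_path[!file.exists(manifest$image_path)]
  if (length(missing) > 0L) {
    abort(sprintf("Image not found: %s", missing[1]), class = "qdcp_io_error")
  }
  manifest
}

#' Write a synthetic dataset to disk
#'
#' Writes PNG files into class-named subdirectories plus a `manifest.csv`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  manifest <- dataset$manifest
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cl <- manifest$class_label[i]
    sub <- file.path(dir, cl)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(manifest$id[i], ".png"))
    write_image(dataset$images[[i]], paths[i])
  }
  out <- tibble(image_path = paths, class_label = manifest$class_label)
  readr::write_csv(out, file.path(dir, "manifest.csv"))
  invisible(out)
}

#' Write / read feature tables
#'
#' CSV round-trip of the feature tibbles produced by [extract_features()]:
#' header `path, label, bin_000, ...`; numeric values survive the round trip
#' exactly (shortest round-trip representation).
#'
#' @param features feature tibble.
#' @param path CSV path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(tbl)
  if (length(nm) < 3L || nm[1] != "path" || nm[2] != "label" ||
      !all(grepl("^bin_", nm[-(1:2)]))) {
    abort("Not a feature table: expected header `path, label, bin_*`.",
          class = "qdcp_format_error")
  }
  tbl
}
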