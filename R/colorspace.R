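#' Color images as numeric arrays
#'
#' A color image is an `H x W x 3` numeric array with a `space` attribute
#' naming the color space of its three channels. 8-bit RGB input is expected
#' to be rescaled to `[0, 1]` before use (image readers in this package do
#' so); the channel scale only affects brightness, never the chromatic
#' orientation that the counter-color descriptor is built from.
#'
#' @param pixels numeric `H x W x 3` array of finite values.
#' @param space one of `"rgb"`, `"ycbcr"`, `"cielab"`, `"i1h2h3"`.
#' @return a `color_image`: the array with `space` attached.
#' @export
color_image <- function(pixels, space = "rgb") {
  space <- match.arg(tolower(space), c("rgb", "ycbcr", "cielab", "i1h2h3"))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 numeric array.",
          class = "qdcp_invalid_input")
  }
  if (!all(is.finite(pixels))) {
    abort("Pixel values must all be finite.", class = "qdcp_invalid_input")
  }
  if (space == "rgb" && any(pixels < 0)) {
    abort("RGB pixel values must be non-negative.",
          class = "qdcp_invalid_input")
  }
  structure(pixels, space = space, class = c("color_image", "array"))
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image %d x %d, space = %s>\n", d[1], d[2], img_space(x)))
  invisible(x)
}

img_space <- function(img) attr(img, "space") %||% "rgb"

`%||%` <- function(a, b) if (is.null(a)) b else a

as_color_array <- function(img, space = "rgb") {
  if (inherits(img, "color_image")) return(img)
  color_image(img, space)
}

# Row-wise transform printed for the luma/chroma decomposition: no offsets,
# so it is a plain linear map and black maps to black.
.ycbcr_matrix <- matrix(c(
  0.299,  0.587,  0.114,
  0.596, -0.274, -0.322,
  0.211, -0.523,  0.312
), nrow = 3, byrow = TRUE)

apply_channel_matrix <- function(pixels, m) {
  d <- dim(pixels)
  flat <- matrix(pixels, ncol = 3L)
  out <- flat %*% t(m)
  array(out, d)
}

#' Convert an RGB image to the YCbCr space
#'
#' Applies the bare 3 x 3 linear luma/chroma transform (no studio-swing
#' offsets) channel-wise. Input channels are expected in `[0, 1]`; the Y
#' output then lies in `[0, 1]` while Cb/Cr may be negative, which is what
#' lets counter-stain chromaticities spread over most of the unit sphere
#' instead of the positive octant.
#'
#' @param img an RGB `color_image` (or plain `H x W x 3` array).
#' @return a `color_image` in the `"ycbcr"` space.
#' @export
rgb_to_ycbcr <- function(img) {
  img <- as_color_array(img, "rgb")
  if (img_space(img) != "rgb") {
    abort("`rgb_to_ycbcr()` expects an RGB image.", class = "qdcp_invalid_input")
  }
  color_image(apply_channel_matrix(unclass(img), .ycbcr_matrix), "ycbcr")
}

#' Convert an RGB image to another color space
#'
#' Supported targets: `"rgb"` (identity), `"ycbcr"` (see [rgb_to_ycbcr()]),
#' `"cielab"` (sRGB to Lab, D65 white point, via [grDevices::convertColor()]),
#' and `"i1h2h3"`, an intensity / opponent-chromaticity linear transform
#' (I1 = (R+G+B)/3, H2 = (R-B)/2, H3 = (2G-R-B)/4) often used for
#' trichrome-stained imagery.
#'
#' @param img an RGB `color_image`.
#' @param target target space name.
#' @return a `color_image` in the requested space.
#' @export
to_color_space <- function(img, target = c("ycbcr", "rgb", "cielab", "i1h2h3")) {
  img <- as_color_array(img, "rgb")
  if (img_space(img) != "rgb") {
    abort("`to_color_space()` expects an RGB image.", class = "qdcp_invalid_input")
  }
  target <- tolower(target[1])
  if (!target %in% c("ycbcr", "rgb", "cielab", "i1h2h3")) {
    abort(sprintf("Unknown color space '%s'.", target),
          class = "qdcp_invalid_input")
  }
  switch(target,
    rgb = img,
    ycbcr = rgb_to_ycbcr(img),
    cielab = {
      d <- dim(img)
      flat <- matrix(unclass(img), ncol = 3L)
      lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
      color_image(array(lab, d), "cielab")
    },
    i1h2h3 = {
      m <- matrix(c(
        1 / 3, 1 / 3, 1 / 3,
        1 / 2, 0,    -1 / 2,
        -1 / 4, 1 / 2, -1 / 4
      ), nrow = 3, byrow = TRUE)
      color_image(apply_channel_matrix(unclass(img), m), "i1h2h3")
    }
  )
}

#' Magnitude-direction decomposition of a color image
#'
#' Splits each pixel vector into its Euclidean norm (brightness) and a
#' unit-length orientation (chromaticity direction). Degenerate pixels with
#' norm at or below `eps` receive the achromatic convention orientation
#' `(1, 0, 0)`, which keeps the orientation field total and unit-norm; in the
#' luma/chroma space this is the direction of a pure achromatic color.
#'
#' @param img a `color_image` in any space.
#' @param eps degeneracy threshold on the pixel norm (default `1e-12`,
#'   far below the quantization step of 8-bit data).
#' @return a list with `magnitude` (`H x W` matrix of norms) and
#'   `orientation` (`H x W x 3` array of unit vectors).
#' @export
md_decompose <- function(img, eps = 1e-12) {
  px <- unclass(as_color_array(img, img_space(img)))
  d <- dim(px)
  flat <- matrix(px, ncol = 3L)
  mag <- sqrt(rowSums(flat * flat))
  degen <- mag <= eps
  safe <- ifelse(degen, 1, mag)
  orient <- flat / safe
  if (any(degen)) {
    orient[degen, 1] <- 1
    orient[degen, 2] <- 0
    orient[degen, 3] <- 0
  }
  list(
    magnitude = matrix(mag, d[1], d[2]),
    orientation = array(orient, d)
  )
}
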