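#' Angular similarity of two unit color vectors
#'
#' The inner product of two unit-length chromaticity vectors, the cosine of
#' the angle between them on the chromatic sphere. A value of 1 means
#' co-linear colors; small or negative values mean counter colors.
#'
#' @param u,v unit 3-vectors (norm 1 within `1e-6`).
#' @return the dot product, clamped to `[-1, 1]`.
#' @export
orientation_similarity <- function(u, v) {
  if (abs(sqrt(sum(u * u)) - 1) > 1e-6 || abs(sqrt(sum(v * v)) - 1) > 1e-6) {
    abort("`u` and `v` must be unit vectors.", class = "qdcp_invalid_input")
  }
  min(1, max(-1, sum(u * v)))
}

#' Color-separation angle of a similarity threshold
#'
#' The similarity threshold is a cosine, so `acos` converts it to the color
#' separation angle it encodes: a threshold of 1 admits any color change
#' (0 degrees) while 0.8 corresponds to about a 36-degree separation.
#'
#' @param t_o similarity threshold in `[-1, 1]`.
#' @return the angle in degrees (continuous; truncate for display).
#' @export
threshold_to_angle <- function(t_o) {
  if (any(!is.finite(t_o)) || any(t_o < -1) || any(t_o > 1)) {
    abort("`t_o` must lie in [-1, 1].", class = "qdcp_invalid_input")
  }
  acos(t_o) * 180 / pi
}

# Vectorized bilinear gather of a full matrix at a constant fractional
# offset (dx, dy), restricted to the interior band where the whole sampling
# ring stays inside the image. Difference form => exact on constant regions.
.offset_sample <- function(m, dx, dy, band) {
  h <- nrow(m); w <- ncol(m)
  rows <- (band + 1):(h - band)  # 1-based valid rows
  cols <- (band + 1):(w - band)
  fy <- dy - floor(dy); fx <- dx - floor(dx)
  r0 <- rows + floor(dy); c0 <- cols + floor(dx)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  v00 <- m[r0, c0, drop = FALSE]; v10 <- m[r0, c1, drop = FALSE]
  v01 <- m[r1, c0, drop = FALSE]; v11 <- m[r1, c1, drop = FALSE]
  v00 + fx * (v10 - v00) + fy * (v01 - v00) +
    fx * fy * (v11 - v10 - v01 + v00)
}

.check_region <- function(h, w, band) {
  if (h < 2 * band + 1 || w < 2 * band + 1) {
    abort(sprintf(
      "Image %d x %d has no valid interior for a radius needing a %d-pixel border.",
      h, w, band), class = "qdcp_empty_region")
  }
}

# Similarity stack m[p, k] between each interior pixel's orientation and its
# k-th ring neighbor (bilinearly sampled, renormalized). Values are snapped
# to +/-1 within 1e-12 to absorb renormalization round-off, then clamped.
.similarity_stack <- function(orient, spec) {
  h <- dim(orient)[1]; w <- dim(orient)[2]
  band <- as.integer(ceiling(spec$radius))
  .check_region(h, w, band)
  offs <- neighbor_offsets(spec)
  rows <- (band + 1):(h - band); cols <- (band + 1):(w - band)
  c1 <- orient[rows, cols, 1, drop = TRUE]
  c2 <- orient[rows, cols, 2, drop = TRUE]
  c3 <- orient[rows, cols, 3, drop = TRUE]
  sim <- array(0, c(length(rows), length(cols), spec$n_samples))
  for (k in seq_len(spec$n_samples)) {
    s1 <- .offset_sample(orient[, , 1], offs$dx[k], offs$dy[k], band)
    s2 <- .offset_sample(orient[, , 2], offs$dx[k], offs$dy[k], band)
    s3 <- .offset_sample(orient[, , 3], offs$dx[k], offs$dy[k], band)
    nv <- sqrt(s1 * s1 + s2 * s2 + s3 * s3)
    degen <- nv <= 1e-12
    if (any(degen)) {
      s1[degen] <- 1; s2[degen] <- 0; s3[degen] <- 0; nv[degen] <- 1
    }
    m <- (c1 * s1 + c2 * s2 + c3 * s3) / nv
    m[m > 1 - 1e-12] <- 1
    m[m < -1 + 1e-12] <- -1
    sim[, , k] <- m
  }
  list(sim = sim, band = band)
}

# Neighbor-value stack for a scalar field (no renormalization).
.scalar_stack <- function(scalar, spec) {
  h <- nrow(scalar); w <- ncol(scalar)
  band <- as.integer(ceiling(spec$radius))
  .check_region(h, w, band)
  offs <- neighbor_offsets(spec)
  vals <- array(0, c(h - 2 * band, w - 2 * band, spec$n_samples))
  for (k in seq_len(spec$n_samples)) {
    vals[, , k] <- .offset_sample(scalar, offs$dx[k], offs$dy[k], band)
  }
  list(vals = vals, band = band)
}

# Raw ring code from a logical H' x W' x N bit stack; bit k has weight 2^k.
.code_from_bits <- function(bits) {
  n <- dim(bits)[3]
  code <- matrix(0L, dim(bits)[1], dim(bits)[2])
  for (k in seq_len(n)) {
    code <- code + bits[, , k] * 2L^(k - 1L)
  }
  code
}

.texton_index <- function(label_core, h, w, band, n_labels) {
  labels <- matrix(NA_integer_, h, w)
  valid <- matrix(FALSE, h, w)
  rows <- (band + 1):(h - band); cols <- (band + 1):(w - band)
  labels[rows, cols] <- label_core
  valid[rows, cols] <- TRUE
  structure(
    list(labels = labels, valid_mask = valid, n_labels = n_labels,
         border = band),
    class = "texton_index"
  )
}

#' @export
print.texton_index <- function(x, ...) {
  cat(sprintf("<texton_index %d x %d, %d labels, %d valid pixels>\n",
              nrow(x$labels), ncol(x$labels), x$n_labels, sum(x$valid_mask)))
  invisible(x)
}

#' Counter-color texton index image (QDCP)
#'
#' For every interior pixel, samples the `N` ring neighbors of its unit
#' orientation vector, computes the angular similarity `m` of each neighbor
#' to the center, binarizes with the strict rule `bit = 1` iff `m < t_o`
#' (equality gives 0), and reduces the ring code to its rotation-invariant
#' dense label. Pixels whose ring leaves the image (a border band of width
#' `ceiling(radius)`) are masked invalid.
#'
#' @param orient `H x W x 3` unit orientation field (see [md_decompose()]).
#' @param spec a [neighborhood_spec()].
#' @param t_o similarity threshold; colors separated by more than
#'   `acos(t_o)` count as counter colors.
#' @param table rotation code table for `spec$n_samples`
#'   (built automatically when omitted).
#' @return a `texton_index` with `labels`, `valid_mask`, `n_labels`.
#' @export
qdcp_index_image <- function(orient, spec = neighborhood_spec(), t_o = 0.8,
                             table = NULL) {
  if (!is.numeric(t_o) || length(t_o) != 1L || !is.finite(t_o)) {
    abort("`t_o` must be a single finite number.", class = "qdcp_invalid_input")
  }
  table <- table %||% build_rotation_code_table(spec$n_samples)
  st <- .similarity_stack(orient, spec)
  code <- .code_from_bits(st$sim < t_o)
  .texton_index(matrix(table$label_of_raw[code + 1L], nrow(code), ncol(code)),
                dim(orient)[1], dim(orient)[2], st$band, table$n_labels)
}

#' Rotation-invariant LBP index image on a scalar field
#'
#' Classic local binary pattern on a brightness-like scalar image: ring
#' neighbors are bilinearly sampled and `bit = 1` iff `neighbor >= center`
#' (ties set the bit). Codes are reduced with the same rotation-invariant
#' table as the counter-color descriptor, so both share the 36-label space
#' for 8 neighbors.
#'
#' @param scalar `H x W` numeric matrix (e.g. the magnitude image or luma).
#' @inheritParams qdcp_index_image
#' @return a `texton_index`.
#' @export
lbp_index_image <- function(scalar, spec = neighborhood_spec(), table = NULL) {
  table <- table %||% build_rotation_code_table(spec$n_samples)
  st <- .scalar_stack(scalar, spec)
  rows <- (st$band + 1):(nrow(scalar) - st$band)
  cols <- (st$band + 1):(ncol(scalar) - st$band)
  center <- scalar[rows, cols, drop = FALSE]
  bits <- st$vals >= as.vector(center)  # recycles center over the 3rd dim
  code <- .code_from_bits(bits)
  .texton_index(matrix(table$label_of_raw[code + 1L], nrow(code), ncol(code)),
                nrow(scalar), ncol(scalar), st$band, table$n_labels)
}
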