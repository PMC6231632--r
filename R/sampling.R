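#' Circular neighborhood specification
#'
#' Defines the classic circular sampling ring used by rotation-invariant
#' texton codes: `n_samples` points equally spaced on a circle of radius
#' `radius` around each pixel. Sample `k` (0-based) sits at angle
#' `angle_origin + 2*pi*k/n_samples`, counterclockwise in image coordinates
#' (x = column, y = row, both 0-based, y increasing downward). The starting
#' sample is immaterial once codes are reduced to rotation orbits.
#'
#' @param n_samples number of ring samples (N >= 2).
#' @param radius ring radius in pixels (> 0).
#' @param angle_origin angle of sample 0, radians (default 0, due east).
#' @return a `neighborhood_spec` list.
#' @export
neighborhood_spec <- function(n_samples = 8L, radius = 1, angle_origin = 0) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    abort("`n_samples` must be an integer >= 2.", class = "qdcp_invalid_input")
  }
  if (!is.finite(radius) || radius <= 0) {
    abort("`radius` must be a positive number.", class = "qdcp_invalid_input")
  }
  structure(
    list(n_samples = n_samples, radius = radius, angle_origin = angle_origin,
         angular_direction = "counterclockwise"),
    class = "neighborhood_spec"
  )
}

#' Ring sample offsets
#'
#' @param spec a [neighborhood_spec()].
#' @return a tibble with columns `k`, `dx`, `dy` (real offsets in pixels).
#' @export
neighbor_offsets <- function(spec) {
  k <- seq_len(spec$n_samples) - 1L
  ang <- spec$angle_origin + 2 * pi * k / spec$n_samples
  tibble(
    k = k,
    dx = zap_tiny(spec$radius * cos(ang)),
    dy = zap_tiny(spec$radius * sin(ang))
  )
}

# cos/sin at multiples of pi/2 should give exact 0/±1 offsets so that the
# cardinal samples land exactly on pixel centers.
zap_tiny <- function(x, tol = 1e-12) {
  x[abs(x) < tol] <- 0
  r <- round(x)
  near <- abs(x - r) < tol
  x[near] <- r[near]
  x
}

#' Bilinear interpolation in a scalar or vector field
#'
#' Interpolates from the four surrounding pixel centers using the difference
#' form `v00 + fx (v10 - v00) + fy (v01 - v00) + fx fy (v11 - v10 - v01 + v00)`,
#' which is exact on constant regions and at integer coordinates. For a
#' 3-vector orientation field the interpolated vector is renormalized to unit
#' length (degenerate results fall back to the achromatic `(1, 0, 0)`).
#'
#' @param field an `H x W` matrix (scalar field) or `H x W x 3` array
#'   (orientation field).
#' @param point numeric `c(x, y)`, 0-based coordinates (x = column, y = row)
#'   inside the convex hull of pixel centers.
#' @return a scalar, or a unit 3-vector for an orientation field.
#' @export
bilinear_sample <- function(field, point) {
  x <- point[1]; y <- point[2]
  d <- dim(field)
  h <- d[1]; w <- d[2]
  if (x < 0 || y < 0 || x > w - 1 || y > h - 1) {
    abort("Sample point lies outside the pixel-center hull.",
          class = "qdcp_out_of_bounds")
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- min(x0 + 1, w - 1); y1 <- min(y0 + 1, h - 1)
  interp1 <- function(m) {
    v00 <- m[y0 + 1, x0 + 1]; v10 <- m[y0 + 1, x1 + 1]
    v01 <- m[y1 + 1, x0 + 1]; v11 <- m[y1 + 1, x1 + 1]
    v00 + fx * (v10 - v00) + fy * (v01 - v00) +
      fx * fy * (v11 - v10 - v01 + v00)
  }
  if (length(d) == 2L) return(interp1(field))
  v <- vapply(1:3, function(c) interp1(field[, , c]), numeric(1))
  nv <- sqrt(sum(v * v))
  if (nv <= 1e-12) return(c(1, 0, 0))
  v / nv
}

#' Rotation-invariant code table for an N-sample ring
#'
#' Enumerates all `2^N` raw binary neighborhood codes, reduces each to the
#' minimum over its cyclic shifts (the binary-necklace representative), and
#' assigns dense labels `0..P-1` to the distinct representatives in ascending
#' order. For N = 8 there are P = 36 rotation-invariant patterns, which fixes
#' the descriptor histogram length.
#'
#' @param n_samples ring size N, between 2 and 16.
#' @return a `rotation_code_table` with `minimized_code_of` (length `2^N`
#'   integer vector indexed by raw code + 1), `label_of_raw` (dense label per
#'   raw code, same indexing), and `n_labels`.
#' @export
build_rotation_code_table <- function(n_samples) {
  n <- as.integer(n_samples)
  if (is.na(n) || n < 2L || n > 16L) {
    abort("`n_samples` must be an integer in 2..16.",
          class = "qdcp_invalid_input")
  }
  codes <- 0:(2^n - 1)
  bits <- matrix(0L, length(codes), n)
  for (i in seq_len(n)) bits[, i] <- bitwAnd(codes %/% 2L^(i - 1L), 1L)
  pow <- 2^(0:(n - 1))
  minimized <- rep(Inf, length(codes))
  for (shift in 0:(n - 1)) {
    # bit i of the raw code moves to position (i + shift) mod n
    weights <- pow[((seq_len(n) - 1L + shift) %% n) + 1L]
    minimized <- pmin(minimized, as.vector(bits %*% weights))
  }
  minimized <- as.integer(minimized)
  reps <- sort(unique(minimized))
  label_map <- integer(2^n)
  label_map[reps + 1L] <- seq_along(reps) - 1L
  structure(
    list(
      neighborhood_size = n,
      minimized_code_of = minimized,
      label_of_raw = label_map[minimized + 1L],
      representatives = reps,
      n_labels = length(reps)
    ),
    class = "rotation_code_table"
  )
}

#' Rotation-invariant dense label of a bit pattern
#'
#' @param bits integer vector of 0/1 of length `table$neighborhood_size`;
#'   bit `k` (1-based position `k+1`) is the comparison outcome at ring
#'   sample `k` and carries weight `2^k` in the raw code.
#' @param table a [build_rotation_code_table()] result.
#' @return the dense label, identical for every cyclic rotation of `bits`.
#' @export
rotation_invariant_code <- function(bits, table) {
  n <- table$neighborhood_size
  if (length(bits) != n) {
    abort("`bits` length must match the table's neighborhood size.",
          class = "qdcp_invalid_input")
  }
  if (!all(bits %in% c(0, 1))) {
    abort("`bits` must be 0/1.", class = "qdcp_invalid_input")
  }
  raw <- sum(bits * 2^(seq_len(n) - 1L))
  table$label_of_raw[raw + 1L]
}
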