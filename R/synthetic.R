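# run code under a temporary RNG state so generators are deterministic
# without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

unit3 <- function(v) v / sqrt(sum(v * v))

.luma_coef <- c(0.299, 0.587, 0.114)

#' Construct an iso-luma counter-stain chromaticity
#'
#' Given a background stain direction (a unit RGB vector), finds a second
#' unit RGB direction at exactly `separation_deg` degrees from it with the
#' same luma coefficient, so the two stains differ only in chromatic
#' direction, not in brightness. Closed form on the circle of directions at
#' fixed angle around the background vector; of the two solutions the one
#' shifted toward green-blue (smaller red share) is returned.
#'
#' @param bg_chroma unit 3-vector with positive components.
#' @param separation_deg angle between the two stain directions, degrees.
#' @return a unit 3-vector with positive components.
#' @export
counter_stain <- function(bg_chroma, separation_deg) {
  u <- unit3(bg_chroma)
  theta <- separation_deg * pi / 180
  # orthonormal basis of the plane perpendicular to u
  a0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(a0 - sum(a0 * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  lu <- sum(.luma_coef * u)
  a <- sum(.luma_coef * e1)
  b <- sum(.luma_coef * e2)
  r0 <- sqrt(a^2 + b^2)
  target <- lu * tan(theta / 2)
  if (abs(target) > r0) {
    abort("No iso-luma direction exists at this separation from `bg_chroma`.",
          class = "qdcp_invalid_input")
  }
  phi0 <- atan2(b, a)
  dphi <- acos(target / r0)
  cand <- lapply(c(phi0 + dphi, phi0 - dphi), function(phi) {
    unit3(cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2))
  })
  ok <- vapply(cand, function(v) all(v > 0), logical(1))
  if (!any(ok)) {
    abort("Iso-luma counter-stain has non-positive RGB components; choose a different background chroma or separation.",
          class = "qdcp_invalid_input")
  }
  cand <- cand[ok]
  reds <- vapply(cand, function(v) v[1], numeric(1))
  cand[[which.min(reds)]]
}

#' Parameters of the synthetic stained-texture generator
#'
#' Defines two-class stained-tissue patches: a "counter" class whose
#' micro-structure interleaves two stain chromaticities (soft-edged disks of
#' a foreground stain scattered over a background stain, like collagen
#' structures in a trichrome-stained glomerulus) and a "smooth" class with a
#' single chromaticity and only brightness texture (like smooth blood-cell
#' crops). Brightness is a smoothed random field applied multiplicatively to
#' the chromaticity, so the classes differ purely in chromatic orientation;
#' by default the two stains are iso-luma, making the luma image genuinely
#' uninformative about class.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param bg_chroma unit RGB direction of the background stain (default a
#'   trichrome-like red).
#' @param chroma_separation_deg angle between background and foreground
#'   stain directions, degrees.
#' @param fg_chroma optional explicit foreground stain direction; when
#'   omitted it is derived iso-luma at the requested separation. If given,
#'   its angle to `bg_chroma` must match `chroma_separation_deg` within 0.1
#'   degrees.
#' @param blob_density expected foreground disks per 100 x 100 pixels.
#' @param blob_radius_range `c(min, max)` disk radius, pixels.
#' @param brightness_field_sigma Gaussian smoothing scale of the brightness
#'   field, pixels.
#' @param brightness_noise_sd relative sd of multiplicative brightness noise.
#' @param seed RNG seed making a single image reproducible.
#' @return a `stain_texture_params` list.
#' @export
stain_texture_params <- function(image_size = c(64, 64),
                                 bg_chroma = unit3(c(0.72, 0.30, 0.32)),
                                 chroma_separation_deg = 40,
                                 fg_chroma = NULL,
                                 blob_density = 120,
                                 blob_radius_range = c(1.5, 3.5),
                                 brightness_field_sigma = 8,
                                 brightness_noise_sd = 0.05,
                                 seed = 1L) {
  bg_chroma <- unit3(bg_chroma)
  if (any(bg_chroma <= 0)) {
    abort("`bg_chroma` must have positive RGB components.",
          class = "qdcp_invalid_input")
  }
  if (is.null(fg_chroma)) {
    fg_chroma <- if (chroma_separation_deg == 0) bg_chroma else
      counter_stain(bg_chroma, chroma_separation_deg)
  } else {
    fg_chroma <- unit3(fg_chroma)
    if (any(fg_chroma <= 0)) {
      abort("`fg_chroma` must have positive RGB components.",
            class = "qdcp_invalid_input")
    }
    ang <- acos(min(1, max(-1, sum(bg_chroma * fg_chroma)))) * 180 / pi
    if (abs(ang - chroma_separation_deg) > 0.1) {
      abort("`fg_chroma` does not match `chroma_separation_deg` within 0.1 degrees.",
            class = "qdcp_invalid_input")
    }
  }
  structure(
    list(image_size = as.integer(image_size), bg_chroma = bg_chroma,
         fg_chroma = fg_chroma,
         chroma_separation_deg = chroma_separation_deg,
         blob_density = blob_density,
         blob_radius_range = blob_radius_range,
         brightness_field_sigma = brightness_field_sigma,
         brightness_noise_sd = brightness_noise_sd,
         seed = as.integer(seed)),
    class = "stain_texture_params"
  )
}

# separable Gaussian blur with reflected borders
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) {
    idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
    pmin(pmax(idx, 1L), n)
  }
  conv_cols <- function(x) {
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[(j - 1L) + seq_len(nrow(x)), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Generate one synthetic stained-tissue patch
#'
#' @param params a [stain_texture_params()].
#' @param class_label `"counter"` (two interleaved stain chromaticities) or
#'   `"smooth"` (single chromaticity, brightness texture only).
#' @return an RGB `color_image` with values in `[0, 1]`; bit-identical for a
#'   fixed `params$seed`.
#' @export
generate_image <- function(params, class_label = c("counter", "smooth")) {
  class_label <- match.arg(class_label)
  h <- params$image_size[1]; w <- params$image_size[2]
  with_local_seed(params$seed, {
    field <- .gauss_blur(matrix(rnorm(h * w), h, w),
                         params$brightness_field_sigma)
    s <- sd(field)
    if (s > 0) field <- (field - mean(field)) / s
    bright <- pmin(pmax(0.7 + 0.15 * field, 0.2), 0.98)
    noise <- matrix(rnorm(h * w, 0, params$brightness_noise_sd), h, w)
    bright <- pmin(pmax(bright * (1 + noise), 0.02), 1)

    tmap <- matrix(0, h, w)
    if (class_label == "counter" && params$blob_density > 0) {
      n_blobs <- rpois(1, params$blob_density * h * w / 1e4)
      if (n_blobs > 0) {
        cx <- runif(n_blobs, 0, w - 1)
        cy <- runif(n_blobs, 0, h - 1)
        rad <- runif(n_blobs, params$blob_radius_range[1],
                     params$blob_radius_range[2])
        xs <- matrix(rep(0:(w - 1), each = h), h, w)
        ys <- matrix(rep(0:(h - 1), times = w), h, w)
        # Soft 1-px edge: one intermediate blend sample keeps the bilinear
        # sampler off hard aliasing while leaving adjacent-pixel color steps
        # at (nearly) the full stain separation, so the counter-color code
        # actually sees the blob boundaries at thresholds around 0.8.
        ramp <- 1
        for (i in seq_len(n_blobs)) {
          d <- sqrt((xs - cx[i])^2 + (ys - cy[i])^2)
          tmap <- pmax(tmap, pmin(pmax((rad[i] - d) / ramp, 0), 1))
        }
      }
    }

    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      dir_ch <- (1 - tmap) * params$bg_chroma[ch] + tmap * params$fg_chroma[ch]
      px[, , ch] <- dir_ch * bright
    }
    color_image(px, "rgb")
  })
}

#' Generate a balanced two-class synthetic dataset
#'
#' @param n_per_class images per class (counter and smooth).
#' @param params base [stain_texture_params()]; per-image seeds are derived
#'   deterministically from `seed`.
#' @param seed master seed.
#' @return a list with `images` (list of RGB `color_image`s), `labels`
#'   (factor with levels `smooth`, `counter`), and `manifest` (a tibble with
#'   `id`, `class_label`, `seed`).
#' @export
generate_dataset <- function(n_per_class, params = stain_texture_params(),
                             seed = 1L) {
  if (n_per_class < 1) {
    abort("`n_per_class` must be >= 1.", class = "qdcp_invalid_input")
  }
  n <- 2L * n_per_class
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  labels <- factor(rep(c("smooth", "counter"), each = n_per_class),
                   levels = c("smooth", "counter"))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- params
    p_i$seed <- seeds[i]
    images[[i]] <- generate_image(p_i, as.character(labels[i]))
  }
  list(
    images = images,
    labels = labels,
    manifest = tibble(id = sprintf("img_%03d", seq_len(n)),
                      class_label = as.character(labels), seed = seeds)
  )
}
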