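# in-code fixtures shared across test files

# random unit orientation field with positive first component (luma-like)
random_orientation_field <- function(h, w, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(h * w * 3), ncol = 3)
    v[, 1] <- abs(v[, 1]) + 0.1
    v <- v / sqrt(rowSums(v^2))
    array(v, c(h, w, 3))
  })
}

random_rgb_image <- function(h, w, seed) {
  withr::with_seed(seed, {
    array(runif(h * w * 3, 0.05, 1), c(h, w, 3))
  })
}

# rotate an image array 90 degrees counterclockwise, n times
rot90_image <- function(a, times = 1) {
  for (i in seq_len(times)) {
    if (length(dim(a)) == 3L) {
      out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
      for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[, , ch])[dim(a)[2]:1, ]
      a <- out
    } else {
      a <- t(a)[ncol(a):1, , drop = FALSE]
    }
  }
  a
}

# orientation field of an image in the default working space
ycbcr_orientation <- function(img) md_decompose(rgb_to_ycbcr(img))$orientation
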