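test_that("orientation similarity is the clamped inner product", {
  expect_equal(orientation_similarity(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(orientation_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(orientation_similarity(c(1, 0, 0), c(0.6, 0.8, 0)), 0.6)
  expect_error(orientation_similarity(c(1, 1, 0), c(1, 0, 0)),
               class = "qdcp_invalid_input")
})

test_that("threshold-angle correspondence", {
  expect_equal(threshold_to_angle(1), 0)
  expect_equal(threshold_to_angle(0), 90)
  expect_equal(trunc(threshold_to_angle(0.8)), 36)
  expect_equal(threshold_to_angle(0.8), acos(0.8) * 180 / pi)
  expect_error(threshold_to_angle(1.01), class = "qdcp_invalid_input")
})

test_that("constant orientation fields give the all-zero code", {
  orient <- array(rep(c(0.6, 0.8, 0), each = 20), c(4, 5, 3))
  for (t_o in c(-1, 0, 0.8, 1)) {
    idx <- qdcp_index_image(orient, neighborhood_spec(8, 1), t_o)
    expect_true(all(idx$labels[idx$valid_mask] == 0L))
  }
})

test_that("threshold extremes give degenerate codes on any image", {
  orient <- ycbcr_orientation(random_rgb_image(10, 10, 42))
  idx_lo <- qdcp_index_image(orient, t_o = -1)
  expect_true(all(idx_lo$labels[idx_lo$valid_mask] == 0L))
  t8 <- build_rotation_code_table(8)
  all_ones <- t8$label_of_raw[256]
  idx_hi <- qdcp_index_image(orient, t_o = 1 + 1e-9)
  expect_true(all(idx_hi$labels[idx_hi$valid_mask] == all_ones))
})

test_that("two-color 5x5 image codes exactly one discordant neighbor", {
  orient <- array(0, c(5, 5, 3))
  orient[, 1:3, 1] <- 1   # left: (1,0,0)
  orient[, 4:5, 2] <- 1   # right: (0,1,0)
  spec <- neighborhood_spec(4, 1)
  t4 <- build_rotation_code_table(4)
  idx <- qdcp_index_image(orient, spec, t_o = 0.5, table = t4)
  one_bit <- t4$label_of_raw[2]
  # boundary columns (0-based cols 2 and 3) see exactly one cross-color sample
  expect_true(all(idx$labels[2:4, 3] == one_bit))
  expect_true(all(idx$labels[2:4, 4] == one_bit))
  expect_true(all(idx$labels[2:4, 2] == 0L))
  # and the whole image matches the naive per-pixel oracle
  expect_identical(idx$labels, oracle_qdcp_labels(orient, 4, 1, 0.5))
})

test_that("valid mask is the border-exclusion band", {
  orient <- random_orientation_field(7, 9, 3)
  idx <- qdcp_index_image(orient, neighborhood_spec(8, 1.5))
  expect_identical(idx$border, 2L)
  expect_true(all(!idx$valid_mask[c(1, 2, 6, 7), ]))
  expect_true(all(!idx$valid_mask[, c(1, 2, 8, 9)]))
  expect_true(all(idx$valid_mask[3:5, 3:7]))
  expect_true(all(idx$labels[idx$valid_mask] < idx$n_labels))
  expect_error(qdcp_index_image(orient[1:2, 1:2, , drop = FALSE]),
               class = "qdcp_empty_region")
})

test_that("index image matches the naive oracle on random fields", {
  for (seed in 1:5) {
    orient <- random_orientation_field(16, 16, seed)
    idx <- qdcp_index_image(orient, neighborhood_spec(8, 1), t_o = 0.8)
    expect_identical(idx$labels, oracle_qdcp_labels(orient, 8, 1, 0.8))
  }
})

test_that("histograms count valid pixels and normalize to one", {
  orient <- random_orientation_field(12, 10, 9)
  idx <- qdcp_index_image(orient, t_o = 0.8)
  h_counts <- texton_histogram(idx, normalize = FALSE)
  expect_equal(sum(h_counts$bins), h_counts$n_valid)
  expect_identical(h_counts$n_valid, sum(idx$valid_mask))
  h_freq <- texton_histogram(idx, normalize = TRUE)
  expect_equal(sum(h_freq$bins), 1, tolerance = 1e-9)
  expect_equal(h_freq$bins * h_freq$n_valid, h_counts$bins)
  # constant image: all mass in bin 0
  const <- array(rep(c(1, 0, 0), each = 25), c(5, 5, 3))
  h0 <- texton_histogram(qdcp_index_image(const, t_o = 0.8), normalize = FALSE)
  expect_equal(h0$bins[1], h0$n_valid)
  expect_true(all(h0$bins[-1] == 0))
})

test_that("descriptor is invariant to global intensity scaling", {
  img <- generate_image(stain_texture_params(seed = 21), "counter")
  h <- qdcp_feature(img, normalize = FALSE)
  for (k in c(0.25, 0.5, 2)) {
    hk <- qdcp_feature(unclass(img) * k, normalize = FALSE)
    expect_identical(hk$bins, h$bins)
  }
})

test_that("descriptor histogram is invariant to image rotation", {
  img <- unclass(generate_image(stain_texture_params(seed = 22), "counter"))
  h <- qdcp_feature(img, normalize = FALSE)
  for (times in 1:3) {
    hr <- qdcp_feature(rot90_image(img, times), normalize = FALSE)
    expect_identical(hr$bins, h$bins)
  }
})

test_that("zero-code mass is non-increasing in the threshold", {
  img <- generate_image(stain_texture_params(seed = 23), "counter")
  orient <- ycbcr_orientation(img)
  grid <- c(-1, -0.5, 0, 0.5, 0.75, 0.8, 0.85, 0.9, 1)
  zero_counts <- vapply(grid, function(t_o) {
    idx <- qdcp_index_image(orient, t_o = t_o)
    sum(idx$labels[idx$valid_mask] == 0L)
  }, numeric(1))
  expect_true(all(diff(zero_counts) <= 0))
})

test_that("degenerate images fail with the empty-region error", {
  tiny <- color_image(array(0.5, c(1, 1, 3)))
  expect_error(qdcp_feature(tiny), class = "qdcp_empty_region")
})
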