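test_that("ring offsets land where trigonometry says", {
  o4 <- neighbor_offsets(neighborhood_spec(4, 1))
  expect_equal(o4$dx, c(1, 0, -1, 0))
  expect_equal(o4$dy, c(0, 1, 0, -1))
  o8 <- neighbor_offsets(neighborhood_spec(8, 1))
  expect_equal(c(o8$dx[2], o8$dy[2]), c(sqrt(2) / 2, sqrt(2) / 2))
  o2 <- neighbor_offsets(neighborhood_spec(2, 2))
  expect_equal(o2$dx, c(2, -2))
  expect_equal(o2$dy, c(0, 0))
  expect_error(neighborhood_spec(1), class = "qdcp_invalid_input")
  expect_error(neighborhood_spec(8, 0), class = "qdcp_invalid_input")
})

test_that("bilinear sampling is exact at integer points and midpoints", {
  withr::with_seed(4, m <- matrix(runif(48), 6, 8))
  expect_identical(bilinear_sample(m, c(3, 5)), m[6, 4])
  m2 <- matrix(c(2, 2, 4, 4), 2, 2)  # values 2 and 4 along x
  expect_equal(bilinear_sample(m2, c(0.5, 0)), 3)
  expect_error(bilinear_sample(m, c(-0.1, 0)), class = "qdcp_out_of_bounds")
  expect_error(bilinear_sample(m, c(0, 5.5)), class = "qdcp_out_of_bounds")
})

test_that("bilinear sampling reproduces affine scalar fields exactly", {
  xs <- matrix(rep(0:7, each = 6), 6, 8)
  ys <- matrix(rep(0:5, times = 8), 6, 8)
  f <- 1.5 + 0.25 * xs - 0.6 * ys
  withr::with_seed(5, pts <- cbind(runif(20, 0, 7), runif(20, 0, 5)))
  for (i in 1:20) {
    expect_equal(bilinear_sample(f, pts[i, ]),
                 1.5 + 0.25 * pts[i, 1] - 0.6 * pts[i, 2], tolerance = 1e-9)
  }
})

test_that("interpolated orientations are renormalized", {
  field <- array(0, c(2, 2, 3))
  field[, 1, 1] <- 1          # left column (1,0,0)
  field[, 2, 2] <- 1          # right column (0,1,0)
  v <- bilinear_sample(field, c(0.5, 0.5))
  expect_equal(v, c(sqrt(2) / 2, sqrt(2) / 2, 0), tolerance = 1e-12)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("rotation code table counts necklaces and fixes extremes", {
  t8 <- build_rotation_code_table(8)
  expect_identical(t8$n_labels, 36L)
  expect_identical(build_rotation_code_table(4)$n_labels, 6L)
  for (n in c(3, 5, 8)) {
    tab <- build_rotation_code_table(n)
    expect_identical(tab$minimized_code_of[1], 0L)
    expect_identical(tab$minimized_code_of[2^n], as.integer(2^n - 1))
    expect_true(all(tab$minimized_code_of <= 0:(2^n - 1)))
  }
  expect_error(build_rotation_code_table(1), class = "qdcp_invalid_input")
  expect_error(build_rotation_code_table(17), class = "qdcp_invalid_input")
})

test_that("label count matches the necklace closed form for N = 2..12", {
  for (n in 2:12) {
    expect_identical(build_rotation_code_table(n)$n_labels,
                     as.integer(necklace_count(n)))
  }
})

test_that("codes are constant on rotation orbits (exhaustive, N <= 10)", {
  for (n in c(4, 7, 8, 10)) {
    tab <- build_rotation_code_table(n)
    for (code in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(code)[1:n])
      base <- rotation_invariant_code(bits, tab)
      for (s in seq_len(n - 1)) {
        shifted <- bits[c((s + 1):n, 1:s)]
        expect_identical(rotation_invariant_code(shifted, tab), base)
      }
    }
  }
})

test_that("single set bits and degenerate inputs behave", {
  t8 <- build_rotation_code_table(8)
  one_bit <- rotation_invariant_code(c(1, rep(0, 7)), t8)
  expect_identical(one_bit, t8$label_of_raw[2])  # minimized code 1
  for (pos in 2:8) {
    bits <- rep(0, 8); bits[pos] <- 1
    expect_identical(rotation_invariant_code(bits, t8), one_bit)
  }
  expect_identical(rotation_invariant_code(rep(0, 8), t8), 0L)
  expect_error(rotation_invariant_code(c(0, 1), t8),
               class = "qdcp_invalid_input")
  expect_error(rotation_invariant_code(c(rep(0, 7), 2), t8),
               class = "qdcp_invalid_input")
})

test_that("table agrees with the independent rotation oracle", {
  for (n in c(4, 8)) {
    tab <- build_rotation_code_table(n)
    expect_identical(tab$label_of_raw, oracle_label_map(n))
  }
})
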