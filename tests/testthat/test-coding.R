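test_that("preferred lattices cover twice the definition range, endpoints included", {
  gv <- visual_grid()
  expect_equal(nrow(gv$preferred), 200)
  expect_equal(range(gv$preferred[, "distance"]), c(-1.5, 4.5))
  expect_equal(range(gv$preferred[, "azimuth"]), c(-180, 180))
  expect_equal(length(unique(gv$preferred[, "distance"])), 10)
  expect_equal(length(unique(gv$preferred[, "azimuth"])), 20)

  gm <- motor_grid()
  expect_equal(nrow(gm$preferred), 100)
  expect_equal(range(gm$preferred), c(-40, 40))
  # regular spacing
  expect_equal(diff(gm$axes$d_alpha), rep(80 / 9, 9))

  g <- build_grid(rbind(c(0, 1), c(0, 1)), c(2, 2), c(1, 1))
  expect_equal(sort(unique(g$preferred[, 1])), c(-0.5, 1.5))
  expect_equal(nrow(g$preferred), 4)

  expect_error(build_grid(rbind(c(1, 0), c(0, 1)), c(2, 2), c(1, 1)), "range")
  expect_error(build_grid(rbind(c(0, 1), c(0, 1)), c(1, 2), c(1, 1)), "n_per_dim")
  expect_error(build_grid(rbind(c(0, 1), c(0, 1)), c(2, 2), c(0, 1)), "half_width")
})

test_that("cosine tuning: peak 1 at the preferred vector, cos fall-off, hard zero", {
  g <- visual_grid()
  i <- 87
  v <- g$preferred[i, ]
  a <- encode(v, g)
  expect_equal(a[i], 1)
  expect_equal(max(a), 1)
  expect_true(all(a >= 0 & a <= 1))

  # 45-degree azimuth offset with the 90-degree half-width: cos(45 deg)
  a <- encode(v + c(0, 45), g)
  expect_equal(a[i], cos(pi / 4), tolerance = 1e-12)

  # beyond the half-width in either dimension the unit is silent
  a <- encode(v + c(1.6, 0), g)
  expect_equal(a[i], 0)
  a <- encode(v + c(0, 95), g)
  expect_equal(a[i], 0)

  # any in-range input activates at least one unit (spacing < half-width)
  set.seed(31)
  for (k in 1:50) {
    v <- c(runif(1, 0, 3), runif(1, -90, 90))
    expect_gt(sum(encode(v, g)), 0)
  }
})

test_that("encoding is equivariant under azimuth reflection", {
  g <- visual_grid()
  # index permutation that flips the azimuth axis (lattice is symmetric)
  n1 <- g$n_per_dim[1]; n2 <- g$n_per_dim[2]
  flip <- as.vector(outer(seq_len(n1), rev(seq_len(n2)) - 1L,
                          function(i, j) i + j * n1))
  set.seed(32)
  for (k in 1:20) {
    v <- c(runif(1, 0, 3), runif(1, -90, 90))
    a <- encode(v, g)
    b <- encode(c(v[1], -v[2]), g)
    expect_equal(b, a[flip], tolerance = 1e-12)
  }
})

test_that("population-vector decoding inverts encoding on the range interior", {
  # degenerate and symmetric populations
  g <- motor_grid()
  a <- numeric(100); a[37] <- 0.4
  expect_equal(unname(decode(a, g)), unname(g$preferred[37, ]))
  expect_equal(unname(decode(rep(1, 100), g)), c(0, 0))  # lattice centroid
  expect_error(decode(numeric(100), g), "all-zero")

  # round trip: error below half a lattice spacing on an interior 9x9 lattice
  for (g in list(motor_grid(), visual_grid())) {
    half_spacing <- vapply(g$axes, function(ax) diff(ax[1:2]) / 2, numeric(1))
    lat <- lapply(1:2, function(d) {
      seq(g$range[d, 1], g$range[d, 2], length.out = 11)[2:10]
    })
    worst <- c(0, 0)
    for (v1 in lat[[1]]) for (v2 in lat[[2]]) {
      err <- abs(decode(encode(c(v1, v2), g), g) - c(v1, v2))
      worst <- pmax(worst, err)
    }
    expect_true(all(worst < half_spacing))
  }
})

test_that("out-of-range preferred units suppress edge bias in the readout", {
  g_doubled <- visual_grid()
  # control grid whose lattice spans only the definition range itself
  g_plain <- build_grid(rbind(c(0.75, 2.25), c(-45, 45)), c(10, 20),
                        half_width = c(1.5, 90),
                        dim_names = c("distance", "azimuth"))
  spacing_az <- diff(g_doubled$axes$azimuth[1:2])
  for (v in list(c(1, 90), c(1, -90), c(2, 90))) {
    bias_doubled <- abs(decode(encode(v, g_doubled), g_doubled)[2] - v[2])
    bias_plain <- abs(decode(encode(v, g_plain), g_plain)[2] - v[2])
    expect_lt(bias_doubled, spacing_az)     # within one lattice spacing
    expect_lt(bias_doubled, bias_plain)     # the doubling is what buys it
  }
})
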