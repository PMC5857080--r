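sep_concave <- function() {
  # Y = 10 - x1^2 - x2^2
  quad_surface(c(10, 0, 0, -1, -1, 0), k = 2)
}

test_that("stationary_point solves and classifies simple surfaces", {
  s <- stationary_point(sep_concave())
  expect_equal(s$point, c(0, 0))
  expect_equal(s$value, 10)
  expect_equal(s$nature, "maximum")

  saddle <- quad_surface(c(0, 0, 0, 1, -1, 0), k = 2)
  expect_equal(stationary_point(saddle)$nature, "saddle")

  bowl <- quad_surface(c(0, 0, 0, 1, 1, 0), k = 2)
  expect_equal(stationary_point(bowl)$nature, "minimum")

  flat <- quad_surface(c(0, 1, 1, 0, 0, 0), k = 2)
  expect_error(stationary_point(flat), "singular")
})

test_that("interior optimum of a separable concave quadratic is the closed form", {
  # Y = 5 + 2 x1 - 3 x2 - x1^2 - 2 x2^2: argmax at (-b_i / 2 b_ii)
  f <- quad_surface(c(5, 2, -3, -1, -2, 0), k = 2)
  opt <- maximize_box(f, lo = -1, hi = 1)
  expect_equal(opt$argmax_coded, c(2 / 2, -3 / 4))
  expect_equal(opt$y_max, predict(f, c(1, -0.75)))
  expect_equal(unname(opt$on_boundary), c(TRUE, FALSE))
})

test_that("maximize_box matches dense grid + coordinate ascent on random surfaces", {
  for (seed in 1:8) {
    k <- sample(2:4, 1)
    f <- random_concave_fit(k, seed = seed * 13)
    opt <- maximize_box(f, lo = -1, hi = 1)
    oracle <- grid_polish_max(f, lo = -1, hi = 1)
    expect_equal(opt$y_max, oracle$value, tolerance = 1e-6,
                 label = sprintf("seed %d (k=%d)", seed, k))
    expect_true(opt$y_max >= oracle$value - 1e-8)
  }
})

test_that("enlarging the box never decreases the maximum", {
  for (seed in 1:5) {
    f <- random_concave_fit(4, seed = seed + 50)
    y1 <- maximize_box(f, -1, 1)$y_max
    y2 <- maximize_box(f, -2, 2)$y_max
    expect_gte(y2, y1 - 1e-10)
  }
})

test_that("interior stationary maximum is returned exactly", {
  f <- sep_concave()
  opt <- maximize_box(f, lo = -2, hi = 2)
  expect_equal(opt$argmax_coded, c(0, 0))
  expect_equal(opt$y_max, 10)
  expect_false(any(opt$on_boundary))
})

test_that("desirability ramp has the documented boundary behaviour", {
  expect_equal(desirability_max(100, 0, 100), 1)
  expect_equal(desirability_max(150, 0, 100), 1)
  expect_equal(desirability_max(0, 0, 100), 0)
  expect_equal(desirability_max(-5, 0, 100), 0)
  expect_equal(desirability_max(36.33, 0, 100), 0.3633)
  expect_error(desirability_max(1, 10, 10), "target > low")
})

test_that("surface_grid is consistent with predict()", {
  fx <- adl15()
  fit <- fit_quadratic(fx$design, fx$y)
  g <- surface_grid(fit, 3, 4, resolution = 3, range = c(-2, 2))
  expect_equal(nrow(g), 9)
  centre <- g[g$x_i == 0 & g$x_j == 0, ]
  expect_equal(centre$y_hat, fit$beta0)
  pts <- matrix(0, nrow(g), 4)
  pts[, 3] <- g$x_i; pts[, 4] <- g$x_j
  expect_equal(g$y_hat, predict(fit, pts))
  expect_error(surface_grid(fit, 2, 2), "differ")
})

test_that("lower NaCl raises predicted mineralisation on the diesel/NaCl surface", {
  fx <- adl15()
  fit <- fit_quadratic(fx$design, fx$y)
  g <- surface_grid(fit, 3, 4, resolution = 41)
  best <- g[which.max(g$y_hat), ]
  expect_lt(best$x_j, 0)   # x_j is the NaCl axis
})
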