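test_that("coded/actual mapping matches the factor coding geometry", {
  ph <- factor_def("pH", "", 7.25, 0.75)
  nacl <- factor_def("nacl", "% w/v", 1.0, 1.0, clamp_floor = 0)
  diesel <- factor_def("diesel", "% v/v", 2.5, 1.5, clamp_floor = 0)

  expect_equal(code_level(ph, 8.75), 2)
  expect_equal(code_level(ph, 7.25), 0)
  expect_equal(code_level(nacl, -1.00), -2)

  expect_equal(decode_level(diesel, -2), -0.5)
  expect_equal(decode_level(diesel, -2, for_bench = TRUE), 0)
  expect_equal(decode_level(ph, code_level(ph, 7.8)), 7.8)

  expect_error(factor_def("x", "", 1, 0), "step")
})

test_that("coding round-trips over random coded levels and factors", {
  set.seed(11)
  for (i in 1:25) {
    f <- factor_def("f", "", center = rnorm(1, 5, 3), step = runif(1, 0.1, 5))
    coded <- runif(7, -3, 3)
    expect_equal(code_level(f, decode_level(f, coded)), coded)
  }
})

test_that("make_ccd produces the factorial/axial/centre structure", {
  d <- make_ccd(default_factors(), alpha = 2, n_center = 6)
  expect_equal(n_runs(d), 30)
  expect_equal(unname(table(d$role)[c("factorial", "axial", "center")]),
               c(16L, 8L, 6L), ignore_attr = TRUE)
  expect_true(all(d$coded[d$role == "center", ] == 0))
  # every non-centre column sums to 0; sum of squares = 2^k + 2 alpha^2
  non_centre <- d$coded[d$role != "center", ]
  expect_equal(unname(colSums(non_centre)), rep(0, 4))
  expect_equal(unname(colSums(non_centre^2)), rep(16 + 2 * 4, 4))

  d2 <- make_ccd(default_factors()[1:2], alpha = 1, n_center = 1)
  expect_equal(n_runs(d2), 9)
  expect_true(all(d2$coded %in% c(-1, 0, 1)))

  expect_error(make_ccd(default_factors()[1], alpha = 2), "2 factors")
})

test_that("CCD coded columns are orthogonal to each other and to interactions", {
  d <- make_ccd(default_factors(), alpha = 2, n_center = 6)
  x <- d$coded
  pairs <- combn(4, 2)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    expect_equal(sum(x[, i] * x[, j]), 0)
    for (l in 1:4) expect_equal(sum(x[, l] * x[, i] * x[, j]), 0)
  }
})

test_that("Plackett-Burman designs are balanced and orthogonal", {
  f <- default_factors()
  for (nr in c(8, 12, 16, 20)) {
    d <- make_plackett_burman(f, n_runs = nr)
    full <- cbind(d$coded, d$dummy)
    expect_equal(ncol(full), nr - 1)
    expect_equal(unname(colSums(full)), rep(0, nr - 1))
    # X'X = n I over the +/-1 columns
    expect_equal(unname(crossprod(full)), diag(nr, nr - 1), ignore_attr = TRUE)
  }
  expect_error(make_plackett_burman(f, n_runs = 9), "8, 12, 16, 20")
  expect_error(make_plackett_burman(rep(f, 3), n_runs = 8), "too many factors")
})

test_that("pb_effects estimates contrasts and flags significance", {
  d <- make_plackett_burman(default_factors(), n_runs = 12)

  eff0 <- pb_effects(d, rep(5, 12))
  expect_equal(eff0$effect, rep(0, 4))
  expect_false(any(eff0$significant))

  y_lin <- 3 * d$coded[, 1]
  eff1 <- pb_effects(d, y_lin)
  expect_equal(eff1$effect[1], 6)
  expect_equal(eff1$effect[-1], rep(0, 3))

  # seeded random response: effects equal the brute-force contrast 2 x'y / n
  set.seed(42)
  y <- rnorm(12, 10, 2)
  eff <- pb_effects(d, y)
  oracle <- as.numeric(2 * crossprod(d$coded, y) / 12)
  expect_equal(eff$effect, oracle)
  pse_oracle <- sqrt(mean((2 * crossprod(d$dummy, y) / 12)^2))
  expect_equal(attr(eff, "pse"), pse_oracle)

  expect_error(pb_effects(d, y[1:5]), "does not match")
  expect_error(pb_effects(make_ccd(default_factors()), rep(1, 30)),
               "Plackett-Burman")
})

test_that("packaged table rows code to exact design levels", {
  for (name in c("table2_adl15", "table4_adl36")) {
    fx <- load_ccd_fixture(name)
    lv <- sort(unique(as.numeric(fx$design$coded)))
    expect_true(all(lv %in% c(-2, -1, 0, 1, 2)))
    expect_equal(unname(table(fx$design$role)[c("factorial", "axial", "center")]),
                 c(16L, 8L, 6L), ignore_attr = TRUE)
  }
})
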