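std_ladder <- function() {
  rt <- alkane_ladder()
  peak_table(rt, rep(1, length(rt)), names(rt), id = "std", kind = "standard")
}

test_that("be_percent implements the area-loss formula with unit behaviour", {
  expect_equal(be_percent(1, 1), 0)
  expect_equal(be_percent(0, 2.5), 100)
  expect_equal(be_percent(0.1625, 1.0), 83.75)
  expect_lt(be_percent(1.5, 1.0), 0)   # grown peak: negative, not clipped
  expect_error(be_percent(1, 0), "> 0")
  expect_error(be_percent(-1, 1), ">= 0")
})

test_that("be_percent is strictly decreasing in sample area and scale invariant", {
  a_s <- seq(0, 2, by = 0.25)
  be <- be_percent(a_s, 1.3)
  expect_true(all(diff(be) < 0))
  for (c_ in c(0.01, 1, 250)) {
    expect_equal(be_percent(c_ * 0.4, c_ * 1.6), be_percent(0.4, 1.6))
  }
})

test_that("match_ladder assigns labels by nearest retention time within tolerance", {
  std <- std_ladder()
  # exact-match peak inherits the label
  p <- peak_table(std$rt[std$label == "n-C12"], 5)
  expect_equal(match_ladder(p, std)$label, "n-C12")
  # peak 2 tolerances away stays unlabelled
  p2 <- peak_table(std$rt[1] + 0.1, 5)
  expect_true(is.na(match_ladder(p2, std, rt_tol = 0.05)$label))
  # equidistant pair: earlier peak wins, with a warning
  rt12 <- unname(std$rt[std$label == "n-C12"])
  p3 <- peak_table(c(rt12 - 0.02, rt12 + 0.02), c(1, 2))
  expect_warning(m3 <- match_ladder(p3, std), "equidistant")
  expect_equal(m3$label, c("n-C12", NA))
})

test_that("jittered 13-peak ladders are labelled completely and order-invariantly", {
  std <- std_ladder()
  set.seed(3)
  jitter <- runif(13, -0.02, 0.02)
  p <- peak_table(std$rt + jitter, runif(13, 0.5, 2))
  m <- match_ladder(p, std, rt_tol = 0.05)
  expect_equal(m$label, std$label)
  # permuting input peak order changes nothing (tables sort by rt)
  perm <- sample(13)
  p_perm <- peak_table(std$rt[perm] + jitter[perm], p$area[order(p$rt)][perm])
  expect_equal(match_ladder(p_perm, std, rt_tol = 0.05), m)
})

test_that("be_table recovers per-alkane reductions and pools totals", {
  std <- std_ladder()
  sim <- simulate_chromatograms(
    reductions = c("n-C12" = 0.8375, "n-C10" = 0.5), seed = 4
  )
  res <- be_table(sim$sample, sim$control, sim$standard)
  expect_equal(res$table$be_percent[res$table$alkane == "n-C12"], 83.75)
  expect_equal(res$table$be_percent[res$table$alkane == "n-C10"], 50)
  expect_equal(res$table$be_percent[res$table$alkane == "n-C8"], 0)
  expect_true(res$total_be_percent >= min(res$table$be_percent) &&
                res$total_be_percent <= max(res$table$be_percent))

  # identical tables: all zero
  res0 <- be_table(sim$control, sim$control, sim$standard)
  expect_equal(res0$table$be_percent, rep(0, 13))
  expect_equal(res0$total_be_percent, 0)

  # near-complete dodecane removal, as after optimised incubation
  sim2 <- simulate_chromatograms(reductions = c("n-C12" = 0.9989), seed = 5)
  res2 <- be_table(sim2$sample, sim2$control, sim2$standard)
  expect_equal(res2$table$be_percent[res2$table$alkane == "n-C12"], 99.89)
})

test_that("be_table handles missing and extra alkanes", {
  std <- std_ladder()
  ctrl <- peak_table(std$rt[1:3], c(1, 2, 3), std$label[1:3],
                     kind = "abiotic_control")
  # sample lost alkane 2 entirely and has a peak unknown to the control
  samp <- peak_table(c(std$rt[1], std$rt[3], std$rt[5]), c(0.5, 3, 9))
  expect_warning(res <- be_table(samp, ctrl, std), "not in control")
  expect_equal(res$table$alkane, std$label[1:3])
  expect_equal(res$table$be_percent, c(50, 100, 0))
  expect_equal(res$total_be_percent, 100 - 100 * 3.5 / 6)
})

test_that("peak_table enforces its invariants", {
  expect_error(peak_table(c(1, -2), c(1, 1)), ">= 0")
  expect_error(peak_table(c(1, 2), c(-1, 1)), ">= 0")
  expect_error(peak_table(c(1, 2), c(1, 1), c("a", "a")), "duplicate")
  p <- peak_table(c(3, 1, 2), c(30, 10, 20))
  expect_equal(p$rt, c(1, 2, 3))
  expect_equal(p$area, c(10, 20, 30))
})
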