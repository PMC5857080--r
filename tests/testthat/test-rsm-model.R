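test_that("model matrix has canonical structure", {
  d <- make_ccd(default_factors(), alpha = 2, n_center = 6)
  mm <- build_model_matrix(d)
  expect_equal(dim(mm), c(30, 15))
  expect_equal(colnames(mm), quadratic_terms(4))
  centre_row <- mm[which(d$role == "center")[1], ]
  expect_equal(unname(centre_row), c(1, rep(0, 14)))
  # axial point on the last axis at -2: squared column = 4, interactions 0
  ax <- which(d$role == "axial" & d$coded[, 4] == -2)
  expect_equal(unname(mm[ax, "D^2"]), 4)
  expect_equal(unname(mm[ax, c("AB", "AC", "AD", "BC", "BD", "CD")]), rep(0, 6))
})

test_that("noiseless quadratic data is recovered to machine precision", {
  truth <- random_concave_fit(4, seed = 7)
  sim <- simulate_ccd_response(truth$coef, noise_sd = 0, seed = 1)
  fit <- fit_quadratic(sim$design, sim$y)
  expect_equal(unname(fit$coef), unname(truth$coef), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("fit_quadratic validates its inputs", {
  fx <- adl15()
  expect_error(fit_quadratic(fx$design, fx$y[1:10]), "does not match")
  set.seed(2)
  d_small <- rsmbe:::new_design(default_factors()[1:2],
                                matrix(runif(10, -1, 1), 5, 2),
                                rep("custom", 5), "custom")
  expect_error(fit_quadratic(d_small, rnorm(5)), "n > p")
})

test_that("leverages and residuals satisfy the least-squares identities", {
  fx <- adl15()
  fit <- fit_quadratic(fx$design, fx$y)
  expect_equal(sum(fit$hat_diag), 15)           # trace(H) = p
  expect_equal(sum(fit$residuals), 0)           # intercept in model
  expect_equal(fit$df_resid, 15)
})

test_that("partial term SS equal brute-force reduced-model refits", {
  fx <- adl36()
  fit <- fit_quadratic(fx$design, fx$y)
  an <- anova_quadratic(fit)
  for (tm in an$rows$term) {
    expect_equal(an$rows$ss[an$rows$term == tm],
                 refit_term_ss(fx$design, fx$y, tm),
                 tolerance = 1e-8, label = paste("SS for", tm))
  }
})

test_that("ANOVA sums of squares are additive on both packaged tables", {
  for (load in list(adl15, adl36)) {
    fx <- load()
    an <- anova_quadratic(fit_quadratic(fx$design, fx$y))
    expect_equal(an$model_row$ss + an$residual_row$ss, an$cor_total_row$ss,
                 tolerance = 0.05)
    expect_equal(an$lack_of_fit_row$ss + an$pure_error_row$ss,
                 an$residual_row$ss, tolerance = 0.05)
    expect_equal(an$fit$pred_r2, 1 - an$fit$press / an$cor_total_row$ss)
    expect_equal(an$fit$r2, 1 - an$residual_row$ss / an$cor_total_row$ss)
  }
})

test_that("pure error from the six centre replicates matches direct computation", {
  fx <- adl15()
  an <- anova_quadratic(fit_quadratic(fx$design, fx$y))
  centre_y <- fx$y[fx$design$role == "center"]
  expect_equal(length(centre_y), 6)
  expect_equal(an$pure_error_row$ss, sum((centre_y - mean(centre_y))^2))
  expect_equal(an$pure_error_row$df, 5)
  # printed pure-error SS 24.98 reproduced within table rounding
  expect_equal(an$pure_error_row$ss, 24.98, tolerance = 0.05)
})

test_that("hat-diagonal PRESS equals explicit leave-one-out refits", {
  for (load in list(adl15, adl36)) {
    fx <- load()
    fit <- fit_quadratic(fx$design, fx$y)
    expect_equal(fit_summary(fit)$press, loo_press(fx$design, fx$y),
                 tolerance = 1e-10)
  }
  # and on random noisy designs
  for (seed in 1:5) {
    truth <- random_concave_fit(3, seed = seed)
    sim <- simulate_ccd_response(truth$coef,
                                 factors = default_factors()[1:3],
                                 noise_sd = 5, seed = seed + 100)
    fit <- fit_quadratic(sim$design, sim$y)
    expect_equal(fit_summary(fit)$press, loo_press(sim$design, sim$y),
                 tolerance = 1e-8)
  }
})

test_that("fit statistics follow their defining formulas", {
  fx <- adl36()
  fit <- fit_quadratic(fx$design, fx$y)
  s <- fit_summary(fit)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((fx$y - mean(fx$y))^2)
  expect_equal(s$std_dev, sqrt(ss_res / 15))
  expect_equal(s$cv_percent, 100 * s$std_dev / mean(fx$y))
  expect_equal(s$r2, 1 - ss_res / ss_tot)
  expect_equal(s$adj_r2, 1 - (ss_res / 15) / (ss_tot / 29))
  expect_equal(s$adeq_precision,
               (max(fit$fitted) - min(fit$fitted)) / sqrt(15 * fit$mse / 30))
})

test_that("quad_surface rebuilds a surface from published coefficients", {
  eq <- load_fixture("eq_adl36")
  surf <- quad_surface(eq)
  expect_equal(surf$k, 4)
  expect_equal(surf$beta0, 88.76)
  expect_equal(unname(predict(surf, rep(0, 4))), 88.76)
  expect_error(quad_surface(setNames(1:15, paste0("x", 1:15))), "names")
})
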