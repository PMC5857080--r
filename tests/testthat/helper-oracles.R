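# Independent brute-force oracles used to validate the closed-form /
# shortcut routes in the package.

# PRESS by explicit leave-one-out refitting: drop each run, refit the full
# quadratic, predict the held-out run.
loo_press <- function(design, y) {
  mm <- build_model_matrix(design)
  sum(vapply(seq_len(nrow(mm)), function(i) {
    f <- stats::lm.fit(mm[-i, , drop = FALSE], y[-i])
    (y[i] - sum(mm[i, ] * f$coefficients))^2
  }, numeric(1)))
}

# Partial SS of a term by refitting the model without it.
refit_term_ss <- function(design, y, term) {
  mm <- build_model_matrix(design)
  full <- sum(stats::lm.fit(mm, y)$residuals^2)
  red <- sum(stats::lm.fit(mm[, setdiff(colnames(mm), term), drop = FALSE],
                           y)$residuals^2)
  red - full
}

# Dense-grid maximisation of a quadratic surface over a box, refined by
# coordinate ascent (1-D exact maximisation per axis until converged).
grid_polish_max <- function(fit, lo, hi, n_grid = 11, iters = 200) {
  k <- fit$k
  lo <- rep_len(lo, k); hi <- rep_len(hi, k)
  grids <- lapply(seq_len(k), function(j) seq(lo[j], hi[j], length.out = n_grid))
  pts <- as.matrix(expand.grid(grids))
  vals <- predict(fit, pts)
  x <- as.numeric(pts[which.max(vals), ])
  B <- rsmbe:::quad_B_matrix(fit)
  b <- as.numeric(fit$beta_lin)
  for (it in seq_len(iters)) {
    x_old <- x
    for (j in seq_len(k)) {
      # Y along axis j: quadratic a2*t^2 + a1*t + const
      a2 <- B[j, j]
      a1 <- b[j] + 2 * sum(B[j, -j] * x[-j])
      cand <- c(lo[j], hi[j])
      if (a2 < 0) cand <- c(cand, min(max(-a1 / (2 * a2), lo[j]), hi[j]))
      vals_j <- a2 * cand^2 + a1 * cand
      x[j] <- cand[which.max(vals_j)]
    }
    if (max(abs(x - x_old)) < 1e-12) break
  }
  list(point = x, value = predict(fit, x))
}

# Random concave quadratic surface (negative-definite quadratic form).
random_concave_fit <- function(k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  B <- -(crossprod(A) + diag(0.5, k))   # negative definite
  beta_quad <- diag(B)
  pairs <- utils::combn(k, 2)
  beta_int <- apply(pairs, 2, function(ij) 2 * B[ij[1], ij[2]])
  co <- c(rnorm(1, 20, 5), rnorm(k, 0, 2), beta_quad, beta_int)
  quad_surface(co, k = k)
}

adl15 <- function() load_ccd_fixture("table2_adl15")
adl36 <- function() load_ccd_fixture("table4_adl36")
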