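#' @title Optimisation of a fitted quadratic surface
#' @name optimize_surface
#' @description Canonical analysis and exact box-constrained maximisation
#'   of the fitted second-order polynomial, plus the single-response
#'   desirability transform and grid export for surface plots.
NULL

# Symmetric Hessian-like matrix B with beta_ii on the diagonal and
# beta_ij / 2 off-diagonal, so that Y = beta0 + b'x + x' B x.
quad_B_matrix <- function(fit) {
  k <- fit$k
  B <- diag(fit$beta_quad, k)
  pairs <- utils::combn(k, 2)
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    B[i, j] <- B[j, i] <- fit$beta_int[m] / 2
  }
  B
}

classify_hessian <- function(B, tol = 1e-10) {
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (all(ev < -tol)) "maximum"
  else if (all(ev > tol)) "minimum"
  else "saddle"
}

#' Stationary point of the fitted surface
#'
#' Solves the gradient system `b + 2 B x = 0` analytically and classifies
#' the stationary point from the eigenvalues of the quadratic-form matrix
#' `B` (negative definite: maximum; positive definite: minimum; mixed
#' signs: saddle).
#'
#' @param fit a `quad_fit`
#' @return list with `point` (coded k-vector), `value` (predicted
#'   response there) and `nature`
#' @export
stationary_point <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  B <- quad_B_matrix(fit)
  if (abs(det(B)) < 1e-12) {
    stop("singular quadratic form: no unique stationary point ",
         "(ridge analysis is out of scope)", call. = FALSE)
  }
  x <- as.numeric(solve(2 * B, -fit$beta_lin))
  list(point = x, value = predict(fit, x), nature = classify_hessian(B))
}

#' Exact maximisation of the quadratic over a coded box
#'
#' Maximises the fitted second-order polynomial over the box
#' `[lo, hi]^k` exactly: every one of the `3^k` face configurations (each
#' coordinate free, pinned at its lower bound, or pinned at its upper
#' bound) is enumerated, the reduced stationary system is solved on the
#' free coordinates, infeasible candidates are discarded, and the best
#' feasible candidate wins. The all-pinned configurations are the box
#' vertices, so the global box maximum is always among the candidates.
#' Ties are broken towards the smallest lexicographic coded coordinates.
#'
#' @param fit a `quad_fit`
#' @param lo,hi box bounds in coded units; scalars are recycled to
#'   k-vectors. Default `[-1, +1]^k`, the factorial cube.
#' @param desirability_low,desirability_target bounds of the
#'   "maximize"-goal desirability ramp applied to the optimum (default
#'   0 and 100, i.e. percent response)
#' @return an `optimum_result`: `argmax_coded`, `argmax_actual` (raw and
#'   bench-clamped, when the fit carries factor definitions), `y_max`,
#'   `nature` of the unconstrained stationary point (NA when singular),
#'   `on_boundary` flags, `desirability`
#' @export
maximize_box <- function(fit, lo = -1, hi = 1,
                         desirability_low = 0, desirability_target = 100) {
  stopifnot(inherits(fit, "quad_fit"))
  k <- fit$k
  lo <- rep_len(as.numeric(lo), k)
  hi <- rep_len(as.numeric(hi), k)
  if (!all(lo < hi)) stop("need lo < hi componentwise", call. = FALSE)
  B <- quad_B_matrix(fit)
  b <- as.numeric(fit$beta_lin)

  candidates <- list()
  states <- expand.grid(rep(list(0:2), k))  # 0 free, 1 at lo, 2 at hi
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    free <- which(st == 0L)
    x <- ifelse(st == 1L, lo, ifelse(st == 2L, hi, 0))
    if (length(free) > 0) {
      Bff <- B[free, free, drop = FALSE]
      if (abs(det(Bff)) < 1e-12) next  # flat direction: optimum found on faces
      fixed <- setdiff(seq_len(k), free)
      rhs <- -b[free]
      if (length(fixed) > 0) {
        rhs <- rhs - 2 * B[free, fixed, drop = FALSE] %*% x[fixed]
      }
      xf <- as.numeric(solve(2 * Bff, rhs))
      if (any(xf < lo[free] - 1e-9) || any(xf > hi[free] + 1e-9)) next
      x[free] <- pmin(pmax(xf, lo[free]), hi[free])
    }
    candidates[[length(candidates) + 1L]] <- x
  }
  X <- do.call(rbind, candidates)
  vals <- predict(fit, X)
  best <- max(vals)
  tied <- which(vals >= best - 1e-12)
  if (length(tied) > 1) {
    ord <- do.call(order, as.data.frame(X[tied, , drop = FALSE]))
    pick <- tied[ord[1]]
  } else pick <- tied
  x_best <- as.numeric(X[pick, ])
  y_max <- vals[pick]

  nature <- tryCatch(stationary_point(fit)$nature, error = function(e) NA_character_)
  actual_raw <- actual_bench <- NULL
  if (!is.null(fit$design)) {
    fs <- fit$design$factors
    actual_raw <- vapply(seq_len(k), function(j) decode_level(fs[[j]], x_best[j]),
                         numeric(1))
    actual_bench <- vapply(seq_len(k), function(j) {
      decode_level(fs[[j]], x_best[j], for_bench = TRUE)
    }, numeric(1))
    names(actual_raw) <- names(actual_bench) <- fit$factor_names
  }
  structure(
    list(
      argmax_coded = x_best,
      argmax_actual = actual_raw,
      argmax_actual_bench = actual_bench,
      y_max = y_max,
      nature = nature,
      on_boundary = x_best <= lo + 1e-9 | x_best >= hi - 1e-9,
      desirability = desirability_max(y_max, desirability_low,
                                      desirability_target),
      box = list(lo = lo, hi = hi)
    ),
    class = "optimum_result"
  )
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("Box-constrained optimum: y = %.2f (desirability %.4f)\n",
              x$y_max, x$desirability))
  cat("  coded:", paste(sprintf("%.3f", x$argmax_coded), collapse = ", "), "\n")
  if (!is.null(x$argmax_actual)) {
    cat("  actual:", paste(sprintf("%s=%.3f", names(x$argmax_actual),
                                   x$argmax_actual), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-response "maximize" desirability
#'
#' Linear ramp: 0 at or below `low`, 1 at or above `target`,
#' `(y - low) / (target - low)` between.
#'
#' @param y_pred predicted response value(s)
#' @param low response value of zero desirability
#' @param target response value of full desirability; must exceed `low`
#' @return desirability in `[0, 1]`
#' @export
desirability_max <- function(y_pred, low = 0, target = 100) {
  if (target <= low) stop("need target > low", call. = FALSE)
  pmin(1, pmax(0, (y_pred - low) / (target - low)))
}

#' Predicted-response grid over two factor axes
#'
#' Evaluates the fitted surface on a regular grid over two coded axes,
#' all remaining factors held at fixed coded values -- the numeric backing
#' of the usual 3D/contour interaction plots.
#'
#' @param fit a `quad_fit`
#' @param axis_i,axis_j factor indices (1-based, distinct)
#' @param fixed coded values of the other `k - 2` factors (default 0);
#'   either a length `k - 2` vector in index order or a full length-k
#'   vector whose `axis_i`/`axis_j` entries are ignored
#' @param range coded range of both axes (default `c(-2, 2)`)
#' @param resolution grid points per axis (default 41)
#' @return data frame with coded coordinates `x_i`, `x_j` and `y_hat`
#' @export
surface_grid <- function(fit, axis_i, axis_j, fixed = 0, range = c(-2, 2),
                         resolution = 41) {
  stopifnot(inherits(fit, "quad_fit"))
  k <- fit$k
  if (axis_i == axis_j) stop("axis_i and axis_j must differ", call. = FALSE)
  others <- setdiff(seq_len(k), c(axis_i, axis_j))
  base <- numeric(k)
  if (length(fixed) == k) base <- as.numeric(fixed)
  else base[others] <- rep_len(as.numeric(fixed), length(others))
  s <- seq(range[1], range[2], length.out = resolution)
  g <- expand.grid(x_i = s, x_j = s)
  pts <- matrix(rep(base, each = nrow(g)), nrow = nrow(g))
  pts[, axis_i] <- g$x_i
  pts[, axis_j] <- g$x_j
  g$y_hat <- predict(fit, pts)
  attr(g, "axes") <- c(axis_i, axis_j)
  g
}
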