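#' @title Second-order response-surface model in coded units
#' @name rsm_model
#' @description Ordinary least squares fit of the full quadratic
#'   polynomial
#'   \deqn{Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'         \sum_{i<j} \beta_{ij} x_i x_j}
#'   to a designed experiment, in coded factor units, together with the
#'   partial-SS ANOVA, lack-of-fit partition and prediction diagnostics
#'   (PRESS, predicted R-squared, adequate precision) customary in
#'   response-surface work.
NULL

# Canonical term labels A, B, C, ... for up to 26 factors.
term_letters <- function(k) LETTERS[seq_len(k)]

#' Canonical quadratic term labels
#'
#' Order: intercept, linear (A, B, ...), squared (A^2, ...), two-way
#' interactions in lexicographic order (AB, AC, AD, BC, BD, CD for k = 4).
#'
#' @param k number of factors
#' @return character vector of length `1 + 2k + k(k-1)/2`
#' @export
quadratic_terms <- function(k) {
  stopifnot(k >= 2)
  lt <- term_letters(k)
  pairs <- utils::combn(k, 2)
  c("(Intercept)", lt, paste0(lt, "^2"),
    apply(pairs, 2, function(ij) paste0(lt[ij[1]], lt[ij[2]])))
}

#' Build the coded quadratic model matrix
#'
#' @param design an `rsm_design`, or a numeric matrix of coded levels
#' @return an `n x p` matrix with `p = 1 + 2k + k(k-1)/2`; columns in
#'   canonical order ([quadratic_terms()])
#' @export
build_model_matrix <- function(design) {
  x <- if (inherits(design, "rsm_design")) design$coded else as.matrix(design)
  k <- ncol(x)
  stopifnot(k >= 2)
  pairs <- utils::combn(k, 2)
  inter <- apply(pairs, 2, function(ij) x[, ij[1]] * x[, ij[2]])
  if (is.null(dim(inter))) inter <- matrix(inter, nrow = nrow(x))
  mm <- cbind(1, x, x^2, inter)
  colnames(mm) <- quadratic_terms(k)
  mm
}

#' Fit the second-order model by ordinary least squares
#'
#' Regression is always performed on the planned coded levels (never on
#' bench-clamped actual values), so the coefficients are directly
#' comparable across factors and the axial runs retain their -2/+2
#' leverage.
#'
#' @param design an `rsm_design`
#' @param y numeric response vector (one value per run), or a data frame
#'   holding a `response` column
#' @param response column name when `y` is a data frame
#' @return an object of class `quad_fit`: coefficients split into
#'   `beta0`, `beta_lin`, `beta_quad`, `beta_int` (plus the full named
#'   vector in `$coef`), residuals, hat diagonals, `mse`, `df_resid`
#' @export
fit_quadratic <- function(design, y, response = "experimental") {
  stopifnot(inherits(design, "rsm_design"))
  if (is.data.frame(y)) {
    if (!response %in% names(y)) {
      stop("response column '", response, "' not found", call. = FALSE)
    }
    y <- y[[response]]
  }
  y <- as.numeric(y)
  n <- nrow(design$coded)
  if (length(y) != n) {
    stop("response length ", length(y), " does not match ", n, " runs",
         call. = FALSE)
  }
  if (!all(is.finite(y))) stop("responses must be finite", call. = FALSE)
  mm <- build_model_matrix(design)
  p <- ncol(mm)
  if (n <= p) {
    stop("cannot fit ", p, " terms to ", n, " runs (need n > p)", call. = FALSE)
  }
  qrx <- qr(mm)
  if (qrx$rank < p) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):p]]
    stop("model matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(mm, y)
  coefs <- fit$coefficients
  resid <- fit$residuals
  hat <- rowSums(qr.Q(qrx)[, seq_len(p), drop = FALSE]^2)
  df_resid <- n - p
  mse <- sum(resid^2) / df_resid
  k <- ncol(design$coded)
  lt <- term_letters(k)
  structure(
    list(
      k = k, terms = colnames(mm),
      coef = coefs,
      beta0 = unname(coefs[1]),
      beta_lin = stats::setNames(unname(coefs[1 + seq_len(k)]), lt),
      beta_quad = stats::setNames(unname(coefs[1 + k + seq_len(k)]),
                                  paste0(lt, "^2")),
      beta_int = coefs[(2 + 2 * k - 1 + 1):length(coefs)],
      fitted = as.numeric(mm %*% coefs),
      residuals = as.numeric(resid),
      hat_diag = as.numeric(hat),
      mse = mse, df_resid = df_resid, n = n,
      design = design, y = y,
      factor_names = colnames(design$coded)
    ),
    class = "quad_fit"
  )
}

#' Construct a `quad_fit` from known coefficients
#'
#' Builds the coefficient surface directly (no data), e.g. from a
#' published regression equation, so that prediction and optimisation can
#' be run on it. Residual diagnostics are absent.
#'
#' @param coef named numeric vector in canonical term order (names as
#'   [quadratic_terms()]), or a data frame with `term` and `coefficient`
#' @param k number of factors (inferred from length when missing)
#' @param factor_names optional factor names for decoding optima
#' @return a `quad_fit` with NULL data slots
#' @export
quad_surface <- function(coef, k = NULL, factor_names = NULL) {
  if (is.data.frame(coef)) coef <- stats::setNames(coef$coefficient, coef$term)
  p <- length(coef)
  if (is.null(k)) {
    # p = 1 + 2k + k(k-1)/2  =>  k = (-3 + sqrt(9 + 8(p-1))) / 2
    k <- round((-3 + sqrt(9 + 8 * (p - 1))) / 2)
  }
  stopifnot(p == 1 + 2 * k + k * (k - 1) / 2)
  want <- quadratic_terms(k)
  if (!is.null(names(coef))) {
    if (!all(want %in% names(coef))) {
      stop("coefficient names must cover: ", paste(want, collapse = ", "),
           call. = FALSE)
    }
    coef <- coef[want]
  } else {
    names(coef) <- want
  }
  lt <- term_letters(k)
  structure(
    list(
      k = k, terms = want, coef = coef,
      beta0 = unname(coef[1]),
      beta_lin = stats::setNames(unname(coef[1 + seq_len(k)]), lt),
      beta_quad = stats::setNames(unname(coef[1 + k + seq_len(k)]),
                                  paste0(lt, "^2")),
      beta_int = coef[(2 * k + 2):p],
      fitted = NULL, residuals = NULL, hat_diag = NULL,
      mse = NA_real_, df_resid = NA_integer_, n = NA_integer_,
      design = NULL, y = NULL,
      factor_names = factor_names
    ),
    class = "quad_fit"
  )
}

#' @export
print.quad_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Second-order model in coded units (%d factors, %d terms)\n",
              x$k, length(x$coef)))
  print(round(x$coef, digits))
  if (!is.null(x$residuals)) {
    cat(sprintf("Residual SD %.2f on %d df\n", sqrt(x$mse), x$df_resid))
  }
  invisible(x)
}

#' Predict from a fitted quadratic surface
#'
#' @param object a `quad_fit`
#' @param coded_points matrix (or vector for one point) of coded levels,
#'   one row per point, `k` columns; defaults to the design points
#' @param ... unused
#' @return numeric vector of predicted responses
#' @export
predict.quad_fit <- function(object, coded_points = NULL, ...) {
  if (is.null(coded_points)) {
    if (is.null(object$design)) stop("no design stored; supply coded_points",
                                     call. = FALSE)
    coded_points <- object$design$coded
  }
  if (is.null(dim(coded_points))) coded_points <- matrix(coded_points, nrow = 1)
  coded_points <- as.matrix(coded_points)
  if (ncol(coded_points) != object$k) {
    stop("points have ", ncol(coded_points), " columns; model has ",
         object$k, " factors", call. = FALSE)
  }
  as.numeric(build_model_matrix(coded_points) %*% object$coef)
}
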