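format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p)))
}

# Residual SS of the model with one named column dropped; used for the
# extra-sum-of-squares (partial, Type-III-style) term SS.
drop_term_rss <- function(mm, y, term) {
  keep <- setdiff(colnames(mm), term)
  f <- stats::lm.fit(mm[, keep, drop = FALSE], y)
  sum(f$residuals^2)
}

# Replicate groups = runs with identical coded rows (tolerance 1e-9).
replicate_groups <- function(coded, tol = 1e-9) {
  key <- apply(round(coded / tol) * tol, 1, paste, collapse = "|")
  split(seq_len(nrow(coded)), key)
}

#' ANOVA for a fitted second-order model
#'
#' Produces the full response-surface ANOVA: per-term partial sums of
#' squares (extra SS -- the increase in residual SS when that single term
#' is dropped from the otherwise full model), the model row, residual row,
#' and a lack-of-fit / pure-error partition based on replicated design
#' points (runs with identical coded rows, e.g. the six centre
#' replicates). Each F statistic divides the term mean square by the
#' residual mean square; the lack-of-fit F uses the pure-error mean
#' square. Terms are flagged significant at `p < alpha`.
#'
#' @param fit a `quad_fit` from [fit_quadratic()]
#' @param alpha significance level (default 0.05)
#' @return an object of class `anova_report`: `$rows` (per-term data
#'   frame: term, ss, df, ms, f, p, significant), `$model_row`,
#'   `$residual_row`, `$lack_of_fit_row`, `$pure_error_row`,
#'   `$cor_total_row`, and `$fit` -- the fit-statistics block of
#'   [fit_summary()]
#' @export
anova_quadratic <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "quad_fit"))
  if (is.null(fit$design)) stop("fit carries no data; ANOVA needs a fitted model",
                                call. = FALSE)
  y <- fit$y
  n <- fit$n
  mm <- build_model_matrix(fit$design)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_model <- ss_tot - ss_res
  df_model <- length(fit$coef) - 1L
  ms_res <- fit$mse

  terms <- setdiff(fit$terms, "(Intercept)")
  ss_term <- vapply(terms, function(tm) drop_term_rss(mm, y, tm) - ss_res,
                    numeric(1))
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, fit$df_resid, lower.tail = FALSE)
  rows <- data.frame(
    term = terms, ss = unname(ss_term), df = 1L, ms = unname(ss_term),
    f = unname(f_term), p = unname(p_term),
    significant = unname(p_term < alpha), row.names = NULL
  )

  f_model <- (ss_model / df_model) / ms_res
  model_row <- list(term = "Model", ss = ss_model, df = df_model,
                    ms = ss_model / df_model, f = f_model,
                    p = stats::pf(f_model, df_model, fit$df_resid, lower.tail = FALSE))
  residual_row <- list(term = "Residual", ss = ss_res, df = fit$df_resid,
                       ms = ms_res, f = NA_real_, p = NA_real_)
  cor_total_row <- list(term = "Cor total", ss = ss_tot, df = n - 1L,
                        ms = NA_real_, f = NA_real_, p = NA_real_)

  groups <- replicate_groups(fit$design$coded)
  df_pe <- sum(vapply(groups, length, integer(1)) - 1L)
  lof_row <- pe_row <- NULL
  if (df_pe > 0) {
    ss_pe <- sum(vapply(groups, function(idx) {
      sum((y[idx] - mean(y[idx]))^2)
    }, numeric(1)))
    ss_lof <- ss_res - ss_pe
    df_lof <- fit$df_resid - df_pe
    ms_pe <- ss_pe / df_pe
    ms_lof <- ss_lof / df_lof
    f_lof <- ms_lof / ms_pe
    lof_row <- list(term = "Lack of fit", ss = ss_lof, df = df_lof,
                    ms = ms_lof, f = f_lof,
                    p = stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE))
    pe_row <- list(term = "Pure error", ss = ss_pe, df = df_pe, ms = ms_pe,
                   f = NA_real_, p = NA_real_)
  } else {
    warning("no replicated design points: lack-of-fit rows omitted")
  }

  structure(
    list(rows = rows, model_row = model_row, residual_row = residual_row,
         lack_of_fit_row = lof_row, pure_error_row = pe_row,
         cor_total_row = cor_total_row, alpha = alpha,
         fit = fit_summary(fit)),
    class = "anova_report"
  )
}

#' Global fit statistics for a second-order model
#'
#' Returns the statistics block customary below a response-surface ANOVA:
#' \itemize{
#'   \item `std_dev`: residual standard deviation, `sqrt(MSE)`
#'   \item `mean`: response mean; `cv_percent = 100 * std_dev / mean`
#'   \item `r2`, `adj_r2`: coefficient of determination and its
#'     df-adjusted version
#'   \item `press`: prediction error sum of squares,
#'     `sum((e_i / (1 - h_ii))^2)` -- algebraically equal to explicit
#'     leave-one-out refitting
#'   \item `pred_r2 = 1 - PRESS / SS_total`
#'   \item `adeq_precision`: signal-to-noise ratio,
#'     `(max yhat - min yhat over the design) / sqrt(p * MSE / n)`
#' }
#'
#' @param fit a `quad_fit`
#' @return list of the statistics above
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  if (is.null(fit$residuals)) stop("fit carries no data", call. = FALSE)
  y <- fit$y
  n <- fit$n
  p <- length(fit$coef)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  press <- NA_real_
  if (any(fit$hat_diag >= 1 - 1e-12)) {
    warning("a leverage of 1 makes PRESS undefined; reported as NA")
  } else {
    press <- sum((fit$residuals / (1 - fit$hat_diag))^2)
  }
  list(
    std_dev = sqrt(fit$mse),
    mean = mean(y),
    cv_percent = 100 * sqrt(fit$mse) / mean(y),
    r2 = 1 - ss_res / ss_tot,
    adj_r2 = 1 - (ss_res / fit$df_resid) / (ss_tot / (n - 1)),
    press = press,
    pred_r2 = if (is.na(press)) NA_real_ else 1 - press / ss_tot,
    adeq_precision = (max(fit$fitted) - min(fit$fitted)) /
      sqrt(p * fit$mse / n)
  )
}

#' @export
print.anova_report <- function(x, ...) {
  cat(format_anova_text(x), sep = "\n")
  invisible(x)
}

# Render the report as an aligned text table mirroring the usual layout:
# Source / SS / df / MS / F / p with significance marks ("*" significant,
# "**" not significant).
format_anova_text <- function(report) {
  stopifnot(inherits(report, "anova_report"))
  mark <- function(p) {
    ifelse(is.na(p), "", ifelse(p < report$alpha, "*", "**"))
  }
  row_line <- function(r) {
    sprintf("%-12s %12.2f %4d %12.2f %8s %10s %s",
            r$term, r$ss, r$df,
            if (is.na(r$ms)) NA else r$ms,
            if (is.na(r$f)) "" else sprintf("%.2f", r$f),
            format_p(r$p), mark(r$p))
  }
  hdr <- sprintf("%-12s %12s %4s %12s %8s %10s", "Source", "Sum sq", "df",
                 "Mean sq", "F", "p")
  body <- c(row_line(report$model_row),
            vapply(seq_len(nrow(report$rows)), function(i) {
              row_line(as.list(report$rows[i, ]))
            }, character(1)),
            row_line(report$residual_row))
  if (!is.null(report$lack_of_fit_row)) {
    body <- c(body, row_line(report$lack_of_fit_row),
              row_line(report$pure_error_row))
  }
  body <- c(body, row_line(report$cor_total_row))
  fs <- report$fit
  footer <- c(
    sprintf("Standard deviation %8.2f    R-squared      %.4f", fs$std_dev, fs$r2),
    sprintf("Mean               %8.2f    Adj R-squared  %.4f", fs$mean, fs$adj_r2),
    sprintf("C.V. %%            %8.2f    Pred R-squared %.4f", fs$cv_percent, fs$pred_r2),
    sprintf("PRESS              %8.2f    Adeq precision %.3f", fs$press, fs$adeq_precision)
  )
  c(hdr, body, "", footer)
}
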