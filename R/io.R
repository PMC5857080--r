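#' @title CSV / JSON interchange for designs and reports
#' @name cli_io
NULL

# Tables copied from print sources carry U+2212 (minus sign) instead of
# ASCII hyphen-minus; normalise before numeric parsing.
normalize_minus <- function(x) gsub("\u2212", "-", x)

parse_numeric_col <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(normalize_minus(trimws(as.character(x)))))
  bad <- which(is.na(v) & !(is.na(x) | trimws(as.character(x)) == ""))
  if (length(bad) > 0) {
    stop("non-numeric value in column '", col, "', row ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  v
}

#' Write a design (and optional response) to CSV
#'
#' One row per run with columns `run_order`, `role`, `<name>_coded` and
#' `<name>_actual` per factor, plus any response columns supplied.
#'
#' @param design an `rsm_design`
#' @param path output CSV path
#' @param responses optional named list / data frame of response columns
#' @return the written data frame, invisibly
#' @export
write_design_csv <- function(design, path, responses = NULL) {
  stopifnot(inherits(design, "rsm_design"))
  df <- data.frame(run_order = design$run_order, role = design$role)
  for (nm in colnames(design$coded)) {
    df[[paste0(nm, "_coded")]] <- design$coded[, nm]
    df[[paste0(nm, "_actual")]] <- design$actual[, nm]
  }
  if (!is.null(responses)) df <- cbind(df, as.data.frame(responses))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a design CSV
#'
#' Parses a CSV in the layout written by [write_design_csv()] (or with
#' only `<name>_actual` columns, in which case coded levels are derived
#' from the factor definitions). When both coded and actual columns are
#' present their consistency under the factor mapping is validated to
#' 1e-6, with row-level error messages. Unicode minus signs are
#' normalised. Actual values outside the +/-2 coded range are retained
#' with a warning.
#'
#' @param path CSV path
#' @param factors named list of [factor_def()]; default the packaged set
#' @param response optional name of a response column to extract
#' @return list with `design` (`rsm_design`, kind `"custom"` unless the
#'   role column identifies a CCD) and `y` (response or NULL)
#' @export
read_design_csv <- function(path, factors = default_factors(),
                            response = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("no runs in ", path, call. = FALSE)
  k <- length(factors)
  fnames <- vapply(factors, `[[`, character(1), "name")
  coded <- actual <- matrix(NA_real_, nrow(df), k)
  for (j in seq_len(k)) {
    ac <- paste0(fnames[j], "_actual")
    cc <- paste0(fnames[j], "_coded")
    if (!ac %in% names(df) && !cc %in% names(df)) {
      stop("missing column '", ac, "' (or '", cc, "') in ", path, call. = FALSE)
    }
    if (ac %in% names(df)) actual[, j] <- parse_numeric_col(df[[ac]], ac, path)
    if (cc %in% names(df)) coded[, j] <- parse_numeric_col(df[[cc]], cc, path)
    if (ac %in% names(df) && cc %in% names(df)) {
      mism <- which(abs(code_level(factors[[j]], actual[, j]) - coded[, j]) > 1e-6)
      if (length(mism) > 0) {
        stop("coded/actual inconsistency for factor '", fnames[j],
             "' in rows ", paste(mism, collapse = ", "), " of ", path,
             call. = FALSE)
      }
    }
    if (all(is.na(coded[, j]))) coded[, j] <- code_level(factors[[j]], actual[, j])
  }
  if (any(abs(coded) > 2 + 1e-9)) {
    warning("some runs lie outside the coded +/-2 region; retained")
  }
  role <- if ("role" %in% names(df)) as.character(df$role) else
    apply(coded, 1, function(r) {
      if (all(abs(r) < 1e-9)) "center"
      else if (sum(abs(r) > 1e-9) == 1 && any(abs(r) > 1 + 1e-9)) "axial"
      else if (all(abs(abs(r) - 1) < 1e-9)) "factorial"
      else "custom"
    })
  run_order <- if ("run_order" %in% names(df)) as.integer(df$run_order) else
    seq_len(nrow(df))
  kind <- if (all(role %in% c("factorial", "axial", "center"))) "ccd" else "custom"
  design <- new_design(factors, coded, role, kind, run_order = run_order)
  y <- NULL
  if (!is.null(response)) {
    if (!response %in% names(df)) {
      stop("response column '", response, "' not found in ", path, call. = FALSE)
    }
    y <- parse_numeric_col(df[[response]], response, path)
  }
  list(design = design, y = y)
}

anova_report_to_list <- function(report) {
  special <- list(report$model_row, report$residual_row,
                  report$lack_of_fit_row, report$pure_error_row,
                  report$cor_total_row)
  special <- special[!vapply(special, is.null, logical(1))]
  list(
    rows = report$rows,
    summary_rows = lapply(special, function(r) r[c("term", "ss", "df", "ms", "f", "p")]),
    fit = report$fit,
    alpha = report$alpha
  )
}

#' Write an ANOVA report to text or JSON
#'
#' The text form is an aligned Source / SS / df / MS / F / p table with
#' significance marks and the fit-statistics footer; p-values below 1e-4
#' print as "< 0.0001". The JSON form round-trips through
#' [read_report_json()].
#'
#' @param report an `anova_report` from [anova_quadratic()]
#' @param path output path
#' @param format `"text"` or `"json"`
#' @return `path`, invisibly
#' @export
write_report <- function(report, path, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "anova_report"))
  if (format == "text") {
    writeLines(format_anova_text(report), path)
  } else {
    jsonlite::write_json(anova_report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read back a JSON ANOVA report
#'
#' @param path JSON path written by [write_report()] with
#'   `format = "json"`
#' @return an `anova_report` (same structure as from
#'   [anova_quadratic()])
#' @export
read_report_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- do.call(rbind, lapply(x$rows, function(r) {
    data.frame(term = r$term, ss = r$ss, df = as.integer(r$df), ms = r$ms,
               f = r$f, p = r$p, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
  spec <- x$summary_rows
  null2na <- function(r) {
    lapply(r, function(v) if (is.null(v)) NA_real_ else v)
  }
  grab <- function(term) {
    hit <- Filter(function(r) identical(r$term, term), spec)
    if (length(hit) == 0) NULL else null2na(hit[[1]])
  }
  structure(
    list(rows = rows,
         model_row = grab("Model"),
         residual_row = grab("Residual"),
         lack_of_fit_row = grab("Lack of fit"),
         pure_error_row = grab("Pure error"),
         cor_total_row = grab("Cor total"),
         alpha = x$alpha,
         fit = lapply(x$fit, function(v) if (is.null(v)) NA_real_ else v)),
    class = "anova_report"
  )
}

#' Write coefficients to CSV
#'
#' @param fit a `quad_fit`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_coef_csv <- function(fit, path) {
  stopifnot(inherits(fit, "quad_fit"))
  utils::write.csv(data.frame(term = fit$terms,
                              coefficient = as.numeric(fit$coef)),
                   path, row.names = FALSE)
  invisible(path)
}
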