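#' Define an experimental factor with coding geometry
#'
#' A factor definition ties a named experimental variable (pH, temperature,
#' diesel concentration, NaCl concentration, ...) to the linear coding used
#' in designed experiments: coded level 0 sits at `center` and each coded
#' unit is worth `step` actual units, so coded levels \{-2, -1, 0, +1, +2\}
#' map to `center + level * step`.
#'
#' `clamp_floor` is an optional lower bound applied only when a level is
#' decoded for bench execution (e.g. a concentration cannot be negative, so
#' a coded -2 diesel level of -0.5 % v/v is pipetted as 0). The clamp never
#' affects coding arithmetic or regression, which always work on the
#' planned coded levels.
#'
#' @param name factor name (used as column prefix in design tables)
#' @param units free-text units label
#' @param center actual value at coded level 0
#' @param step actual increment per coded unit; must be > 0
#' @param clamp_floor optional actual lower bound enforced at the bench
#' @return an object of class `factor_def`
#' @examples
#' ph <- factor_def("pH", "", center = 7.25, step = 0.75)
#' code_level(ph, 8.75)   # +2
#' @export
factor_def <- function(name, units = "", center, step, clamp_floor = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  center <- as.numeric(center)
  step <- as.numeric(step)
  if (!is.finite(step) || step <= 0) {
    stop("invalid factor definition for '", name, "': step must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, units = as.character(units), center = center,
         step = step, clamp_floor = as.numeric(clamp_floor)),
    class = "factor_def"
  )
}

#' @export
print.factor_def <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: center %g, step %g", x$name, x$units,
              x$center, x$step))
  if (is.finite(x$clamp_floor)) cat(sprintf(", bench floor %g", x$clamp_floor))
  cat("\n")
  invisible(x)
}

#' Convert an actual factor value to its coded level
#'
#' @param factor a [factor_def()]
#' @param actual actual value(s) in the factor's units
#' @return coded level(s), `(actual - center) / step`
#' @export
code_level <- function(factor, actual) {
  stopifnot(inherits(factor, "factor_def"))
  (as.numeric(actual) - factor$center) / factor$step
}

#' Convert a coded level back to actual units
#'
#' With `for_bench = TRUE` the optional `clamp_floor` of the factor is
#' applied, reproducing the convention that a negative planned
#' concentration is executed as zero. The unclamped value is always
#' available with `for_bench = FALSE` (the default), so the mapping stays
#' invertible.
#'
#' @param factor a [factor_def()]
#' @param coded coded level(s)
#' @param for_bench apply the bench clamp floor?
#' @return actual value(s), `center + coded * step`
#' @export
decode_level <- function(factor, coded, for_bench = FALSE) {
  stopifnot(inherits(factor, "factor_def"))
  actual <- factor$center + as.numeric(coded) * factor$step
  if (isTRUE(for_bench) && is.finite(factor$clamp_floor)) {
    actual <- pmax(actual, factor$clamp_floor)
  }
  actual
}

#' Read a factor configuration file
#'
#' Accepts YAML or JSON holding a list of factor entries with fields
#' `name`, `units`, `center`, `step` and optional `clamp_floor`, or a CSV
#' with those columns.
#'
#' @param path path to a `.yaml`/`.yml`, `.json` or `.csv` file
#' @return a named list of [factor_def()] objects
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) stop("factor config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  entries <- switch(
    ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    "csv" = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    },
    stop("unsupported factor config format: .", ext, call. = FALSE)
  )
  factors <- lapply(entries, function(e) {
    cf <- e$clamp_floor
    if (is.null(cf) || is.na(cf) || identical(cf, "")) cf <- NA_real_
    factor_def(e$name, if (is.null(e$units) || is.na(e$units)) "" else e$units,
               as.numeric(e$center), as.numeric(e$step), as.numeric(cf))
  })
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  factors
}
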