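#' @title Experimental designs: central composite and Plackett-Burman
#' @name designs
#' @description Generators for the two design families used in the
#'   two-stage optimisation workflow: a Plackett-Burman two-level screen
#'   to flag influential factors, and a central composite design (CCD)
#'   supporting a full second-order response-surface fit.
NULL

new_design <- function(factors, coded, role, kind, run_order = seq_len(nrow(coded))) {
  k <- length(factors)
  stopifnot(ncol(coded) == k)
  fnames <- vapply(factors, `[[`, character(1), "name")
  colnames(coded) <- fnames
  actual <- coded
  for (j in seq_len(k)) actual[, j] <- decode_level(factors[[j]], coded[, j])
  structure(
    list(factors = factors, coded = coded, actual = actual,
         role = role, run_order = as.integer(run_order), kind = kind),
    class = "rsm_design"
  )
}

#' @export
print.rsm_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors (%s)\n",
              toupper(x$kind), nrow(x$coded), ncol(x$coded),
              paste(colnames(x$coded), collapse = ", ")))
  if (x$kind == "ccd") {
    cat("  roles:", paste(sprintf("%s=%d", names(table(x$role)), table(x$role)),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of runs in a design
#' @param design an `rsm_design`
#' @return integer run count
#' @export
n_runs <- function(design) nrow(design$coded)

#' Generate a central composite design
#'
#' Builds the classical Box-Wilson CCD: a full two-level factorial block at
#' coded +/-1 (2^k runs), axial (star) points at +/-`alpha` on one axis at a
#' time (2k runs), and `n_center` replicated centre points. With four
#' factors and `alpha = 2` this is the 30-run, five-level
#' (-2, -1, 0, +1, +2) design used for the dodecane-mineralisation
#' optimisation. Runs are returned in generation order (factorial, axial,
#' centre); pass `shuffle_seed` for a seeded random run order.
#'
#' @param factors list of [factor_def()] objects (k >= 2)
#' @param alpha axial distance in coded units (> 0); default 2
#' @param n_center number of centre replicates (>= 1); default 6
#' @param shuffle_seed optional integer; if given, rows are randomised
#'   reproducibly
#' @return an `rsm_design` of kind `"ccd"` with roles
#'   factorial/axial/center
#' @examples
#' f <- default_factors()
#' d <- make_ccd(f)      # 16 + 8 + 6 = 30 runs
#' table(d$role)
#' @export
make_ccd <- function(factors, alpha = 2, n_center = 6, shuffle_seed = NULL) {
  k <- length(factors)
  if (k < 2) stop("unsupported design: a CCD needs at least 2 factors", call. = FALSE)
  stopifnot(alpha > 0, n_center >= 1)
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (j in seq_len(k)) {
    axial[2 * j - 1, j] <- -alpha
    axial[2 * j, j] <- alpha
  }
  centre <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, centre)
  dimnames(coded) <- NULL
  role <- c(rep("factorial", nrow(fact)), rep("axial", nrow(axial)),
            rep("center", n_center))
  if (!is.null(shuffle_seed)) {
    set.seed(as.integer(shuffle_seed))
    idx <- sample.int(nrow(coded))
    coded <- coded[idx, , drop = FALSE]
    role <- role[idx]
  }
  new_design(factors, coded, role, "ccd")
}

# Plackett-Burman first-row generators (cyclic construction): the first
# column is rotated to give n-1 columns; a row of -1 completes the design.
pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1)
)

#' Generate a Plackett-Burman screening design
#'
#' Two-level orthogonal main-effect screen built by the standard cyclic
#' construction for 8, 12, 16 or 20 runs. The first `length(factors)`
#' columns carry the real factors at coded -1/+1; the remaining
#' `n_runs - 1 - k` columns are kept as dummy factors whose apparent
#' effects estimate experimental error (see [pb_effects()]).
#'
#' @param factors list of [factor_def()] objects; at most `n_runs - 1`
#' @param n_runs one of 8, 12, 16, 20
#' @param shuffle_seed optional integer for a seeded random run order
#' @return an `rsm_design` of kind `"plackett_burman"`; dummy columns are
#'   stored in `$dummy` as a coded matrix
#' @export
make_plackett_burman <- function(factors, n_runs = 12, shuffle_seed = NULL) {
  key <- as.character(n_runs)
  if (!key %in% names(pb_generators)) {
    stop("unsupported Plackett-Burman size ", n_runs,
         "; supported run counts: 8, 12, 16, 20", call. = FALSE)
  }
  k <- length(factors)
  if (k > n_runs - 1) {
    stop("too many factors (", k, ") for a ", n_runs, "-run design", call. = FALSE)
  }
  g <- pb_generators[[key]]
  m <- length(g)
  full <- matrix(0, n_runs, m)
  for (i in seq_len(m)) {
    full[i, ] <- g[((seq_len(m) - i) %% m) + 1]
  }
  full[n_runs, ] <- -1
  if (!is.null(shuffle_seed)) {
    set.seed(as.integer(shuffle_seed))
    full <- full[sample.int(n_runs), , drop = FALSE]
  }
  coded <- full[, seq_len(k), drop = FALSE]
  d <- new_design(factors, coded, rep("pb", n_runs), "plackett_burman")
  dummy <- full[, setdiff(seq_len(m), seq_len(k)), drop = FALSE]
  if (ncol(dummy) > 0) colnames(dummy) <- paste0("dummy", seq_len(ncol(dummy)))
  d$dummy <- dummy
  d
}

#' Estimate main effects from a Plackett-Burman screen
#'
#' The main effect of each factor is the mean response at its high (+1)
#' level minus the mean at its low (-1) level. The unassigned (dummy)
#' columns of the design carry no real factor, so their apparent effects
#' estimate pure experimental error: the pseudo standard error of an
#' effect is `sqrt(mean(dummy_effects^2))` with one degree of freedom per
#' dummy column, and each real effect is t-tested against it at
#' `alpha = 0.05`.
#'
#' @param design an `rsm_design` of kind `"plackett_burman"`
#' @param y response vector, one value per run
#' @param alpha significance level for flagging (default 0.05)
#' @return data frame with columns `factor`, `effect`, `t`, `p`,
#'   `significant`; dummy-derived `pse` and `df` attached as attributes
#' @export
pb_effects <- function(design, y, alpha = 0.05) {
  stopifnot(inherits(design, "rsm_design"))
  if (design$kind != "plackett_burman") {
    stop("pb_effects() needs a Plackett-Burman design", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(design$coded)) {
    stop("response length ", length(y), " does not match the ",
         nrow(design$coded), " design runs", call. = FALSE)
  }
  eff_of <- function(col) mean(y[col > 0]) - mean(y[col < 0])
  effects <- apply(design$coded, 2, eff_of)
  dummy_eff <- if (!is.null(design$dummy) && ncol(design$dummy) > 0) {
    apply(design$dummy, 2, eff_of)
  } else numeric(0)
  n_dummy <- length(dummy_eff)
  pse <- if (n_dummy > 0) sqrt(mean(dummy_eff^2)) else NA_real_
  tval <- effects / pse
  pval <- 2 * stats::pt(abs(tval), df = n_dummy, lower.tail = FALSE)
  out <- data.frame(
    factor = colnames(design$coded),
    effect = as.numeric(effects),
    t = as.numeric(tval),
    p = as.numeric(pval),
    significant = !is.na(pval) & pval < alpha,
    row.names = NULL
  )
  attr(out, "pse") <- pse
  attr(out, "df") <- n_dummy
  attr(out, "dummy_effects") <- as.numeric(dummy_eff)
  out
}

#' Default factor set for the dodecane-mineralisation CCD
#'
#' The four medium/culture factors and their coding geometry used for both
#' isolates: pH (centre 7.25, step 0.75), temperature (centre 20 degC,
#' step 10), diesel concentration (centre 2.5 % v/v, step 1.5, bench floor
#' 0) and NaCl concentration (centre 1.0 % w/v, step 1.0, bench floor 0).
#'
#' @return named list of four [factor_def()] objects
#' @export
default_factors <- function() {
  list(
    pH = factor_def("pH", "", 7.25, 0.75),
    temperature = factor_def("temperature", "degC", 20, 10),
    diesel = factor_def("diesel", "% v/v", 2.5, 1.5, clamp_floor = 0),
    nacl = factor_def("nacl", "% w/v", 1.0, 1.0, clamp_floor = 0)
  )
}
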