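#' @title Seeded synthetic data for the optimisation pipeline
#' @name synthetic_data
#' @description Generators that exercise the whole workflow without any
#'   external data: CCD responses drawn from a known quadratic truth plus
#'   homoscedastic Gaussian noise (noise SD anchored by default to the
#'   residual SDs of the two packaged fits, 4.17 and 7.50), and C8-C20
#'   n-alkane chromatogram ladders with prescribed per-alkane area
#'   reductions.
NULL

#' Simulate CCD responses from a known quadratic surface
#'
#' Builds the CCD with [make_ccd()], evaluates the true second-order
#' polynomial at every coded point and adds iid Gaussian noise. With
#' `noise_sd = 0` the responses are exactly on the surface, so
#' [fit_quadratic()] recovers the truth to machine precision -- the basic
#' self-check of the fitting route.
#'
#' @param truth named coefficient vector / data frame as accepted by
#'   [quad_surface()], e.g. `load_fixture("eq_adl36")`
#' @param factors list of [factor_def()]; default [default_factors()]
#' @param noise_sd response noise standard deviation (>= 0)
#' @param alpha axial distance (default 2)
#' @param n_center centre replicates (default 6)
#' @param seed integer seed; same seed, same responses
#' @return list with `design` (`rsm_design`) and `y` (response vector)
#' @export
simulate_ccd_response <- function(truth, factors = default_factors(),
                                  noise_sd = 0, alpha = 2, n_center = 6,
                                  seed = 1) {
  stopifnot(noise_sd >= 0)
  surf <- if (inherits(truth, "quad_fit")) truth else quad_surface(truth)
  design <- make_ccd(factors, alpha = alpha, n_center = n_center)
  stopifnot(surf$k == ncol(design$coded))
  mu <- predict(surf, design$coded)
  set.seed(as.integer(seed))
  y <- mu + stats::rnorm(length(mu), 0, noise_sd)
  list(design = design, y = y, truth = surf)
}

#' Default C8-C20 retention-time ladder
#'
#' Linear elution model `rt = a + b * carbon_number` (defaults a = 2.0
#' min, b = 0.9 min per carbon) -- a documented stand-in, since no real
#' retention times back the packaged tables.
#'
#' @param carbons integer carbon numbers (default 8:20)
#' @param a,b intercept and slope of the elution model (minutes)
#' @return named numeric vector of retention times ("n-C8" ... "n-C20")
#' @export
alkane_ladder <- function(carbons = 8:20, a = 2.0, b = 0.9) {
  stats::setNames(a + b * carbons, paste0("n-C", carbons))
}

#' Simulate control / sample / standard chromatogram peak tables
#'
#' The abiotic control carries the specified areas; the sample's areas
#' are `control * (1 - reduction)`, optionally perturbed by relative
#' Gaussian noise of coefficient of variation `area_noise_cv`; the
#' standard is the ladder at unit area. Retention times follow
#' [alkane_ladder()] with an optional jitter on the non-standard tables.
#'
#' @param reductions named vector of per-alkane fractional reductions in
#'   `[0, 1]` (names must be ladder labels); alkanes not named get 0
#' @param control_areas named vector of control areas (> 0); default 1.0
#'   for every ladder alkane
#' @param ladder retention-time map (default [alkane_ladder()])
#' @param area_noise_cv relative SD of multiplicative area noise
#' @param rt_jitter_sd SD (minutes) of retention-time jitter applied to
#'   control and sample peaks
#' @param seed integer seed
#' @return list of three [peak_table()]s: `control`, `sample`, `standard`
#' @export
simulate_chromatograms <- function(reductions, control_areas = NULL,
                                   ladder = alkane_ladder(),
                                   area_noise_cv = 0, rt_jitter_sd = 0,
                                   seed = 1) {
  if (is.null(control_areas)) {
    control_areas <- stats::setNames(rep(1, length(ladder)), names(ladder))
  }
  stopifnot(all(names(control_areas) %in% names(ladder)),
            all(control_areas > 0))
  red <- stats::setNames(rep(0, length(control_areas)), names(control_areas))
  if (length(reductions) > 0) {
    stopifnot(!is.null(names(reductions)),
              all(names(reductions) %in% names(red)),
              all(reductions >= 0), all(reductions <= 1))
    red[names(reductions)] <- reductions
  }
  set.seed(as.integer(seed))
  alk <- names(control_areas)
  rt0 <- ladder[alk]
  jit <- function() if (rt_jitter_sd > 0) stats::rnorm(length(alk), 0, rt_jitter_sd) else 0
  noise <- function() if (area_noise_cv > 0) 1 + stats::rnorm(length(alk), 0, area_noise_cv) else 1
  control <- peak_table(rt0 + jit(), control_areas, alk,
                        id = "abiotic control", kind = "abiotic_control")
  sample_area <- pmax(control_areas * (1 - red) * noise(), 0)
  sample <- peak_table(rt0 + jit(), sample_area, alk,
                       id = "sample", kind = "sample")
  standard <- peak_table(ladder, rep(1, length(ladder)), names(ladder),
                         id = "standard", kind = "standard")
  # simulated tables already carry truth labels; strip them so matching
  # against the standard is exercised, not bypassed
  control$label <- NA_character_
  sample$label <- NA_character_
  list(control = control, sample = sample, standard = standard)
}

fixture_names <- c("table1_factors", "table2_adl15", "table4_adl36",
                   "eq_adl15", "eq_adl36")

#' Load a packaged fixture
#'
#' The central composite design/response tables of the two isolates and
#' their fitted coded-unit regression equations ship with the package as
#' plain CSV:
#' \describe{
#'   \item{table1_factors}{the four factor definitions (named list of
#'     [factor_def()])}
#'   \item{table2_adl15, table4_adl36}{30-run design tables in actual
#'     units with experimental and predicted response columns
#'     (data frame)}
#'   \item{eq_adl15, eq_adl36}{published coded-unit coefficient sets
#'     (data frame with `term`, `coefficient`)}
#' }
#'
#' @param name one of `table1_factors`, `table2_adl15`, `table4_adl36`,
#'   `eq_adl15`, `eq_adl36`
#' @return the parsed object (see above)
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "rsmbe",
                      mustWork = TRUE)
  if (name == "table1_factors") return(read_factor_config(path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a packaged design table as a design + response
#'
#' Convenience wrapper: reads `table2_adl15` or `table4_adl36`, codes the
#' actual factor columns with the packaged factor definitions, assigns
#' design roles and returns the pieces ready for [fit_quadratic()]. The
#' run order of the printed table (its randomised bench order) is kept.
#'
#' @param name `"table2_adl15"` or `"table4_adl36"`
#' @return list with `design`, `y` (experimental response),
#'   `predicted` (the table's printed predicted column)
#' @export
load_ccd_fixture <- function(name = c("table2_adl15", "table4_adl36")) {
  name <- match.arg(name)
  factors <- load_fixture("table1_factors")
  df <- load_fixture(name)
  k <- length(factors)
  coded <- matrix(NA_real_, nrow(df), k)
  for (j in seq_len(k)) {
    col <- paste0(names(factors)[j], "_actual")
    coded[, j] <- code_level(factors[[j]], df[[col]])
  }
  role <- apply(coded, 1, function(r) {
    if (all(abs(r) < 1e-9)) "center"
    else if (sum(abs(r) > 1e-9) == 1) "axial"
    else "factorial"
  })
  design <- new_design(factors, coded, role, "ccd", run_order = df$run_order)
  list(design = design, y = df$experimental, predicted = df$predicted)
}
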