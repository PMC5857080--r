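#!/usr/bin/env Rscript
# Stage 3: locate the optimum of each fitted surface over the factorial
# cube [-1,+1]^4 in coded units (the region actually spanned by the
# factorial runs), report desirability against a 100 % target, and
# export diesel-vs-NaCl surface grids for plotting.

suppressPackageStartupMessages(library(rsmbe))
dir.create("results", showWarnings = FALSE)

for (strain in c("adl15", "adl36")) {
  fx <- load_ccd_fixture(paste0(ifelse(strain == "adl15", "table2_", "table4_"),
                                strain))
  fit <- fit_quadratic(fx$design, fx$y)
  opt <- maximize_box(fit, lo = -1, hi = 1)
  cat(sprintf("== %s ==\n", toupper(strain)))
  print(opt)
  cat("  bench-clamped actual:",
      paste(sprintf("%s=%.3f", names(opt$argmax_actual_bench),
                    opt$argmax_actual_bench), collapse = ", "), "\n")
  st <- tryCatch(stationary_point(fit), error = function(e) NULL)
  if (!is.null(st)) {
    cat(sprintf("  unconstrained stationary point: %s at (%s), y = %.2f\n",
                st$nature, paste(sprintf("%.2f", st$point), collapse = ", "),
                st$value))
  }
  g <- surface_grid(fit, 3, 4, resolution = 41)
  write.csv(g, sprintf("results/%s_surface_diesel_nacl.csv", strain),
            row.names = FALSE)
  out <- data.frame(strain = toupper(strain),
                    t(setNames(opt$argmax_coded,
                               paste0(names(fit$design$factors), "_coded"))),
                    y_max = opt$y_max, desirability = opt$desirability)
  write.csv(out, sprintf("results/%s_optimum.csv", strain), row.names = FALSE)
  cat("\n")
}
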