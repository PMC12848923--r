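#!/usr/bin/env Rscript
# Step 5 — Shrub-herb biomass model: stability regimes and bifurcation.
#
# Evaluates the eigenvalue stability classification at each site's
# estimated R_h/s, scans the ratio axis for regime changes, and runs the
# regime-calibration search against the three-class pattern implied by
# the ratio thresholds, reporting whether that pattern is attainable for
# the model's Jacobian structure.

suppressPackageStartupMessages(library(hydroniche))

site_table <- utils::read.csv("results/site_table.csv")
params <- dyn_params()

cat("Eigenvalue classification at each site's estimated ratio:\n")
dyn <- do.call(rbind, lapply(seq_len(nrow(site_table)), function(i) {
  st <- site_stability(site_table$R_hs[i], params)
  data.frame(site_id = site_table$site_id[i],
             R_hs = round(site_table$R_hs[i], 2),
             max_re = round(st$max_re, 3), regime = st$regime)
}))
print(dyn, row.names = FALSE)

scan <- bifurcation_scan(params, R_grid = seq(0.3, 2.5, by = 0.005))
cross <- attr(scan, "bifurcations")
cat(sprintf("\nBifurcation scan over R in [0.3, 2.5]: %d sign change(s)%s\n",
            length(cross),
            if (length(cross)) paste0(" at R = ",
                                      paste(round(cross, 3), collapse = ", "))
            else ""))

# Can the three-class ratio pattern be reproduced by the Jacobian's
# eigenvalues for some modulation parameters?
targets <- data.frame(
  R = c(0.81, 0.86, 1.01, 1.03, 1.05, 1.08, 1.45, 1.61),
  regime = c("stable", "stable", "marginal", "marginal", "marginal",
             "marginal", "unstable", "unstable"))
fit <- calibrate_regimes(targets, params)
cat(sprintf("\nRegime calibration: pattern attainable = %s (%d of %d misclassified)\n",
            fit$attainable, fit$misclassified, nrow(targets)))
print(fit$report, row.names = FALSE, digits = 3)
if (fit$attainable) {
  cat(sprintf("  calibrated breakpoints: R0 = %.3f, Rc = %.3f, k = %.3f, b = %.3f\n",
              fit$params$R0, fit$params$Rc, fit$params$k, fit$params$b))
  cat("  mechanism: strong herb-shrub cross-coupling near the sigmoid midpoint\n")
  cat("  stabilizes low ratios (det > 0, tr < 0); as the coupling fades at high\n")
  cat("  ratios the determinant changes sign and a saddle appears. Note the\n")
  cat("  published eigenvalue magnitudes are still not reproduced - only the\n")
  cat("  class labels - and the package defaults keep R0 = 0.9, Rc = 1.4\n")
} else {
  cat("  no parameter combination reproduced the full pattern; discrepancies\n")
  cat("  are listed above and the ratio thresholds stand on their own as an\n")
  cat("  empirical classification\n")
}

dir.create("results", showWarnings = FALSE)
utils::write.csv(dyn, "results/dynamics_table.csv", row.names = FALSE)
utils::write.csv(scan, "results/bifurcation_scan.csv", row.names = FALSE)
utils::write.csv(fit$report, "results/regime_calibration.csv", row.names = FALSE)
cat("  -> results/dynamics_table.csv, results/bifurcation_scan.csv, results/regime_calibration.csv\n")
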