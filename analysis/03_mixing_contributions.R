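#!/usr/bin/env Rscript
# Step 3 — Bayesian mixing: soil-layer contributions per species and site.
#
# Runs the dual-isotope mixing model for every species at every site,
# aggregates the 8 source layers to the reporting depth groups
# (0-20 / 20-40 / 40-100 / 100-120 cm), and writes the full posterior
# summary plus the group-level main-layer table. Chains are sized for a
# desk run; raise `iterations` toward 3e5 for a publication-length run.

suppressPackageStartupMessages(library(hydroniche))
seed <- 1L

cfg <- pipeline_config(
  generator = generator_settings(seed = seed),
  mixing = mixing_config(),   # 3 x 20k / 10k burn-in / thin 10
  seed = seed)
bundle <- suppressWarnings(run_pipeline(cfg))

dir.create("results", showWarnings = FALSE)
utils::write.csv(bundle$contributions, "results/contributions.csv", row.names = FALSE)
utils::write.csv(bundle$group_table, "results/group_table.csv", row.names = FALSE)
utils::write.csv(bundle$site_table, "results/site_table.csv", row.names = FALSE)

cat("Per-group main-layer water sources (posterior means over species x sites):\n")
print(bundle$group_table, row.names = FALSE, digits = 3)
cat(sprintf("  worst split-Rhat across runs: %.3f\n", max(bundle$contributions$max_rhat)))
tr <- bundle$truth
if (!is.null(tr)) {
  m <- merge(bundle$contributions, tr[, c("site_id", "group", "main_group", "true_main_pct")],
             by.x = c("site_id", "group", "source"),
             by.y = c("site_id", "group", "main_group"))
  cat(sprintf("  recovery: mean |posterior - truth| on main layers = %.1f points (n = %d)\n",
              mean(abs(m$mean_pct - m$true_main_pct)), nrow(m)))
}
cat("  -> results/contributions.csv, results/group_table.csv, results/site_table.csv\n")
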