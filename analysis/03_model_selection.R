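#!/usr/bin/env Rscript

# Step 3 — log-linear model selection over the transition table.
#
# Fits the lattice of hierarchical log-linear models from the null model
# (transitions unaffected by any factor) through every combination of
# vessel condition, time block, season, and the time-by-season
# interaction acting on the preceding-by-succeeding association.  Each
# model is fitted by iterative proportional fitting; models are compared
# by G-squared against the saturated model and ranked by AIC.

suppressPackageStartupMessages(library(duskybudget))

tab_path <- "results/chains/transition_table.csv"
if (!file.exists(tab_path)) stop("run analysis/02_build_chains.R first")
out_dir <- "results/models"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tab <- read_transition_table(tab_path)
lat <- run_lattice(tab)

write_lattice_report(lat, file.path(out_dir, "lattice_report.csv"))
write_lattice_dot(lat, file.path(out_dir, "lattice.dot"))

print(lat$table[, c("label", "g2", "df", "aic", "rank")], digits = 5)
sig <- lat$edges[lat$edges$significant, c("from", "added", "p_value")]
message(sprintf("AIC-best model: %s", lat$best))
message(sprintf("%d of %d single-term additions significant at alpha = %.2f",
                nrow(sig), nrow(lat$edges), lat$alpha))
message("Wrote lattice_report.csv and lattice.dot under ", out_dir)
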