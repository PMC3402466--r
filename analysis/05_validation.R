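#!/usr/bin/env Rscript

# Step 5 — validation experiments and published-table consistency.
#
# Checks the machinery against independent oracles (closed-form IPF,
# power iteration, a reference Z statistic), measures parameter-recovery
# and model-selection error rates on synthetic data of known truth, and
# verifies that the shipped published stratum totals and seasonal vessel
# counts are internally consistent with the study's stated totals.
# Replicate counts here are moderate; scripts/acceptance.R runs the full
# versions.

suppressPackageStartupMessages(library(duskybudget))

out_dir <- "results/validation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20100131

rows <- list()
add <- function(quantity, value) {
  rows[[length(rows) + 1]] <<- data.frame(quantity = quantity, value = value)
  message(sprintf("%-44s %.10g", quantity, value))
}

tot <- published_stratum_totals()
add("published_transition_total", sum(tot$count))
vs <- published_vessel_summary()
add("published_vessel_total", sum(vs$vessels_observed))

add("ipf_independence_max_error", ipf_independence_error(100, seed))
add("stationary_oracle_max_error", stationary_oracle_error(200, seed + 1))
add("ztest_max_abs_error", ztest_reference_error(500, seed + 2))
add("budget_recovery_rate", budget_recovery_rate(50, 10000, seed = seed + 3))
add("budget_recovery_rate_study_matrices",
    budget_recovery_rate(20, 10000, seed = seed + 4, matrices = "study"))
add("vessel_term_selection_rate_planted",
    vessel_term_selection_rate(25, 10000, 0.15, seed = seed + 5))
add("vessel_term_selection_rate_null",
    vessel_term_selection_rate(25, 10000, 0, seed = seed + 6))
add("control_buffer_exclusion_rate",
    buffer_violation_exclusion_rate(50, seed + 7))
add("saturated_g2_max", saturated_g2_max(2, seed + 8))

write.csv(do.call(rbind, rows), file.path(out_dir, "validation.csv"),
          row.names = FALSE)
message("Wrote validation.csv under ", out_dir)
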