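#!/usr/bin/env Rscript
# Operating characteristics of the full pipeline: 20 seeded replicates
# per scenario, each simulated and refit from scratch; tabulates the
# significance decisions and change-point localization against truth.

library(bucpsced)

dir.create("results", showWarnings = FALSE)
rows <- list()
for (name in c("responder", "stable_null", "drifting_null")) {
  out <- suppressWarnings(recovery_study(name, replicates = 20, seed = 303))
  out$scenario <- name
  rows[[name]] <- out
  cat(sprintf("%-13s: decision rate %.2f | median |cp error| %.1f | max PSRF %.3f\n",
              name, attr(out, "decision_rate"),
              attr(out, "median_cp_error"), max(out$max_psrf)))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/operating_characteristics.csv", row.names = FALSE)
cat("\nWrote per-replicate table to results/operating_characteristics.csv\n")
cat("Expected pattern: the responder fires in >=90% of replicates with the\n")
cat("change point located within a week; the nulls fire in <=10%.\n")
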