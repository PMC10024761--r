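#!/usr/bin/env Rscript
# Cohort statistics: the printed contingency tables recomputed, the
# behavioral indices, and a combined machine-readable report over the
# tables produced by stages 02-05 (which must be run first).
# Writes results/contingency_tests.csv and results/cohort_report.json.

suppressPackageStartupMessages(library(hippophys))
dir.create("results", showWarnings = FALSE)

# Contingency statistics with counts taken from the slice cohort design
# (3/20 vs 11/20 seizing slices; 6/5 vs 21/16 initiation compartments;
# 1/4 vs 7/9 cortical initiation subregions).
tabs <- list(
  slice_class = matrix(c(3, 17, 11, 9), 2, byrow = TRUE),
  initiation_compartment = matrix(c(6, 5, 21, 16), 2, byrow = TRUE),
  cortical_initiation = matrix(c(1, 4, 7, 9), 2, byrow = TRUE))
ct <- do.call(rbind, lapply(names(tabs), function(nm) {
  res <- fisher_exact_2x2(tabs[[nm]])
  data.frame(contrast = nm, method = res$method,
             p_value = signif(res$p_value, 4))
}))
write.csv(ct, "results/contingency_tests.csv", row.names = FALSE)
print(ct)

# Behavioral indices: identity check on the control exploration ratio
bi <- behavior_indices(0.562, 1 - 0.562)
message(sprintf("preference %.3f -> discrimination %.3f",
                bi$preference, bi$discrimination))

# Combined report over the session and cell tables, if present
report <- list(contingency = ct)
if (file.exists("results/lfp_session_table.csv")) {
  tab <- read.csv("results/lfp_session_table.csv")
  long <- do.call(rbind, lapply(c("theta_slm", "gamma_sp"), function(m) {
    data.frame(unit_id = tab$session_id, group = tab$genotype,
               measure = m, value = tab[[m]])
  }))
  rl <- build_report(long)
  report$lfp <- list(descriptives = rl$descriptives,
                     p_values = lapply(rl$tests, `[[`, "p_value"))
}
if (file.exists("results/psc_cell_table.csv")) {
  cells <- read.csv("results/psc_cell_table.csv")
  long <- do.call(rbind, lapply(c("frequency_hz", "mean_amplitude_pa"),
                                function(m) {
    data.frame(unit_id = cells$cell_id, group = cells$genotype,
               measure = m, value = cells[[m]])
  }))
  rl <- build_report(long)
  report$psc <- list(descriptives = rl$descriptives,
                     p_values = lapply(rl$tests, `[[`, "p_value"))
}
jsonlite::write_json(report, "results/cohort_report.json",
                     auto_unbox = TRUE, digits = 6, dataframe = "rows")
message("wrote results/cohort_report.json")
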