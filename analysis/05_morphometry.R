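#!/usr/bin/env Rscript
# Morphometry: Sholl profiles and tree metrics for a control vs mutant
# set of simulated CA1-pyramidal-like morphologies (mutant apical trees
# grown longer, as in the recorded phenotype), spine densities, and the
# cell-density normalisations. Writes results/sholl_profiles.csv and
# results/morphology_metrics.csv.

suppressPackageStartupMessages(library(hippophys))
dir.create("results", showWarnings = FALSE)

simulate_cell <- function(genotype, idx, seed) {
  n_br <- if (genotype == "mutant") 46 else 40  # longer, not more branched
  spines <- if (genotype == "mutant") 1.5 else 1.2
  m <- generate_morphology(morph_sim_params(
    n_branches = n_br, branch_length_um = 30,
    spine_density_per_um = spines, seed = seed))
  list(id = sprintf("%s_%02d", genotype, idx), genotype = genotype, m = m)
}

cells <- c(lapply(1:8, function(i) simulate_cell("control", i, 9000 + i)),
           lapply(1:7, function(i) simulate_cell("mutant", i, 9100 + i)))

sholl <- do.call(rbind, lapply(cells, function(cl) {
  sp <- sholl_profile(cl$m, 10, "apical")
  data.frame(cell_id = cl$id, genotype = cl$genotype,
             radius_um = sp$radius_um, intersections = sp$intersections)
}))
write.csv(sholl, "results/sholl_profiles.csv", row.names = FALSE)

metrics <- do.call(rbind, lapply(cells, function(cl) {
  tm <- tree_metrics(cl$m, "apical")
  spine_density <- nrow(cl$m$spines) /
    tree_metrics(cl$m, "all")$total_length_um
  data.frame(cell_id = cl$id, genotype = cl$genotype,
             apical_length_um = tm$total_length_um,
             n_branch_points = tm$n_branch_points,
             n_terminals = tm$n_terminals,
             spine_density_per_um = spine_density)
}))
write.csv(metrics, "results/morphology_metrics.csv", row.names = FALSE)

for (msr in c("apical_length_um", "n_branch_points",
              "spine_density_per_um")) {
  mw <- rank_tests(split(metrics[[msr]], metrics$genotype),
                   "mann_whitney")
  message(sprintf("%s: Mann-Whitney p = %.4g", msr, mw$p_value))
}

# density normalisations: bilateral counts to cells/mm along the fissure
left <- linear_density(42, 0.5, "cells/mm")
right <- linear_density(38, 0.5, "cells/mm")
message(sprintf("bilateral CR density: %.0f %s",
                bilateral_mean(left, right)$density, left$units))
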