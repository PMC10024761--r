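#!/usr/bin/env Rscript
# Simulate one example of each recording modality with ground truth and
# write them to plain-text containers under results/simulated/.
# The cohorts used by the later stages are regenerated there from seeds,
# so this stage is illustrative: it shows what the generators emit.

suppressPackageStartupMessages(library(hippophys))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# A 60-s laminar LFP session: theta/gamma during mobility bouts, delta
# during immobility, 1/f background and 50-Hz mains on 16 contacts.
lfp <- generate_laminar_lfp(lfp_sim_params(duration_s = 60, seed = 1),
                            session_id = "demo", genotype = "control")
write_recording(lfp$recording, file.path(out, "lfp_demo"))
write.csv(data.frame(sample = seq_along(lfp$truth$state_track),
                     mobile = lfp$truth$state_track),
          file.path(out, "lfp_demo_state.csv"), row.names = FALSE)
message(sprintf("LFP: %d channels x %d samples, %.0f%% mobility",
                nrow(lfp$recording$samples), ncol(lfp$recording$samples),
                100 * mean(lfp$truth$state_track)))

# A 2-min slice on a small grid: noise, bursts in DG, one propagating
# seizure-like discharge.
mea <- generate_mea_recording(mea_sim_params(
  duration_s = 120, rate_hz = 2000, grid_shape = c(2, 6),
  seizure_rate_per_min = 0.6, burst_rate_per_min = 3, seed = 1),
  slice_id = "demo")
write_recording(mea$recording, file.path(out, "mea_demo"))
write.csv(mea$truth$events, file.path(out, "mea_demo_truth.csv"),
          row.names = FALSE)
message(sprintf("MEA: %d events injected (%d seizure-like)",
                nrow(mea$truth$events),
                sum(mea$truth$events$class == "seizure")))

# A 4-min voltage-clamp trace of spontaneous inward currents at -60 mV.
psc <- generate_psc_trace(psc_sim_params(duration_s = 240, seed = 1))
write_recording(psc$trace, file.path(out, "psc_demo"))
write.csv(psc$truth, file.path(out, "psc_demo_truth.csv"),
          row.names = FALSE)
message(sprintf("PSC: %d events at %.2f Hz true rate",
                nrow(psc$truth), nrow(psc$truth) / 240))

# A reconstructed-like pyramidal-cell morphology in SWC.
m <- generate_morphology(morph_sim_params(n_branches = 40, seed = 1))
write_swc(m, file.path(out, "neuron_demo.swc"))
message(sprintf("Morphology: %.0f um total dendrite, %d spines",
                tree_metrics(m, "all")$total_length_um, nrow(m$spines)))
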