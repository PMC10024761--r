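# Generators: determinism, zero-noise limits, ground-truth consistency,
# and the statistical structure the downstream analyses rely on.

test_that("zero-noise single-state LFP is a pure theta tone at the SLM amplitude", {
  p <- lfp_sim_params(
    duration_s = 20, rate_hz = 500, n_channels = 4,
    layer_labels = c("SO", "SP", "SR", "SLM"), state_dwell_s = 1e6,
    theta_amp_profile = c(0, 0, 0, 100), gamma_amp_profile = rep(0, 4),
    delta_amp_profile = rep(0, 4), noise_1overf_scale = 0, line_hz = 0,
    seed = 3)
  g <- generate_laminar_lfp(p)
  expect_true(all(g$truth$state_track))
  x <- g$recording$samples[4, ]
  expect_equal(max(x), 100, tolerance = 1e-3)
  expect_equal(min(x), -100, tolerance = 1e-3)
  # all spectral mass inside the theta band
  ps <- psd_segment(x, 500)
  in_theta <- ps$freq_hz >= 4 & ps$freq_hz <= 12
  expect_gt(sum(ps$psd[in_theta]) / sum(ps$psd), 0.999)
  # other channels silent
  expect_equal(max(abs(g$recording$samples[1:3, ])), 0)
})

test_that("generators are bit-identical for identical (params, seed)", {
  p <- lfp_sim_params(duration_s = 10, rate_hz = 400, n_channels = 4,
                      seed = 7)
  expect_identical(generate_laminar_lfp(p)$recording$samples,
                   generate_laminar_lfp(p)$recording$samples)
  pm <- mea_sim_params(duration_s = 10, rate_hz = 1000,
                       grid_shape = c(3, 6), seed = 7)
  expect_identical(generate_mea_recording(pm)$recording$traces,
                   generate_mea_recording(pm)$recording$traces)
  pp <- psc_sim_params(duration_s = 10, seed = 7)
  expect_identical(generate_psc_trace(pp)$trace$samples,
                   generate_psc_trace(pp)$trace$samples)
  pmorph <- morph_sim_params(n_branches = 15, seed = 7)
  expect_identical(generate_morphology(pmorph)$nodes,
                   generate_morphology(pmorph)$nodes)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_laminar_lfp(lfp_sim_params(duration_s = 5,
                                                rate_hz = 400,
                                                n_channels = 4, seed = 1)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("empirical state dwell time matches the configured mean within 30%", {
  dwells <- unlist(lapply(1:20, function(s) {
    g <- generate_laminar_lfp(lfp_sim_params(
      duration_s = 600, rate_hz = 400, n_channels = 1,
      layer_labels = "SLM", theta_amp_profile = 10,
      gamma_amp_profile = 1, delta_amp_profile = 10,
      state_dwell_s = 10, seed = s))
    r <- rle(g$truth$state_track)
    # drop the censored first and last dwells
    len <- r$lengths
    if (length(len) > 2) len <- len[-c(1, length(len))]
    len / 400
  }))
  expect_gt(length(dwells), 100)
  expect_lt(abs(mean(dwells) - 10) / 10, 0.3)
})

test_that("1/f and Gaussian noise SDs match their configured scales", {
  g <- generate_laminar_lfp(lfp_sim_params(
    duration_s = 60, rate_hz = 400, n_channels = 1,
    layer_labels = "SLM", theta_amp_profile = 0, gamma_amp_profile = 0,
    delta_amp_profile = 0, noise_1overf_scale = 15, line_hz = 0,
    seed = 5))
  expect_lt(abs(sd(g$recording$samples[1, ]) - 15) / 15, 0.05)
  gm <- generate_mea_recording(mea_sim_params(
    duration_s = 60, rate_hz = 1000, grid_shape = c(2, 6), noise_sd = 4,
    burst_rate_per_min = 0, seizure_rate_per_min = 0, seed = 5))
  expect_lt(abs(sd(gm$recording$traces[1, ]) - 4) / 4, 0.05)
  gp <- generate_psc_trace(psc_sim_params(
    duration_s = 60, rate_hz = 5000, event_rate_hz = 0,
    baseline_sd_pa = 3, seed = 5))
  expect_lt(abs(sd(gp$trace$samples) - 3) / 3, 0.05)
})

test_that("cohort with zero coupling decouples density from rhythm gain", {
  rs <- vapply(1:40, function(s) {
    coh <- generate_session_cohort(
      15, 15, coupling = list(gamma_sp = 0, theta_slm = 0,
                              session_noise_sd = 0.10),
      seed = s, recordings = FALSE)
    cor(coh$table$cr_density, coh$table$true_gamma_gain)
  }, numeric(1))
  # under independence |r| < 0.3 at n = 30 holds for ~89% of seeds
  # (exact null); allow binomial noise around that and check the null
  # is centred on zero
  expect_gte(mean(abs(rs) < 0.3), 0.8)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("positive coupling makes the true gamma gain increase with density", {
  coh <- generate_session_cohort(14, 14, seed = 11, recordings = FALSE)
  ord <- order(coh$table$cr_density)
  gain <- coh$table$true_gamma_gain / 1  # includes lognormal session noise
  # the deterministic part is monotone: check after removing session noise
  coh0 <- generate_session_cohort(
    14, 14, coupling = list(gamma_sp = 0.25, theta_slm = 0.15,
                            session_noise_sd = 0),
    seed = 11, recordings = FALSE)
  expect_true(all(diff(coh0$table$true_gamma_gain[
    order(coh0$table$cr_density)]) >= 0))
  # mutants draw higher densities on average
  expect_gt(mean(coh$table$cr_density[coh$table$genotype == "mutant"]),
            mean(coh$table$cr_density[coh$table$genotype == "control"]))
})

test_that("cohort and coupling parameter validation errors", {
  expect_error(generate_session_cohort(0, 5), "at least one session")
  expect_error(generate_session_cohort(
    3, 3, coupling = list(gamma_sp = 0.1, theta_slm = 0.1,
                          session_noise_sd = -1), recordings = FALSE),
    "non-negative")
  expect_error(lfp_sim_params(rate_hz = 100), "rate_hz")
  expect_error(lfp_sim_params(n_channels = 3,
                              layer_labels = c("SO", "SP")),
               "layer_labels")
})

test_that("MEA taxonomy limits are enforced at generation", {
  expect_error(mea_sim_params(burst_duration_s = 5), "shorter than 5")
  expect_error(mea_sim_params(seizure_duration_s = 5), "more than 5")
  expect_error(mea_sim_params(propagation_delay_s = c(DG = -1)),
               "non-negative")
})

test_that("silent MEA simulation yields pure noise and no detections", {
  g <- generate_mea_recording(mea_sim_params(
    duration_s = 30, rate_hz = 1000, grid_shape = c(2, 6),
    burst_rate_per_min = 0, seizure_rate_per_min = 0, seed = 2))
  expect_equal(nrow(g$truth$events), 0)
  res <- analyze_mea_slice(g$recording)
  expect_equal(res$report$n_seizures, 0)
  expect_equal(res$report$n_bursts, 0)
  expect_equal(res$report$activity_class, "silent")
})

test_that("seizure ground truth starts on the initiation region with delays", {
  p <- mea_sim_params(duration_s = 120, rate_hz = 1000,
                      grid_shape = c(2, 6),
                      seizure_rate_per_min = 1.5, burst_rate_per_min = 0,
                      seizure_duration_s = 12,
                      initiation_region = "DG",
                      propagation_delay_s = c(DG = 0, CA3 = 0.05, CA1 = 0.1,
                                              Sub = 0.15, Ent = 0.2,
                                              "PRh/Ect" = 0.25),
                      seed = 4)
  g <- generate_mea_recording(p)
  sz <- g$truth$events[g$truth$events$class == "seizure", ]
  expect_gt(nrow(sz), 0)
  dg_el <- g$recording$region_map$electrode[
    g$recording$region_map$region == "DG"]
  expect_true(all(sz$electrode %in% dg_el))
  expect_true(all(sz$region == "DG"))
})

test_that("burst counts are Poisson-consistent with the configured rate", {
  counts <- vapply(1:10, function(s) {
    g <- generate_mea_recording(mea_sim_params(
      duration_s = 600, rate_hz = 200, grid_shape = c(1, 6),
      burst_rate_per_min = 2, seizure_rate_per_min = 0, seed = s))
    sum(g$truth$events$class == "burst")
  }, numeric(1))
  expected <- 2 * (600 - 0.6) / 60
  # mean of 10 Poisson(≈20) draws: allow 3 standard errors
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / 10) + 1)
})

test_that("PSC trace zero-noise limit reaches the configured amplitude", {
  g <- generate_psc_trace(psc_sim_params(
    duration_s = 10, rate_hz = 10000, event_rate_hz = 0.5,
    amp_mean_pa = 50, amp_sd_pa = 0, baseline_sd_pa = 0, seed = 7))
  expect_gt(nrow(g$truth), 0)
  expect_equal(min(g$trace$samples), -50, tolerance = 2e-3)
  g0 <- generate_psc_trace(psc_sim_params(
    duration_s = 10, event_rate_hz = 0, seed = 7))
  expect_equal(nrow(g0$truth), 0)
})

test_that("PSC event counts follow the Poisson rate", {
  counts <- vapply(1:10, function(s) {
    nrow(generate_psc_trace(psc_sim_params(
      duration_s = 240, rate_hz = 5000, event_rate_hz = 2,
      seed = s))$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 480), 3 * sqrt(480 / 10) + 1)
})

test_that("PSC parameter validation", {
  expect_error(psc_sim_params(rise_ms = 8, decay_ms = 2), "rise time")
  expect_error(psc_sim_params(rate_hz = 500, rise_ms = 1), "resolve")
})

test_that("morphology generator obeys its contracts", {
  expect_error(morph_sim_params(n_branches = 0), "empty-tree")
  m <- generate_morphology(morph_sim_params(n_branches = 30,
                                            spine_density_per_um = 2,
                                            seed = 2))
  tm <- tree_metrics(m, "all")
  expect_equal(nrow(m$spines), round(2 * tm$total_length_um))
  # apical/basal split approximately follows apical_fraction
  comp <- table(m$nodes$compartment)
  expect_equal(unname(comp["apical"]), 18)
  expect_equal(unname(comp["basal"]), 12)
})

test_that("recordings round-trip through the text container", {
  g <- generate_laminar_lfp(lfp_sim_params(duration_s = 2, rate_hz = 400,
                                           n_channels = 4, seed = 1))
  pre <- file.path(tempdir(), "rec1")
  write_recording(g$recording, pre)
  back <- read_recording(pre)
  expect_equal(back$samples, g$recording$samples, tolerance = 1e-8)
  expect_identical(back$channel_labels, g$recording$channel_labels)
})
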