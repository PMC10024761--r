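# Theta/delta segmentation and band power: channel selection, ratio
# track, threshold fit, interval extraction, band power contracts.

make_tone_recording <- function(freq, amp = 100, duration = 60,
                                rate = 500, n_ch = 1,
                                labels = rep("SLM", n_ch)) {
  t <- seq.int(0L, round(duration * rate) - 1L) / rate
  samples <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch),
                    nrow = n_ch, byrow = TRUE)
  laminar_recording(samples, rate, labels)
}

test_that("theta channel selection follows maximal theta power with tie rule", {
  t <- seq(0, 30, by = 1 / 500)[-1]
  theta <- sin(2 * pi * 8 * t)
  samples <- rbind(10 * theta, 10 * theta, 100 * theta, 10 * theta)
  rec <- laminar_recording(samples, 500, c("SO", "SP", "SR", "SLM"))
  expect_equal(select_theta_channel(rec), 3)
  # exact tie -> lowest index
  samples2 <- rbind(50 * theta, 50 * theta)
  rec2 <- laminar_recording(samples2, 500, c("SP", "SLM"))
  expect_equal(select_theta_channel(rec2), 1)
  expect_error(select_theta_channel(
    laminar_recording(matrix(0, 2, 1000), 500, c("SP", "SLM"))),
    "degenerate")
})

test_that("channel selection agrees with a bandpass-variance oracle", {
  g <- generate_laminar_lfp(lfp_sim_params(
    duration_s = 30, rate_hz = 500, n_channels = 8, state_dwell_s = 1e6,
    theta_amp_profile = c(5, 30, 12, 80, 45, 20, 60, 10),
    seed = 21))
  rec <- g$recording
  picked <- select_theta_channel(rec)
  oracle <- which.max(apply(rec$samples, 1, oracle_bandpass_variance,
                            rate_hz = 500, band = c(4, 12)))
  expect_equal(picked, oracle)
})

test_that("ratio track window arithmetic and band separation", {
  rec <- make_tone_recording(8, duration = 60)
  tr <- compute_ratio_track(rec, channel = 1)
  expect_equal(nrow(tr), 111)  # floor((60-5)/0.5)+1
  expect_true(all(tr$ratio > 100))
  rec1 <- make_tone_recording(1, duration = 30)
  tr1 <- compute_ratio_track(rec1, channel = 1)
  expect_true(all(tr1$ratio < 0.01))
  expect_error(compute_ratio_track(make_tone_recording(8, duration = 3),
                                   channel = 1),
               "insufficient")
})

test_that("per-window powers match a direct-DFT oracle within 1%", {
  g <- generate_laminar_lfp(lfp_sim_params(
    duration_s = 12, rate_hz = 400, n_channels = 1,
    layer_labels = "SLM", theta_amp_profile = 60, gamma_amp_profile = 10,
    delta_amp_profile = 40, state_dwell_s = 3, seed = 9))
  rec <- g$recording
  cfg <- lfp_analysis_config()
  tr <- compute_ratio_track(rec, cfg, channel = 1)
  for (i in c(1, 7, nrow(tr))) {
    idx <- round(tr$start_s[i] * 400 + 1):round(tr$end_s[i] * 400)
    o <- oracle_psd(rec$samples[1, idx], 400)
    th_o <- mean(o$psd[o$freq_hz >= 4 & o$freq_hz <= 12])
    de_o <- mean(o$psd[o$freq_hz >= 0.1 & o$freq_hz <= 4])
    expect_equal(tr$theta_power[i], th_o, tolerance = 0.01)
    expect_equal(tr$delta_power[i], de_o, tolerance = 0.01)
  }
})

test_that("bimodal threshold lands between well-separated mixture modes", {
  lr <- hippophys:::local_seed(42, c(rnorm(300, -1, 0.1),
                                     rnorm(300, 1, 0.1)))
  fit <- fit_bimodal_threshold(exp(lr))
  expect_gt(fit$log_threshold, -0.5)
  expect_lt(fit$log_threshold, 0.5)
  expect_true(fit$diagnostics$bimodal)
  # symmetric equal-variance crossing is the midpoint of the means
  expect_equal(hippophys:::gaussian_crossing(0.5, -1, 0.1, 0.5, 1, 0.1),
               0, tolerance = 1e-10)
})

test_that("degenerate ratio distributions fall back to Otsu with a warning", {
  expect_warning(
    fit <- fit_bimodal_threshold(rep(2, 100) * exp(rnorm(100, 0, 1e-4))),
    "unimodal")
  expect_equal(fit$diagnostics$method, "otsu_fallback")
  expect_error(fit_bimodal_threshold(rep(1, 10)), "at least 50")
})

test_that("interval extraction merges runs and respects bookkeeping", {
  # all supra-threshold -> one interval covering the session
  tr <- build_ratio_track(rep(10, 40))
  seg <- extract_mobility_intervals(tr, 1)
  expect_equal(nrow(seg$intervals), 1)
  expect_equal(seg$intervals$start_s, 0)
  expect_equal(seg$intervals$end_s, attr(tr, "duration_s"))
  expect_equal(seg$coverage_fraction, 1)
  # all sub-threshold -> empty
  seg0 <- extract_mobility_intervals(tr, 100)
  expect_equal(nrow(seg0$intervals), 0)
  expect_equal(seg0$coverage_fraction, 0)
  # isolated supra windows separated by > window_s -> one interval each
  ratios <- rep(0.1, 60)
  ratios[c(10, 30, 50)] <- 10
  seg1 <- extract_mobility_intervals(build_ratio_track(ratios), 1)
  expect_equal(nrow(seg1$intervals), 3)
  expect_equal(seg1$intervals$end_s - seg1$intervals$start_s, rep(5, 3))
  # intervals disjoint and ordered; mobility + rest = total
  ratios2 <- rep(0.1, 80)
  ratios2[c(5:12, 14, 20:26, 60:70)] <- 10
  seg2 <- extract_mobility_intervals(build_ratio_track(ratios2), 1)
  iv <- seg2$intervals
  expect_true(all(diff(iv$start_s) > 0))
  expect_true(all(iv$end_s[-nrow(iv)] < iv$start_s[-1]))
  expect_lt(sum(iv$end_s - iv$start_s), attr(tr, "duration_s") * 2)
  # every supra window lies inside an interval
  centers <- seg2$window_center_s[seg2$window_state]
  inside <- vapply(centers, function(c0) {
    any(c0 >= iv$start_s & c0 <= iv$end_s)
  }, logical(1))
  expect_true(all(inside))
})

test_that("band power obeys Parseval and band separation", {
  rec <- make_tone_recording(8, amp = 120, duration = 60)
  tr <- compute_ratio_track(rec, channel = 1)
  seg <- extract_mobility_intervals(tr, 0)  # full mobility
  bp <- band_power(rec, seg)
  theta <- bp$per_channel[bp$per_channel$band == "theta", ]
  expect_equal(theta$integrated, 120^2 / 2, tolerance = 0.01)
  # total integrated spectrum equals signal variance within 1%
  df <- bp$freq_hz[2] - bp$freq_hz[1]
  expect_equal(sum(bp$psd[1, ]) * df, var(rec$samples[1, ]),
               tolerance = 0.01)
  # out-of-band tone contributes < 1% to theta and gamma
  rec20 <- make_tone_recording(20, amp = 100, duration = 60)
  bp20 <- band_power(rec20,
                     extract_mobility_intervals(
                       compute_ratio_track(rec20, channel = 1), 0))
  tot <- sum(bp20$psd[1, ]) * df
  pc <- bp20$per_channel
  expect_lt(pc$integrated[pc$band == "theta"] / tot, 0.01)
  expect_lt(pc$integrated[pc$band == "gamma"] / tot, 0.01)
})

test_that("mains exclusion keeps gamma power stable under 50-Hz noise", {
  t <- seq.int(0, 60 * 500 - 1) / 500
  gamma <- 30 * sin(2 * pi * 60 * t)
  base <- laminar_recording(matrix(gamma, 1), 500, "SP")
  spiked <- laminar_recording(matrix(gamma + 300 * sin(2 * pi * 50 * t), 1),
                              500, "SP")
  seg <- extract_mobility_intervals(
    compute_ratio_track(base, channel = 1), 0)
  g0 <- band_power(base, seg)$per_channel
  g1 <- band_power(spiked, seg)$per_channel
  expect_equal(g1$integrated[g1$band == "gamma"],
               g0$integrated[g0$band == "gamma"], tolerance = 0.02)
})

test_that("gamma band power scales quadratically with injected amplitude", {
  bp_at <- function(k) {
    g <- generate_laminar_lfp(lfp_sim_params(
      duration_s = 30, rate_hz = 500, n_channels = 1,
      layer_labels = "SP", theta_amp_profile = 40,
      gamma_amp_profile = 20 * k, delta_amp_profile = 0,
      state_dwell_s = 1e6, noise_1overf_scale = 0, line_hz = 0,
      seed = 13))
    rec <- g$recording
    seg <- extract_mobility_intervals(
      compute_ratio_track(rec, channel = 1), 0)
    pc <- band_power(rec, seg)$per_channel
    pc$integrated[pc$band == "gamma"]
  }
  expect_equal(bp_at(2) / bp_at(1), 4, tolerance = 0.02)
})

test_that("session analysis recovers injected amplitudes and is deterministic", {
  p <- lfp_sim_params(duration_s = 60, rate_hz = 500, n_channels = 4,
                      layer_labels = c("SO", "SP", "SR", "SLM"),
                      state_dwell_s = 10, noise_1overf_scale = 1,
                      line_hz = 0, seed = 2)
  g <- generate_laminar_lfp(p)
  res1 <- suppressWarnings(analyze_session(g$recording))
  res2 <- suppressWarnings(analyze_session(g$recording))
  expect_identical(res1$summary$theta_slm, res2$summary$theta_slm)
  expect_identical(res1$segmentation$intervals, res2$segmentation$intervals)
  # with the ground-truth mobility windows, the injected 100-uV theta
  # tone at SLM is recovered as A^2/2 band-integrated power
  truth_runs <- rle(g$truth$state_track)
  ends <- cumsum(truth_runs$lengths) / 500
  starts <- c(0, ends[-length(ends)])
  iv <- data.frame(start_s = starts[truth_runs$values],
                   end_s = ends[truth_runs$values])
  iv <- iv[iv$end_s - iv$start_s >= 5, , drop = FALSE]
  seg <- structure(list(threshold = 1, intervals = iv,
                        coverage_fraction = sum(iv$end_s - iv$start_s) / 60,
                        duration_s = 60,
                        window_state = TRUE, window_center_s = 2.5),
                   class = "mobility_segmentation")
  bp <- band_power(g$recording, seg)
  expect_equal(bp$theta_slm, 100^2 / 2, tolerance = 0.05)
})

test_that("immobile-only sessions raise the no-mobility error", {
  rec <- make_tone_recording(1, duration = 40)  # delta only
  cfg <- lfp_analysis_config(threshold_method = "manual",
                             manual_threshold = 10)
  expect_error(analyze_session(rec, cfg), "no mobility")
})

test_that("density-power correlation matches the t-based critical value", {
  tab <- data.frame(cr_density = 1:10)
  tab$gamma_sp <- 2 * tab$cr_density + 1
  res <- correlate_density_power(tab, "gamma_sp")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p_two_tailed, 1e-12)
  # independent normals: |r| below the 5% critical value in ~95% of seeds
  frac <- mean(vapply(1:200, function(s) {
    xy <- hippophys:::local_seed(s, matrix(rnorm(56), ncol = 2))
    abs(cor(xy[, 1], xy[, 2])) < 0.374
  }, logical(1)))
  expect_gt(frac, 0.90)
  expect_lt(frac, 0.99)
  expect_error(correlate_density_power(
    data.frame(cr_density = rep(1, 5), gamma_sp = 1:5), "gamma_sp"),
    "constant")
})
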