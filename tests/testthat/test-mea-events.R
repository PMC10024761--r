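# MEA pipeline: noise estimation, discharge detection, the burst/seizure
# taxonomy with exact boundaries, slice assembly and cohort tables.

test_that("noise SD estimation uses a quiet window and slides past events", {
  rate <- 1000
  noise <- hippophys:::local_seed(1, rnorm(5 * rate, 0, 4))
  est <- estimate_noise_sd(noise, rate)
  expect_lt(abs(est$sd - 4) / 4, 0.1)
  expect_equal(est$window_s, c(0, 0.5))
  # all-zero trace is degenerate
  z <- estimate_noise_sd(rep(0, 2 * rate), rate)
  expect_equal(z$sd, 0)
  expect_true(z$degenerate)
  expect_error(detect_discharges(rep(0, rate), rate, z$sd), "degenerate")
  # event at 0.2 s, quiet afterwards: the window must move past it
  contaminated <- noise
  contaminated[round(0.2 * rate):round(0.45 * rate)] <- 400
  est2 <- estimate_noise_sd(contaminated, rate)
  expect_gte(est2$window_s[1], 0.45)
  # no quiet window at all: large discharges hit every candidate window
  busy <- hippophys:::local_seed(4, rnorm(4 * rate, 0, 1))
  busy[round(seq(0.1, 3.9, by = 0.2) * rate)] <- 500
  expect_error(estimate_noise_sd(busy, rate), "no quiet window")
})

test_that("discharge detection thresholds, merges and measures durations", {
  rate <- 1000
  noise <- hippophys:::local_seed(2, rnorm(20 * rate, 0, 2))
  expect_equal(nrow(detect_discharges(noise, rate, 2)), 0)
  # single 3-s event at 10x sd
  x <- noise
  ev <- round(5 * rate):round(8 * rate - 1)
  x[ev] <- 20 * sin(2 * pi * 9 * seq_along(ev) / rate) + 22
  d <- detect_discharges(x, rate, 2, electrode = 1L)
  expect_equal(nrow(d), 1)
  expect_equal(d$duration_s, 3, tolerance = 2 / rate / 3)
  # two excursions separated by 0.5 s merge into one discharge
  y <- rep(0.0, 10 * rate)
  y[(2 * rate):(3 * rate)] <- 30
  y[(3.5 * rate):(4.5 * rate)] <- 30
  y <- y + hippophys:::local_seed(3, rnorm(length(y), 0, 2))
  d2 <- detect_discharges(y, rate, 2)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$duration_s, 2.5, tolerance = 0.01)
})

test_that("burst/seizure boundary is exact to one sample", {
  rate <- 1000
  cfg <- mea_config()
  just_under <- build_discharges(0, 5 - 1 / rate)
  just_over <- build_discharges(0, 5)
  expect_equal(classify_events(just_under, cfg)$class, "burst")
  expect_equal(classify_events(just_over, cfg)$class, "seizure")
  expect_equal(classify_events(build_discharges(0, 3), cfg)$class,
               "burst")
  expect_equal(classify_events(build_discharges(0, 12), cfg)$class,
               "seizure")
})

test_that("seizure separation rule is exact at the 10-s gap", {
  rate <- 1000
  two <- build_discharges(c(0, 8 + 10), c(8, 6))       # gap exactly 10 s
  merged <- classify_events(two, mea_config())
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_s, 24)
  two_plus <- build_discharges(c(0, 8 + 10 + 1 / rate), c(8, 6))
  sep <- classify_events(two_plus, mea_config())
  expect_equal(nrow(sep), 2)
  two_minus <- build_discharges(c(0, 8 + 10 - 1 / rate), c(8, 6))
  expect_equal(nrow(classify_events(two_minus, mea_config())), 1)
  # 8-s and 6-s with 4-s gap -> one 18-s seizure; with 11-s gap -> two
  g4 <- classify_events(build_discharges(c(0, 12), c(8, 6)), mea_config())
  expect_equal(g4$duration_s, 18)
  g11 <- classify_events(build_discharges(c(0, 19), c(8, 6)), mea_config())
  expect_equal(nrow(g11), 2)
  # bursts inside a merged seizure span are absorbed
  mix <- rbind(build_discharges(c(0, 17), c(8, 6)),
               build_discharges(10, 2))
  out <- classify_events(mix, mea_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$class, "seizure")
})

test_that("slice seizures are assembled with initiation and involvement", {
  rmap <- default_region_map(c(2, 6))
  dg_el <- rmap$electrode[rmap$region == "DG"][1]
  ca3_el <- rmap$electrode[rmap$region == "CA3"][1]
  ev <- rbind(
    cbind(build_discharges(10.00, 8, electrode = dg_el, slope = 2),
          class = "seizure"),
    cbind(build_discharges(10.05, 8, electrode = ca3_el, slope = 5),
          class = "seizure"))
  sz <- assemble_slice_seizures(ev, rmap)
  expect_equal(nrow(sz), 1)
  expect_equal(sz$initiating_region, "DG")
  expect_equal(sz$initiating_compartment, "hippocampal formation")
  expect_equal(sz$involved_regions, "CA3,DG")
  # identical onsets: the larger initial slope wins
  ev2 <- rbind(
    cbind(build_discharges(10, 8, electrode = dg_el, slope = 2),
          class = "seizure"),
    cbind(build_discharges(10, 8, electrode = ca3_el, slope = 5),
          class = "seizure"))
  expect_equal(assemble_slice_seizures(ev2, rmap)$initiating_region,
               "CA3")
  # slope tie as well: lower electrode index
  ev3 <- rbind(
    cbind(build_discharges(10, 8, electrode = 5, slope = 2),
          class = "seizure"),
    cbind(build_discharges(10, 8, electrode = 3, slope = 2),
          class = "seizure"))
  expect_equal(assemble_slice_seizures(ev3, rmap)$initiating_electrode, 3)
  # unmapped electrode errors
  expect_error(assemble_slice_seizures(
    cbind(build_discharges(1, 8, electrode = 99), class = "seizure"),
    rmap), "missing from region_map")
})

test_that("slice summary arithmetic and classes", {
  sz <- data.frame(onset_s = c(10, 100, 300), offset_s = c(40, 130, 320),
                   duration_s = c(30, 30, 20),
                   initiating_electrode = 1,
                   initiating_region = c("DG", "CA3", "Ent"),
                   initiating_compartment = c("hippocampal formation",
                                              "hippocampal formation",
                                              "cortex"),
                   n_electrodes = 2,
                   involved_regions = c("CA3,DG", "CA3", "CA3,DG,Ent"),
                   stringsAsFactors = FALSE)
  rep_ <- summarize_slice(sz, NULL, 600)
  expect_equal(rep_$seizure_freq_per_min, 0.3)
  expect_equal(rep_$activity_class, "seizure")
  expect_equal(unname(rep_$propagation_fractions["CA3"]), 1)
  expect_equal(unname(rep_$propagation_fractions["DG"]), 2 / 3)
  expect_equal(unname(rep_$initiation_counts$compartment["cortex"]), 1)
  bursts <- data.frame(onset_s = 1, offset_s = 2, n_electrodes = 1)
  rep2 <- summarize_slice(sz[0, ], bursts, 600)
  expect_equal(rep2$activity_class, "bursting")
  expect_true(is.na(rep2$mean_seizure_duration_s))
})

test_that("synthetic slices are recovered end to end", {
  recovered <- vapply(1:5, function(s) {
    p <- mea_sim_params(duration_s = 60, rate_hz = 2000,
                        grid_shape = c(2, 6),
                        seizure_rate_per_min = 1, burst_rate_per_min = 2,
                        seizure_duration_s = 15,
                        initiation_region = "CA3", seed = s)
    g <- generate_mea_recording(p)
    res <- analyze_mea_slice(g$recording)
    truth_sz <- sum(g$truth$events$class == "seizure")
    truth_b <- sum(g$truth$events$class == "burst")
    res$report$n_seizures == truth_sz &&
      res$report$n_bursts == truth_b &&
      (truth_sz == 0 ||
         all(res$seizures$initiating_region == "CA3"))
  }, logical(1))
  expect_true(all(recovered))
})

test_that("cohort contingency reproduces the slice-class Fisher test", {
  mk_report <- function(n_seiz) {
    sz <- if (n_seiz > 0) {
      data.frame(onset_s = seq_len(n_seiz) * 30,
                 offset_s = seq_len(n_seiz) * 30 + 20,
                 duration_s = 20, initiating_electrode = 1,
                 initiating_region = "CA3",
                 initiating_compartment = "hippocampal formation",
                 n_electrodes = 1, involved_regions = "CA3",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(onset_s = numeric(0), offset_s = numeric(0),
                 duration_s = numeric(0),
                 initiating_electrode = integer(0),
                 initiating_region = character(0),
                 initiating_compartment = character(0),
                 n_electrodes = integer(0),
                 involved_regions = character(0), stringsAsFactors = FALSE)
    }
    summarize_slice(sz, NULL, 600)
  }
  reports <- c(lapply(c(1, 1, 1, rep(0, 17)), mk_report),
               lapply(c(rep(1, 11), rep(0, 9)), mk_report))
  genotypes <- rep(c("control", "mutant"), each = 20)
  cc <- cohort_contingency(reports, genotypes)
  expect_equal(cc$slice_class$table["seizure", "control"], 3)
  expect_equal(cc$slice_class$table["seizure", "mutant"], 11)
  expect_equal(cc$slice_class$test$p_value, 0.0187, tolerance = 1e-3)
})
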