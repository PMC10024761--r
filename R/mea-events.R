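# MEA discharge detection, burst/seizure taxonomy, slice-level seizure
# assembly with initiation and propagation mapping, and cohort contingency
# statistics.

#' Configuration for MEA event analysis
#'
#' @param noise_window_s Length of the noise-estimation window (default
#'   0.5 s, taken from the start of the recording when quiet).
#' @param threshold_factor Detection threshold as a multiple of the noise
#'   SD (default 5).
#' @param burst_seizure_boundary_s Duration separating bursts from
#'   seizure-like events (default 5 s; a discharge lasting exactly 5 s is
#'   classified as a seizure so the rule is a half-open partition).
#' @param separation_gap_s Minimum silent/bursting interval between
#'   successive seizures for them to count as separate events (default
#'   10 s; gaps of exactly 10 s are merged).
#' @param intra_discharge_merge_gap_s Threshold-crossing gaps up to this
#'   long are merged into a single discharge (default 1 s), standing in
#'   for the operator's visual check on oscillatory discharges.
#' @param quiet_window_peak_factor A candidate noise window qualifies as
#'   "free of electrical activity" when its peak absolute amplitude is
#'   below this multiple of the whole-trace robust scale (default 5).
#' @param min_duration_s Discharges shorter than this are discarded as
#'   isolated noise excursions (default 0.05 s); epileptiform discharges
#'   are oscillatory events far longer than single threshold crossings.
#' @return An object of class `"mea_config"`.
#' @export
mea_config <- function(noise_window_s = 0.5,
                       threshold_factor = 5,
                       burst_seizure_boundary_s = 5,
                       separation_gap_s = 10,
                       intra_discharge_merge_gap_s = 1,
                       quiet_window_peak_factor = 5,
                       min_duration_s = 0.05) {
  for (nm in c("noise_window_s", "threshold_factor",
               "burst_seizure_boundary_s", "separation_gap_s",
               "intra_discharge_merge_gap_s", "quiet_window_peak_factor")) {
    check_positive(get(nm), nm)
  }
  if (separation_gap_s <= burst_seizure_boundary_s) {
    stop_config("separation_gap_s",
                "must exceed the burst/seizure boundary")
  }
  structure(list(
    noise_window_s = noise_window_s, threshold_factor = threshold_factor,
    burst_seizure_boundary_s = burst_seizure_boundary_s,
    separation_gap_s = separation_gap_s,
    intra_discharge_merge_gap_s = intra_discharge_merge_gap_s,
    quiet_window_peak_factor = quiet_window_peak_factor,
    min_duration_s = min_duration_s
  ), class = "mea_config")
}

#' Estimate the noise SD on a quiet window
#'
#' Uses the first `noise_window_s` of the trace when its peak absolute
#' amplitude stays below `quiet_window_peak_factor` times the whole-trace
#' robust scale (median absolute deviation); otherwise the window slides
#' forward in 100-ms steps to the first qualifying stretch.
#'
#' @param trace Numeric vector (one electrode, uV).
#' @param rate_hz Sampling rate.
#' @param cfg An [mea_config()].
#' @return List with `sd`, `window_s` (`c(start, end)` of the window
#'   used), and `degenerate` (`TRUE` for an all-zero trace).
#' @export
estimate_noise_sd <- function(trace, rate_hz, cfg = mea_config()) {
  wlen <- round(cfg$noise_window_s * rate_hz)
  if (length(trace) < wlen) {
    stop("trace shorter than the noise window", call. = FALSE)
  }
  if (all(trace == 0)) {
    return(list(sd = 0, window_s = c(0, cfg$noise_window_s),
                degenerate = TRUE))
  }
  robust <- stats::mad(trace)
  if (robust == 0) robust <- stats::sd(trace)
  step <- round(0.1 * rate_hz)
  starts <- seq.int(1L, length(trace) - wlen + 1L, by = step)
  for (s in starts) {
    w <- trace[s:(s + wlen - 1L)]
    if (max(abs(w)) < cfg$quiet_window_peak_factor * robust) {
      return(list(sd = stats::sd(w),
                  window_s = c((s - 1L), (s - 1L + wlen)) / rate_hz,
                  degenerate = FALSE))
    }
  }
  stop("no quiet window free of electrical activity found", call. = FALSE)
}

#' Detect supra-threshold discharges on one electrode
#'
#' Flags samples with `|x| > threshold_factor * sd` and merges
#' supra-threshold excursions separated by gaps of at most
#' `intra_discharge_merge_gap_s` into single discharges. Onset is the
#' first crossing, offset the last sub-threshold return.
#'
#' @param trace Numeric vector (uV).
#' @param rate_hz Sampling rate.
#' @param sd Noise SD from [estimate_noise_sd()]; must be positive.
#' @param cfg An [mea_config()].
#' @param electrode Electrode index recorded on the output rows.
#' @return Data frame of discharges: `electrode`, `onset_s`, `offset_s`,
#'   `duration_s`, `peak_uv`, `onset_slope_uv_ms`.
#' @export
detect_discharges <- function(trace, rate_hz, sd, cfg = mea_config(),
                              electrode = NA_integer_) {
  if (!is.finite(sd) || sd <= 0) {
    stop("degenerate threshold: noise sd must be positive", call. = FALSE)
  }
  thr <- cfg$threshold_factor * sd
  idx <- which(abs(trace) > thr)
  empty <- data.frame(electrode = integer(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      peak_uv = numeric(0), onset_slope_uv_ms = numeric(0))
  if (length(idx) == 0L) return(empty)
  gap_samples <- cfg$intra_discharge_merge_gap_s * rate_hz
  brk <- which(diff(idx) > gap_samples)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  slope_win <- max(2L, round(0.02 * rate_hz))
  out <- data.frame(
    electrode = electrode,
    onset_s = (starts - 1L) / rate_hz,
    offset_s = ends / rate_hz,
    duration_s = (ends - starts + 1L) / rate_hz,
    peak_uv = vapply(seq_along(starts), function(k) {
      max(abs(trace[starts[k]:ends[k]]))
    }, numeric(1)),
    onset_slope_uv_ms = vapply(seq_along(starts), function(k) {
      j <- starts[k]:min(ends[k], starts[k] + slope_win)
      if (length(j) < 2L) return(0)
      max(abs(diff(trace[j]))) * rate_hz / 1000
    }, numeric(1))
  )
  out[out$duration_s >= cfg$min_duration_s, , drop = FALSE]
}

#' Classify discharges into bursts and seizure-like events
#'
#' Discharges shorter than the 5-s boundary are bursts; those lasting 5 s
#' or longer are seizures. Successive seizures separated by a gap of at
#' most `separation_gap_s` (silent or bursting activity in between) are
#' merged into a single seizure spanning both; bursts falling inside a
#' merged seizure span are absorbed into it.
#'
#' @param discharges Data frame from [detect_discharges()], ordered by
#'   onset.
#' @param cfg An [mea_config()].
#' @return The input with a `class` column, after seizure merging.
#' @export
classify_events <- function(discharges, cfg = mea_config()) {
  d <- discharges[order(discharges$onset_s), , drop = FALSE]
  d$class <- ifelse(d$duration_s >= cfg$burst_seizure_boundary_s,
                    "seizure", "burst")
  if (sum(d$class == "seizure") > 1L) {
    sz <- which(d$class == "seizure")
    merged <- list()
    cur <- d[sz[1], , drop = FALSE]
    for (i in sz[-1]) {
      gap <- d$onset_s[i] - cur$offset_s
      if (gap <= cfg$separation_gap_s) {
        cur$offset_s <- max(cur$offset_s, d$offset_s[i])
        cur$peak_uv <- max(cur$peak_uv, d$peak_uv[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- d[i, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    sz_df <- do.call(rbind, merged)
    sz_df$duration_s <- sz_df$offset_s - sz_df$onset_s
    bursts <- d[d$class == "burst", , drop = FALSE]
    if (nrow(bursts)) {
      inside <- vapply(seq_len(nrow(bursts)), function(k) {
        any(bursts$onset_s[k] >= sz_df$onset_s &
              bursts$offset_s[k] <= sz_df$offset_s)
      }, logical(1))
      bursts <- bursts[!inside, , drop = FALSE]
    }
    d <- rbind(bursts, sz_df)
    d <- d[order(d$onset_s), , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

compartment_of <- function(region) {
  ifelse(region %in% HIPPOCAMPAL_REGIONS, "hippocampal formation",
         ifelse(region %in% c("Ent", "PRh/Ect"), "cortex", NA_character_))
}

# group events (rows sorted by onset) by temporal overlap
group_by_overlap <- function(ev) {
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  group <- integer(nrow(ev))
  g <- 0L
  cur_end <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$onset_s[i] < cur_end) {
      group[i] <- g
      cur_end <- max(cur_end, ev$offset_s[i])
    } else {
      g <- g + 1L
      group[i] <- g
      cur_end <- ev$offset_s[i]
    }
  }
  split(ev, group)
}

#' Assemble slice-level seizures from per-electrode events
#'
#' Per-electrode seizure-class events with overlapping time spans are
#' grouped into one slice-level seizure. The initiating electrode is the
#' one with the earliest onset (ties broken by larger initial peak slope,
#' then by lower electrode index); the involved subregions are those of
#' all grouped electrodes, and the initiating compartment follows the
#' hippocampal-formation / cortex split (DG, CA3, CA1, Sub vs Ent,
#' PRh/Ect).
#'
#' @param events Data frame of labelled per-electrode events (from
#'   [classify_events()], row-bound across electrodes) with an
#'   `electrode` column.
#' @param region_map Electrode-to-subregion data frame.
#' @param cfg An [mea_config()].
#' @return Data frame of slice seizures: `onset_s`, `offset_s`,
#'   `duration_s`, `initiating_electrode`, `initiating_region`,
#'   `initiating_compartment`, `n_electrodes`, and `involved_regions`
#'   (comma-separated, alphabetical).
#' @export
assemble_slice_seizures <- function(events, region_map,
                                    cfg = mea_config()) {
  sz <- events[events$class == "seizure", , drop = FALSE]
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0),
                      initiating_electrode = integer(0),
                      initiating_region = character(0),
                      initiating_compartment = character(0),
                      n_electrodes = integer(0),
                      involved_regions = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sz) == 0L) return(empty)
  missing_el <- setdiff(unique(sz$electrode), region_map$electrode)
  if (length(missing_el)) {
    stop(sprintf("electrode(s) %s missing from region_map",
                 paste(missing_el, collapse = ", ")), call. = FALSE)
  }
  region_of <- function(el) {
    region_map$region[match(el, region_map$electrode)]
  }
  groups <- group_by_overlap(sz)
  do.call(rbind, lapply(groups, function(g) {
    first <- g[g$onset_s == min(g$onset_s), , drop = FALSE]
    if (nrow(first) > 1L) {
      first <- first[order(-first$onset_slope_uv_ms, first$electrode), ,
                     drop = FALSE]
    }
    init_el <- first$electrode[1]
    init_reg <- region_of(init_el)
    regions <- sort(unique(region_of(g$electrode)))
    data.frame(
      onset_s = min(g$onset_s),
      offset_s = max(g$offset_s),
      duration_s = max(g$offset_s) - min(g$onset_s),
      initiating_electrode = init_el,
      initiating_region = init_reg,
      initiating_compartment = compartment_of(init_reg),
      n_electrodes = length(unique(g$electrode)),
      involved_regions = paste(regions, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

#' Summarise slice-level activity
#'
#' @param seizures Slice-seizure data frame from
#'   [assemble_slice_seizures()].
#' @param bursts Data frame of slice-level bursts (per-electrode bursts
#'   grouped by overlap; may be the per-electrode table).
#' @param duration_s Recording duration in seconds.
#' @return A `slice_report` list: `activity_class` (`"seizure"`,
#'   `"bursting"` or `"silent"`), counts, `seizure_freq_per_min`,
#'   `mean_seizure_duration_s`, `propagation_fractions` (per subregion,
#'   fraction of seizures involving it), and `initiation_counts` per
#'   subregion and compartment.
#' @export
summarize_slice <- function(seizures, bursts, duration_s) {
  check_positive(duration_s, "duration_s")
  n_seiz <- nrow(seizures)
  n_burst <- if (is.null(bursts)) 0L else nrow(bursts)
  activity <- if (n_seiz > 0) "seizure" else
    if (n_burst > 0) "bursting" else "silent"
  prop <- setNames(rep(0, length(MEA_REGIONS)), MEA_REGIONS)
  init_reg <- setNames(rep(0L, length(MEA_REGIONS)), MEA_REGIONS)
  init_comp <- c("hippocampal formation" = 0L, cortex = 0L)
  if (n_seiz > 0) {
    inv <- strsplit(seizures$involved_regions, ",", fixed = TRUE)
    for (r in MEA_REGIONS) {
      prop[r] <- mean(vapply(inv, function(v) r %in% v, logical(1)))
    }
    t1 <- table(seizures$initiating_region)
    init_reg[names(t1)] <- as.integer(t1)
    t2 <- table(seizures$initiating_compartment)
    init_comp[names(t2)] <- as.integer(t2)
  }
  structure(list(
    activity_class = activity,
    n_bursts = n_burst,
    n_seizures = n_seiz,
    seizure_freq_per_min = n_seiz / (duration_s / 60),
    mean_seizure_duration_s = if (n_seiz > 0) mean(seizures$duration_s)
      else NA_real_,
    propagation_fractions = prop,
    initiation_counts = list(region = init_reg, compartment = init_comp)
  ), class = "slice_report")
}

#' Full MEA slice analysis
#'
#' Runs noise estimation, discharge detection and burst/seizure
#' classification on every electrode, assembles slice-level seizures and
#' bursts, and summarises the slice. Electrodes whose noise estimate is
#' degenerate (flat trace) are skipped.
#'
#' @param rec An `mea_recording`.
#' @param cfg An [mea_config()].
#' @return List with `events` (per-electrode labelled events),
#'   `seizures` (slice level), `bursts` (slice level), and `report`
#'   (a `slice_report`).
#' @export
analyze_mea_slice <- function(rec, cfg = mea_config()) {
  stopifnot(inherits(rec, "mea_recording"))
  per_el <- lapply(seq_len(nrow(rec$traces)), function(el) {
    ns <- estimate_noise_sd(rec$traces[el, ], rec$rate_hz, cfg)
    if (ns$degenerate || ns$sd <= 0) return(NULL)
    d <- detect_discharges(rec$traces[el, ], rec$rate_hz, ns$sd, cfg,
                           electrode = el)
    if (nrow(d) == 0L) return(NULL)
    classify_events(d, cfg)
  })
  events <- do.call(rbind, per_el)
  duration_s <- ncol(rec$traces) / rec$rate_hz
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(electrode = integer(0), onset_s = numeric(0),
                         offset_s = numeric(0), duration_s = numeric(0),
                         peak_uv = numeric(0),
                         onset_slope_uv_ms = numeric(0),
                         class = character(0), stringsAsFactors = FALSE)
  }
  seizures <- assemble_slice_seizures(events, rec$region_map, cfg)
  bursts_el <- events[events$class == "burst", , drop = FALSE]
  bursts <- if (nrow(bursts_el)) {
    do.call(rbind, lapply(group_by_overlap(bursts_el), function(g) {
      data.frame(onset_s = min(g$onset_s), offset_s = max(g$offset_s),
                 n_electrodes = length(unique(g$electrode)))
    }))
  } else {
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               n_electrodes = integer(0))
  }
  report <- summarize_slice(seizures, bursts, duration_s)
  list(events = events, seizures = seizures, bursts = bursts,
       report = report)
}

#' Cohort contingency tables and tests
#'
#' Builds the 2 x 2 slice-class table (seizure vs non-seizure by genotype,
#' Fisher's exact test), the seizure-initiation compartment table
#' (hippocampal formation vs cortex by genotype, Fisher) and the
#' per-subregion initiation table (chi-square) from per-slice reports.
#'
#' @param reports List of `slice_report` objects.
#' @param genotypes Character vector (`"control"`/`"mutant"`), one per
#'   report.
#' @return List with `slice_class` (table + `test`),
#'   `initiation_compartment` (table + `test`) and
#'   `initiation_subregion` (table + `test`).
#' @export
cohort_contingency <- function(reports, genotypes) {
  stopifnot(length(reports) == length(genotypes))
  groups <- unique(genotypes)
  if (length(groups) < 2L) {
    stop("need at least one slice per genotype group", call. = FALSE)
  }
  has_seizure <- vapply(reports, function(r) r$n_seizures > 0, logical(1))
  slice_tab <- rbind(
    vapply(groups, function(g) sum(has_seizure[genotypes == g]), 0),
    vapply(groups, function(g) sum(!has_seizure[genotypes == g]), 0)
  )
  dimnames(slice_tab) <- list(c("seizure", "no_seizure"), groups)
  comp_tab <- vapply(groups, function(g) {
    Reduce(`+`, lapply(reports[genotypes == g],
                       function(r) r$initiation_counts$compartment))
  }, numeric(2))
  reg_tab <- vapply(groups, function(g) {
    Reduce(`+`, lapply(reports[genotypes == g],
                       function(r) r$initiation_counts$region))
  }, numeric(length(MEA_REGIONS)))
  list(
    slice_class = list(table = slice_tab,
                       test = fisher_exact_2x2(t(slice_tab))),
    initiation_compartment = list(
      table = comp_tab,
      test = fisher_exact_2x2(t(comp_tab))),
    initiation_subregion = list(
      table = reg_tab,
      # degenerate when fewer than two subregions ever initiate
      test = tryCatch(
        suppressWarnings(
          chi_square(t(reg_tab[rowSums(reg_tab) > 0, , drop = FALSE]))),
        error = function(e) NULL))
  )
}
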