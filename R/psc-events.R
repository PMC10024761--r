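# Threshold-based detection of spontaneous post-synaptic currents, event
# summaries and intrinsic membrane properties.

#' Configuration for PSC detection
#'
#' @param filter_cutoff_hz Low-pass cutoff for the zero-phase 4th-order
#'   Butterworth filter applied before detection (default 3000 Hz).
#' @param threshold_factor Detection threshold as a multiple of the
#'   baseline SD (default 2).
#' @param analysis_window_s Window over which event frequency is computed
#'   (default 240 s, i.e. a 4-min recording period).
#' @param amplitude_n_events Number of (chronologically first) events
#'   averaged for the amplitude summary (default 100).
#' @param smooth_ms Light moving-average smoothing (ms) applied only when
#'   scanning the rising phase for secondary peaks, so single noisy
#'   kernels are not broken up.
#' @param min_width_ms A deflection must stay above threshold for at
#'   least this long (default 2 ms, on the order of the rise time) to
#'   count as a synaptic event; at a 2 x SD threshold brief noise
#'   excursions cross constantly and would otherwise swamp detection.
#' @return An object of class `"psc_config"`.
#' @export
psc_config <- function(filter_cutoff_hz = 3000,
                       threshold_factor = 2,
                       analysis_window_s = 240,
                       amplitude_n_events = 100,
                       smooth_ms = 0.3,
                       min_width_ms = 2) {
  check_positive(filter_cutoff_hz, "filter_cutoff_hz")
  check_positive(threshold_factor, "threshold_factor")
  check_positive(analysis_window_s, "analysis_window_s")
  structure(list(
    filter_cutoff_hz = filter_cutoff_hz,
    threshold_factor = threshold_factor,
    analysis_window_s = analysis_window_s,
    amplitude_n_events = amplitude_n_events,
    smooth_ms = smooth_ms,
    min_width_ms = min_width_ms
  ), class = "psc_config")
}

#' Construct a current-trace container
#'
#' @param samples Numeric vector (pA).
#' @param rate_hz Sampling rate (samples/s).
#' @param holding_mv Holding potential (mV); also used to infer polarity
#'   when `polarity = "auto"` (negative for holding <= -30 mV).
#' @param polarity `"negative"`, `"positive"`, or `"auto"`.
#' @param cell_id Cell identifier.
#' @return An object of class `"current_trace"`.
#' @export
current_trace <- function(samples, rate_hz, holding_mv = -60,
                          polarity = "auto", cell_id = "cell") {
  check_positive(rate_hz, "rate_hz")
  if (!all(is.finite(samples))) stop_config("samples", "must be finite")
  if (polarity == "auto") {
    polarity <- if (holding_mv <= -30) "negative" else "positive"
  }
  structure(list(samples = samples, rate_hz = rate_hz,
                 holding_mv = holding_mv, polarity = polarity,
                 cell_id = cell_id), class = "current_trace")
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  sm <- stats::filter(c(rep(x[1], k), x, rep(x[length(x)], k)),
                      rep(1 / k, k), sides = 2)
  as.numeric(sm[(k + 1L):(k + length(x))])
}

#' Detect post-synaptic current events
#'
#' The trace is low-pass filtered (zero-phase 4th-order Butterworth at
#' `filter_cutoff_hz`), and the baseline SD is estimated robustly, then
#' re-estimated once after excising initial detections. Deflections in
#' the configured polarity exceeding `threshold_factor` x SD become
#' events with time at the threshold crossing and amplitude as the
#' absolute difference between the peak and the local pre-event baseline.
#' Overlapping deflections within one supra-threshold stretch are
#' separated only when the trace descends at least 50% of the way from
#' the previous peak back toward the threshold. Events with a secondary
#' local maximum (prominence above half the threshold) strictly between
#' onset and peak are moved to the excluded list with reason
#' `"second peak in rising phase"`.
#'
#' @param trace A `current_trace`.
#' @param cfg A [psc_config()].
#' @return A `psc_train` list: `events` (`time_s`, `peak_s`,
#'   `amplitude_pa`), `excluded_events` (`time_s`, `reason`),
#'   `baseline_sd_pa`, `threshold_pa`, `polarity`.
#' @export
detect_psc <- function(trace, cfg = psc_config()) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  rate <- trace$rate_hz
  if (stats::sd(x) == 0) {
    stop("degenerate baseline: trace has zero variance", call. = FALSE)
  }
  if (cfg$filter_cutoff_hz < rate / 2) {
    bf <- signal::butter(4, cfg$filter_cutoff_hz / (rate / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  sgn <- if (trace$polarity == "negative") -1 else 1
  d <- sgn * (x - stats::median(x))

  min_width <- max(2L, round(cfg$min_width_ms / 1000 * rate))
  # supra-threshold runs: keep runs at least min_width long (brief noise
  # excursions are not events), then coalesce qualifying runs separated
  # by sub-threshold gaps shorter than min_width (noise dither around
  # the crossing on an event's decay)
  qualifying_runs <- function(flag) {
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    up <- which(r$values & r$lengths >= min_width)
    if (!length(up)) return(NULL)
    rs <- s[up]; re <- e[up]
    if (length(up) > 1L) {
      merged_s <- rs[1]; merged_e <- re[1]
      out_s <- c(); out_e <- c()
      for (k in seq_along(up)[-1]) {
        if (rs[k] - merged_e - 1L < min_width) {
          merged_e <- re[k]
        } else {
          out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
          merged_s <- rs[k]; merged_e <- re[k]
        }
      }
      rs <- c(out_s, merged_s); re <- c(out_e, merged_e)
    }
    cbind(start = rs, end = re)
  }

  sd0 <- stats::mad(d)
  if (sd0 == 0) sd0 <- stats::sd(d)
  thr0 <- cfg$threshold_factor * sd0
  # excise initial detections (with margins) and re-estimate once
  margin_pre <- round(0.01 * rate)
  margin_post <- round(0.05 * rate)
  excised <- logical(length(d))
  runs0 <- qualifying_runs(d > thr0)
  if (!is.null(runs0)) {
    for (k in seq_len(nrow(runs0))) {
      excised[max(1L, runs0[k, 1] - margin_pre):
                min(length(d), runs0[k, 2] + margin_post)] <- TRUE
    }
  }
  base_sd <- if (all(excised)) sd0 else stats::sd(d[!excised])
  thr <- cfg$threshold_factor * base_sd

  supra <- d > thr
  out_empty <- structure(list(
    events = data.frame(time_s = numeric(0), peak_s = numeric(0),
                        amplitude_pa = numeric(0)),
    excluded_events = data.frame(time_s = numeric(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE),
    baseline_sd_pa = base_sd, threshold_pa = thr,
    polarity = trace$polarity), class = "psc_train")
  runs2 <- qualifying_runs(supra)
  if (is.null(runs2)) return(out_empty)
  starts <- runs2[, 1]
  ends <- runs2[, 2]
  runs <- seq_len(nrow(runs2))
  ksm <- max(1L, round(cfg$smooth_ms / 1000 * rate))
  ds <- moving_average(d, ksm)
  # heavier smoothing for the rising-phase scan: shoulders from a second
  # kernel are ms-scale, noise ripple is sample-scale
  drise <- moving_average(d, max(ksm, round(0.001 * rate)))

  events <- list(); excluded <- list()
  baseline_at <- function(i0) {
    lo <- max(1L, i0 - round(0.015 * rate))
    hi <- max(1L, i0 - round(0.005 * rate))
    w <- lo:hi
    w <- w[!supra[w]]
    if (length(w) < 3L) 0 else stats::median(d[w])
  }
  for (run in runs) {
    i0 <- starts[run]; i1 <- ends[run]
    seg <- ds[i0:i1]
    # split the stretch where it re-approaches threshold by >= 50% of the
    # preceding peak height above threshold
    split_pts <- integer(0)
    cur_peak <- seg[1]
    armed_valley <- NA_integer_
    for (j in seq_along(seg)[-1]) {
      if (seg[j] > cur_peak) {
        cur_peak <- seg[j]
        armed_valley <- NA_integer_
      } else if (seg[j] <= thr + 0.5 * (cur_peak - thr)) {
        if (is.na(armed_valley) || seg[j] < seg[armed_valley]) {
          armed_valley <- j
        }
      }
      if (!is.na(armed_valley) && j > armed_valley &&
          seg[j] > seg[armed_valley] + 0.5 * (cur_peak - thr)) {
        split_pts <- c(split_pts, armed_valley)
        cur_peak <- seg[j]
        armed_valley <- NA_integer_
      }
    }
    bounds <- c(1L, split_pts, length(seg) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      a0 <- i0 + bounds[b] - 1L
      a1 <- i0 + bounds[b + 1L] - 2L
      pk_rel <- which.max(drise[a0:a1])
      pk <- a0 + pk_rel - 1L
      onset_t <- (a0 - 1L) / rate
      # peak read on the lightly smoothed trace: taking the raw argmax
      # value would add the expected maximum of the noise at the peak
      amp <- drise[pk] - baseline_at(a0)
      # secondary maximum in the rising phase? require prominence on both
      # sides (a rise out of the preceding valley and a genuine descent
      # toward the absolute peak) and at least 1 ms of separation, so
      # noise ripple on a monotone rise cannot trigger the exclusion
      double_peak <- FALSE
      min_sep <- round(0.001 * rate)
      if (pk - a0 >= 3L) {
        rp <- drise[a0:pk]
        nrp <- length(rp)
        if (nrp >= 3L) {
          loc_max <- which(rp[2:(nrp - 1L)] > rp[1:(nrp - 2L)] &
                             rp[2:(nrp - 1L)] >= rp[3:nrp]) + 1L
          loc_max <- loc_max[nrp - loc_max >= min_sep]
          for (m in loc_max) {
            left_prom <- rp[m] - min(rp[seq_len(m)])
            right_prom <- rp[m] - min(rp[m:nrp])
            rise_after <- rp[nrp] - min(rp[m:nrp])
            if (left_prom > 0.5 * thr && right_prom > 0.5 * thr &&
                rise_after > 0.5 * thr) {
              double_peak <- TRUE
              break
            }
          }
        }
      }
      if (double_peak) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          time_s = onset_t, reason = "second peak in rising phase",
          stringsAsFactors = FALSE)
      } else {
        events[[length(events) + 1L]] <- data.frame(
          time_s = onset_t, peak_s = (pk - 1L) / rate,
          amplitude_pa = amp)
      }
    }
  }
  structure(list(
    events = if (length(events)) do.call(rbind, events) else
      out_empty$events,
    excluded_events = if (length(excluded)) do.call(rbind, excluded) else
      out_empty$excluded_events,
    baseline_sd_pa = base_sd, threshold_pa = thr,
    polarity = trace$polarity), class = "psc_train")
}

#' Summarise a detected PSC train
#'
#' Frequency is the count of all detected events over the analysis window
#' (default 4 min), including events excluded from the amplitude analysis
#' by the rising-phase rule; amplitude is the mean over the first
#' `amplitude_n_events` retained events chronologically (all of them,
#' with `few_events = TRUE`, if fewer were detected).
#'
#' @param train A `psc_train` from [detect_psc()].
#' @param cfg A [psc_config()].
#' @return A `psc_summary` list: `frequency_hz`, `mean_amplitude_pa`,
#'   `n_detected` (all detections), `n_retained`, `few_events`.
#' @export
summarize_psc <- function(train, cfg = psc_config()) {
  stopifnot(inherits(train, "psc_train"))
  n_keep <- nrow(train$events)
  n_all <- n_keep + nrow(train$excluded_events)
  k <- min(n_keep, cfg$amplitude_n_events)
  structure(list(
    frequency_hz = n_all / cfg$analysis_window_s,
    mean_amplitude_pa = if (k > 0)
      mean(train$events$amplitude_pa[seq_len(k)]) else NA_real_,
    n_detected = n_all,
    n_retained = n_keep,
    few_events = n_keep < cfg$amplitude_n_events
  ), class = "psc_summary")
}

#' Intrinsic membrane properties from current-clamp steps
#'
#' RMP is the mean of the 0-pA trace; input resistance comes from the
#' steady-state voltage deflection (last 200 ms of the step vs the
#' pre-step baseline) of the -10-pA hyperpolarising step; the F-I curve
#' counts spikes per step as upward 0-mV crossings with at least 1 ms
#' refractory separation.
#'
#' @param vm_traces List of numeric membrane-potential traces (mV), one
#'   per current step.
#' @param currents_pa Injected current (pA) per trace; must include 0 and
#'   -10.
#' @param rate_hz Sampling rate (samples/s).
#' @param step_on_s Step onset time within each trace (s).
#' @param step_dur_s Step duration (default 1 s).
#' @return List with `rmp_mv`, `input_resistance_mohm`, and `fi_curve`
#'   (data frame `current_pa`, `n_spikes`).
#' @export
intrinsic_properties <- function(vm_traces, currents_pa, rate_hz,
                                 step_on_s = 0.5, step_dur_s = 1) {
  stopifnot(length(vm_traces) == length(currents_pa))
  if (!0 %in% currents_pa || !(-10) %in% currents_pa) {
    stop("need both a 0-pA and a -10-pA step", call. = FALSE)
  }
  idx0 <- which(currents_pa == 0)[1]
  idxh <- which(currents_pa == -10)[1]
  rmp <- mean(vm_traces[[idx0]])
  vh <- vm_traces[[idxh]]
  base_idx <- seq_len(max(1L, round(step_on_s * rate_hz)))
  tail_idx <- seq.int(round((step_on_s + step_dur_s - 0.2) * rate_hz) + 1L,
                      round((step_on_s + step_dur_s) * rate_hz))
  tail_idx <- tail_idx[tail_idx <= length(vh)]
  dv <- mean(vh[tail_idx]) - mean(vh[base_idx])
  ri <- dv / (-10) * 1000  # mV/pA -> MOhm
  refr <- max(1L, round(0.001 * rate_hz))
  fi <- do.call(rbind, lapply(seq_along(vm_traces), function(i) {
    v <- vm_traces[[i]]
    win <- seq.int(round(step_on_s * rate_hz) + 1L,
                   min(length(v), round((step_on_s + step_dur_s) * rate_hz)))
    vv <- v[win]
    up <- which(vv[-1] >= 0 & vv[-length(vv)] < 0) + 1L
    if (length(up) > 1L) {
      keep <- c(TRUE, diff(up) >= refr)
      up <- up[keep]
    }
    data.frame(current_pa = currents_pa[i], n_spikes = length(up))
  }))
  list(rmp_mv = rmp, input_resistance_mohm = ri,
       fi_curve = fi[order(fi$current_pa), ])
}
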