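# Synthetic multi-electrode-array generator: Gaussian channel noise plus
# injected bursts (<5 s) and propagating seizure-like discharges (>5 s)
# over an entorhinal-hippocampal subregion map.

MEA_REGIONS <- c("DG", "CA3", "CA1", "Sub", "Ent", "PRh/Ect")
HIPPOCAMPAL_REGIONS <- c("DG", "CA3", "CA1", "Sub")

#' Default electrode-to-subregion map for a rectangular grid
#'
#' Assigns the six entorhinal-hippocampal subregions to contiguous column
#' blocks of the grid (DG, CA3, CA1, Sub, Ent, PRh/Ect from left to
#' right), mimicking the spatial layout of a horizontal slice on a planar
#' array.
#'
#' @param grid_shape Integer vector `c(rows, cols)`.
#' @return Data frame with columns `electrode`, `row`, `col`, `region`.
#' @export
default_region_map <- function(grid_shape = c(12, 12)) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  block <- ceiling(seq_len(cols) * length(MEA_REGIONS) / cols)
  data.frame(
    electrode = seq_len(rows * cols),
    row = rep(seq_len(rows), times = cols),
    col = rep(seq_len(cols), each = rows),
    region = MEA_REGIONS[rep(block, each = rows)],
    stringsAsFactors = FALSE
  )
}

#' Parameters for the MEA simulator
#'
#' @param duration_s Recording duration (s).
#' @param rate_hz Sampling rate (default 10000 samples/s).
#' @param grid_shape Electrode grid `c(rows, cols)` (default 12 x 12).
#' @param region_map Electrode-to-subregion map as produced by
#'   [default_region_map()]; must cover every electrode.
#' @param noise_sd Gaussian channel noise SD (uV).
#' @param burst_rate_per_min,seizure_rate_per_min Mean Poisson event rates.
#' @param burst_duration_s Mean burst duration; must be < 5 s (bursts are
#'   defined as discharges shorter than 5 s).
#' @param seizure_duration_s Mean seizure duration; must be > 5 s.
#' @param burst_amp_uv,seizure_amp_uv Event envelope amplitudes (uV).
#' @param duration_jitter Fractional jitter applied to event durations
#'   (clamped so the burst/seizure taxonomy is never violated).
#' @param initiation_region Subregion whose electrodes carry seizure onset.
#' @param propagation_delay_s Named per-subregion onset lag (s, >= 0)
#'   relative to the initiation region.
#' @param involved_regions Subregions reached by seizures.
#' @param quiet_start Keep the first 500 ms event-free (default `TRUE`) so
#'   noise can be estimated there; set `FALSE` to exercise the fallback
#'   quiet-window search.
#' @param seed Integer seed.
#' @return An object of class `"mea_sim_params"`.
#' @export
mea_sim_params <- function(duration_s = 120,
                           rate_hz = 10000,
                           grid_shape = c(12, 12),
                           region_map = NULL,
                           noise_sd = 5,
                           burst_rate_per_min = 6,
                           burst_duration_s = 2,
                           seizure_rate_per_min = 0.3,
                           seizure_duration_s = 30,
                           burst_amp_uv = 100,
                           seizure_amp_uv = 200,
                           duration_jitter = 0.2,
                           initiation_region = "DG",
                           propagation_delay_s = c(DG = 0, CA3 = 0.05,
                                                   CA1 = 0.10, Sub = 0.15,
                                                   Ent = 0.20,
                                                   "PRh/Ect" = 0.25),
                           involved_regions = MEA_REGIONS,
                           quiet_start = TRUE,
                           seed = 1L) {
  check_positive(duration_s, "duration_s")
  check_positive(rate_hz, "rate_hz")
  if (burst_duration_s >= 5) {
    stop_config("burst_duration_s",
                "bursts are discharges shorter than 5 s")
  }
  if (seizure_duration_s <= 5) {
    stop_config("seizure_duration_s",
                "seizure-like events last more than 5 s")
  }
  if (any(propagation_delay_s < 0)) {
    stop_config("propagation_delay_s", "delays must be non-negative")
  }
  if (is.null(region_map)) region_map <- default_region_map(grid_shape)
  n_el <- prod(grid_shape)
  if (!all(seq_len(n_el) %in% region_map$electrode)) {
    stop_config("region_map", "must cover every electrode of the grid")
  }
  if (!initiation_region %in% involved_regions) {
    involved_regions <- c(initiation_region, involved_regions)
  }
  structure(list(
    duration_s = duration_s, rate_hz = rate_hz, grid_shape = grid_shape,
    region_map = region_map, noise_sd = noise_sd,
    burst_rate_per_min = burst_rate_per_min,
    burst_duration_s = burst_duration_s,
    seizure_rate_per_min = seizure_rate_per_min,
    seizure_duration_s = seizure_duration_s,
    burst_amp_uv = burst_amp_uv, seizure_amp_uv = seizure_amp_uv,
    duration_jitter = duration_jitter,
    initiation_region = initiation_region,
    propagation_delay_s = propagation_delay_s,
    involved_regions = unique(involved_regions),
    quiet_start = quiet_start, seed = seed
  ), class = "mea_sim_params")
}

#' Construct an MEA recording container
#'
#' @param traces Electrodes x time numeric matrix (uV).
#' @param rate_hz Sampling rate (samples/s).
#' @param region_map Electrode-to-subregion data frame.
#' @param slice_id Slice identifier.
#' @param genotype `"control"` or `"mutant"`.
#' @return An object of class `"mea_recording"`.
#' @export
mea_recording <- function(traces, rate_hz, region_map,
                          slice_id = "slice", genotype = "control") {
  if (!is.matrix(traces)) stop_config("traces", "must be a matrix")
  if (!all(seq_len(nrow(traces)) %in% region_map$electrode)) {
    stop_config("region_map", "must be defined for every electrode")
  }
  check_positive(rate_hz, "rate_hz")
  structure(list(traces = traces, rate_hz = rate_hz,
                 region_map = region_map, slice_id = slice_id,
                 genotype = genotype),
            class = "mea_recording")
}

# trapezoidal on/off envelope with `ramp_s` attack and release
trapezoid_env <- function(t_rel, dur, ramp_s = 0.1) {
  pmax(0, pmin(1, t_rel / ramp_s, (dur - t_rel) / ramp_s))
}

# burst morphology: fast oscillation followed by a slow negative shift
burst_waveform <- function(t_rel, dur, amp) {
  env <- trapezoid_env(t_rel, dur, ramp_s = min(0.1, dur / 6))
  fast <- sin(2 * pi * 15 * t_rel) * exp(-2 * t_rel / dur)
  shift <- -0.6 * pmax(0, (t_rel - 0.4 * dur) / (0.6 * dur))
  amp * env * (fast + shift)
}

# seizure morphology: sustained large-amplitude 6-Hz spiking envelope with
# a DC offset so the discharge stays supra-threshold throughout
seizure_waveform <- function(t_rel, dur, amp) {
  env <- trapezoid_env(t_rel, dur, ramp_s = 0.1)
  amp * env * (0.7 * sin(2 * pi * 6 * t_rel) - 0.45)
}

# greedy non-overlapping event placement with a minimum gap between events
place_events <- function(n, dur, t_min, t_max, occupied, min_gap) {
  onsets <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      on <- stats::runif(1, t_min, t_max - dur)
      lo <- on - min_gap
      hi <- on + dur + min_gap
      clash <- any(occupied$start < hi & occupied$end > lo)
      if (!clash) {
        occupied <- rbind(occupied, data.frame(start = on, end = on + dur))
        onsets <- c(onsets, on)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  list(onsets = sort(onsets), occupied = occupied)
}

#' Generate a synthetic MEA recording
#'
#' Injects Poisson-timed bursts and seizure-like discharges into Gaussian
#' channel noise. Seizures start on the initiation subregion's electrodes
#' and reach the other involved subregions after the configured lags;
#' bursts are confined to the initiation subregion. Events are placed with
#' a minimum 2-s separation so detection cannot merge distinct events, and
#' with the first 500 ms guaranteed quiet when `quiet_start` is `TRUE`.
#'
#' @param params An [mea_sim_params()] object.
#' @param slice_id,genotype Metadata stored on the recording.
#' @return List with `recording` (an `mea_recording`) and `truth`: a data
#'   frame `events` (`onset_s`, `offset_s`, `class`, `electrode`,
#'   `region`) of slice-level ground truth plus the list-column-free
#'   `involved` (list of subregion character vectors, one per event).
#' @export
generate_mea_recording <- function(params, slice_id = "slice",
                                   genotype = "control") {
  stopifnot(inherits(params, "mea_sim_params"))
  p <- params
  n <- round(p$duration_s * p$rate_hz)
  n_el <- prod(p$grid_shape)
  local_seed(p$seed, {
    traces <- matrix(stats::rnorm(n_el * n, 0, p$noise_sd),
                     nrow = n_el, ncol = n)
    t_min <- if (p$quiet_start) 0.6 else 0.05
    usable_min <- (p$duration_s - t_min) / 60
    n_seiz <- stats::rpois(1, p$seizure_rate_per_min * usable_min)
    n_burst <- stats::rpois(1, p$burst_rate_per_min * usable_min)
    jit <- function(d) d * stats::runif(1, 1 - p$duration_jitter,
                                        1 + p$duration_jitter)
    occupied <- data.frame(start = numeric(0), end = numeric(0))

    max_delay <- max(0, p$propagation_delay_s[p$involved_regions], na.rm = TRUE)
    events <- list(); involved <- list()
    init_electrodes <- p$region_map$electrode[
      p$region_map$region == p$initiation_region]
    if (length(init_electrodes) == 0L) {
      stop_config("initiation_region", "has no electrodes in region_map")
    }

    add_event <- function(onset, dur, class, regions) {
      offset <- onset + dur + if (class == "seizure") max_delay else 0
      events[[length(events) + 1L]] <<- data.frame(
        onset_s = onset, offset_s = min(offset, p$duration_s),
        class = class, electrode = min(init_electrodes),
        region = p$initiation_region, stringsAsFactors = FALSE)
      involved[[length(involved) + 1L]] <<- regions
    }

    inject <- function(electrode, onset, dur, fun, amp) {
      i0 <- floor(onset * p$rate_hz) + 1L
      i1 <- min(n, floor((onset + dur) * p$rate_hz))
      if (i1 <= i0) return(invisible())
      idx <- i0:i1
      t_rel <- (idx - 1L) / p$rate_hz - onset
      traces[electrode, idx] <<- traces[electrode, idx] +
        fun(t_rel, dur, amp)
      invisible()
    }

    if (n_seiz > 0) {
      dur_s <- vapply(seq_len(n_seiz), function(i) {
        max(5.5, jit(p$seizure_duration_s))
      }, numeric(1))
      for (k in seq_len(n_seiz)) {
        span <- dur_s[k] + max_delay
        pl <- place_events(1L, span, t_min, p$duration_s, occupied,
                           min_gap = max(2, 12))
        occupied <- pl$occupied
        if (length(pl$onsets) == 0L) next
        on <- pl$onsets[1]
        for (reg in p$involved_regions) {
          lag <- p$propagation_delay_s[reg]
          if (is.na(lag)) lag <- 0
          lag <- lag - p$propagation_delay_s[p$initiation_region]
          lag <- max(0, lag)
          for (el in p$region_map$electrode[p$region_map$region == reg]) {
            inject(el, on + lag, dur_s[k], seizure_waveform,
                   p$seizure_amp_uv)
          }
        }
        add_event(on, dur_s[k], "seizure", p$involved_regions)
      }
    }
    if (n_burst > 0) {
      for (k in seq_len(n_burst)) {
        dur <- min(4.8, max(0.3, jit(p$burst_duration_s)))
        pl <- place_events(1L, dur, t_min, p$duration_s, occupied,
                           min_gap = 2)
        occupied <- pl$occupied
        if (length(pl$onsets) == 0L) next
        on <- pl$onsets[1]
        for (el in init_electrodes) {
          inject(el, on, dur, burst_waveform, p$burst_amp_uv)
        }
        add_event(on, dur, "burst", p$initiation_region)
      }
    }
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(onset_s = numeric(0), offset_s = numeric(0),
                 class = character(0), electrode = integer(0),
                 region = character(0), stringsAsFactors = FALSE)
    ord <- order(ev$onset_s)
    rec <- mea_recording(traces, p$rate_hz, p$region_map,
                         slice_id = slice_id, genotype = genotype)
    list(recording = rec,
         truth = list(events = ev[ord, , drop = FALSE],
                      involved = involved[ord]))
  })
}
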