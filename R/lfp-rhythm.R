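# Theta/delta-ratio brain-state segmentation and layer-resolved band power
# over appended mobility periods.

#' Configuration for laminar LFP spectral analysis
#'
#' @param window_s Sliding-window length in seconds for the ratio track
#'   (default 5).
#' @param step_s Window step in seconds (default 0.5).
#' @param theta_band,delta_band,gamma_band Frequency intervals in Hz
#'   (defaults 4-12, 0.1-4 and 40-80; a 40-60 gamma band is selectable).
#' @param line_hz Mains frequency whose bins (and harmonics) are excluded
#'   from quantitative band power; `0` disables exclusion.
#' @param line_half_width_hz Exclusion half-width around the mains
#'   frequency and each harmonic (default 2 Hz).
#' @param threshold_method `"mixture"` (two-component Gaussian mixture on
#'   log-ratios, the default), `"otsu"`, or `"manual"`.
#' @param manual_threshold Ratio-scale threshold used when
#'   `threshold_method = "manual"`.
#' @return An object of class `"lfp_analysis_config"`.
#' @export
lfp_analysis_config <- function(window_s = 5,
                                step_s = 0.5,
                                theta_band = c(4, 12),
                                delta_band = c(0.1, 4),
                                gamma_band = c(40, 80),
                                line_hz = 50,
                                line_half_width_hz = 2,
                                threshold_method = c("mixture", "otsu",
                                                     "manual"),
                                manual_threshold = NULL) {
  check_positive(window_s, "window_s")
  check_positive(step_s, "step_s")
  if (step_s > window_s) stop_config("step_s", "must not exceed window_s")
  for (nm in c("theta_band", "delta_band", "gamma_band")) {
    b <- get(nm)
    if (length(b) != 2L || any(b < 0) || b[1] >= b[2]) {
      stop_config(nm, "must be an ordered positive interval")
    }
  }
  structure(list(
    window_s = window_s, step_s = step_s, theta_band = theta_band,
    delta_band = delta_band, gamma_band = gamma_band, line_hz = line_hz,
    line_half_width_hz = line_half_width_hz,
    threshold_method = match.arg(threshold_method),
    manual_threshold = manual_threshold
  ), class = "lfp_analysis_config")
}

#' Select the channel of maximal theta power
#'
#' Returns the index of the channel whose whole-session mean theta-band
#' power is largest (in practice usually an SLM contact); ties are broken
#' by the lowest channel index.
#'
#' @param rec A `laminar_recording`.
#' @param cfg An [lfp_analysis_config()].
#' @return Integer channel index.
#' @export
select_theta_channel <- function(rec, cfg = lfp_analysis_config()) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (all(rec$samples == 0)) {
    stop("degenerate signal: recording is all zero", call. = FALSE)
  }
  theta <- apply(rec$samples, 1, function(x) {
    p <- psd_welch(x, rec$rate_hz, cfg$window_s)
    band_from_psd(p$freq_hz, p$psd, cfg$theta_band)$mean_density
  })
  which.max(theta)  # which.max returns the first (lowest) index on ties
}

#' Compute the theta/delta ratio track
#'
#' Slides a window of `window_s` seconds every `step_s` seconds over the
#' selected channel; each fully contained window yields the Hann-tapered
#' periodogram's mean band density for theta and delta and their ratio.
#' Windows extending past the recording end are dropped, not padded.
#'
#' @param rec A `laminar_recording`.
#' @param cfg An [lfp_analysis_config()].
#' @param channel Channel index (defaults to [select_theta_channel()]).
#' @return A `ratio_track` data frame with columns `center_s`, `start_s`,
#'   `end_s`, `theta_power`, `delta_power`, `ratio`; the source channel is
#'   stored as attribute `"channel"`.
#' @export
compute_ratio_track <- function(rec, cfg = lfp_analysis_config(),
                                channel = NULL) {
  stopifnot(inherits(rec, "laminar_recording"))
  n <- ncol(rec$samples)
  duration <- n / rec$rate_hz
  if (duration < cfg$window_s) {
    stop(sprintf("insufficient data: %.2f s recorded, window is %g s",
                 duration, cfg$window_s), call. = FALSE)
  }
  if (is.null(channel)) channel <- select_theta_channel(rec, cfg)
  x <- rec$samples[channel, ]
  wlen <- round(cfg$window_s * rec$rate_hz)
  step <- cfg$step_s * rec$rate_hz
  n_windows <- floor((n - wlen) / step) + 1L
  starts <- round((seq_len(n_windows) - 1L) * step) + 1L
  rows <- vapply(starts, function(s) {
    p <- psd_segment(x[s:(s + wlen - 1L)], rec$rate_hz)
    th <- band_from_psd(p$freq_hz, p$psd, cfg$theta_band)$mean_density
    de <- band_from_psd(p$freq_hz, p$psd, cfg$delta_band)$mean_density
    c(th, de)
  }, numeric(2))
  start_s <- (starts - 1L) / rec$rate_hz
  track <- data.frame(
    center_s = start_s + cfg$window_s / 2,
    start_s = start_s,
    end_s = start_s + cfg$window_s,
    theta_power = rows[1, ],
    delta_power = rows[2, ],
    ratio = rows[1, ] / rows[2, ]
  )
  attr(track, "channel") <- channel
  attr(track, "rate_hz") <- rec$rate_hz
  attr(track, "duration_s") <- duration
  class(track) <- c("ratio_track", "data.frame")
  track
}

# Equal-density crossing of two weighted Gaussians, restricted to the
# interval between the means; falls back to the weighted midpoint if the
# quadratic has no root there.
gaussian_crossing <- function(w1, m1, s1, w2, m2, s2) {
  if (m1 > m2) {
    tmp <- c(w1, m1, s1); w1 <- w2; m1 <- m2; s1 <- s2
    w2 <- tmp[1]; m2 <- tmp[2]; s2 <- tmp[3]
  }
  a <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  b <- m2 / s2^2 - m1 / s1^2
  cc <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) + log(w1 / w2) + log(s2 / s1)
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return((m1 + m2) / 2)
    x <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return((m1 + m2) / 2)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots >= m1 & roots <= m2]
    x <- if (length(inside)) inside[1] else (m1 + m2) / 2
  }
  x
}

#' Fit a bimodality threshold to theta/delta ratios
#'
#' The default method fits a two-component Gaussian mixture (shared
#' variance) to the log-ratios and returns the equal-density crossing
#' between the component means, mapped back to the ratio scale. If the fit
#' is degenerate (a component weight below 0.05 or means closer than 0.1
#' log-units) a unimodal-distribution warning is raised and the method
#' falls back to Otsu's threshold; the fallback is recorded in the
#' diagnostics.
#'
#' @param ratios Numeric vector of theta/delta ratios (or a `ratio_track`).
#' @param cfg An [lfp_analysis_config()]; `threshold_method` selects
#'   `"mixture"`, `"otsu"` or `"manual"`.
#' @return List with `threshold` (ratio scale), `log_threshold`, and
#'   `diagnostics` (component means/sds/weights on the log scale, the
#'   method actually used, and a `bimodal` flag).
#' @export
fit_bimodal_threshold <- function(ratios, cfg = lfp_analysis_config()) {
  if (inherits(ratios, "ratio_track")) ratios <- ratios$ratio
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  if (length(ratios) < 50L) {
    stop("need at least 50 ratio values to fit a threshold", call. = FALSE)
  }
  lr <- log(ratios)
  method <- cfg$threshold_method
  if (method == "manual") {
    if (is.null(cfg$manual_threshold)) {
      stop_config("manual_threshold", "required for the manual method")
    }
    return(list(threshold = cfg$manual_threshold,
                log_threshold = log(cfg$manual_threshold),
                diagnostics = list(method = "manual", bimodal = NA)))
  }
  diag <- list(method = method, bimodal = FALSE)
  if (method == "mixture") {
    # shared-variance components: the immobile (LIA) mode is much broader
    # than the mobile mode on the log scale, and an unequal-variance fit
    # would park the crossing against the narrow mobile mode
    fit <- tryCatch(
      suppressWarnings(mclust::densityMclust(lr, G = 2, modelNames = "E",
                                             verbose = FALSE, plot = FALSE)),
      error = function(e) NULL)
    degenerate <- TRUE
    if (!is.null(fit)) {
      w <- fit$parameters$pro
      m <- fit$parameters$mean
      s <- sqrt(fit$parameters$variance$sigmasq)
      if (length(s) == 1L) s <- rep(s, 2L)
      degenerate <- min(w) < 0.05 || abs(diff(m)) < 0.1
      diag$weights <- as.numeric(w)
      diag$means <- as.numeric(m)
      diag$sds <- as.numeric(s)
    }
    if (!degenerate) {
      lt <- gaussian_crossing(w[1], m[1], s[1], w[2], m[2], s[2])
      diag$bimodal <- TRUE
      return(list(threshold = exp(lt), log_threshold = lt,
                  diagnostics = diag))
    }
    warning("unimodal ratio distribution; falling back to Otsu threshold",
            call. = FALSE)
    diag$method <- "otsu_fallback"
  }
  lt <- otsu_threshold(lr)
  list(threshold = exp(lt), log_threshold = lt, diagnostics = diag)
}

#' Extract mobility intervals from a ratio track
#'
#' Runs of consecutive supra-threshold windows are merged into intervals
#' spanning from the first window's start to the last window's end
#' (half-open `[start, end)` seconds); overlapping intervals from nearby
#' runs are coalesced so the result is disjoint and ordered. A track that
#' is sub-threshold everywhere yields an empty segmentation.
#'
#' @param track A `ratio_track` from [compute_ratio_track()].
#' @param threshold Ratio-scale threshold (a number or the result of
#'   [fit_bimodal_threshold()]).
#' @return A `mobility_segmentation` list: `threshold`, `intervals`
#'   (data frame `start_s`/`end_s`), `coverage_fraction`, `duration_s`,
#'   and the per-window logical `window_state`.
#' @export
extract_mobility_intervals <- function(track, threshold) {
  stopifnot(inherits(track, "ratio_track"))
  if (is.list(threshold)) threshold <- threshold$threshold
  duration <- attr(track, "duration_s")
  supra <- track$ratio > threshold
  intervals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    intervals <- data.frame(
      start_s = track$start_s[starts[runs]],
      end_s = pmin(track$end_s[ends[runs]], duration)
    )
    # coalesce overlapping intervals (runs closer than one window length)
    if (nrow(intervals) > 1L) {
      out_s <- c(); out_e <- c()
      cur_s <- intervals$start_s[1]; cur_e <- intervals$end_s[1]
      for (i in seq_len(nrow(intervals))[-1]) {
        if (intervals$start_s[i] <= cur_e) {
          cur_e <- max(cur_e, intervals$end_s[i])
        } else {
          out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
          cur_s <- intervals$start_s[i]; cur_e <- intervals$end_s[i]
        }
      }
      out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      intervals <- data.frame(start_s = out_s, end_s = out_e)
    }
  }
  structure(list(
    threshold = threshold,
    intervals = intervals,
    coverage_fraction = sum(intervals$end_s - intervals$start_s) / duration,
    duration_s = duration,
    window_state = supra,
    window_center_s = track$center_s
  ), class = "mobility_segmentation")
}

#' Band power over appended mobility periods
#'
#' Within each mobility interval the spectrum is estimated by a
#' Hann-tapered averaged periodogram (segments of `window_s` seconds, 50%
#' overlap); interval spectra are then combined as a duration-weighted
#' mean, which is the spectral equivalent of appending mobility periods
#' without creating concatenation artifacts at the seams. Bins within
#' `line_half_width_hz` of the mains frequency and its harmonics are
#' excluded from the quantitative band summaries (never interpolated).
#' Both the band-mean density (uV^2/Hz) and the band-integrated power
#' (uV^2) are reported per channel and band.
#'
#' @param rec A `laminar_recording`.
#' @param seg A `mobility_segmentation`.
#' @param cfg An [lfp_analysis_config()].
#' @return A `band_power_summary` list: `per_channel` data frame (one row
#'   per channel x band with `mean_density` and `integrated`), scalar
#'   summaries `theta_slm`, `gamma_slm`, `gamma_sp` (band-integrated power
#'   averaged over the labelled channels), `mobility_duration_s`, and the
#'   pooled `freq_hz`/`psd` matrix (channels x bins).
#' @export
band_power <- function(rec, seg, cfg = lfp_analysis_config()) {
  stopifnot(inherits(rec, "laminar_recording"),
            inherits(seg, "mobility_segmentation"))
  if (seg$coverage_fraction <= 0 || nrow(seg$intervals) == 0L) {
    stop(paste0("no mobility detected in session '", rec$session_id,
                "'; report the session as unusable"), call. = FALSE)
  }
  rate <- rec$rate_hz
  nseg <- round(cfg$window_s * rate)
  n_ch <- nrow(rec$samples)
  weights <- seg$intervals$end_s - seg$intervals$start_s
  psd_acc <- NULL
  freq <- NULL
  for (k in seq_len(nrow(seg$intervals))) {
    i0 <- max(1L, floor(seg$intervals$start_s[k] * rate) + 1L)
    i1 <- min(ncol(rec$samples), ceiling(seg$intervals$end_s[k] * rate))
    seg_psd <- t(vapply(seq_len(n_ch), function(ch) {
      p <- psd_welch(rec$samples[ch, i0:i1], rate, cfg$window_s)
      p$psd
    }, numeric(floor(nseg / 2))))
    if (is.null(psd_acc)) {
      psd_acc <- seg_psd * weights[k]
      freq <- seq_len(floor(nseg / 2)) * rate / nseg
    } else {
      psd_acc <- psd_acc + seg_psd * weights[k]
    }
  }
  psd <- psd_acc / sum(weights)
  keep <- line_exclusion_mask(freq, cfg$line_hz, cfg$line_half_width_hz)
  bands <- list(theta = cfg$theta_band, delta = cfg$delta_band,
                gamma = cfg$gamma_band)
  per_channel <- do.call(rbind, lapply(seq_len(n_ch), function(ch) {
    do.call(rbind, lapply(names(bands), function(b) {
      s <- band_from_psd(freq, psd[ch, ], bands[[b]], keep)
      data.frame(channel = ch, label = rec$channel_labels[ch], band = b,
                 mean_density = s$mean_density, integrated = s$integrated,
                 stringsAsFactors = FALSE)
    }))
  }))
  scalar <- function(band, label) {
    rows <- per_channel$band == band & per_channel$label == label
    if (!any(rows)) return(NA_real_)
    mean(per_channel$integrated[rows])
  }
  structure(list(
    per_channel = per_channel,
    theta_slm = scalar("theta", "SLM"),
    gamma_slm = scalar("gamma", "SLM"),
    gamma_sp = scalar("gamma", "SP"),
    mobility_duration_s = sum(weights),
    freq_hz = freq,
    psd = psd
  ), class = "band_power_summary")
}

#' Run the full per-session LFP analysis chain
#'
#' Chains channel selection, ratio-track computation, bimodality
#' thresholding, mobility-interval extraction and mobility band power,
#' propagating stage errors with the session id attached. Deterministic
#' for a fixed input.
#'
#' @param rec A `laminar_recording`.
#' @param cfg An [lfp_analysis_config()].
#' @return List with `track`, `segmentation`, `summary`, `channel`, and
#'   the threshold `diagnostics`.
#' @export
analyze_session <- function(rec, cfg = lfp_analysis_config()) {
  withCallingHandlers(
    {
      channel <- select_theta_channel(rec, cfg)
      track <- compute_ratio_track(rec, cfg, channel)
      thr <- fit_bimodal_threshold(track, cfg)
      seg <- extract_mobility_intervals(track, thr)
      summ <- band_power(rec, seg, cfg)
      list(track = track, segmentation = seg, summary = summ,
           channel = channel, diagnostics = thr$diagnostics)
    },
    error = function(e) {
      stop(sprintf("session '%s': %s", rec$session_id, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' Assemble a session table from analysed sessions
#'
#' @param results List of [analyze_session()] results.
#' @param recordings The matching list of `laminar_recording`s (for
#'   session ids and genotypes).
#' @param cr_density Optional numeric vector of per-session CR densities
#'   (cells/mm) to attach.
#' @return A `session_table` data frame with one row per session.
#' @export
session_table <- function(results, recordings, cr_density = NULL) {
  stopifnot(length(results) == length(recordings))
  out <- do.call(rbind, lapply(seq_along(results), function(i) {
    data.frame(session_id = recordings[[i]]$session_id,
               genotype = recordings[[i]]$genotype,
               theta_slm = results[[i]]$summary$theta_slm,
               gamma_slm = results[[i]]$summary$gamma_slm,
               gamma_sp = results[[i]]$summary$gamma_sp,
               mobility_s = results[[i]]$summary$mobility_duration_s,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cr_density)) out$cr_density <- cr_density
  class(out) <- c("session_table", "data.frame")
  out
}

#' Pearson correlation between CR density and a band-power column
#'
#' @param table A `session_table` (or any data frame) with a `cr_density`
#'   column.
#' @param band_column Name of the power column to correlate (e.g.
#'   `"gamma_sp"` or `"theta_slm"`).
#' @return List with `r`, `p_two_tailed`, and `n`.
#' @export
correlate_density_power <- function(table, band_column) {
  x <- table$cr_density
  y <- table[[band_column]]
  if (is.null(x) || is.null(y)) {
    stop("table must contain 'cr_density' and the requested band column",
         call. = FALSE)
  }
  res <- pearson_test(x, y)
  list(r = res$statistic_r, p_two_tailed = res$p_value, n = res$n)
}
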