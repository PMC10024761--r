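# Independent oracles and small builders shared across tests.

# Direct-DFT one-sided periodogram (independent of the fft-based path in
# the package): explicit sums over e^{-i 2 pi k n / N}.
oracle_psd <- function(x, rate_hz) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L)))
  xw <- x * w
  nf <- floor(n / 2)
  tt <- seq.int(0L, n - 1L)
  psd <- vapply(seq_len(nf), function(k) {
    re <- sum(xw * cos(2 * pi * k * tt / n))
    im <- sum(xw * sin(2 * pi * k * tt / n))
    (re^2 + im^2) * 2 / (rate_hz * sum(w^2))
  }, numeric(1))
  list(freq_hz = seq_len(nf) * rate_hz / n, psd = psd)
}

# Dense-sampling Sholl oracle: sample each segment finely and count sign
# changes of (distance to soma - r).
oracle_sholl <- function(m, radii, compartment = "all", n_samp = 4000L) {
  segs <- hippophys:::filter_compartment(
    hippophys:::segment_lengths(m), compartment)
  soma <- as.numeric(m$nodes[m$nodes$parent == -1, c("x", "y", "z")])
  vapply(radii, function(r) {
    tot <- 0L
    for (i in seq_len(nrow(segs))) {
      tt <- seq(0, 1, length.out = n_samp)
      px <- segs$x0[i] + tt * (segs$x1[i] - segs$x0[i]) - soma[1]
      py <- segs$y0[i] + tt * (segs$y1[i] - segs$y0[i]) - soma[2]
      pz <- segs$z0[i] + tt * (segs$z1[i] - segs$z0[i]) - soma[3]
      dd <- sqrt(px^2 + py^2 + pz^2) - r
      tot <- tot + sum(abs(diff(sign(dd))) > 0)
    }
    tot
  }, integer(1))
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher p-value
# (point-probability convention), fixing all margins.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  point_p <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(n, c1))
  }
  p_obs <- point_p(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, function(a) {
    p <- point_p(a)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# Per-channel band power via an independent route: zero-phase Butterworth
# bandpass variance.
oracle_bandpass_variance <- function(x, rate_hz, band) {
  bf <- signal::butter(4, band / (rate_hz / 2), type = "pass")
  stats::var(signal::filtfilt(bf, x))
}

# Window-level agreement between a mobility segmentation and the
# generator's ground-truth state track (majority state per window).
window_agreement <- function(seg, state_track, rate_hz,
                             window_s = 5) {
  half <- window_s / 2
  mean(vapply(seq_along(seg$window_center_s), function(i) {
    c0 <- seg$window_center_s[i]
    idx <- max(1L, round((c0 - half) * rate_hz + 1)):
      min(length(state_track), round((c0 + half) * rate_hz))
    (mean(state_track[idx]) > 0.5) == seg$window_state[i]
  }, logical(1)))
}

# Build a current trace of well-separated biexponential events on
# Gaussian noise (for detector tests where Poisson coincidences must be
# ruled out). Returns the trace plus true onset times.
build_psc_trace <- function(onsets_s, amps_pa, duration_s, rate_hz = 10000,
                            rise_ms = 1.5, decay_ms = 8, noise_sd = 0,
                            polarity = "negative", seed = 1) {
  n <- round(duration_s * rate_hz)
  x <- if (noise_sd > 0) {
    hippophys:::local_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else rep(0, n)
  kt <- seq.int(0L, round(0.08 * rate_hz)) / rate_hz
  kern <- psc_kernel(kt, rise_ms, decay_ms)
  sgn <- if (polarity == "negative") -1 else 1
  for (k in seq_along(onsets_s)) {
    i0 <- floor(onsets_s[k] * rate_hz) + 1L
    i1 <- min(n, i0 + length(kern) - 1L)
    x[i0:i1] <- x[i0:i1] + sgn * amps_pa[k] * kern[seq_len(i1 - i0 + 1L)]
  }
  current_trace(x, rate_hz,
                holding_mv = if (polarity == "negative") -60 else 0,
                polarity = polarity)
}

# Minimal ratio_track builder for interval-extraction tests.
build_ratio_track <- function(ratios, window_s = 5, step_s = 0.5,
                              duration_s = NULL) {
  n <- length(ratios)
  start_s <- (seq_len(n) - 1L) * step_s
  if (is.null(duration_s)) duration_s <- start_s[n] + window_s
  track <- data.frame(
    center_s = start_s + window_s / 2,
    start_s = start_s,
    end_s = start_s + window_s,
    theta_power = ratios, delta_power = rep(1, n), ratio = ratios
  )
  attr(track, "channel") <- 1L
  attr(track, "rate_hz") <- 100
  attr(track, "duration_s") <- duration_s
  class(track) <- c("ratio_track", "data.frame")
  track
}

# Small labelled-discharge table builder for taxonomy tests.
build_discharges <- function(onsets, durations, electrode = 1L,
                             slope = 1) {
  data.frame(electrode = electrode, onset_s = onsets,
             offset_s = onsets + durations, duration_s = durations,
             peak_uv = 100, onset_slope_uv_ms = slope)
}
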