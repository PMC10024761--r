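# Internal helpers shared across modules.

#' Evaluate code with a local RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the previous
#' global RNG state, so generators are pure functions of their arguments and
#' never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with the offending field named, for configuration errors
stop_config <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_config(field, "must be a single positive number")
  }
  invisible(x)
}

# Hann window (periodic symmetric form used for averaged periodograms)
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L)))
}

#' One-sided power spectral density of a single segment
#'
#' Hann-tapered periodogram normalised so that the integral of the one-sided
#' density over (0, Nyquist] equals the variance of the (demeaned) segment;
#' for a sinusoid of amplitude A the band-integrated power is A^2/2.
#'
#' @param x Numeric vector (one channel segment).
#' @param rate_hz Sampling rate in samples/s.
#' @param taper Logical; apply a Hann taper (default `TRUE`).
#' @return List with `freq_hz` (positive frequencies) and `psd`
#'   (density, signal units squared per Hz).
#' @export
psd_segment <- function(x, rate_hz, taper = TRUE) {
  n <- length(x)
  if (n < 4L) stop("segment too short for a periodogram", call. = FALSE)
  x <- x - mean(x)
  w <- if (taper) hann_window(n) else rep(1, n)
  X <- stats::fft(x * w)
  nf <- floor(n / 2)
  # one-sided: double all positive-frequency bins (Nyquist doubling error is
  # negligible at the band edges used here)
  p <- (Mod(X[2:(nf + 1L)])^2) * 2 / (rate_hz * sum(w^2))
  list(freq_hz = seq_len(nf) * rate_hz / n, psd = p)
}

#' Welch-averaged power spectral density
#'
#' Averages Hann-tapered periodograms over segments of `segment_s` seconds
#' with 50% overlap. A trailing remainder shorter than one segment is
#' dropped; if `x` is shorter than one segment the whole stretch is used as
#' a single (shorter) segment.
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate (samples/s).
#' @param segment_s Segment length in seconds (default 5).
#' @return List with `freq_hz`, `psd`, and `n_segments`.
#' @export
psd_welch <- function(x, rate_hz, segment_s = 5) {
  nseg <- round(segment_s * rate_hz)
  n <- length(x)
  if (n < nseg) {
    out <- psd_segment(x, rate_hz)
    out$n_segments <- 1L
    return(out)
  }
  step <- floor(nseg / 2)
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    p <- psd_segment(x[s:(s + nseg - 1L)], rate_hz)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  freq <- seq_len(floor(nseg / 2)) * rate_hz / nseg
  list(freq_hz = freq, psd = acc / length(starts), n_segments = length(starts))
}

# Frequency-bin mask excluding mains frequency and harmonics
line_exclusion_mask <- function(freq_hz, line_hz, half_width_hz) {
  if (is.null(line_hz) || is.na(line_hz) || line_hz <= 0) {
    return(rep(TRUE, length(freq_hz)))
  }
  keep <- rep(TRUE, length(freq_hz))
  h <- line_hz
  while (h <= max(freq_hz) + half_width_hz) {
    keep <- keep & (abs(freq_hz - h) > half_width_hz)
    h <- h + line_hz
  }
  keep
}

# Band summaries from a PSD: mean density within band and band-integrated
# power (density * bin width, summed over retained bins).
band_from_psd <- function(freq_hz, psd, band, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(freq_hz))
  sel <- freq_hz >= band[1] & freq_hz <= band[2] & keep
  df <- if (length(freq_hz) > 1L) freq_hz[2] - freq_hz[1] else NA_real_
  if (!any(sel)) {
    return(list(mean_density = 0, integrated = 0, n_bins = 0L))
  }
  list(
    mean_density = mean(psd[sel]),
    integrated = sum(psd[sel]) * df,
    n_bins = sum(sel)
  )
}

# Otsu's threshold on a numeric vector (histogram-based between-class
# variance maximisation); returns a value on the input scale.
otsu_threshold <- function(x, n_bins = 128L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w <- cumsum(counts)
  total <- w[length(w)]
  mu <- cumsum(counts * mids)
  mu_t <- mu[length(mu)]
  w0 <- w[-length(w)]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, length(w0))
  between[valid] <- (mu_t * w0[valid] - total * mu[-length(mu)][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  (mids[k] + mids[k + 1L]) / 2
}

# 1/f-shaped Gaussian noise via spectral shaping of white noise; the series
# is rescaled so its sample SD equals sd_target exactly.
pink_noise <- function(n, sd_target, exponent = 1) {
  if (sd_target <= 0) return(rep(0, n))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  idx <- seq.int(0L, n - 1L)
  f <- pmin(idx, n - idx)             # symmetric over positive/negative freqs
  f[f == 0] <- 1                      # avoid dividing the DC bin by zero
  shaped <- X / (f^(exponent / 2))
  shaped[1] <- 0
  y <- Re(stats::fft(shaped, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}
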