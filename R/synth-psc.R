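# Synthetic post-synaptic current traces: Poisson-timed biexponential
# events of configurable polarity on a noisy baseline.

#' Parameters for the PSC trace simulator
#'
#' @param duration_s Trace duration (s).
#' @param rate_hz Sampling rate (samples/s); must resolve the rise time
#'   (at least two samples per `rise_ms`).
#' @param event_rate_hz Mean Poisson event rate (events/s).
#' @param amp_mean_pa,amp_sd_pa Event amplitude distribution (pA,
#'   magnitudes before the polarity sign; truncated at zero).
#' @param rise_ms,decay_ms Biexponential kernel time constants
#'   (`rise_ms < decay_ms`).
#' @param baseline_sd_pa Gaussian baseline noise SD (pA).
#' @param polarity `"negative"` (inward currents, EPSC-like at -60 mV) or
#'   `"positive"` (outward, IPSC-like at 0 mV).
#' @param seed Integer seed.
#' @return An object of class `"psc_sim_params"`.
#' @export
psc_sim_params <- function(duration_s = 240,
                           rate_hz = 10000,
                           event_rate_hz = 2,
                           amp_mean_pa = 30,
                           amp_sd_pa = 8,
                           rise_ms = 1.5,
                           decay_ms = 8,
                           baseline_sd_pa = 2,
                           polarity = c("negative", "positive"),
                           seed = 1L) {
  check_positive(duration_s, "duration_s")
  check_positive(rate_hz, "rate_hz")
  if (event_rate_hz < 0) stop_config("event_rate_hz", "must be >= 0")
  if (rise_ms >= decay_ms) {
    stop_config("rise_ms", "rise time must be shorter than decay time")
  }
  if (amp_mean_pa <= 0) stop_config("amp_mean_pa", "must be positive")
  if (rate_hz * rise_ms / 1000 < 2) {
    stop_config("rate_hz", "too low to resolve rise_ms (need >= 2 samples)")
  }
  structure(list(
    duration_s = duration_s, rate_hz = rate_hz,
    event_rate_hz = event_rate_hz, amp_mean_pa = amp_mean_pa,
    amp_sd_pa = amp_sd_pa, rise_ms = rise_ms, decay_ms = decay_ms,
    baseline_sd_pa = baseline_sd_pa, polarity = match.arg(polarity),
    seed = seed
  ), class = "psc_sim_params")
}

#' Biexponential PSC kernel
#'
#' `(exp(-t/decay) - exp(-t/rise))`, normalised to unit peak.
#'
#' @param t_s Time from event onset (s, >= 0).
#' @param rise_ms,decay_ms Time constants (ms).
#' @return Kernel values in `[0, 1]`.
#' @export
psc_kernel <- function(t_s, rise_ms, decay_ms) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  raw <- exp(-t_s / td) - exp(-t_s / tr)
  t_peak <- (tr * td / (td - tr)) * log(td / tr)
  peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  raw / peak
}

#' Generate a synthetic PSC trace
#'
#' Poisson-timed biexponential deflections of the configured polarity on a
#' Gaussian baseline. Ground-truth onset times, peak times and amplitudes
#' are returned.
#'
#' @param params A [psc_sim_params()] object.
#' @param cell_id,holding_mv Metadata stored on the trace.
#' @return List with `trace` (a `current_trace`: `samples`, `rate_hz`,
#'   `holding_mv`, `polarity`, `cell_id`) and `truth` (data frame
#'   `onset_s`, `peak_s`, `amplitude_pa`).
#' @export
generate_psc_trace <- function(params, cell_id = "cell",
                               holding_mv = NULL) {
  stopifnot(inherits(params, "psc_sim_params"))
  p <- params
  if (is.null(holding_mv)) {
    holding_mv <- if (p$polarity == "negative") -60 else 0
  }
  n <- round(p$duration_s * p$rate_hz)
  local_seed(p$seed, {
    x <- stats::rnorm(n, 0, p$baseline_sd_pa)
    n_ev <- stats::rpois(1, p$event_rate_hz * p$duration_s)
    onsets <- sort(stats::runif(n_ev, 0.05, p$duration_s - 0.1))
    amps <- pmax(0.1, stats::rnorm(n_ev, p$amp_mean_pa, p$amp_sd_pa))
    tr <- p$rise_ms / 1000
    td <- p$decay_ms / 1000
    t_peak <- (tr * td / (td - tr)) * log(td / tr)
    klen <- min(n, round((t_peak + 8 * td) * p$rate_hz))
    kt <- seq.int(0L, klen - 1L) / p$rate_hz
    kernel <- psc_kernel(kt, p$rise_ms, p$decay_ms)
    sign_ <- if (p$polarity == "negative") -1 else 1
    for (k in seq_len(n_ev)) {
      i0 <- floor(onsets[k] * p$rate_hz) + 1L
      i1 <- min(n, i0 + klen - 1L)
      x[i0:i1] <- x[i0:i1] + sign_ * amps[k] * kernel[seq_len(i1 - i0 + 1L)]
    }
    trace <- structure(list(
      samples = x, rate_hz = p$rate_hz, holding_mv = holding_mv,
      polarity = p$polarity, cell_id = cell_id
    ), class = "current_trace")
    truth <- data.frame(onset_s = onsets, peak_s = onsets + t_peak,
                        amplitude_pa = amps)
    list(trace = trace, truth = truth)
  })
}
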