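# Synthetic laminar LFP generator: state-gated theta/gamma/delta oscillators
# with layer-specific amplitude profiles, 1/f background and mains noise.

DEFAULT_LAYERS <- c("SO", "SO", "SP", "SP", "SR", "SR", "SR", "SR",
                    "SR", "SR", "SLM", "SLM", "SLM", "SLM", "SLM", "SLM")

#' Parameters for the laminar LFP simulator
#'
#' Builds a validated parameter set for [generate_laminar_lfp()]. The
#' simulator emulates a 16-contact linear probe spanning CA1: during
#' mobility states a theta oscillator (maximal at SLM) and a gamma
#' oscillator (maximal at SP) are active; during immobility a large
#' irregular delta-band component dominates. A 1/f background and mains
#' (line) contamination with harmonics are added on every channel.
#'
#' @param duration_s Recording duration in seconds.
#' @param rate_hz Sampling rate (samples/s); must be at least 4x the upper
#'   gamma band edge.
#' @param n_channels Number of probe contacts.
#' @param layer_labels Character vector (length `n_channels`) of layer tags
#'   in `{"SO","SP","SR","SLM"}` ordered along the probe.
#' @param state_dwell_s Mean dwell time (s) of the mobility/immobility
#'   semi-Markov states; length 1 (shared) or 2 `(mobility, immobility)`.
#' @param theta_hz,delta_hz,gamma_hz Oscillator centre frequencies (Hz).
#' @param theta_amp_profile,gamma_amp_profile,delta_amp_profile Per-channel
#'   amplitudes (uV). Defaults peak at SLM (theta), SP (gamma) and are
#'   uniform for delta.
#' @param noise_1overf_scale SD (uV) of the 1/f background per channel.
#' @param line_hz Mains frequency (Hz); `0` disables line noise.
#' @param line_amp_uv Amplitudes (uV) of the mains fundamental and
#'   successive harmonics.
#' @param genotype_effects Named list of multiplicative factors
#'   `theta_slm`, `gamma_sp`, `gamma_slm` applied to the corresponding
#'   layer amplitudes (the rhythmopathy dials).
#' @param seed Integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @return An object of class `"lfp_sim_params"`.
#' @export
lfp_sim_params <- function(duration_s = 60,
                           rate_hz = 500,
                           n_channels = 16,
                           layer_labels = NULL,
                           state_dwell_s = 10,
                           theta_hz = 8,
                           delta_hz = 1.5,
                           gamma_hz = 60,
                           theta_amp_profile = NULL,
                           gamma_amp_profile = NULL,
                           delta_amp_profile = NULL,
                           noise_1overf_scale = 15,
                           line_hz = 50,
                           line_amp_uv = c(20, 5),
                           genotype_effects = list(theta_slm = 1, gamma_sp = 1,
                                                   gamma_slm = 1),
                           seed = 1L) {
  check_positive(duration_s, "duration_s")
  check_positive(rate_hz, "rate_hz")
  if (n_channels < 1) stop_config("n_channels", "need at least one channel")
  if (is.null(layer_labels)) {
    layer_labels <- if (n_channels == 16L) DEFAULT_LAYERS else
      c("SO", "SP", "SR", "SLM")[ceiling(seq_len(n_channels) * 4 / n_channels)]
  }
  if (length(layer_labels) != n_channels) {
    stop_config("layer_labels", "must have one label per channel")
  }
  if (!all(layer_labels %in% c("SO", "SP", "SR", "SLM"))) {
    stop_config("layer_labels", "labels must be SO, SP, SR or SLM")
  }
  upper_edge <- max(80, gamma_hz)
  if (rate_hz < 4 * upper_edge) {
    stop_config("rate_hz", sprintf(
      "must be at least 4 x the upper gamma edge (%g Hz)", upper_edge))
  }
  profile_by_layer <- function(map) unname(map[layer_labels])
  if (is.null(theta_amp_profile)) {
    theta_amp_profile <- profile_by_layer(
      c(SO = 20, SP = 30, SR = 60, SLM = 100))
  }
  if (is.null(gamma_amp_profile)) {
    gamma_amp_profile <- profile_by_layer(
      c(SO = 10, SP = 30, SR = 10, SLM = 15))
  }
  if (is.null(delta_amp_profile)) {
    delta_amp_profile <- rep(80, n_channels)
  }
  for (nm in c("theta_amp_profile", "gamma_amp_profile", "delta_amp_profile")) {
    v <- get(nm)
    if (length(v) != n_channels || any(v < 0)) {
      stop_config(nm, "must be non-negative with one value per channel")
    }
  }
  if (length(state_dwell_s) == 1L) state_dwell_s <- rep(state_dwell_s, 2L)
  if (any(state_dwell_s <= 0)) stop_config("state_dwell_s", "must be positive")
  structure(list(
    duration_s = duration_s, rate_hz = rate_hz, n_channels = n_channels,
    layer_labels = layer_labels, state_dwell_s = state_dwell_s,
    theta_hz = theta_hz, delta_hz = delta_hz, gamma_hz = gamma_hz,
    theta_amp_profile = theta_amp_profile,
    gamma_amp_profile = gamma_amp_profile,
    delta_amp_profile = delta_amp_profile,
    noise_1overf_scale = noise_1overf_scale,
    line_hz = line_hz, line_amp_uv = line_amp_uv,
    genotype_effects = genotype_effects, seed = seed
  ), class = "lfp_sim_params")
}

#' Construct a laminar recording container
#'
#' @param samples Channels x time numeric matrix (uV).
#' @param rate_hz Sampling rate (samples/s).
#' @param channel_labels Layer tag per channel.
#' @param speed Optional per-sample locomotion speed trace.
#' @param session_id Session identifier.
#' @param genotype `"control"` or `"mutant"`.
#' @return An object of class `"laminar_recording"`.
#' @export
laminar_recording <- function(samples, rate_hz, channel_labels,
                              speed = NULL, session_id = "session",
                              genotype = "control") {
  if (!is.matrix(samples)) stop_config("samples", "must be a matrix")
  if (nrow(samples) != length(channel_labels)) {
    stop_config("channel_labels", "must have one label per channel row")
  }
  check_positive(rate_hz, "rate_hz")
  structure(list(samples = samples, rate_hz = rate_hz,
                 channel_labels = channel_labels, speed = speed,
                 session_id = session_id, genotype = genotype),
            class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("laminar_recording '%s' (%s): %d channels x %.1f s @ %g Hz\n",
              x$session_id, x$genotype, nrow(x$samples),
              ncol(x$samples) / x$rate_hz, x$rate_hz))
  invisible(x)
}

# Two-state semi-Markov state track (TRUE = mobility) with exponential dwells
simulate_state_track <- function(n, rate_hz, dwell_s) {
  state <- stats::runif(1) < 0.5
  flags <- logical(n)
  i <- 1L
  while (i <= n) {
    dwell <- stats::rexp(1, rate = 1 / dwell_s[if (state) 1L else 2L])
    len <- max(1L, round(dwell * rate_hz))
    j <- min(n, i + len - 1L)
    flags[i:j] <- state
    state <- !state
    i <- j + 1L
  }
  flags
}

# Smooth a 0/1 gate with a short moving average so oscillators ramp on/off
smooth_gate <- function(flag, rate_hz, ramp_s = 0.25) {
  k <- max(1L, round(ramp_s * rate_hz))
  if (k == 1L || all(flag) || !any(flag)) return(as.numeric(flag))
  kern <- rep(1 / k, k)
  padded <- c(rep(flag[1], k), as.numeric(flag), rep(flag[length(flag)], k))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(k + 1L):(k + length(flag))])
}

#' Generate a synthetic laminar LFP recording
#'
#' Produces a channels x time matrix in which theta and gamma oscillators are
#' gated on during mobility states and a delta-band oscillation dominates
#' immobility, each scaled by its per-channel layer amplitude profile, with
#' 1/f background and mains contamination added. The ground-truth state
#' track is returned alongside. Identical `(params, seed)` give bit-identical
#' output.
#'
#' @param params An [lfp_sim_params()] object.
#' @param session_id,genotype Metadata stored on the recording.
#' @return List with `recording` (a `laminar_recording`) and `truth`
#'   (list with per-sample logical `state_track` and the per-window helper
#'   `mobility_fraction` function input data).
#' @export
generate_laminar_lfp <- function(params, session_id = "session",
                                 genotype = "control") {
  stopifnot(inherits(params, "lfp_sim_params"))
  p <- params
  n <- round(p$duration_s * p$rate_hz)
  local_seed(p$seed, {
    t <- seq.int(0L, n - 1L) / p$rate_hz
    single_state <- all(p$state_dwell_s >= p$duration_s * 100)
    flags <- if (single_state) rep(TRUE, n) else
      simulate_state_track(n, p$rate_hz, p$state_dwell_s)
    gate_m <- smooth_gate(flags, p$rate_hz)
    gate_i <- 1 - gate_m

    ph <- stats::runif(4, 0, 2 * pi)   # theta, gamma, delta, line phases
    theta_osc <- sin(2 * pi * p$theta_hz * t + ph[1]) * gate_m
    gamma_osc <- sin(2 * pi * p$gamma_hz * t + ph[2]) * gate_m
    delta_osc <- sin(2 * pi * p$delta_hz * t + ph[3]) * gate_i

    eff <- p$genotype_effects
    theta_amp <- p$theta_amp_profile
    gamma_amp <- p$gamma_amp_profile
    is_slm <- p$layer_labels == "SLM"
    is_sp <- p$layer_labels == "SP"
    theta_amp[is_slm] <- theta_amp[is_slm] * eff$theta_slm
    gamma_amp[is_sp] <- gamma_amp[is_sp] * eff$gamma_sp
    gamma_amp[is_slm] <- gamma_amp[is_slm] * eff$gamma_slm

    line <- if (p$line_hz > 0 && any(p$line_amp_uv > 0)) {
      rowSums(vapply(seq_along(p$line_amp_uv), function(h) {
        p$line_amp_uv[h] * sin(2 * pi * p$line_hz * h * t + ph[4] * h)
      }, numeric(n)))
    } else rep(0, n)

    samples <- matrix(0, nrow = p$n_channels, ncol = n)
    for (ch in seq_len(p$n_channels)) {
      bg <- pink_noise(n, p$noise_1overf_scale)
      samples[ch, ] <- theta_amp[ch] * theta_osc +
        gamma_amp[ch] * gamma_osc +
        p$delta_amp_profile[ch] * delta_osc +
        bg + line
    }
    speed <- pmax(0, gate_m * 12 + stats::rnorm(n, 0, 1))
    rec <- laminar_recording(samples, p$rate_hz, p$layer_labels,
                             speed = speed, session_id = session_id,
                             genotype = genotype)
    list(recording = rec, truth = list(state_track = flags))
  })
}

#' Generate a cohort with fixed genotype effects
#'
#' Convenience wrapper that simulates `n_control` sessions with unit
#' genotype effects and `n_mutant` sessions with `effects_mutant`
#' (e.g. attenuated theta at SLM, enhanced gamma at SP), with independent
#' per-session seeds derived from `seed`.
#'
#' @param n_control,n_mutant Session counts per group.
#' @param effects_mutant Named list of multiplicative factors for mutants
#'   (`theta_slm`, `gamma_sp`, `gamma_slm`).
#' @param params Base [lfp_sim_params()] shared by all sessions.
#' @param session_noise_sd SD of the lognormal between-session amplitude
#'   variability applied to both contrasts.
#' @param seed Integer master seed.
#' @return List of `generate_laminar_lfp()` results with a `genotype`
#'   attribute per element.
#' @export
generate_genotype_cohort <- function(n_control, n_mutant,
                                     effects_mutant = list(theta_slm = 0.75,
                                                           gamma_sp = 1.30,
                                                           gamma_slm = 1.30),
                                     params = lfp_sim_params(),
                                     session_noise_sd = 0.10,
                                     seed = 1L) {
  if (n_control < 1 || n_mutant < 1) {
    stop_config("n_control/n_mutant", "need at least one session per group")
  }
  n_total <- n_control + n_mutant
  seeds <- local_seed(seed, sample.int(2^31 - 1, n_total))
  noise <- local_seed(seed + 1L,
                      matrix(stats::rlnorm(2 * n_total, 0, session_noise_sd),
                             ncol = 2))
  lapply(seq_len(n_total), function(i) {
    mutant <- i > n_control
    eff <- if (mutant) effects_mutant else
      list(theta_slm = 1, gamma_sp = 1, gamma_slm = 1)
    eff$theta_slm <- eff$theta_slm * noise[i, 1]
    eff$gamma_sp <- eff$gamma_sp * noise[i, 2]
    eff$gamma_slm <- eff$gamma_slm * noise[i, 2]
    p <- params
    p$genotype_effects <- eff
    p$seed <- seeds[i]
    generate_laminar_lfp(p,
                         session_id = sprintf("s%02d", i),
                         genotype = if (mutant) "mutant" else "control")
  })
}

#' Generate a session cohort with density-coupled rhythm amplitudes
#'
#' Simulates per-session Cajal-Retzius cell densities along the hippocampal
#' fissure (cells/mm; mutants draw from a higher distribution) and couples
#' them to the oscillator amplitudes: gamma gain at SP/SLM rises and theta
#' amplitude at SLM falls linearly with the density z-score. The ground
#' truth table carries the genotype, density and true modulation factors.
#'
#' @param n_control,n_mutant Session counts.
#' @param coupling Named list: `gamma_sp` and `theta_slm` (fractional change
#'   per density SD; `0` decouples amplitude from density) and
#'   `session_noise_sd` (SD of lognormal session-level amplitude noise,
#'   must be non-negative).
#' @param params Base [lfp_sim_params()] for every session.
#' @param density Named list of the density distributions
#'   (`control_mean`, `control_sd`, `mutant_mean`, `mutant_sd`) and the
#'   fixed standardisation reference (`ref_mean`, `ref_sd`).
#' @param seed Integer master seed.
#' @param recordings Set `FALSE` to skip simulating the LFP matrices and
#'   return only the ground-truth table (`sessions` is then `NULL`); the
#'   table is identical either way for a given seed.
#' @return List with `sessions` (list of `generate_laminar_lfp()` results)
#'   and `table` (ground-truth `session_table` data frame: `session_id`,
#'   `genotype`, `cr_density`, `true_theta_factor`, `true_gamma_gain`).
#' @export
generate_session_cohort <- function(n_control, n_mutant,
                                    coupling = list(gamma_sp = 0.25,
                                                    theta_slm = 0.15,
                                                    session_noise_sd = 0.10),
                                    params = lfp_sim_params(),
                                    density = list(control_mean = 38.33,
                                                   control_sd = 3.95,
                                                   mutant_mean = 52.76,
                                                   mutant_sd = 15.66,
                                                   ref_mean = 45,
                                                   ref_sd = 12),
                                    seed = 1L,
                                    recordings = TRUE) {
  if (n_control < 1 || n_mutant < 1) {
    stop_config("n_control/n_mutant", "need at least one session per group")
  }
  if (is.null(coupling$session_noise_sd)) coupling$session_noise_sd <- 0
  if (coupling$session_noise_sd < 0) {
    stop_config("coupling$session_noise_sd", "variance must be non-negative")
  }
  n_total <- n_control + n_mutant
  draws <- local_seed(seed, {
    genotype <- rep(c("control", "mutant"), c(n_control, n_mutant))
    mu <- ifelse(genotype == "mutant", density$mutant_mean,
                 density$control_mean)
    sd_ <- ifelse(genotype == "mutant", density$mutant_sd,
                  density$control_sd)
    d <- pmax(1, stats::rnorm(n_total, mu, sd_))
    list(genotype = genotype, density = d,
         seeds = sample.int(2^31 - 1, n_total),
         noise = matrix(stats::rlnorm(2 * n_total, 0,
                                      coupling$session_noise_sd), ncol = 2))
  })
  z <- (draws$density - density$ref_mean) / density$ref_sd
  gamma_gain <- pmax(0.05, 1 + coupling$gamma_sp * z) * draws$noise[, 1]
  theta_factor <- pmax(0.05, 1 - coupling$theta_slm * z) * draws$noise[, 2]
  sessions <- if (!recordings) NULL else lapply(seq_len(n_total), function(i) {
    p <- params
    p$genotype_effects <- list(theta_slm = theta_factor[i],
                               gamma_sp = gamma_gain[i],
                               gamma_slm = gamma_gain[i])
    p$seed <- draws$seeds[i]
    generate_laminar_lfp(p, session_id = sprintf("s%02d", i),
                         genotype = draws$genotype[i])
  })
  table <- data.frame(
    session_id = sprintf("s%02d", seq_len(n_total)),
    genotype = draws$genotype,
    cr_density = draws$density,
    true_theta_factor = theta_factor,
    true_gamma_gain = gamma_gain,
    stringsAsFactors = FALSE
  )
  list(sessions = sessions, table = table)
}
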