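---
title: "Methods: rhythm, seizure, synaptic and morphometric analyses in hippophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm, seizure, synaptic and morphometric analyses in hippophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippophys)
```

`hippophys` implements a chain of electrophysiology and morphometry
analyses around a single biological question: how a surplus of
Cajal-Retzius cells (CRs) along the hippocampal fissure reshapes CA1
network function — attenuated theta and enhanced gamma oscillations in
vivo, a shift from bursting to seizure-like activity in
entorhinal-hippocampal slices, more frequent spontaneous inhibitory
currents, and longer, spinier apical dendrites. Raw recordings of this
kind are rarely redistributable, so the package pairs every analysis
stage with a seeded synthetic generator that emulates the statistical
structure of the corresponding recording and carries ground-truth
labels. All claims a test makes are claims about recovery of that known
ground truth.

## Brain-state segmentation and band power (laminar LFP)

**Model.** A laminar recording is a channels-by-time matrix from a
linear probe spanning CA1 (layers tagged SO, SP, SR, SLM). Power
spectra are estimated on 5-s windows stepped every 0.5 s in the channel
of maximal theta power (usually an SLM contact). For each window the
mean periodogram density in the theta (4–12 Hz) and delta (0.1–4 Hz)
bands gives a theta/delta ratio; its distribution over a session is
bimodal, separating theta-dominated mobility from large irregular
activity during immobility. A two-component Gaussian mixture is fitted
to the log-ratios and the equal-density crossing between the component
means becomes the mobility threshold. Runs of supra-threshold windows
are merged into half-open mobility intervals `[start, end)`; band power
is then computed per interval with a Hann-tapered averaged periodogram
(5-s segments, 50% overlap) and intervals are combined as a
duration-weighted mean — the spectral equivalent of appending mobility
periods without creating discontinuity artifacts at the seams.

**Numerical choices.**

* *Log-ratios, shared variance.* Ratio distributions are right-skewed,
  so the mixture is fitted on the log scale. The two components are
  constrained to a shared variance: the immobility mode is several
  times broader than the mobility mode on the log scale, and an
  unequal-variance fit parks the crossing against the narrow mobile
  mode, mislabelling transition windows (window agreement drops from
  ≥ 0.95 to ≈ 0.83 on synthetic sessions). If the fit is degenerate
  (component weight < 0.05 or means closer than 0.1 log-units) the
  method warns and falls back to Otsu's threshold, recorded in the
  diagnostics; a manual threshold is also selectable.
* *Gamma band.* The default quantification band is 40–80 Hz, with
  40–60 Hz selectable in the configuration.
* *Mains handling.* Bins within 2 Hz of 50 Hz and its harmonics are
  excluded from the quantitative band summaries, never interpolated;
  interpolation is a display device, not a measurement.
* *Normalisation.* The one-sided density is scaled so its integral over
  (0, Nyquist] equals the signal variance; a sinusoid of amplitude A
  carries band-integrated power A²/2. Both the band-mean density
  (µV²/Hz) and the band-integrated power (µV²) are reported, since
  boxplot conventions differ between labs.
* *Windows.* Windows extending past the recording end are dropped, not
  zero-padded. Speed, when present, is carried along but never used for
  state detection — the criterion is purely spectral.

**What the generator emulates.** Mobility/immobility alternate as a
two-state semi-Markov process with exponential dwell times (default
mean 10 s); theta (8 Hz, maximal at SLM) and gamma (60 Hz, maximal at
SP) are gated on during mobility, a delta-band oscillation dominates
immobility, and 1/f background (spectrally shaped white noise, exponent
1) plus 50-Hz mains with harmonics contaminate every channel. Genotype
enters as multiplicative factors on theta@SLM and gamma@SP/SLM. It does
*not* emulate phase-amplitude coupling, theta asymmetry, sharp-wave
ripples, or electrode drift, so passing tests certify the segmentation
and band-power machinery, not robustness to every feature of real LFP.

With 5-s windows and 10-s mean dwells roughly half the windows straddle
a state transition; recovered window-level agreement with ground truth
is ≈ 96% pooled over ten 600-s sessions (range ≈ 94–98%), which is the
transition-smear limit of this window length rather than a threshold
artifact.

**Cohorts.** Two cohort builders mirror the study designs: a fixed
genotype contrast (17 control vs 16 mutant sessions; mutants −25%
theta@SLM, +30% gamma@SP by default) and a density-coupled cohort in
which per-session CR densities are drawn from the printed control and
mutant distributions (38.33 ± 3.95 and 52.76 ± 15.66 cells/mm) and
scale the gamma gain up and the theta amplitude down linearly in the
density z-score (defaults 0.25 and 0.15 per SD, 10% lognormal session
noise). The coupling defaults were chosen once, for a clearly
detectable monotone relationship at n ≈ 30 sessions, and are not tuned
to any test outcome.

```{r lfp-demo}
g <- generate_laminar_lfp(lfp_sim_params(duration_s = 60, seed = 1))
res <- suppressWarnings(analyze_session(g$recording))
c(channel = res$channel,
  coverage = round(res$segmentation$coverage_fraction, 2),
  theta_slm = round(res$summary$theta_slm),
  gamma_sp = round(res$summary$gamma_sp))
```

## Burst/seizure taxonomy and initiation mapping (MEA)

**Model.** Each electrode's detection threshold is five times the noise
SD, estimated on the first 500 ms of recording when that window is free
of electrical activity (peak below five times the whole-trace robust
scale) and otherwise on the first qualifying window found sliding
forward in 100-ms steps. Supra-threshold excursions of |signal| merged
across gaps of at most 1 s form discharges. Discharges shorter than 5 s
are bursts; 5 s or longer are seizure-like events (exactly 5 s is a
seizure, making the rule a half-open partition); successive seizures
separated by at most 10 s of silent or bursting activity merge into one
event, and bursts inside a merged span are absorbed. Per-electrode
seizures with overlapping time spans group into slice-level seizures:
onset is the earliest electrode onset, the initiating electrode is the
earliest one (ties by larger initial slope over the first 20 ms, then
lower index), involvement is the set of subregions of all grouped
electrodes, and the initiating compartment follows the hippocampal
formation (DG, CA3, CA1, Sub) versus cortex (Ent, PRh/Ect) split.

**Numerical choices.** Detection uses the absolute signal (events are
both fast oscillations and negative shifts). A minimum discharge
duration of 50 ms discards isolated threshold crossings: at five sigma
over millions of noise samples, single-sample excursions are expected
by chance, and removing them replaces the operator's real-time visual
check, as does the 1-s intra-discharge merge gap. Slice-level grouping
is temporal only — no spatial adjacency requirement — and a "silent"
activity class covers event-free inputs. The boundary and separation
rules are exact to one sample by construction and tested as such.

**Generator.** Gaussian channel noise (default 5 µV SD) with a
guaranteed-quiet first 500 ms (a flag disables this to exercise the
fallback search); bursts as a decaying 15-Hz oscillation followed by a
negative shift, confined to the initiation subregion; seizures as a
sustained 6-Hz spiking envelope with a DC offset, starting on the
initiation subregion and reaching each involved subregion after its
configured lag (defaults 50–250 ms). Events are placed with at least
2 s separation (12 s between seizures) so detection and ground truth
correspond one-to-one. Waveform morphology beyond these envelopes —
spike-wave microstructure, regional amplitude gradients — is not
modelled. The full 12 × 12 grid at 10 kHz is the generator default;
the bundled analyses and tests run reduced grids (2 × 6 to 6 × 6, 1–2
kHz) to keep desk runtimes in minutes, which leaves the per-electrode
algorithms untouched.

## Post-synaptic current detection (patch clamp)

**Model.** Traces are low-pass filtered with a zero-phase 4th-order
Butterworth at 3 kHz. The baseline SD is estimated robustly (MAD),
initial detections are excised with margins, and the SD is re-estimated
once on the remainder; events are deflections of the configured
polarity exceeding twice that SD. Event time is the threshold crossing;
amplitude is the peak (read on a lightly smoothed trace) minus the
local pre-event baseline median. Frequency is the count of all detected
events over a 4-min window; mean amplitude averages the first 100
retained events chronologically (all of them, flagged, if fewer).
Events with a secondary peak in the rising phase of the first current
are excluded from the amplitude analysis with a stated reason.

**Numerical choices.** Three guards make the textbook threshold rule
operational at 2 × SD, where raw Gaussian noise crosses constantly:
a deflection must stay supra-threshold for at least 2 ms (the scale of
a synaptic rise time); qualifying excursions separated by sub-2-ms
dither gaps are coalesced (noise around the crossing on a decay);
and within one excursion, two events are separated only where the trace
descends at least half-way from the previous peak back toward the
threshold. The rising-phase exclusion scans a 1-ms-smoothed trace and
fires only for a secondary maximum at least 1 ms before the absolute
peak with at least half-threshold prominence on both sides plus a
half-threshold rise after its valley — without these guards, crest
noise on isolated events at SNR 10–30 triggers spurious exclusions.
Intrinsic properties follow the fixed conventions: RMP as the mean of
the 0-pA trace, input resistance from the steady-state deflection (last
200 ms) of a 1-s −10-pA step, and F–I spike counts as upward 0-mV
crossings with 1-ms refractoriness.

**Generator.** Poisson-timed biexponential kernels (default rise
1.5 ms, decay 8 ms, 30 ± 8 pA) of either polarity on Gaussian baseline
noise. Real synaptic noise is not white, kinetics vary across events,
and series-resistance artifacts exist in real traces; none of these are
modelled, so the recovery tests certify the detector's rules, not its
behaviour on every real cell.

```{r psc-demo}
g <- generate_psc_trace(psc_sim_params(duration_s = 240,
                                       event_rate_hz = 2, seed = 1))
sm <- summarize_psc(detect_psc(g$trace))
c(true_hz = round(nrow(g$truth) / 240, 2),
  detected_hz = round(sm$frequency_hz, 2),
  mean_amp_pa = round(sm$mean_amplitude_pa, 1))
```

## Morphometry

Morphologies are rooted 3D trees (single point soma at the origin;
straight segments between nodes; apical/basal tags are input
properties, with apical conventionally the dendrites exiting the top of
the soma). Sholl intersections at radius r count the crossings of each
segment with the sphere of radius r centred at the soma, solved exactly
from the per-segment quadratic: a chain crossing exactly at a node
counts once (attributed to the downstream segment), a terminal tip
exactly at r touches without crossing, and a segment dipping through a
sphere twice counts twice — matching a dense-sampling sign-change
oracle exactly on random trees. The default 10-µm radius step resolves
the 120–160-µm window where apical complexity differences concentrate.
Tree metrics are total Euclidean length, branch points (non-root nodes
with two or more children) and terminals. Densities are exact
count/extent records with units, and bilateral (left/right) counts
average to a single observation. SWC files (type 3 basal, 4 apical)
round-trip through `read_swc()`/`write_swc()`.

## Statistics

Contingency, rank and correlation tests delegate to the standard R
routines, wrapped to fix the pipeline's conventions: Fisher's exact
test is two-sided by the point-probability method (summing
hypergeometric probabilities of tables at most as probable as the
observed one), which reproduces all three printed slice-cohort
p-values (0.0187, 1.000, 0.6065) and equals an exhaustive enumeration
oracle on small tables; chi-square is Pearson's without continuity
correction, with expected counts reported and a low-expected flag;
Mann-Whitney/Wilcoxon use exact enumeration for total n ≤ 12 and the
continuity-corrected normal approximation otherwise; Pearson
correlations are tested two-tailed via the t-distribution on n − 2
degrees of freedom. Behavioral indices are preference
t_new/(t_new + t_fam) and discrimination (t_new − t_fam)/(t_new +
t_fam), which satisfy discrimination = 2·preference − 1 identically.
Group descriptives are mean ± SEM with n the number of labelled
independent units. Repeated-measures ANOVA machinery is deliberately
out of scope; the two-group and k-group contrasts here are rank-based.

```{r stats-demo}
fisher_exact_2x2(matrix(c(3, 17, 11, 9), 2, byrow = TRUE))
behavior_indices(0.562, 1 - 0.562)
```

## Problem sizes, determinism and limitations

Every generator is a pure function of its parameters and seed
(bit-identical output, caller's RNG stream untouched). The bundled
analysis scripts and the test suite use session lengths of 60–600 s at
400–500 Hz for LFP, reduced MEA grids at 1–2 kHz, and 240-s PSC traces
at 10 kHz — sizes chosen so a full desk run of simulation, analysis and
statistics completes in minutes while keeping every rule (5-s windows,
5-s/10-s taxonomy boundaries, 2-ms event widths) at its native scale.

Known limitations: the mixture threshold assumes two latent states and
will warn and fall back on genuinely unimodal sessions; window-level
state agreement is bounded by transition smear at ≈ 96% for 10-s
dwells; waveform-shape similarity as an additional cue for separating
successive seizures is deliberately omitted — the duration and gap
rules alone define event identity here; and amplitude summaries on cells with amplitude-dependent
detection loss are biased toward larger events, as in any thresholded
mini analysis.
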