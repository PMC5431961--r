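---
title: "Modelling and detecting hippocampal paroxysmal discharges under DC stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and detecting hippocampal paroxysmal discharges under DC stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpdsim)
```

`hpdsim` simulates the local field potential (LFP) of an epileptic dentate
gyrus, reproduces its hippocampal paroxysmal discharges (HPD) as a
stochastic renewal process, models the pathway from a current-controlled
bipolar stimulator down to per-population membrane polarization, and scores
the result with the same detection pipeline one would apply to recorded
LFP. This vignette describes the model and the design decisions behind the
defaults; every empirical number quoted here is computed by the package's
tests or by `scripts/acceptance.R`.

## The neural mass model

The model describes three interacting subpopulations of the dentate gyrus:
granule cells (GC, the principal excitatory population, with recurrent
excitatory collaterals), slow dendritic-projecting GABAergic interneurons
(ISDI) and fast somatic-projecting GABAergic interneurons (IFSI). Each
population is a pair of transfer functions:

* **Pulse-to-wave (synaptic kernel).** Presynaptic firing rate is converted
  into a postsynaptic potential by a linear second-order low-pass filter
  with transfer function $H(s) = W/(s + 1/\tau_w)^2$ — impulse response
  $h(t) = W\,t\,e^{-t/\tau_w}$, static gain $W\tau_w^2$. The amplitude/rate
  convention used throughout the neural mass literature ($A\,a\,t\,e^{-at}$)
  maps onto it as $W = A a$, $\tau_w = 1/a$, and `synaptic_kernel()` accepts
  both. Default time constants: 10 ms (excitatory), 20 ms (slow dendritic
  inhibition), 2 ms (fast somatic inhibition).
* **Wave-to-pulse (sigmoid).** Mean membrane potential is converted into a
  population firing rate by
  $S(v) = 2e_0 / (1 + e^{r(v_0 - v)})$ with $e_0 = 2.5\,\mathrm{s^{-1}}$,
  $v_0 = 6$ mV, $r = 0.56\,\mathrm{mV^{-1}}$: half-maximal at $v_0$,
  bounded in $(0, 2e_0)$.

The wiring is the established hippocampal configuration of this model
family: the GC population receives Gaussian input noise $p(t)$ plus its own
collateral excitation and the two inhibitory feedback loops (amplitudes
$B$, slow, and $G$, fast); the ISDI population inhibits both the GC and the
IFSI population. Seven dimensionless connectivity constants $C_1..C_7$
(fractions of a single $C = 135$) set the loop gains. The LFP output is the
net summed postsynaptic potential at the GC population, $y_1 - y_2 - y_3$
(excitatory minus slow- and fast-inhibitory PSPs).

### Integration

Each kernel is advanced with its exact zero-order-hold state transition:
for the double pole at $-1/\tau_w$ the matrix exponential is available in
closed form, so the only discretization error is the sample-and-hold on the
kernel input. This keeps the 2 ms fast kernel accurate at the default
512 Hz simulation rate, where a plain forward-Euler step ($\Delta t
\approx \tau_w$) would badly distort it; it is also what makes the
integration-convergence test (halving the step changes the trace RMS by
under 2%) pass with margin.

Noise is drawn once per step. The configured `noise_sd` is referenced to
512 Hz and the per-step deviate is scaled by $\sqrt{f_s/512}$, so the noise
spectral density — and therefore the statistics of the output — do not
depend on the simulation rate. Defaults $p(t) \sim \mathcal N(90, 30)$
s$^{-1}$ follow the conventions of this model family.

## Discharge generation: the INMF

HPD are intermittent, sustained discharges: the system leaves its
background fixed point for a limit cycle and returns, with stochastic
residence times. The package represents this with an Input Noise
Modulation Function (INMF): an alternating renewal process draws a
background duration $\Delta_{BKG} \sim \Gamma(a', b')$ then a discharge
duration $\Delta_{HPD} \sim \Gamma(a, b)$, and during discharge slots a
constant step $K$ is added to $p(t)$. Gamma laws are used because neither
duration can be null (an exponential law, $a = 1$, is explicitly the
excluded special case); `fit_gamma()` implements the shape/rate maximum
likelihood fit used to identify the laws from detected intervals, with the
gamma-function normalization so non-integer shapes are valid.

**Default laws.** The duration laws shipped in `inmf_config()` are the
package's study conditions: $\Delta_{HPD} \sim \Gamma(3, 0.3)$ (mean 10 s,
clearly non-exponential, occasional discharges beyond 30 s) and
$\Delta_{BKG} \sim \Gamma(2.5, 0.08)$ (mean ≈ 31 s). This yields a
baseline relative discharge duration near 0.24, in the middle of the range
reported for chronically epileptic mice (≈ 0.18–0.37).

**Operating point.** The tuned kernel amplitudes of the published discharge
regime are not printed anywhere, so the preset was calibrated: with
$A = 4$, $B = 30$, $G = 10$ mV the model sits at a quiet fixed point under
the default noise (peak-to-peak ≈ 2 mV over 20 s) and crosses into a
large-amplitude spiking limit cycle (peak-to-peak ≈ 20 mV, spike rate
≈ 4 Hz) when the input rises by $K = 200\ \mathrm{s^{-1}}$. The
`background` preset is the same operating point with $K = 0$; the
calibration criterion was (i) zero detected events over 400 s of
background and (ii) reliable detection of every modulation slot, and the
values were frozen before the acceptance checks were written.

## The stimulation pathway

**Interface circuit.** An implanted metal electrode is modelled as a
faradaic impedance $Z_f$ in parallel with a double-layer capacitance
$C_{dl}$, in series with the solution resistance $R_s$:
$C_{dl}\,\dot V_{dl} = i - V_{dl}/Z_f$. Stainless-steel defaults
$Z_f = 0.1$ MΩ and $C_{dl} = 1$ mF give the charge-accumulation time
constant $Z_f C_{dl} = 100$ s. $R_s$ is the resistance of a uniform
cylindrical conductor with the tip cross-section spanning the inter-tip
separation — $R_s = L / (\sigma \pi (d/2)^2) \approx 93$ kΩ for
$\sigma = 0.35$ S/m, $d = 125$ µm, $L = 400$ µm. In the default
current-controlled mode the tissue current equals the drive and the
circuit only shapes the electrode voltage; voltage mode is provided
because charge accumulation then attenuates the delivered current toward
$V/(R_s + Z_f)$.

**Coupling.** A linear model maps tissue current to additive membrane
polarization per population: $dV_j(t) = k_j\, i(t)$ with $(k_1, k_2, k_3)$
in mV/µA for GC, IFSI and ISDI. The offsets are added to each population's
summed presynaptic potential immediately before its sigmoid, which is the
model's agnostic representation of both somatic and synaptic-terminal
polarization. The stimulation offset at the GC input is not included in
the LFP output (it is a stimulation artifact, not synaptic activity).

**Protocols.** `build_protocol("protocol1")` is the polarity study: two
sub-sessions an hour apart, four epochs each of 1 µA for 50 s separated by
300 s, the second sub-session with inverted polarity.
`build_protocol("protocol2")` is the time-course study: 11 epochs of
1 µA / 50 s every 5 minutes, flanked by one-hour stimulation-free blocks.
Epoch waveforms are monophasic and deliberately charge-imbalanced — the
accumulated charge per epoch is exactly amplitude × 50 s.

**Field map.** The potential of the bipolar electrode is the source–sink
superposition $V = I/(4\pi\sigma r_+) - I/(4\pi\sigma r_-)$, evaluated
with the 3-D kernel on a 1 mm² plane through both tips; the field is its
analytic gradient. Cells within one physical tip radius (62.5 µm) are
masked — the point-source model is invalid inside the conductor. With the
default parameters the midpoint field is
$2I/(4\pi\sigma(d/2)^2) \approx 11.4$ V/m and the on-axis maximum off the
mask is ≈ 60 V/m, both well above typical transcranial field strengths.
Iso-field contour levels default to logarithmic spacing over 0.1–100 V/m.

## Detection and quantification

The detection chain mirrors what one would run on recorded LFP:

1. **Band-pass 20–80 Hz**, 4th-order Butterworth applied
   forward–backward. Zero-phase filtering matters because the event slots
   are anchored to detected peak times (−0.1 s / +0.4 s); a causal filter's
   group delay would bias all onsets.
2. **Page–Hinkley change detection.** The cumulative statistic
   $m_t = \sum_i (x_i - \bar x - \delta)$ alarms when
   $m_t - \min_{s\le t} m_s \ge \lambda$, resetting after each alarm. Two
   baseline modes are provided: the classical running mean since the last
   alarm, and a fixed reference level $\bar x = \mu_0$ learned from
   discharge-free data. The *default pipeline* (`detect_hpd()`) runs a
   one-sided test with a fixed baseline on the **squared** band-passed
   signal. Two properties force this choice: a discharge is a sustained,
   nearly zero-mean oscillation, so a mean-change statistic on the raw
   band-passed trace accumulates almost nothing; and a running mean
   re-adapts after the first alarm, so a sustained discharge produces one
   alarm at onset instead of the dense spike train the event-construction
   rules expect (measured alarm gaps exceeded 20 s mid-discharge). On the
   squared signal with a fixed background baseline, every spike's in-band
   energy drives the statistic past $\lambda$ within ≈ 0.2–0.3 s, and the
   drift term $\delta$ keeps background windows quiet.
3. **Calibration.** `calibrate_ph()` learns the three constants from a
   discharge-free reference segment: $\mu_0 = \mathrm{median}$,
   $\delta = 3\times\mathrm{MAD}$, $\lambda = 5000\times\mathrm{MAD}$ of
   the squared reference. The multipliers were set by the false-alarm
   criterion — zero alarms on 60 s background windows across 20 seeds —
   while keeping within-discharge alarm gaps far below the merge threshold.
   By default the analyzed trace itself serves as reference (median and
   MAD are robust as long as discharges are a minority); experiment code
   always calibrates on a separate background simulation instead, because
   a cartography sweep produces conditions where discharge occupancy is
   anything between 0 and 100%.
4. **Event construction.** Each alarm spawns a slot $[t - 0.1, t + 0.4]$ s;
   consecutive slots merge when they overlap or are separated by less than
   0.5 s (so two peaks less than 1.0 s apart share a discharge); the merged
   event runs from the first onset to the last end. Merging is idempotent.
   Intervals are half-open, in seconds.
5. **Features.** Per analysis window $t_{win}$: total and relative
   duration; energy
   $E = \sum_{i=1}^{D} \frac{1}{N(i)} \sqrt{\sum_{j=1}^{N(i)} \vartheta_j^2}$
   over the $D$ detected discharges ($N(i)$ samples each); peak count; and
   RMS over the within-event samples only.
6. **Interval statistics.** Event lengths feed the $\Delta_{HPD}$ fit and
   inter-event gaps the $\Delta_{BKG}$ fit; the censored partial gaps
   before the first and after the last event are excluded.

**Stimulation-edge guard.** An instantaneous current step leaves a
broadband transient in the band-passed trace that the detector would score
as a discharge. Experiment code excludes detected peaks within
[−0.2 s, +0.5 s] of each epoch edge (`stim_edge_guard()`) — the in-silico
analog of the amplifier-saturation window that is discarded around epochs
in vivo.

## In-silico experiments

`sweep_triplets()` maps mean detected HPD duration over a grid of coupling
triplets (five 60 s replicates per triplet by default, one 50 s / 1 µA
epoch each). Replicate streams are seeded from the triplet *values*, so
the map does not depend on grid ordering and can be recomputed piecewise.
`run_protocol()` simulates a whole session, scores one window per epoch
plus matched stimulation-free baseline windows, and summarizes each
condition with boxplot statistics; `compare_conditions()` is the two-sided
Mann–Whitney test (exact null up to n = 20 per group without ties,
tie-corrected normal approximation otherwise). No multiple-comparison
correction is applied, matching the single-test usage the protocols were
designed for.

**Scoring window.** Epoch windows start at the epoch onset by default
(`score = "stim"`). The model is fully observable during stimulation, and
its stimulation effect is instantaneous and memoryless — there is no
plasticity mechanism, and in current mode the polarization vanishes at the
epoch end — so any acute effect lives within the epoch itself.
`score = "post"` and `blank = TRUE` are provided to emulate the in vivo
situation, where amplifiers saturate during epochs and scoring starts at
the epoch end; with this model they measure only the (absent) carry-over.

**Orientation presets.** In this realization the interneuron populations
sit on a short, steep stretch of their sigmoid (their input $C_3 y_0$
spans only a few mV), so dendritic-interneuron couplings beyond
$|k_3| \approx 2$ mV/µA saturate the response in *either* direction:
strong ISDI depolarization locks inhibition on (discharge suppression),
strong ISDI hyperpolarization removes the slow loop and tips the model
into low-voltage fast activity with little 20–80 Hz energy — which the
detector, correctly, does not score as HPD. Large positive GC couplings
($k_1 \gtrsim 30$) likewise produce depolarization block. The cartography
is therefore informative at moderate $|k_1|$ and small $|k_3|$, and the
orientation presets are scaled accordingly: `"suppressive"` =
$(-10, 5, 1)$ (GC hyperpolarized, IFSI and ISDI depolarized) and
`"excitatory"` = $(10, 5, -1)$. The published condition triplets
$(30, 5, -5)$ ("cathodal") and $(-30, 5, 5)$ ("anodal") are kept as
presets under their published labels; note the documented sign ambiguity —
the mechanism described for suppression (GC hyperpolarization plus
dendritic-interneuron depolarization) corresponds numerically to the
*anodal* triplet under this convention, and both conventions are
selectable rather than silently resolved.

With the suppressive orientation, detected discharge time in the minute
covering each epoch drops by roughly 80% relative to baseline (rank-sum
p < 0.001 over 12 replicates); the opposite orientation shows no
reduction. Protocol 1 reproduces the polarity dissociation within a single
session: the suppressive sub-session is nearly discharge-free while the
inverted sub-session matches baseline.

## What the synthetic data do and do not show

The test fixtures emulate what makes detection hard in this setting —
spiky 20–80 Hz transients over coloured background noise, gamma-renewal
burst timing, stimulation step artifacts — and the simulator reproduces
the qualitative phenomenology of the in vivo system: intermittent
high-amplitude discharges, polarity-asymmetric DC effects, realistic duty
cycles. Passing tests therefore show that the pipeline recovers what the
generator put in, at matched signal scales. They do not show that the
detector's constants transfer to recorded data (real LFP has artifacts,
nonstationary background and hardware filtering; `calibrate_ph()` should
be re-run on a discharge-free segment of each recording), nor that the
model's effect sizes predict in vivo effect sizes — the model has no
plasticity, so the cumulative and post-stimulation effects seen in animals
are outside its scope by construction.

## Numerical choices and degenerate inputs

* Problem sizes: unit tests run seconds-to-minutes of simulated time; the
  statistical checks use a single 10,000 s run (gamma recovery, within 15%
  for all four parameters) and 12 replicates of 60 s per condition for the
  polarity effect.
* `sample_schedule()` truncates a final discharge slot at the run end,
  as a finite recording would; interval extraction excludes censored gaps.
* `fit_gamma()` rejects fewer than two samples, non-positive durations and
  all-equal samples (degenerate MLE).
* `peaks_to_events()` treats a gap of exactly 0.5 s as separating (strict
  inequality), and event intervals are half-open.
* The EDF writer quantizes to 16 bits over the signal range (round-trip
  error bounded by one quantization step) and pads the last one-second
  record; `read_signal()` refuses non-uniform time axes rather than
  resampling silently.
* Unknown configuration keys are rejected rather than ignored.

## Known limitations

* Single dentate gyrus source: no propagation to CA3/CA1, no multi-channel
  output.
* No plasticity: lasting and cumulative stimulation effects cannot emerge.
* The stimulation couplings are phenomenological scalars; the field map and
  the couplings are not yet linked by a biophysical neuron-orientation
  model.
* The 2-D field map assumes a homogeneous, isotropic medium and point
  sources.
* Monophasic DC only; charge-balanced pulsed waveforms are out of scope.
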