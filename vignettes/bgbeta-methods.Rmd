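---
title: "bgbeta: model, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bgbeta: model, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical decisions behind
the package: the neuron and network model, the dopamine-depletion and
perturbation knobs, the construction and calibration of the two-loop
Simplified Model, the spectral pipeline, and what the simulations do
and do not emulate about real basal-ganglia recordings.

## Network model

The Complete Model comprises six populations (sizes in parentheses):
striatal D1 (6000) and D2 (6000) medium spiny neurons, fast-spiking
interneurons FSN (420), the pallidal populations GPe-TA (264) and
GPe-TI (780), and the subthalamic nucleus STN (408). GPi and SNr are
deliberately absent: they receive BG output but feed nothing back to
the modelled nuclei, so they cannot shape the oscillation dynamics
studied here. All sizes, neuron parameters and the 19 internal plus 6
external connectivity entries live in
`inst/extdata/complete_model.yaml`; the builders treat that document as
the single source of truth (`bg_config()`).

Neurons are adaptive conductance-based point models integrated with
classical RK4 at `h = 0.1` ms: adaptive exponential
integrate-and-fire for STN/GPe-TI/GPe-TA, adaptive quadratic for
D1/D2, and a quadratic variant with a cubic adaptation nullcline below
a pivot voltage (`V_b`) for FSN. Units follow the usual convention
(pF, mV, nS, pA, ms; external rates in kHz), under which all terms of
the membrane equation are in pA. Spike handling is event-based at step
boundaries: a step whose final voltage reaches `V_peak` is accepted,
the spike is timestamped at the end of the step, the voltage is reset
and the adaptation current incremented by `b` before the next step.
Synaptic and adaptation "delta" terms are exact conductance/current
jumps (the exponential kernels make this exact). Every connection is
an independent Bernoulli draw per ordered neuron pair (no autapses, no
multi-edges), with a fixed axonal delay rounded to the step grid.
External input is an independent Poisson train per neuron whose
synaptic weight is drawn once at build time, uniformly within
`ext_weight ± dev_ext_weight` (the "amplitude" is read as the
half-width of the distribution).

Two numerical guards make the blow-up models safe at a fixed step: the
right-hand side is evaluated with the voltage clamped to `V_peak`
(standard fixed-step AdEx practice — the upward divergence *is* the
spike, and clamping keeps the RK4 stages finite), and the voltage is
floored at −150 mV. In the compiled core the exponential of the AdEx
current is evaluated by a range-reduced polynomial (relative error
below 1e-8); the test suite verifies that compiled single-neuron
trajectories match the pure-R reference integrator to 1e-5 mV over
100 ms including resets, and that the integrator shows the expected
4th-order error scaling on spike-free trajectories.

Randomness is fully owned by the simulator: a master seed spawns
independent counter-derived streams per connection (wiring), per
population (initial conditions and external-weight jitter) and per
population (Poisson drive), so rasters are bit-for-bit reproducible
from `(network, seed)` and independent of R's RNG state.

## Dopamine depletion and perturbations

Dopamine depletion is modelled purely as a gain on the D2 external
drive, `nu_ext(D_d) = D_d * nu_ext_1` (also applied to the auxiliary
D2\* population of the Simplified Model). Raising `D_d` raises D2
activity and, through D2→D1 inhibition, lowers D1 activity; both stay
in the 0.5–2.5 Hz physiological window over the explored range
(`D_d ∈ [0.85, 1.15]`). Effects of dopamine on connectivity strengths
are deliberately not modelled.

Optogenetic-like perturbations (`opto_perturbation()`) operate on the
pathological baseline `D_d = 1.03`: cortical silencing multiplies the
STN drive by 0.75 and the drive of a randomly chosen motor fraction
(20%) of each striatal population by 0.25; STN modulation multiplies
the STN drive by `kappa ∈ [0.65, 1.7]` (spanning STN rates of roughly
10–30 Hz); pallidal silencing subtracts 480 pA (GPe-TA) and 120 pA
(GPe-TI) from the constant currents.

Population-size scaling multiplies every size by `n` and divides every
internal connection probability by `n`, preserving expected in-degrees;
spectra are always computed over a fixed subsample of reference size so
that the shot-noise floor is comparable across `n`.

## The Simplified Model and its calibration

The ablation screen (`ablation_screen()`) quantifies each non-self
connection by the residual summed beta power after replacing it with a
rate-matched, externally driven copy of its source population; the
five connections that dominate beta generation form two loops sharing
GPe-TI: the STN loop (STN ⇄ GPe-TI) and the striatal loop
(D2 → GPe-TI → FSN → D2). The Simplified Model keeps exactly these
players, splitting GPe-TI into equal halves GPTI-A (STN loop) and
GPTI-B (striatal loop). Inter-loop connection probabilities are scaled
by `epsilon`; auxiliary populations D2\*, STN\*, GPTI\* (half size,
external drive only, rate-matched) restore the complementary
`(1 - epsilon)` fraction so the mean input to every nucleus is
epsilon-invariant (probabilities from the halved-size D2\*/STN\* are
doubled). Cross-half GPe-TI inhibition is treated as inter-loop
(epsilon-scaled) with GPTI\* compensation, keeping total pallidal
self-inhibition epsilon-invariant; a config switch (`gpti_cross`)
exposes the alternatives since the split of the self-inhibition
between halves is a modelling choice.

The original parameter adaptations of the Simplified Model are not
available, so the package derives its own with
`calibrate_simplified()` and ships the result as
`inst/extdata/simplified_model.yaml`. Choices made there:

* **Rate targets.** The midpoints of the physiological windows
  (D2 1.5 Hz, FSN 15 Hz, GPe-TI halves 50 Hz, STN 16 Hz). With D1 and
  GPe-TA absent, most populations lose inhibition, so the external
  rates of the real populations are re-tuned by damped multiplicative
  iteration in the assembled `epsilon = 0` network until all rates hit
  the targets; the striatal loop is stiff (its gain is the point of
  the model), hence the heavy damping and step clipping.
* **Auxiliary drives.** Calibrated by bisection on `nu_ext` rather
  than on the constant current: a Poisson-driven auxiliary emits
  irregular trains like the population it replaces, whereas a purely
  DC-driven one would fire quasi-periodically and inject a spurious
  rhythm.
* **Loop intensities.** With only the two beta loops left, the
  connection intensities determine whether each isolated loop shows a
  clear resonance and how the coupled system synchronises. The
  striatal-loop weights are scaled ×1.75 and the STN-loop weights
  ×1.4, selected on a coarse grid as the values at which (i) the
  isolated loops resonate at their natural frequencies (~13 Hz and
  ~19 Hz band-mean), (ii) both resonances stand clearly above the
  shot-noise floor, and (iii) at the STN and D2 read-outs the beta
  power decays with population size in the uncoupled state but is
  preserved at full coupling — the qualitative fingerprint the
  Simplified Model exists to reproduce. This recalibration is the main
  fidelity caveat: the resulting parameters are not the original ones
  (loop-frequency comparisons carry ±1 Hz slack), and at this
  operating point the isolated striatal loop's pallidal half (GPTI-B)
  sits slightly above the oscillation threshold, so its own beta does
  not vanish in the large-size limit the way the loop read-outs do.

## Spectral pipeline

Population activity is the 1-ms-binned spike count of the observed
subsample, expressed as rate per neuron. Spectra use Welch's method
with 2000-sample segments, 1000 overlap and a Tukey(0.25) taper, with
a constant detrend per segment and one-sided density normalisation
(`signal-unit²/Hz`); a 10 s series yields 9 segments on a 0.5 Hz grid.
Band statistics on 8–24 Hz use trapezoidal quadrature on the discrete
grid (both band edges lie exactly on the grid): the power-weighted
mean frequency, and the band-averaged power corrected by the
Monte-Carlo floor `Q(nu0, N)` of an i.i.d. binomial surrogate with the
same observed size and per-bin spike probability. Because data and
surrogate pass through the identical pipeline, the corrected quantity
(`PSD†`) is independent of the normalisation convention; it may be
slightly negative for pure noise and is reported as computed. Averages
over four independent seeds (with across-seed SDs) are the reporting
convention for headline numbers.

Time-resolved spectra (`time_resolved()`) default to 2000 ms windows
stepped by 500 ms, matching the Welch segment. Burst statistics are
the exception: `burst_analysis()` uses 500 ms windows stepped by
125 ms, because beta bursts last fractions of a second — 2 s windows
average them away entirely — and because a 10 s run must provide well
over 30 windowed samples for a meaningful skewness. At 500 ms the band
still spans 9 frequency bins, enough for the band integrals. The
windowed beta-power distribution is summarised by the adjusted
Fisher–Pearson sample skewness (right-skewed: transient bursting; near
zero: sustained oscillation) and by the fraction of windows in which a
below-median STN–D2 frequency gap coincides with above-median beta
power (synchronous epochs carrying the bursts).

## What the tests show, and what they do not

All inputs are generated by the model itself; there is no external
data. The simulations emulate stationary cortical drive (independent
Poisson trains), random unstructured connectivity and rodent-scale
population counts. They do not emulate temporally structured or
correlated cortical input (cortical beta bursts), synaptic plasticity,
spatially organised connectivity, dopamine effects on synaptic
strengths, or primate/human scales — conclusions about those features
cannot be drawn from passing tests. The test suite runs desk-scale
versions of every experiment (5 s simulations, one or two seeds, size
factors up to n = 4, and a 5-point coupling grid), while
`scripts/acceptance.R` recomputes the headline quantities at the full
10 s / 4-seed protocol; these problem sizes are the package's reporting
convention.

Two quantitative limitations are known and deliberate. First, the
model's effective dopamine axis is slightly offset: D1 reaches the
lower edge of its physiological window near `D_d = 1.0` already (and
the striatal loop is correspondingly strong there), which also leaves
the severed-STN-loop ablation ratio `R(STN→GPe-TI)` just above the 1/3
selection threshold even though the ranking of connections is exactly
the expected one. Second, with the shipped pallido-subthalamic weight
(0.08 nS at ~30 afferents per STN neuron) the GPe contributes only a
few Hz of inhibition to STN, so pallidal silencing raises STN activity
by tens of percent, not the much larger increase seen in vivo; the
directions of all perturbation effects (and the selective collapse of
beta under pallidal silencing) are nevertheless reproduced. Both are
properties of the printed parameter set as implemented here; no
parameter was adjusted to mask them.

```{r}
library(bgbeta)
# reproduce the headline pipeline at full scale
net <- build_complete_model(D_d = 1.03)
raster <- run_simulation(net, duration = 10000, warmup = 500, seed = 1)
corrected_beta_psd(welch_psd(bin_rates(raster, "STN")))
```
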