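---
title: "The linear-dynamical cascade model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linear-dynamical cascade model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strfcascade)
```

# The model

`strfcascade` simulates how intrinsic membrane dynamics shape the rate
code of cortical-level auditory neurons in songbirds (the caudal
mesopallium, CM). A model neuron is a cascade of three stages:

1. **Linear front end.** A parametric spectrotemporal receptive field
   (STRF) — a separable Gabor over time lag and frequency — is convolved
   with the spectrogram of a song stimulus, producing a driving current
   $I_{stim}(t)$.
2. **Noise.** A stimulus-independent current $I_{noise}(t)$ with a
   $1/f^\alpha$ power spectrum (red, $\alpha = 2$, by default) is added
   at a fixed signal-to-noise ratio, regenerated each trial.
3. **Dynamical back end.** The summed current drives a conductance-based
   single-compartment neuron. The low-threshold potassium conductance
   $g_{KLT}$ switches the cell between *tonic* firing (sustained spiking
   during depolarization; $g_{KLT} = 0$ nS, $C = 60$ pF) and *phasic*
   firing (spikes only at depolarization onsets; $g_{KLT} = 50$ nS,
   $C = 40$ pF).

Spikes are extracted from the voltage trace, converted to per-syllable
rates $r_{ij}$ (syllable class $i$, trial $j$), and scored with
rate-coding metrics: activity-fraction selectivity
$A = \left[1 - (\sum_i r_i/N)^2 / (\sum_i r_i^2/N)\right] / (1 - 1/N)$,
total entropy $H(R)$, noise entropy $H(R|S)$, mutual information
$MI = H(R) - H(R|S)$, and coding efficiency $1 - H(R|S)/H(R)$, all on
rates discretized into 15 equal-width bins spanning each model's own
rate range, with plug-in probabilities and deliberately *no* small-sample
bias correction (paired models see identical stimuli and trials, so the
bias largely cancels in comparisons).

# The biophysical back end

The membrane equation is

$$C\dot V = -g_{Na} m^3 h\,(V - E_{Na})
          - g_{KHT}(0.85 n^2 + 0.15 p)(V - E_K)
          - g_{KLT} w^4 z\,(V - E_K)
          - g_{KA} a^4 b c\,(V - E_K)
          - g_h r\,(V - E_h) - g_{lk}(V - E_{lk}) + I(t),$$

with every gating variable relaxing as
$\dot x = (x_\infty(V) - x)/\tau_x(V)$. The steady-state and
time-constant functions are those of the ventral cochlear nucleus
channel family of Rothman & Manis (2003), which is the source lineage of
CM models with IKLT, with three adjustments that adapt them to the CM
membrane scale (high input resistance: $g_{lk} = 1.3$ nS on
$C = 40$–$60$ pF gives $\tau_m \approx 30$–$46$ ms, an order of
magnitude slower than the cochlear-nucleus cells the kinetics were fit
to):

* the Na-inactivation midpoint is depolarized by 10 mV — otherwise a
  slow subthreshold approach to threshold fully inactivates the sodium
  current before a spike can start, and no input rate ever produces
  repetitive firing;
* the high-threshold K$^+$ activation midpoints ($n$, $p$) are
  hyperpolarized by 15 mV — otherwise spikes cannot repolarize against a
  sustained drive delivered through a 1.3 nS leak, and the tonic cell
  blocks at a −34 mV plateau after one or two spikes;
* all time constants are halved, a rate correction toward avian body
  temperature from the reference temperature of the source kinetics.

With these adjustments and the published conductance values, the tonic
cell has a rheobase near 49 pA and fires throughout a 500 ms step at
1.5× rheobase (≥ 13 spikes), while the phasic cell (rheobase ≈ 232 pA)
fires exactly one onset spike and stays phasic up to ≈ 400 pA steps. An
additional `phi` parameter scales all gating rates (a Q10-style knob,
default 1) for users who want to explore temperature dependence; the
voltage shifts are part of the model definition and are not exposed as
parameters.

Integration uses an adaptive Cash–Karp 5th-order Runge–Kutta scheme with
mixed absolute/relative error tolerance $10^{-5}$, input currents
linearly interpolated between their 1 ms samples, a step-size cap of
1 ms so no input feature is stepped over, and cubic-Hermite dense output
of the voltage on a uniform 0.025 ms grid. Initial conditions come from
a deterministic resting-state relaxation (1 s of zero input from −70 mV
with gating at steady state), so the only trial-to-trial variability in
an experiment is the noise current. The integrator is cross-checked in
the test suite against `deSolve::lsoda` at $10^{-8}$ tolerance on an
independently written R implementation of the vector field (agreement
well under 0.5 mV RMS away from spike times) and against a fixed-step
RK4 path compiled alongside it.

# The linear front end

**Spectrograms.** Short-time Fourier transform, 256-sample Hanning
window, window starts on an exact 1 ms grid (left-aligned, tail
zero-padded), magnitudes averaged into 50 equal-width channels on
0–8 kHz (bands narrower than the FFT bin spacing are filled by linear
interpolation at the band center). Amplitude is log-scaled by default:
dB above a floor 70 dB below the spectrogram peak, so silence maps to 0.
Log scaling is the standard representation in songbird STRF work; a
linear mode is available and is what the convolution-linearity tests
use.

**Gabor STRFs.** `build_rf()` samples
$RF(t, f) = H(t)\,G(f)$ with
$H(t) = e^{-\frac{1}{2}[(t - t_0)/\sigma_t]^2}
\cos(2\pi\Omega_t (t - t_0) + P_t)$ and
$G(f) = e^{-\frac{1}{2}[(f - f_0)/\sigma_f]^2}
\cos(2\pi\Omega_f (f - f_0))$ on a 100-lag × 50-channel grid.

**Normalization.** The classical convention normalizes the filter's
integral to one, but the algebraic sum of an oscillatory Gabor shrinks
as $e^{-2(\pi\Omega_t\sigma_t)^2}\cos P_t$ and crosses zero with phase:
across a random ensemble the sum spans four orders of magnitude and
flips sign, so dividing by it produces arbitrarily amplified, arbitrarily
signed filters. The default here is therefore unit *energy* (L2)
normalization, followed by a sign orientation that makes each filter net
excitatory (positive integral; for near-zero-sum Gabors the dominant
lobe decides) — preserving the intent of the integral convention
(excitatory filters of commensurate strength) without its degeneracy.
`norm = "integral"` (with an L1 fallback), `"l1"` and `"none"` remain
available and the applied mode is recorded in the object.

**Drive.** The convolution is causal in lag, zero-padded at stimulus
onset, divided by the RF's spectral bandwidth $\sigma_f$ (in kHz) to
equalize narrowband and broadband filters, and computed on a
mean-centered spectrogram so the current fluctuates about zero (an
un-centered non-negative spectrogram hands every net-excitatory filter a
large standing offset that has nothing to do with spectrotemporal
match).

**Gain calibration.** The absolute pA scale of the convolution is not
identified by the model, so it is calibrated: each RF's gain is set so
that its drive, pooled over the stimulus set, has a standard deviation
of 200 pA. At this level tonic models fire at 20–30 Hz and phasic
models at 5–10 Hz across seeds, with no silent models — the firing-rate
regime of cortical-level auditory neurons. Calibration is per-RF by
default because the residual amplitude spread of an L2-normalized
ensemble against any one stimulus set is still roughly tenfold
(filters tuned to modulations the stimulus lacks receive weak drive):
one shared gain either silences the weakly matched third of the
ensemble or drives the strongly matched models into depolarization
block. Phasic/tonic partners share their RF's gain, so every paired
comparison is unaffected by this choice; a pooled `"shared"` mode is
available. In the temporal-modulation sweep, the variants of a base RF
share one gain (calibrated on their pooled drives) so that the sweep
retains the natural decline of drive power with $\Omega_t$ — per-variant
calibration would equalize away the very gradient under study. All
gains are frozen per experiment, so sweep conditions differ only in the
swept variable.

**Noise.** $1/f^\alpha$ currents are synthesized in the frequency
domain (amplitudes $\propto f^{-\alpha/2}$, uniform random phases, DC
zeroed), giving the exact target spectrum in $O(n\log n)$, then scaled
so that the RMS-amplitude ratio of that trial's $I_{stim}$ to
$I_{noise}$ equals the configured SNR (default 4; a power-ratio
convention is available). Noise seeds derive deterministically from
(base seed, RF, stimulus, trial) — and not from the dynamics type — so
the phasic and tonic members of a pair receive bit-identical noise.

# The synthetic song generator

Experiments run on generated song-like stimuli so that no recordings
need to be distributed. Each song is a sequence of syllables (50–200 ms)
separated by silent gaps (10–60 ms), preceded by 50 ms of low-level
noise that pads the convolution. Syllables are broadband, as zebra finch
syllables are: harmonic stacks (fundamentals 500–2000 Hz, harmonics
extending toward 8 kHz with slow $k^{-1/2}$ decay, over a weak broadband
noise bed) or band-limited noise bursts spanning low and high band
edges. Envelopes carry deep, irregular amplitude modulation (two
sinusoidal components in 10–50 Hz, variable depth), because phasic cells
respond to envelope events and real syllables contain strong internal
modulation. Syllable types differ in level over a ~12 dB range, and a
configurable fraction of syllables are repeats of an earlier type,
sharing its class label as repeated motifs do. Layout is computed in
integer samples, so boundaries are exact and reproducible from the seed.

What the generator does *not* emulate: frequency-modulated sweeps,
song-level syntax, ambient reverberation, and the full modulation
spectrum of natural song (its temporal modulation energy falls off
faster above ~50 Hz than real song's). Passing tests on these stimuli
demonstrate the mechanics of the cascade and the direction of the
dynamics effects, not quantitative agreement with responses to natural
song.

# Experiment scales

The default desk-scale profile is 20 RF pairs × 10 songs of 1 s × 5
trials (2 000 one-second simulations, about half a minute on one CPU
with the compiled ODE core); the `"paper"` profile selects the
full-scale design (60 pairs × 30 songs of 2.025 s × 10 trials). The
temporal-modulation sweep default is 4 base RFs × Ω_t ∈ {10, 40, 80} Hz
× both dynamics on 5 songs × 5 trials, and the g_KLT sweep 10 RFs ×
{0, 10, …, 50} nS × 5 songs × 3 trials. Every random stream (stimuli,
RF ensemble, noise trials) derives from one base seed through a
multiplicative hash, making full runs bit-reproducible.

# Numerical conventions

* Units: mV, ms, pF, nS, pA (so $g \cdot V$ is in pA and $I/C$ in
  mV/ms); user-facing times are in seconds.
* Spike detection: upward crossing of −20 mV followed by the local
  maximum within 2 ms; crossings within 2 ms of the previous spike are
  ignored. Model spikes overshoot 0 mV, so detection is insensitive to
  the threshold over a wide range.
* Syllable assignment: half-open intervals $[onset, offset)$; a spike
  exactly at an offset belongs to the next interval or gap. Repeated
  syllables pool counts and durations within a trial before dividing
  (pooled-rate convention).
* Discretization: 15 equal-width bins over each model's min–max rate,
  top bin right-closed; a model whose rates are all equal is flagged
  degenerate with zero entropies; an entirely silent model has undefined
  selectivity (`NA`) and is excluded from ensemble correlations.
* Statistical layer: classical paired t, Pearson correlation,
  two-sample Kolmogorov–Smirnov, and the interaction F from
  `metric ~ dynamics * covariate`, all two-sided and uncorrected.

# Known limitations

The exact CM recalibration of the channel kinetics used by the original
cascade is specified in supplementary material that is not reproduced in
the main text, so this package's adjustments (above) were derived from
first principles: make the zero-g_KLT cell fire tonically, the
50 nS cell phasically, from the published conductances. Most ensemble
results are insensitive to the details; one is not. Our phasic cell is a
*hard* slope detector — it needs ≈ 400 pA excursions to follow a 10 Hz
modulation, ≈ 250 pA at 20–40 Hz — so weakly or slowly modulated drives
silence it entirely rather than engaging it broadly. Two consequences,
both visible as failed expectations in the acceptance test suite and
worth knowing before interpreting results:

* the paired mutual-information difference comes out in favor of the
  *tonic* model on average (≈ −0.3 bits): phasic reliability (noise
  entropy ≈ 0.6 bits below tonic, in every pair) is outweighed by a
  total-entropy deficit (≈ 1 bit) created by the syllables the phasic
  cell never responds to;
* phasic selectivity is not monotonically increasing in the RF's
  temporal modulation frequency: at Ω_t = 10 Hz the phasic cell is
  "starved-selective" (responds to almost nothing) instead of broadly
  responsive, which flattens or inverts the low end of the gradient.

Attempts to soften the phasic threshold within this kinetic family
(shifting the KLT activation midpoint) destroy phasic firing itself
within +4 mV, so the behavior appears intrinsic to the consensus
kinetics rather than a tuning artifact. The selectivity, reliability,
total-entropy and efficiency effects of phasic dynamics — including
their abolition under white noise and their monotone scaling with
g_KLT — do not depend on this and reproduce robustly.
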