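---
title: "Methods: layer-specific analysis of evoked laminar LFPs during low-frequency tACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-specific analysis of evoked laminar LFPs during low-frequency tACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A linear multielectrode ("laminar probe") inserted perpendicular to the
cortical surface records local field potentials (LFPs) simultaneously
across all cortical layers. When a flash stimulus evokes a response, its
first positive component (P1, near 75 ms) and first negative component
(N1, near 120 ms) grow with depth. If a weak sinusoidal current (tACS)
is applied at the scalp at the same time, two analysis problems arise:

1. the stimulation artifact in the recording is orders of magnitude
   larger than the LFP and must be removed without distorting the evoked
   response, and
2. the scientific question — does the stimulation phase at which a flash
   arrives modulate the evoked components, and in which layers? —
   requires circular statistics with careful permutation nulls, because
   amplitudes sorted by phase bin are noisy and any parametric assumption
   about their circular distribution is unwarranted.

`lamtacs` implements the full chain: preprocessing, artifact removal,
stimulation biophysics, layer assignment, phase-dependency statistics,
a cluster-based condition comparison, multi-unit (spiking) analysis, and
a reduced mechanistic demonstrator. A synthetic session generator with
known ground truth makes every stage testable end to end.

# The synthetic session generator

The generator emulates the recording conditions the pipeline targets:

* 23 contacts at 0.1 mm spacing bracketing the cortex (default layer
  truth: 3 contacts above the cortex, 2 in L1, 5 in L2/3, 2 in L4AB,
  4 in L4C, 4 in L5/6, 3 in white matter);
* flashes at 2.3 Hz, stimulation at 1.5 Hz with 30 s cosine ramps; the
  two rates are non-harmonic, so onset phases cover the cycle almost
  uniformly (the ratio 15/23 visits 23 equally spaced phases);
* evoked responses built from two Gaussian lobes (P1 at 75 ms,
  sigma 8 ms; N1 at 120 ms, sigma 12 ms — the literature constrains peak
  windows, not waveform shape, so the smoothest parameter-transparent
  choice was used), with amplitude profiles monotone increasing with
  depth, plus a depth-localized early deflection at 45 ms centered on
  L4C that reproduces the early input-layer sink used for layer
  assignment;
* a stimulation artifact with a depth profile whose spatial gradient
  (electric field) peaks in L2/3 at ~2.5 V/m; the mean artifact
  potential is roughly 50-100x the deep-layer component amplitudes.
  Recordings do not constrain the artifact-to-LFP ratio at the probe,
  so this is a deliberate default, exposed through
  `ac_amplitude_scale`;
* phase-dependent modulation of the deep-layer (L4AB/L4C/L5/6)
  components: `a(phi) = a0 (1 + m cos(phi - phi_pref))` (unimodal) or
  with doubled angle (axial), default depth `m = 0.3` and preferred
  phase -90 degrees (the rising phase); the N1 preference is offset by
  180 degrees, as a driving-force mechanism implies;
* pink (1/f) noise per contact with a 20% common-mode component
  (volume conduction), 60 Hz line noise, and a x10 acquisition gain;
* optionally a 20 kHz wideband stream carrying the volume-conducted
  LFP, white noise, and Poisson spike trains (1 ms biphasic templates,
  ~10x noise SD) with higher deep-layer rates and an evoked rate
  increase after each flash.

What the generator does **not** emulate: absolute microvolt scales of
any particular recording, spike waveform diversity, non-sinusoidal
artifacts, electrode drift, or spontaneous oscillatory activity. Tests
passing on these synthetics therefore demonstrate the correctness of
the algorithms under controlled conditions, not performance on any
specific animal dataset.

Noise streams for the two conditions derive from one master seed in a
fixed order (Flash noise, Flash+AC noise, Flash spikes, Flash+AC
spikes), so runs are reproducible without artificially pairing the
conditions' noise.

# Preprocessing

The LFP path applies a 4th-order Butterworth band-pass (0.5-100 Hz) and
a 60 Hz biquad notch (Q = 35), both forward-reverse. Zero-phase
application is essential — component latencies must not shift — and
doubles the effective magnitude roll-off; this is accepted and
documented rather than compensated. The record is then decimated to the
1 kHz analysis rate (the band ends at 100 Hz, so plain decimation after
filtering is alias-free).

Epochs span -50..250 ms around each onset (301 samples at 1 kHz,
closed endpoints), baseline-corrected by the mean over [-50, 0) ms.
Trial rejection uses a mean +/- 5 SD envelope computed per contact and
timepoint across trials; a trial is excluded if any sample leaves its
envelope. The pooling axis of that rule is a genuine design choice (it
could also pool over contacts, or use per-trial RMS); per-contact/
timepoint was chosen as the most sensitive variant and the per-trial-RMS
alternative is available via `analysis_config(reject_pool =
"per_trial_rms")`. Peak searches break ties toward the earliest sample
so results are deterministic.

P1 is the maximum in 55-90 ms, N1 the minimum in 100-140 ms, per trial
on layer-averaged traces.

# Artifact removal

Second-order blind identification (SOBI): the record is whitened
(eigenvector subspace covering 99.999% of variance — the artifact
dominates variance and must never be discarded; genuinely null
directions are dropped with a warning), lagged covariance matrices are
symmetrized and jointly diagonalized by Jacobi sweeps, and sources are
the rotated whitened channels. Choices the source texts leave open:

* **Lag set**: 50 log-spaced lags spanning 1-500 ms, so the covariance
  stack sees both the slow artifact and LFP-band structure.
* **Estimation rate**: lagged covariances are estimated on an
  anti-alias-safe decimated copy (~500 Hz; the filtered content ends at
  100 Hz), purely for speed; the unmixing is applied at the full rate.
* **Flagging criterion**: a source is flagged when its power in
  `f0 +/- 0.1` Hz exceeds 10x the local spectral background (median
  power within +/-0.75 Hz, excluding the +/-0.15 Hz core). A broadband
  reference would mis-flag 1/f neural noise, which concentrates power
  at low frequencies. Harmonic bands (3 and 4.5 Hz) are reported but do
  not drive flagging.
* **Subtraction**: only the least-squares-fitted `f0` sinusoid is
  subtracted from each flagged source (not the whole component), fitted
  on the stimulation plateau (the 30 s ramps are excluded, where the
  artifact is nonstationary) and subtracted everywhere. Back-projection
  then removes exactly a per-contact sinusoid; the cleaned record plus
  the removed reconstruction equals the input identically.

On the default synthetic session this attenuates the 1.5 Hz line by
70-100 dB per contact while leaving the evoked average correlated > 0.99
with the clean truth.

# Stimulation biophysics

The stimulation potential is extracted per contact by a 4th-order
zero-phase Butterworth band-pass at 0.5-2 Hz and divided by the
acquisition gain (x10). A direct transfer-function design at 0.5-2 Hz
against a 1 kHz Nyquist is numerically ill-conditioned, so the band-pass
runs on an anti-aliased decimated copy (~100 Hz) and the band-limited
result is spline-interpolated back to 1 kHz; for content below 2 Hz the
interpolation error is far below 1%.

The electric field along the probe is the numerical gradient (central
differences, one-sided ends) of the per-contact voltage amplitudes:
mV over mm gives V/m directly. Amplitude and phase at the dominant
frequency come from an FFT peak pick (power-of-two prefix; prime-length
transforms are quadratic) refined by maximizing the fitted sinusoid
amplitude, then a least-squares fit over an integer number of cycles.

Phase labels use the analytic-signal (Hilbert) angle of the narrowband
waveform at each onset sample, under the package-wide cosine convention
(0 degrees = artifact peak, -90 = rising zero-crossing); onsets within
one stimulation cycle of the record edges are marked invalid. The
default label source is the contact with the largest artifact; the
pipeline computes labels from the **raw** (pre-cleaning) record because
the sinusoid subtraction removes exactly the signal that defines phase.
The virtual-AC control labels the no-stimulation condition against a
fictitious 1.5 Hz cosine starting at record time zero.

# Layers

CSD is the plain second spatial difference (`-(phi[i-1] - 2 phi[i] +
phi[i+1]) / h^2`, unit conductivity, no spline or spatial smoothing),
defined at interior contacts, with sinks negative (the convention is
recorded on the object). Layer assignment codifies the combined rule
used with laminar probes: the L1 boundary is the first contact where
the field rises above the outside-cortex reference (mean + 2 SD of the
topmost contacts — "begins to increase" is qualitative, so k = 2 is the
codified default); L4C is centered on the interior contact with the
earliest post-stimulus CSD sink (first crossing below 5 pooled baseline
SDs inside 20-100 ms; per-contact baseline SDs proved too unstable to
threshold against); remaining boundaries are filled from prior extents
(2 contacts L1, 5 L2/3, 2 L4AB, 4 L4C, 4 L5/6). When either signal is
absent the map falls back to the priors with a warning. This fill-in
rule is the package's codification of an informal practice and is
flagged as such in the output (`provenance` column).

Evoked traces can be normalized to the maximum absolute value of the
L5/6 trace (idempotent, scale-invariant).

# Phase dependency

Trials are sorted into 20 bins of 18 degrees (right-open edges, +180
joining the last bin). The circular resultant is computed over bin
centers weighted by per-bin **mean** amplitudes — means, not sums, so
the statistic is invariant to unequal bin occupancy; this choice is
open in the source texts and is the package default. Weights are
magnitudes (N1 enters as |N1|); a signed-weight mode exists but is off
by default. The axial (bimodal) mode doubles angles and halves the
direction, reported in (-90, 90].

The permutation test shuffles the amplitude-to-bin assignment (bin
occupancy is invariant under the shuffle, which the vectorized
implementation exploits), computes the surrogate vector length
`n_perm = 5000` times, and reports `z = (R_obs - mean) / sd`,
`p = (#{R_surr >= R_obs} + 1) / (n_perm + 1)` (never exactly zero), and
a significance flag `R_obs > 95th percentile` of the surrogates. By
default surrogates use the same mode as the observed statistic; a
`surrogate_mode = "unimodal"` switch reproduces the asymmetric
comparison of an axial observed length against unimodal surrogates.
Vector lengths below 1e-12 are treated as exact zeros so that constant
amplitudes give `p = 1` rather than floating-point coin flips.

The Rayleigh test (`z = n R^2` with the finite-n corrected p) checks
label uniformity.

# Cluster-based condition comparison

Pointwise pooled-variance unpaired t statistics at every (contact,
time) cell over kept trials (trial counts differ between conditions, so
an unpaired design is required); cells with |t| above the two-sided
pointwise 0.05 threshold are clustered. Adjacency is spatiotemporal by
default — along time within a contact, and across neighboring contacts
at overlapping times — because reported clusters span multiple
neighboring contacts; a pure temporal mode is exposed and the mode used
is recorded in the output. Cluster mass is the sum of member t values;
positive and negative clusters stay separate. The null is the maximum
absolute cluster mass over 2000 label shuffles; cluster
`p = (#{null >= |mass|} + 1) / (n_perm + 1)`, significant at the 0.01
critical value. The smallest attainable p is therefore 1/2001.

# Multi-unit activity

The wideband stream is band-passed 300-5000 Hz (4th order,
forward-reverse; zero phase keeps spike peak times). The detection
threshold is `alpha * median(|x|) / 0.6745` with `alpha = 3.5` — the
robust Gaussian noise-SD estimate, insensitive to the spikes themselves.
Events are positive-going threshold crossings with a 1 ms dead time
(polarity and refractory handling are open in the source texts; the
positive-crossing choice matches the generator's spike polarity and a
negative-crossing mode is a one-line change). PSTHs count spikes in
10 ms bins over 0-250 ms, converted to spikes/s, averaged over trials
then over a layer's contacts. Peak/trough trials are those within
+/-45 degrees of 0/180 — a window consistent with roughly a quarter of
trials per set. Rate comparisons are standard paired (between layers
within a condition) and unpaired (between conditions) t tests.

# The driving-force demonstrator

The full mechanistic account lives in a biophysically detailed cortical
column model that is far outside desk scale; the package instead ships
a deliberately reduced single-compartment demonstrator of the same
mechanism, for sign and monotonicity only. A passive membrane
(`tau_m = 10` ms, `E_L = -70` mV) is polarized by a 1.5 Hz field
(default 16 V/m — i.e., 16 mV/mm — with coupling `lambda_E = 0.2`
mV/(V/m), a free parameter at this level of reduction) and receives an
alpha-function excitatory conductance (`E_syn = 0` mV) centered either
on the polarization maximum or minimum (the RC lag `atan(omega tau)` is
accounted for). Heun integration at 0.1 ms with a `tau_m/10` stability
guard; conductance onsets are snapped to the integration grid so a zero
field yields an exactly zero peak-trough difference. Depolarization at
the field peak weakens the driving force `V - E_syn`, so the peak EPSC
is less negative: the peak-minus-trough current difference is positive
throughout the input window, antisymmetric in the field sign, and
monotone in field amplitude.

# Problem sizes used by the test suite

The suite regenerates everything it tests. The study-scale pair (240 s,
~413 trials) backs the end-to-end checks; structural checks run on a
90 s pair. Calibration suites use: 200 null runs of the phase
permutation test (400 trials, 2000 shuffles each); 100 null runs of the
cluster test (60 trials/condition on a 23 x 151 grid, 500 shuffles);
50 seeds for preferred-phase recovery at m = 0.3 with trial-amplitude
noise of half the mean amplitude ("moderate" noise, chosen to sit
between the clean and the hopeless regimes); 8 seeded sessions for
laminar boundary recovery. These sizes are the package's choices for a
desk-scale reproduction and are stated here so they can be scaled up
deliberately.

# Known limitations

* SOBI is fit on the whole record (a per-segment option would suit
  nonstationary artifacts; the default artifact here is stationary
  between ramps).
* The DFT subtraction removes a single stationary sinusoid per flagged
  source; amplitude-drifting artifacts would leave a residual.
* Layer assignment depends on the presence of an early input-layer sink
  and a detectable field rise; absent either, it degrades to priors.
* Phase labels cannot be recomputed after cleaning (the cleaning removes
  the phase-defining sinusoid); the pipeline orders stages accordingly.
* The driving-force module demonstrates a mechanism's sign structure;
  it makes no quantitative prediction about LFP amplitudes.
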