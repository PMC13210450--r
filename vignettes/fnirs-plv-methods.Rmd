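---
title: "Methods: simulation, preprocessing, and PLV network inference for prefrontal fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing, and PLV network inference for prefrontal fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fnirsplv` implements a complete analysis chain for block-design prefrontal
fNIRS experiments that contrast two task conditions — here labeled OOC
(other-oriented consumption) and SOC (self-oriented consumption), two
framings of a product-selection task — together with a synthetic data
generator that makes every stage testable without access to recordings.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic tests
can show.

## The experimental design being modeled

A 15-channel continuous-wave NIRS montage covers the forehead with 3 cm
source–detector separation, sampled at 8.138 Hz at two wavelengths
(defaults 780/850 nm). Each trial is a 0.5 s introduction, a 24 s task
period presented as three consecutive 8 s stimulus screens (one product
selection each), and 35 s of rest; each condition comprises a contiguous
block of 10 trials, so a condition block spans 595 s (~10 min) and yields
30 selections. Condition order is randomized per subject (counterbalanced
across a cohort by varying `order_seed`). `generate_paradigm()` encodes
this schedule; `selection_counts()` and the schedule invariants (contiguous
non-overlapping trials, screens at task onset + 0/8/16 s) are enforced at
construction.

The 15 channels partition into seven regions of interest (`roi_map()`):
lateral right (Ch01–02), upper right (Ch03/05/06), lower right (Ch04/07),
center (Ch08), upper left (Ch09/11/12), lower left (Ch10/13), and lateral
left (Ch14/15). The central ROI4, adjacent to the medial prefrontal cortex,
is the seed for the seed-based profile S1..S6 (S5 = ROI6–ROI4).

## Synthetic data model

`simulate_hemodynamics()` generates ΔHbO per channel as the sum of:

* **Task response** — a canonical double-gamma hemodynamic response
  function (`hrf_double_gamma()`, positive lobe peaking near 6 s,
  undershoot near 16 s, ratio 1/6) convolved with the condition's 24 s task
  boxcars. The session response waveform is normalized to unit peak so the
  `amplitude` argument is the peak evoked ΔHbO in μM (default 0.5 μM, a
  typical cortical response magnitude). A channel × condition amplitude
  matrix plants condition-specific activation effects. The canonical HRF
  shape is a standard modeling choice; nothing in the analysis depends on
  its exact parameters because the connectivity band (0.005–0.05 Hz) is far
  below the HRF's spectral detail.
* **Band-limited background** — Gaussian noise filtered to 0.005–0.05 Hz
  with standard deviation `band_sd_um` (default 0.15 μM). This is the
  component that carries planted phase coupling: for channels listed in a
  `coupling_spec()`, a fraction `strength` of the band-limited variance is
  replaced by a shared sinusoidal oscillator (frequency inside the band,
  default 0.02 Hz; per-channel phase lags). Strength 1 with no wideband
  noise therefore forces a phase-locking value of 1 on the designated pair,
  and strength 0 reduces to independent backgrounds — the two analytic
  anchors the recovery tests use.
* **Physiological and instrumental noise** (`noise_spec()`) — sinusoids
  with per-channel random phase at the cardiac (~1 Hz, 0.2 μM),
  respiratory (~0.3 Hz, 0.1 μM), and Mayer-wave (~0.1 Hz, 0.1 μM)
  frequencies; white noise (0.1 μM); a per-channel linear drift (slope up
  to 5e-4 μM/s); optional motion spikes, off by default since the analysis
  chain deliberately contains no motion-correction stage.

ΔHbR is emitted as −1/3 of ΔHbO plus small independent noise: the analysis
uses ΔHbO only, and ΔHbR exists to exercise the two-chromophore
Beer–Lambert algebra and for reference plots. All randomness flows from a
single integer seed; sub-generators derive child seeds deterministically,
so equal (arguments, seed) yields bit-identical output.

Because all channels share the task response, band-limited activity is
task-locked across the montage and baseline PLV is high (~0.8 with the
defaults) — as in real block designs, where strong within-task coherence is
expected and the published threshold-0.7 binary maps are well populated.
Planted coupling is detected *relative to* that baseline.

`forward_mbll()` maps (ΔHbO, ΔHbR) to dual-wavelength intensities through
ΔOD(λ) = (ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR)·d·DPF(λ), I = I₀·10^(−ΔOD), with
defaults d = 3 cm, DPF = 6 at both wavelengths, and decadic extinction
coefficients of the usual magnitude for 780/850 nm (all overridable; the
inversion is exact regardless of the constants chosen, provided the same
table is used both ways). `mbll_invert()` solves the per-sample 2 × 2
system; the round-trip is the identity to ~1e-14 μM.

`simulate_behavior()` emits one record per selection: response times from a
normal truncated to (0, 8000] ms and a low-price choice indicator. Default
probabilities of choosing the lower-priced option are 7/30 (OOC) and
22.97/30 (SOC) — the observed selection-frequency regime — while default RT
means are equal across conditions with a between-subject condition shift
(sd 900 ms), so the group RT contrast is null but individual subjects show
sizeable differences of either sign, matching the reported pattern
(many individually significant subjects, no group effect).

## Preprocessing chain

`mbll_invert() → resample_series() → bandpass_series() →
epoch_and_baseline()`, mirroring the acquisition-to-epochs order:

* **Resampling to 2 Hz.** A zero-phase Butterworth anti-alias low-pass
  (order 6, cutoff 0.8 × target Nyquist = 0.8 Hz) followed by cubic-spline
  evaluation on the 2 Hz grid. This construction was chosen over a
  rational-ratio polyphase FIR because the 8.138→2 conversion has the
  awkward ratio 1000/4069 and the polyphase implementation available to us
  lost ~15% amplitude on an in-band 0.02 Hz sinusoid; the filter-plus-spline
  route preserves in-band amplitude to <0.01% (asserted in tests). Marker
  times are seconds and carry over unchanged.
* **Band-pass 0.005–0.05 Hz.** Third-order Butterworth applied forward and
  backward (zero phase, squared magnitude response). Edge handling uses
  odd-symmetric reflection padding of 3 × the slowest filter time scale
  (1/f_low), with a floor of 100 × order samples so the recursion's own
  state transient dies inside the padding, capped at n−1. The measured
  stop-band attenuation at 0.3 Hz equals the analytic squared order-3
  response to within 0.01%.
* **Epoching.** Half-open window [−1, 61) s relative to task onset at 2 Hz
  → exactly 124 samples per epoch; the onset sample is the first sample at
  or after the marker. Baseline correction subtracts the mean over
  [−1, 0) s per epoch and channel. Trials whose window exceeds the record
  are dropped with a recorded reason — hence the generator's 5 s lead-in
  and 10 s tail defaults, which make all 10 trials epochable. Filtering is
  always applied to the continuous record, never per epoch.

Resampling before filtering follows the stated processing order of the
modeled pipeline; since both operations are linear and the band of interest
lies far below both Nyquist rates, the order is numerically immaterial
(the in-band round-trip error is <2% RMS end-to-end).

## Connectivity

Instantaneous phase is the angle of the analytic signal, built by FFT
half-spectrum doubling (`instantaneous_phase()`); the transform's circular
boundary distorts phase near the record ends, so 50 s (about one cycle at
the band's lower-middle frequencies) is trimmed from each end before use.
The phase-locking value of two channels is

PLV = | (1/N) Σₜ exp(i·Δφₜ) |,

computed over one continuous condition segment (first trial onset to last
rest end; concatenation across blocks is never allowed because instantaneous
phase requires unbroken time). Segments shorter than 400 s — two cycles of
the lowest band frequency — are rejected rather than padded. Under
independent uniform phases E[PLV] = √π / (2√N), the Monte-Carlo anchor used
in tests. `plv_matrix()` yields the symmetric 15 × 15 matrix with unit
diagonal; `roi_mean_connectivity()` averages channel pairs between ROIs
(within-ROI diagonal = mean of internal pairs, set to 1 for the singleton
ROI4 and excluded from all statistics); `seed_profile()` extracts S1..S6;
`binarize()` applies the strict > 0.7 threshold for visualization only —
graph metrics are always computed on the full weighted matrix.

## Network metrics

On the 7 × 7 ROI matrix with zeroed diagonal: nodal strength (row sums),
weighted global efficiency (mean inverse shortest-path length with edge
length = 1/weight, Dijkstra via igraph), Onnela weighted clustering
(triangle geometric means normalized by the network maximum weight), and
local efficiency (global efficiency of each node's neighbor-induced
subgraph). The reciprocal-weight length transform and the Onnela form are
the conventions of the standard brain-connectivity toolbox; alternatives
(Barrat, Zhang clustering; density thresholding before metrics) are out of
scope. Tests verify Dijkstra against a Floyd–Warshall brute force to 1e-12
and the scaling laws (strength ∝ c, efficiency ∝ c, clustering invariant
under weight rescaling).

## Group inference

All contrasts are two-tailed paired t-tests across subjects with paired
effect size dz = mean(diff)/sd(diff), corrected by Benjamini–Hochberg FDR
within explicitly declared families: 15 channels (activation), 105 channel
pairs or 21 ROI pairs (connectivity), 6 seed connections, 21 nodal-metric
units; global efficiency is tested alone. Rejection uses adjusted p < q
(strict, q = 0.05). Zero-variance differences are degenerate and report
p = 1, dz = 0 with a warning — identical inputs can never be declared
significant. `required_n_paired()` scans the noncentral-t power function
for the smallest n reaching the target power; at dz = 0.5, α = 0.05,
power = 0.90 it returns 44, the study's design size (power 0.8931 at n = 43,
0.9000 at n = 44).

For power and type-I studies of this inference layer, the package provides
statistic-level cohort generators (`simulate_plv_cohort()`,
`simulate_activation_cohort()`) that draw per-subject summary values with an
exactly planted paired effect size: the planted edge receives a shift of
dz·√2·σ_edge in one condition, making the population dz exact. This is the
right level at which to plant an effect quoted in dz units, because no
mapping from signal-level coupling strength to dz is available. A caveat
worth stating plainly: with one true effect of dz = 0.45 among five nulls,
the BH-corrected detection probability at n = 44 is ≈ 0.59 (the raw
two-sided power is 0.83) — so a single study detecting such an effect after
FDR, as reported, is entirely plausible, but it is not a high-probability
event. The acceptance machinery reports both rates.

The behavioral layer mirrors the two published analyses: per-subject Welch
t-tests on the 30-vs-30 selection RTs plus a group paired t-test on subject
means, and low-price selection counts per subject per condition with a
group paired t-test (primary, df = n_subjects − 1) plus a "selection-slot"
mode that pairs the 30 slot frequencies across conditions (df = 29) for
comparability with slot-level reporting. Ratios are computed from counts as
mean/30 × 100.

## Pipeline, determinism, and problem sizes

`fnirs_config()` collects every tunable with the study defaults;
`run_pipeline()` runs simulate → forward MBLL → invert → resample → filter
→ epoch → PLV → ROI → seed → network → group stats → behavior, and writes
delimited tables plus a manifest (package version, seed, config MD5) —
identical configs reproduce identical outputs, manifest included. The unit
test suite exercises the full chain at 3–8 trials and a handful of
subjects; the acceptance script (`scripts/acceptance.R`) runs the complete
44-subject, 10-trial pipeline, 100-replicate signal-level coupling
recovery, and 100/500-replicate detection/null studies of the seed
contrast. These sizes were chosen so the whole evidence base recomputes in
a couple of minutes on one CPU.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of the experiment — timing, rates,
band-limited coupling, physiological sinusoids, drift, truncated RTs,
choice frequencies — and therefore validates the arithmetic and inferential
properties of every stage: exact inverses, filter contracts, PLV oracles,
graph-metric identities, FDR control, power arithmetic, determinism. It
does not emulate real optical physics (no photon transport; the
Beer–Lambert model is the generator's own forward map), superficial/systemic
physiology beyond additive sinusoids, motion artifacts under the default
settings, or spatial correlation induced by shared tissue — so passing
tests certify the pipeline, not any claim about what real recordings would
show. Channel-level response amplitudes are free parameters of the
generator, not calibrated to any dataset. SNIRF/HDF5 I/O is not provided;
the delimited recording, events, and behavior-log formats are the
interchange surface.
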