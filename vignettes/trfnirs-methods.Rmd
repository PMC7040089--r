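---
title: "Methods: time-resolved fNIRS decoding and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved fNIRS decoding and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the passing test suite does and does
not establish. It covers the forward physics, the measurement model, the
inverse chain, the decoding statistics, and the numerical decisions that
were genuinely open.

## 1. Forward physics

### Layered photon transport

The head is a stack of plane-parallel layers — by default ten 2-mm layers
with the last one extended to semi-infinity, absorption
`mu_a = 0.017 mm^-1`, reduced scattering `mu_s' = 1.0 mm^-1` and refractive
index 1.4 throughout, generic adult-head values. Layers 5–10 are treated
as brain. `run_photon_mc()` launches a pencil beam and follows isotropic
scattering steps at the reduced scattering rate (the similarity relation:
for moment estimation at 30-mm separation, isotropic scattering at `mu_s'`
is statistically equivalent to forward-peaked scattering at `mu_s`, at a
fraction of the cost). The top surface applies unpolarised Fresnel
reflection against air; photons escaping inside an annulus of half-width
2 mm around the 30-mm source–detector separation are detected.

Absorption is deliberately *not* applied during flight. Each detected
photon carries its exact per-layer pathlengths `l_k`, so the survival
weight `exp(-sum_k mu_a,k l_k)` can be recomputed for any absorption
profile afterwards: one photon set serves the baseline, every perturbed
frame of a simulated run, and every finite-difference step of the
sensitivity analysis. A consequence is that the classical Russian-roulette
termination has nothing to act on; photons are instead terminated when
their pathlength exceeds the 12.5-ns repetition window, which is exact
rather than approximate for this acquisition. Two invariants pin the
bookkeeping: `sum_k l_k = (c/n) t` per photon (checked to 1e-9 relative),
and the sensitivity conservation law below.

### Sensitivity factors

The mean time-of-flight sensitivity factor of layer `k` is
`MTSF_k = d<t>/d mu_a,k`, estimated by exact reweighting at a
finite-difference step of 0.001 mm^-1 (well inside the linear regime).
Two independent identities are used as oracles in the tests:
`MTSF_k = -Cov_w(t, l_k)` in the small-step limit, and
`sum_k MTSF_k = -(c/n) Var_w(t)`. Delta-method standard errors accompany
every estimate so agreement can be asserted in Monte-Carlo standard-error
units rather than ad-hoc tolerances. The brain factor is the sum over the
brain layers.

The printed layer convention has an arithmetic tension: "below 1 cm" with
2-mm layers would be layers 6–10, but the index set 5–10 is what is
printed, so 5–10 is the default and the set is configurable
(`layered_medium(brain_layers = ...)`).

## 2. Measurement model (what the simulator emulates)

One run is 30 s of baseline followed by five 30-s answer/rest cycles
(330 s, 1100 frames at 300 ms). For every channel (4) and wavelength
(760, 830 nm) each frame is a 1024-bin histogram spanning the 12.5-ns
window of an 80-MHz pulse train. The generator composes, per frame:

- **Activation**: for a "yes", a boxcar over the answer blocks convolved
  with a single-gamma hemodynamic kernel (shape 6, time-to-peak 7 s),
  scaled to the participant's plateau amplitudes; ΔHbO2 drawn from
  N(0.5, 0.15) µM truncated at 0.1, ΔHb = −0.3 ΔHbO2. Activation maps to
  per-wavelength brain absorption through the extinction coefficients and
  perturbs the binned photon ensemble via the per-bin mean brain
  pathlengths (first order; the binned and exact per-photon forward agree
  to 1e-4 at physiological amplitudes, and the exact mode is used wherever
  a single frame is perturbed).
- **Superficial physiology** in the scalp layer: cardiac (~1.1 Hz, 0.4 µM),
  Mayer waves (~0.1 Hz, 0.4 µM), linear drift plus a random walk.
- **Cerebral nuisance** in the brain layers: spontaneous low-frequency
  oscillation (~0.09 Hz, 0.1 µM) and a slow random walk. This is what makes
  some "no" runs look weakly active — the depth-sensitive moment cannot
  distinguish spontaneous cerebral oscillations from activation, which is
  the dominant specificity limit of the real method.
- **Instrument response**: Gaussian, 400-ps FWHM, applied after the
  absorption perturbation.
- **Motion**: Poisson events (0.3/min) lasting a few frames, each shifting
  the time origin (sd 8 bins ≈ 100 ps) and scaling the amplitude.
- **Counting noise**: independent Poisson draws at an expected 1e5 counts
  per frame, giving ~1-ps frame-to-frame noise on the windowed mean — the
  same order as the ~1-ps activation signal, so single frames are
  uninformative and averaging is essential, as in practice.

Amplitudes were fixed once from these physical anchors; they are scales a
time-domain practitioner would call plausible, not fits. Per-participant
log-normal factors (sd 0.2) vary the noise between virtual participants,
and a configurable fraction (default 12%, the middle of the 10–15% range
reported for healthy adults) are non-responders with zero activation.

What the generator does **not** emulate: afterpulsing, dead time, dark
counts (hence no background-subtraction step before thresholding — there
is no background to subtract), wavelength-dependent optical properties
(both wavelengths share one photon ensemble by default; per-wavelength
record sets are accepted), curved or MRI-derived geometry, and EEG-cap
optode repositioning. Passing tests therefore establish the correctness
and statistical behaviour of the *chain*, not the field performance of
the instrument.

A second generator mode (`mode = "concentration"`) expresses the identical
activation and physiology model directly in µM with white measurement
noise at the level the photon chain produces (~0.55 µM/frame). It exists
for decoding-statistics studies (permutation nulls, accuracy-vs-cycles
over many cohorts) where the optics adds cost but no information; every
closed-loop and acceptance-level claim runs the full DTOF mode.

## 3. The inverse chain and its numerical decisions

### Windowed moments and the continuity problem

Each DTOF is truncated at 10% of its peak on the rising side and 1% on the
falling side, and ⟨t⟩ is the count-weighted mean within the window,
recomputed per frame. The thresholds reference the raw per-frame
histogram.

One numerical decision matters more than any other here. With whole-bin
windows, the inclusion or exclusion of a single tail bin moves ⟨t⟩ by an
amount comparable to the ~1-ps activation signal, so the noise-free
response to a brain absorption change is a staircase: measured over small
absorption steps it wanders between roughly −10,000 and −22,000 ps·mm for
a model whose smooth response is ≈ −11,000 ps·mm. Under Poisson noise the
staircase is dithered away, but an inversion calibrated on the noise-free
staircase is then biased by tens of percent. The per-frame pipeline
therefore weights the two boundary bins by the linearly interpolated
threshold crossing, which makes the windowed moment continuous in the
underlying histogram; deterministic and dithered responses then agree
(both ≈ −11,000 ps·mm on the default model) and the closed loop recovers
an injected 0.5-µM plateau to 0.1% without noise. The scalar functions
`truncate_window()` / `mean_time_of_flight()` keep the plain whole-bin
semantics (and `edge_interp = FALSE` reproduces them in the vectorised
path) so the windowing rule itself remains exactly testable.

### Baseline, cleaning

⟨t⟩₀ is the mean over the entire 30-s baseline (100 frames) rather than
the literal first frame — averaging is noise-optimal and the choice is
configurable. Cleaning follows the fixed order motion → detrend → smooth:

- Motion: moving-SD detection (1-s window, k = 3 × median), spline
  subtraction within flagged segments, segment levels re-anchored to
  neighbouring clean samples. R's `smooth.spline` spar parameterisation
  (default 0.7) replaces the csaps `p` of the original MARA formulation.
- Detrending: projection onto a discrete-cosine basis, removing all
  regressors (including the constant) with period above 128 s. Projection
  rather than an IIR filter because "cut-off period" is the fMRI
  convention and projection has exact, testable passband behaviour on a
  330-s record (512-s components attenuated > 90%, 10-s components
  preserved > 95%).
- Smoothing: unit-area Gaussian of 4-s FWHM, reflect-padded. The
  specification of a smoothing kernel by FWHM alone leaves the shape open;
  a symmetric unit-area kernel keeps baselines unbiased, whereas a causal
  gamma kernel would delay and skew the epochs.

### Sensitivity calibration and inversion

`delta_mua_from_mtof()` implements `Δmu_a = Δ⟨t⟩ / MTSF`. Because the
measured moment is windowed and IRF-convolved, the factor used by the
pipeline is not the raw-moment MTSF but an acquisition-matched
calibration (`windowed_mtsf()`): perturbed photon ensembles are pushed
through the identical binning/IRF/truncation operator and the
through-origin slope of windowed ⟨t⟩ versus absorption step is taken over
the physiological operating range. That range is wavelength-specific —
the same oxy-up/deoxy-down pattern produces roughly six-fold smaller
absorption changes at 760 nm than at 830 nm — so each wavelength's grid is
derived from a reference concentration span (0–0.6 µM ΔHbO2 with
ΔHb = −0.3 ΔHbO2) mapped through the extinction coefficients. The
raw-moment estimator remains available (`method = "moments"`) and is the
object the physics oracles constrain.

The two-wavelength inversion solves the 2 × 2 Beer–Lambert system per
frame with shipped compiled extinction coefficients
(760 nm: 586.0 / 1548.52; 830 nm: 974.0 / 693.04 M⁻¹cm⁻¹, log10
convention, converted by ln(10)·10⁻⁷ to mm⁻¹µM⁻¹); the table is a
versioned CSV and swappable. The matrix condition number is checked
(< 100). Conversion runs per channel before any averaging.

## 4. Epochs, features, decoding

Epochs average the first *k* cycles (default all 5) and then the channels;
the 60-s epoch is re-zeroed to its 15-s pre-task mean (features are
offset-invariant regardless; re-zeroing only anchors plots), and
per-sample standard errors across the averaged cycle × channel units are
attached. Features from the oxyhemoglobin epoch only: SM (median of the
task excluding its first 10 s minus the pre-task median), SS (OLS slope of
the first 16 s of the task; a 7-s variant is an argument), CNR (task−rest
mean difference over rest SD, full 30-s task window — the 10-s exclusion
is stated only for SM), r (Pearson correlation of the full epoch against
the boxcar ⊗ kernel model pushed through the identical epoch extraction).
A zero-variance rest segment — possible only on noiseless synthetic input
— routes CNR and r to 0 with a `degenerate` flag instead of erroring.

Decoding pools all question records (72 for 18 × 4) into one leave-one-out
cross-validation; features are standardised by each training fold's mean
and SD, LDA uses a pooled covariance with equal priors, the SVM a linear
kernel with C = 1 (unstated in the original analysis; the minimal
assumption for four features at this sample size). All 15 non-empty
feature subsets are evaluated; ties are broken deterministically (fewest
features, then SM < SS < CNR < r). Selecting the subset by its own LOOCV
accuracy is optimistically biased — the package mirrors that procedure
because it is the procedure under study, and the full 15-row table is
always reported so the bias is visible. Folds whose training set collapses
to one class predict the training majority and are flagged.

## 5. Problem sizes and determinism

Default study conditions: 18 participants × 4 questions, 12%
non-responders, 10⁶ photon packets for the sensitivity model. The test
suite runs its physics oracles on a 10⁶-packet ensemble, routine optics
tests on a cached 2 × 10⁵ ensemble, the full-pipeline decoding check on
the complete default cohort, and the cycles-curve and permutation-null
statistics on concentration-mode cohorts (10 cohorts / 100 label draws).
Every stochastic entry point takes an explicit seed; the Monte-Carlo core
draws from R's RNG stream, so a seed fixes the entire analysis bit-for-bit.

## 6. Known limitations

- The moment chain is first-order in the absorption perturbation;
  amplitudes beyond ~1 µM ΔHbO2 would need the exact per-photon forward.
- A single photon ensemble serves both wavelengths unless per-wavelength
  ensembles are supplied; wavelength-dependent scattering is not modelled.
- The accuracy figures on synthetic cohorts are upper bounds relative to
  human data: the generator's nuisance structure is stationary Gaussian/
  Poisson, real motion and physiology are not, and the cohort contains no
  signal-quality exclusions.
- `subset_search` accuracy is selection-biased by design (see above);
  nested cross-validation is the obvious extension and is not implemented.
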