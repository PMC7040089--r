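# trfnirs

Time-resolved fNIRS motor-imagery decoding — a complete, tested R
implementation of the analysis chain behind "mental communication"
brain-computer interfaces based on time-domain near-infrared spectroscopy,
together with a physics-based simulator that generates the raw data the
chain consumes.

## The problem and who this is for

In a time-resolved fNIRS BCI, a participant answers yes/no questions by
performing motor imagery ("imagine playing tennis") for *yes* and resting
for *no*, while picosecond lasers (760 and 830 nm) and single-photon
counting record, every 300 ms, the full **distribution of times-of-flight
(DTOF)** of photons re-emerging from the head. Because late photons travel
deeper, the first moment of the DTOF — the mean time-of-flight ⟨t⟩ — is
preferentially sensitive to the brain rather than the scalp. The package is
aimed at researchers who want to study or extend this decoding chain
(features, classifiers, protocols, noise conditions) without access to a
time-resolved instrument or to human recordings.

## The method

For each channel and wavelength the pipeline computes, frame by frame:

1. **Windowed moment** — each DTOF is truncated at 10% of its peak on the
   ascending side and 1% on the descending side, and ⟨t⟩ is the
   count-weighted mean of the remaining bins. Δ⟨t⟩ = ⟨t⟩ − ⟨t⟩₀ is
   referenced to the 30-s baseline.
2. **Cleaning** — motion artifacts are detected by a moving standard
   deviation and corrected by spline subtraction; slow drift is removed by
   discrete-cosine projection (cut-off period 128 s); fast physiology is
   suppressed by a unit-area Gaussian kernel of 4-s FWHM.
3. **Moment inversion** — Δμₐ(λ) = Δ⟨t⟩ / MTSF(λ), where the MTSF (mean
   time-of-flight sensitivity factor, ps·mm, negative) is the derivative of
   ⟨t⟩ with respect to the absorption coefficient of the brain layers
   (layers 5–10 of a 10 × 2 mm layered head model), obtained from a layered
   Monte-Carlo photon-transport simulation with per-photon partial
   pathlengths.
4. **Beer–Lambert inversion** — the 2 × 2 system
   Δμₐ(λ) = ε_HbO₂(λ)·ΔC_HbO₂ + ε_Hb(λ)·ΔC_Hb is solved per frame for the
   oxy- and deoxyhemoglobin concentration changes (µM).
5. **Epochs and features** — concentrations are block-averaged over the
   five 30-s answer cycles and four channels into a 60-s epoch
   (15 s rest + 30 s task + 15 s rest), from whose oxyhemoglobin trace four
   features are taken: SM (median task−rest shift), SS (slope of the first
   16 s of the task), CNR (task−rest contrast over rest SD), and r
   (correlation with a boxcar ⊗ hemodynamic-response model).
6. **Decoding** — linear-kernel SVM (C = 1) and pooled-covariance LDA are
   evaluated by leave-one-out cross-validation over all 15 non-empty
   feature subsets; accuracy, sensitivity (yes) and specificity (no) are
   reported, along with accuracy as a function of the number of cycles and
   per-question accuracies.

The simulator runs the same physics forward: truth-dependent activation
(boxcar ⊗ single-gamma HRF peaking at 7 s, ΔHbO₂ up and ΔHb down, confined
to the brain layers), superficial cardiac/Mayer/drift physiology in the
scalp layer, cerebral low-frequency oscillations, DTOF perturbation of the
Monte-Carlo photon ensemble, a Gaussian instrument response, motion spikes,
and Poisson counting noise — for a configurable cohort with a non-responder
fraction (default 12%).

## Worked example

```r
library(trfnirs)

# photon-transport model and sensitivity factors
records <- run_photon_mc(n_photons = 2e5, seed = 42)
sens <- compute_mtsf(records)
print(sens)
#> sensitivity_factors: brain MTSF = -11985 +/- 645 ps mm (layers 5-10)
mtsf <- pipeline_sensitivity(records)  # acquisition-matched, per wavelength

# one simulated question run, processed end to end
protocol <- build_protocol()           # 30 s baseline + 5 x (30 s + 30 s)
profile  <- participant_profile("P01", amp_hbo2 = 0.5, amp_hb = -0.15)
template <- dtof_run_template(records)
run   <- simulate_run(protocol, profile, "yes", template, seed = 7)
conc  <- process_run(run, mtsf)
epoch <- average_epochs(conc$hbo2_by_channel, protocol)
extract_features(epoch, protocol)
#> $SM 0.472   $SS 0.033   $CNR 14.3   $r 0.979

# a small cohort, decoded
cfg <- read_config(NULL)
cfg$optics$n_photons     <- 2e5
cfg$cohort$n_participants <- 8
cfg$cohort$master_seed    <- 11
report <- run_pipeline(cfg, verbose = FALSE)
print(report)
#> pipeline_report
#>   MTSF: 760 nm: -12614, 830 nm: -12566 ps mm
#>   SVM best: SM at 84.4% (sens 81.2%, spec 87.5%)
#>   LDA best: SM at 81.2%
#>   per-question accuracy: 75%, 100%, 88%, 75%
```

The injected plateau here is 0.5 µM of ΔHbO₂; the recovered epoch's SM of
0.47 µM shows the closed loop (forward physics → moment inversion)
recovering the injected amplitude, and `r = 0.98` says the epoch follows
the hemodynamic model shape. Cohort accuracies land well above the 70%
threshold conventionally required for a communication BCI, with errors
concentrated in the simulated non-responders.

## Layout

- `R/`, `src/` — implementation (Monte-Carlo transport in Rcpp)
- `vignettes/trfnirs-methods.Rmd` — model, assumptions, parameter choices,
  numerical decisions, limitations
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `inst/extdata/extinction_hbo2_hb.csv` — hemoglobin extinction table
- `inst/scripts/run_pipeline.R` — command-line wrapper
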