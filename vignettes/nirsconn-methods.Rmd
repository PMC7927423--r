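---
title: "Wavelet coherence connectivity for fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet coherence connectivity for fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsconn)
```

## The scientific problem

Continuous-wave fNIRS measures light attenuation at two wavelengths
(690 and 830 nm here) through the scalp and skull. Attenuation changes
track changes in oxygenated (HbO) and deoxygenated (HbR) hemoglobin in
the underlying tissue. During a block-design motor task, the
concentration series of two cortical regions can co-oscillate within
the *neurovascular coupling* band (0.02–0.05 Hz), and the strength and
phase stability of that co-oscillation — *wavelet coherence* (WCO) and
*wavelet phase coherence* (WPCO) — serve as inter-regional functional
connectivity metrics. `nirsconn` implements the full chain from raw
dual-wavelength intensities to group-level statistics over ten region
pairs of five regions (LPFC, CPFC, RPFC, LMM1, SMA), together with a
seeded synthetic generator that plants known coupling so every stage
can be validated without access to subject recordings.

## Preprocessing model

The chain is, in order, with no temporal filtering anywhere (coherence
analysis needs the full band):

1. **Pruning.** A channel is kept iff its intensity level
   `20·log10(mean I / 1e-6 detector units)` lies in [80, 140] dB at
   both wavelengths. The 1e-6 reference is a package convention chosen
   so the unit source intensity sits at 120 dB, in the middle of the
   window.
2. **Optical density.** `OD(t) = −ln(I(t)/mean I)` per
   channel/wavelength. The log-ratio makes every downstream quantity
   invariant to constant channel gain, which the tests assert
   end-to-end.
3. **PCA motion correction.** Motion is global: an event loads
   coherently on all channels, so the leading principal component of
   the multichannel OD matrix captures it and is projected out (one
   component by default). On a recording with *no* artifacts the
   leading component is instead the shared physiological/evoked mode,
   so the no-motion validation scenarios run the stage with zero
   components — the stage is still exercised; removal is reserved for
   data that contain what it is designed to remove.
4. **Beer–Lambert inversion.** Per channel the 2×2 system
   `OD(λ)/(d·PPF(λ)) = E · (ΔHbO, ΔHbR)` is solved with partial
   path-length factors 6.4 (690 nm) and 5.8 (830 nm) and extinction
   coefficients from the standard compiled tabulation (276/2051.96 and
   974/693.04 base-10 cm⁻¹M⁻¹, converted to natural-log µM⁻¹mm⁻¹
   internally).
5. **Short-separation GLM.** Each long (30–40 mm) channel's HbO series
   is regressed by OLS on (a) task regressors built from a consecutive
   Gaussian basis (σ = 1 s, spacing 1 s) over the peristimulus window
   [0, task duration + 16 s], placed at every task onset, (b) a cubic
   polynomial drift, and (c) the HbO series of the 8 mm short channel
   sharing the same source, which sees only superficial (scalp)
   physiology. The *cortical* series passed to the connectivity layer
   is measurement − drift − short-channel fit: the task structure is
   retained, because coherence is computed on HbO time series, not on
   HRF estimates. The reconstructed task component alone is available
   behind `output = "hrf"` for users who want the alternative reading.
6. **Region aggregation.** Region series are the mean of the surviving
   long channels per region; a region losing all channels is a hard
   error.

All fits share one design matrix per (paradigm, rate, basis)
configuration; its QR decomposition is cached and the per-channel
augmented systems are solved in closed form from the projected
residuals, so cohort-scale runs cost one decomposition.

## Wavelet coherence model

The analytic Morlet wavelet (central frequency ω₀ = 6, the standard
choice balancing time and frequency resolution) is evaluated by
frequency-domain multiplication on a logarithmic grid (12 voices per
octave over 0.005–2 Hz, ~104 frequencies, ≥ 16 grid points inside band
IV). The FFT buffer is padded past the longest wavelet's support so
circular wrap-around is below 1e-10; tests verify the transform against
a direct time-domain convolution oracle to 1e-6 relative error.

Edge effects bias coefficients within one e-folding span (√2·s at
scale s) of either end of the record; this *cone of influence* is
excluded from every average. With `w₁`, `w₂` the coefficients of the
two series at frequency `f` and the time average `⟨·⟩` running over the
jointly COI-valid samples (the effective N at each frequency is the
count of those samples):

- `WCO(f) = |⟨w₁w₂*⟩|² / (P₁(f)·P₂(f))`, with
  `Pᵢ(f) = ⟨|wᵢ|²⟩` the time-averaged wavelet power. Defining the
  powers as time averages over the same samples is the only reading
  that bounds WCO by 1 (Cauchy–Schwarz) and makes self-coherence
  exactly 1.
- `WPCO(f) = sqrt(⟨cos Δφ⟩² + ⟨sin Δφ⟩²)` with
  `Δφ = arg w₁ − arg w₂`: the resultant length of the phase-difference
  distribution.

Frequencies with zero jointly valid samples yield explicit missing
values, never silent zeros, and band averages (unweighted means over
grid frequencies in `[f_low, f_high)`) propagate that missingness.
Coherence is computed over the full session (trials and rests as
recorded) rather than per trial: band IV–V periods (20–200 s) exceed
the COI-valid span of a single 5-minute trial.

The smoothed time–frequency map (`timefreq_coherence_map()`) exists
for visualization only. Pointwise magnitude-squared coherence of
wavelet coefficients is identically 1 — each time-frequency atom has a
single amplitude and phase — so the map smooths the cross-spectrum over
the wavelet scale in time and over adjacent scales before forming the
ratio. No statistic consumes it.

## Synthetic cohort generator

The generator emulates the study conditions so that parameter recovery
can stand in for results on the (unavailable) human recordings:

- **Paradigm**: alternating blocks — a 30 s lead-in rest (the protocol
  does not state one; 30 s is a typical settling period), then task
  blocks of up to 300 s each followed by 60 s rests; surgeon-cohort
  profiles run 5 trials, control profiles 3.
- **Evoked response**: the task boxcar convolved with the canonical
  double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6), amplitude
  1 µM by default — a typical motor-task HbO excursion.
- **Spontaneous band-IV oscillators**: band-limited Gaussian noise
  synthesised in the frequency domain (so band containment is exact),
  0.3 µM standard deviation. A pure sinusoid would make WPCO trivially
  1; narrowband noise gives the phase diffusion that makes coherence
  estimation non-trivial. For a coupled pair with strength κ and lag
  φ, the second region's oscillator is
  `κ·(phase-lagged first oscillator) + sqrt(1−κ²)·(own oscillator)`,
  so the ground-truth band coherence is κ² and band metrics are
  monotone in κ.
- **Systemic physiology**: one representative sinusoid per
  physiological band (cardiac 1 Hz, respiratory 0.25 Hz, myogenic
  0.1 Hz, endothelial 0.01 Hz) with seeded phases, shared between the
  long and short channels of each source up to a per-source gain.
  Short channels receive *only* systemic terms.
- **Optics**: channel-wise modified Beer–Lambert forward model
  (`I = I₀·e^{−OD}`, I₀ = 1 detector unit), ΔHbR = −ΔHbO/3 by default
  so the two-wavelength inversion is well-posed.
- **Motion**: global spikes (Gaussian OD transients) and baseline
  steps at seeded times, identical timing across channels with
  per-channel amplitude jitter — a rank-1 structure in channel space,
  which is exactly what the PCA stage removes. Cohorts are generated
  with 3 spikes and 1 shift per recording by default.
- **Sampling**: 10 Hz by default (the acquisition rate is not a
  published constant of the instrument configuration; 10 Hz resolves
  the cardiac band and is typical for CW systems).

What the generator does **not** emulate: anatomy or photon transport
(no partial-volume heterogeneity beyond channel gain), skill-learning
dynamics across training days (coupling is fixed per session and
supplied by configuration), serially correlated physiological noise
outside the modelled bands, and any group difference in evoked
amplitude — groups differ only in coupling by default. Passing
recovery tests therefore demonstrates that the *pipeline* measures
what was planted under these conditions, not that real cohorts would
separate this cleanly.

## Statistics layer

- Shapiro–Wilk normality per group and dependent variable, Levene's
  test (mean-centred, as in mainstream ANOVA software) for variance
  homogeneity; both flagged at α = 0.01. Constant cells are reported
  untestable rather than failing.
- One-way MANOVA: Wilks' Λ = det(E)/det(E+H) from the within- and
  between-group SSCP matrices, Rao's F approximation (exact for two
  groups, where it coincides with the Hotelling T² transform — the
  test suite checks both equivalences). The per-variable partial η² is
  `SS_between/(SS_between+SS_within)`.
- Two-tailed Mann–Whitney U with midrank ties. The p-value is exact
  (null enumeration) whenever there are no ties and both n ≤ 50, and a
  tie-corrected normal approximation with continuity correction
  otherwise. The exact path matters: with groups of 9 and 5 the
  smallest attainable two-sided exact p is 2/2002 ≈ 0.000999, whereas
  the normal approximation cannot go below ~0.0027, so an
  approximation-first rule would make a p < 0.001 criterion
  structurally unreachable at these group sizes.
- Bonferroni adjustment `min(1, m·p)`; a priori power for two-sample
  t-tests by noncentral-t search for the smallest integer n per group.

The reported MANOVA degrees of freedom follow the standard Rao
formula. For two groups, 10 dependent variables and n subjects they
are (10, n − 11); no attempt is made to mimic nonstandard df
conventions of other software.

## Validation problem sizes

The package's own validation (test suite and analytic targets) uses
desk-scale instances chosen to keep the full suite in a few minutes:
600 s two-trial sessions at 10 Hz for pipeline-level recovery; 50
replicate cohorts of 9 + 5 subjects for the planted-difference
detection study (rejection by exact Mann–Whitney at α = 0.001 in ≥ 80%
of replicates); 20 seeded subjects per κ ∈ {0, 0.3, 0.6, 0.9} for
monotonicity; 200 region-level replicates of 8 + 8 null subjects
(300 s at 5 Hz) for type-I calibration, whose rejection count is
checked against the binomial 95% interval at the exact test's
attainable size (~0.050 at 8 v 8); and 256-sample series for the
convolution oracle. Band-restricted frequency grids are used where
only band-IV quantities are consumed — band averages depend only on
in-band grid points, so this is exact, not an approximation.

## Known limitations

- The two-wavelength inversion fixes the HbR/HbO ratio when HbR is not
  supplied; a mis-specified ratio biases recovered amplitudes (not
  coherence, which is amplitude-invariant).
- WCO/WPCO null levels rise as records shorten (fewer independent
  wavelet atoms in band IV); group comparisons remain valid because
  all subjects share a session length, but absolute coherence values
  are not comparable across different session lengths.
- PCA motion correction assumes motion is the dominant shared variance
  component; with strong shared systemic and weak motion it can remove
  physiology instead. Short-channel regression downstream mitigates
  this for the systemic part.
- No surrogate-data significance testing of individual coherence
  values, and no directed (lagged/causal) connectivity measures.
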