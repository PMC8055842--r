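---
title: "Methods: simulation, quantification and statistics for whole-brain 31P MRS p-BEM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, quantification and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `pbem31p`: what the synthetic
data generator emulates and deliberately omits, how the spectral
quantification works numerically, how the statistical pipeline is
calibrated, and which design decisions were genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The signal model

A ³¹P free induction decay is modeled as a sum of damped complex
exponentials, one per resonance:

$$ s(t) \;=\; \sum_k 2 A_k f_0 \,
   e^{2\pi i \nu_k t}\; e^{-\pi L_k t}\; e^{-(\pi G_k t)^2 / (4 \ln 2)}
   \;+\; \varepsilon(t), $$

where $f_0$ is the transmitter frequency in MHz (Hz per ppm), $\nu_k$ the
offset of resonance $k$ from the carrier, and $L_k$, $G_k$ its Lorentzian
and Gaussian full widths at half maximum in Hz. The real part of the
one-sided Fourier transform of the noiseless signal is then an *exact*
Voigt profile for every resonance — the simulator and the fitting model
share one analytic family, so quantification accuracy can be tested
without model mismatch. The amplitude convention makes the ppm-axis
integral of each absorptive peak equal to $A_k$ (areas are relative
concentrations; no absolute quantification is attempted, and no T1
saturation or nuclear Overhauser weighting is modeled).

Noise is additive circular complex Gaussian on the FID, the standard MR
thermal-noise model; `noise_for_snr()` converts a target spectral SNR
(PCr peak height over frequency-domain noise SD) into the time-domain
noise level. A smooth baseline, when requested, is a low-order polynomial
added to the real part after transform, mimicking broad macromolecule and
baseline roll.

Acquisition defaults mirror a 7T whole-brain protocol: 2048 complex
points, zero-filled to 4096 before the transform, TR 0.5 s, TE 0.5 ms,
spectral width 6 kHz with the carrier at −5 ppm so the full metabolite
range (+6.8 to −16.4 ppm) sits comfortably inside the window. The α- and
β-ATP resonances are simulated as singlets, matching their appearance at
7T; J-coupled multiplet structure (relevant at 1.5–3T) is not modeled.
Region spectra are generated directly as region sums: every downstream
quantity consumes region-summed spectra, so simulating a full multi-slice
voxel grid would add cost without adding testable structure.

Default resonance positions (PE 6.78, PC 6.24, Pi~ex~ 5.25, Pi~in~ 4.82,
GPE 3.50, GPC 3.01, MM ≈ 2.1 broad, PCr 0, γ-ATP −2.53, α-ATP −7.63, NAD
−8.31, UDPG −9.81, β-ATP −16.39 ppm) are standard ³¹P literature values;
only PCr = 0 ppm is fixed by the referencing convention. The β-ATP
default equals the α-ATP prior minus the α−β shift difference at the
default Mg²⁺ state, so the panel is internally consistent.

## 2. pH and Mg²⁺ from chemical shifts

Intracellular pH follows the Henderson–Hasselbalch relation applied to
the intracellular Pi shift relative to PCr; free Mg²⁺ follows a 1:1
Mg–ATP binding isotherm applied to δ(α-ATP) − δ(β-ATP). The calibration
constants (pKₐ = 6.75, acid/base limiting shifts 3.27/5.69 ppm; K_d =
0.05 mM, free/bound limiting differences 10.82/8.24 ppm) are the values
in common use for in-vivo ³¹P work; published calibrations differ
slightly between laboratories, so all six constants live in
`mrs_calibration()` rather than in code. Both maps are strict bijections
on their domains with exact closed-form inverses (`delta_pi_from_ph()`,
`delta_ab_from_mg()`), which the simulator uses to position Pi~in~ and
β-ATP — the round trips are tested to 1e−10.

## 3. Spectral quantification

`fit_spectrum()` fits all 13 resonances to the real part of the phased
spectrum (never the magnitude, which mixes lineshapes):

* **True Voigt profile.** The Gaussian⊗Lorentzian convolution is
  evaluated through the Faddeeva function $w(z)$, implemented with
  Weideman's rational approximation (N = 64, near machine precision on
  the closed upper half-plane). The Gaussian and Lorentzian limits and a
  brute-force numerical convolution serve as independent oracles in the
  tests.
* **Baseline.** A degree-4 polynomial is first estimated from
  signal-free points (outside ±0.7 ppm of every prior, ±2 ppm for the
  broad MM component) and subtracted; a second polynomial of the same
  degree is then co-fitted with the peaks. The co-fit matters: a
  baseline estimated only from signal-free points cannot distinguish
  broad peak tails from baseline and would bias areas by a few percent.
* **Optimization.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  over 52 peak parameters plus the baseline coefficients, with an
  analytic Jacobian (via $dw/dz = -2zw + 2i/\sqrt{\pi}$), in two stages:
  widths first held at their template values while centers, areas and
  baseline adapt, then everything released. Initialization is
  deterministic — centers at the local maximum of a lightly smoothed
  trace within the prior window, areas from trapezoidal integrals,
  widths at the template values — so identical inputs give identical
  fits.
* **Bounds and priors.** Centers are bounded to the template ±0.5 ppm to
  prevent peak swapping (±0.15 ppm for extracellular Pi, whose shift
  range is physiologically narrow); widths to (0, 1] ppm; the MM
  component is forced broad (Gaussian width ≥ 0.3 ppm, Lorentzian width
  ≤ 0.6 ppm) so it cannot absorb metabolite signal. Two soft priors are
  scaled by the spectral noise level (estimated robustly from
  first differences of signal-free points, hence exactly zero for
  noiseless data): widths are pulled toward the template values with a
  ~20 % prior SD, and the co-fitted baseline refinement carries a
  per-point amplitude prior of ~3 noise SDs. Both priors address the
  Voigt width–area degeneracy that otherwise dominates the error budget
  at realistic SNR, and both vanish for noiseless spectra, where
  recovery is exact to numerical precision.
* **Degenerate inputs.** A profile with both widths zero is an error;
  non-convergence is flagged in the returned object, never silent; a
  missing template resonance is an error.

At spectral SNR 20 the PCr and ATP areas are recovered with ~3 % RMS
error — close to the information limit for a free-width Voigt — while
intracellular Pi, overlapped by the extracellular pool and the MM
component, is wider (~5–7 % RMS); mean biases stay below ~1 %. These
numbers are computed by the test suite and the acceptance script, not
asserted from elsewhere.

Automatic phasing (`auto_phase()`) minimizes the entropy of the absolute
first derivative of the real part plus a negativity penalty, refined by
Nelder–Mead from a fixed grid of zero-order starts; it exists because
interactive scanner-side phasing is not reproducible in code.
Quantification apodization defaults to 0 Hz (line broadening is a display
matter; an 8 Hz exponential is conventional for figures and available via
`apodize()`).

## 4. The synthetic cohort

`simulate_cohort()` generates the three-group study the statistics
consume: 15 cognitively normal, 15 aMCI and 11 mild AD participants, with
age (SD 6.2 y), education and a binary gender indicator, four regional
marker sets, five cognitive domain z-scores, and optionally the
region-summed FIDs themselves.

**Markers.** The generative model works on components so that tabulated
markers and generated spectra can never disagree: log-normal biological
parts for PCr/t-ATP, Pi/t-ATP and Pi~ex~/t-ATP share a t-ATP component
whose SD is 1.96× the metabolite components'. That single ratio makes the
three designed temporal-lobe effects mutually consistent, because the
metabolic state indicator is *identically* consumption/reserve — its
group effect is emergent, not set. Group effects enter as standardized
shifts on the log scale; the defaults carry the direction pattern of the
three-group 7T study this generator emulates (reserve and consumption
lower in aMCI and AD, metabolic state elevated and Mg²⁺ reduced in AD,
membrane index flat, other regions null), with magnitudes calibrated so
that the implied Tukey significance pattern (e.g. p ≈ 0.009 for the
aMCI–CN reserve contrast at n = 15/15) matches the pattern the package is
designed to reproduce. Printed mean differences on a common-variance
display scale understate those standardized contrasts, which is why the
calibration anchors on the p-values rather than the displayed
differences.

**Covariates.** Age, gender and (weakly) education contribute additively
on the measured-ratio scale, together explaining 55 % of each marker's
variance — strong enough that covariate adjustment is worthwhile, which
is the situation the pipeline is built for. Additivity is deliberate: a
linear adjustment cannot exactly remove multiplicative covariate
effects, and the resulting curvature leak would miscalibrate the null.
By default the covariate distributions are *common across groups*. With
a demographically imbalanced cohort (say an AD group 8 years older), any
two-step residual adjustment leaves covariate-mean sampling variance in
the group contrast that the downstream F test does not model, inflating
the null rejection rate to ~0.15–0.20 at n = 41; balanced covariates
keep the two-step pipeline exactly calibrated. `cohort_design(age_means=)`
exposes the imbalanced variant for anyone who wants to study that
distortion.

**Cognition.** Domain z-scores receive group shifts calibrated to the
one-way F statistics typical of this design (episodic memory deficits in
both patient groups, executive/attention/language/visuospatial deficits
concentrated in AD; implied F ≈ 17–50 at (15, 15, 11)), plus a
within-group coupling to temporal-lobe Mg²⁺ in the CN group only
(slopes 0.3–0.45), emulating a cofactor–cognition correspondence that is
present in health and lost in disease.

**What the generator does not emulate:** relaxation weighting and
saturation effects, J-coupling multiplets, frequency drift and
eddy-current artifacts, voxel-level spatial structure and partial-volume
mixing, brain atrophy, non-Gaussian physiology, missing data, and any
dependence between regions beyond the shared covariates. Passing tests
therefore demonstrate internal consistency and statistical calibration
of the pipeline under a faithful signal model — not robustness to every
artifact of real scanner data.

## 5. The statistical pipeline

The order is fixed: adjust for covariates, then symmetrize, then (for
correspondence analyses) scale to common variance.

* **Adjustment** (`adjust_covariates()`) regresses each variable on age,
  education and gender and returns residuals plus the grand mean, making
  the adjusted values exactly orthogonal to each covariate. An optional
  `groups` argument estimates the slopes from within-group variation
  (the covariance-analysis convention) — useful under demographic
  imbalance, though at n = 41 it slightly overfits the within-group
  variance; the pipeline reports use the plain global form.
* **Shifted-log transform** (`shifted_log()`): positive skew ↦
  log(x − a), negative skew ↦ −log(a − x); the tie (skew exactly 0)
  takes the positive branch. The shift constant a is chosen by a
  one-dimensional search minimizing the absolute adjusted
  Fisher–Pearson skewness of the transformed sample, with
  a = min(x) − 0.1·range (resp. max + 0.1·range) as fallback if the
  search cannot reduce the skewness.
* **Group differences**: classical one-way ANOVA (df = (2, 38) at
  n = 41) at α = 0.10 for BEM markers and 0.01 for cognitive measures,
  Tukey HSD at familywise α = 0.05 for pairwise contrasts, and
  Benjamini–Hochberg FDR reported across the marker × region F tests.
* **Marker–cognition correspondence**: the fixed-effects interaction
  model y = b₀ + b₁ I(aMCI) + b₂ I(AD) + b₃ x + b₄ x·I(aMCI) +
  b₅ x·I(AD) + e with x centered at its grand mean and CN as reference;
  the 2-df interaction F and all six coefficients are reported, tests at
  α = 0.05. The model contains no random effect — it is ordinary least
  squares — and is implemented as such.

Null calibration and power are measured by simulation in the test suite:
ANOVA type-I error within Monte-Carlo tolerance of 0.10 over 2000 null
replicates, Tukey familywise error ≤ 0.065, detection of the designed
temporal-lobe contrasts (aMCI < CN reserve; AD > CN metabolic state) in
well over 80 % of 200 cohort replicates, and ±2 SE coverage of b₃ at its
nominal ~94.7 % over 1000 replicates.

## 6. Classification

Features are all 32 regional markers plus the five cognitive z-scores.
Within every training split of a stratified 10-fold cross-validation
(fold sizes 4–5 at n = 41, every class represented in every training
split, fold assignment from a required seed), features are standardized,
reduced to the first two principal components (sign convention: the
largest-magnitude loading of each component is positive), and classified
with a quadratic discriminant — Gaussian class-conditional densities
with class-specific covariances and empirical priors; exact posterior
ties resolve to the earlier class in CN < aMCI < AD order. Exactly one
held-out prediction per subject feeds a predicted × true confusion
matrix; cv error is the off-diagonal fraction and its standard error the
binomial √(e(1−e)/n). Two components are fixed by design; the explained
variance fraction is reported for transparency. Per-class sensitivity,
specificity, PPV and NPV come from `confusion_metrics()`, with empty
denominators reported as NA rather than 0.

## 7. Problem sizes and interfaces

The test suite and the acceptance script use: single-spectrum fits at
4096 points; 100 noise realizations for the SNR-20 Monte Carlo; 2000
null replicates for type-I/FWER calibration; 200 cohort replicates for
detection rates; 1000 replicates for interaction coverage; and a reduced
(5/5/5, 1024-point) cohort for the end-to-end spectra-fitting smoke
test. These sizes were chosen to give Monte-Carlo standard errors well
inside the asserted tolerances while keeping a full run to a few
minutes.

The package's interface is its functions — `simulate_cohort()`,
`quantify_fid()`, `group_difference_report()`, `crossval_10fold()`,
`run_pipeline()` — plus the plain-text spectra container
(`write_fid()`/`read_fid()`: key/value header + index,real,imaginary CSV)
and tab-separated cohort, marker and report tables. `run_pipeline()`
writes a provenance log (seeds, configuration, package version) next to
its reports so a run can be reproduced bit for bit. No shell entry point
is shipped; `scripts/acceptance.R` shows the scripted-use pattern.

## 8. Known limitations

* The fitter assumes a phased, baseline-correctable real spectrum; it
  has no time-domain variant and no prior-knowledge amplitude ratios
  between ATP spins (each spin is fitted independently, then averaged).
* Marker-level covariate adjustment is performed on each ratio; adjusting
  metabolite signals before forming ratios is equivalent only to first
  order.
* The soft width priors trade a small bias for a large variance
  reduction; with strongly atypical linewidths the templates should be
  updated or `width_prior_weight` set to 0.
* The two-step adjust-then-test pipeline is exactly calibrated only when
  covariate distributions do not differ by group (see §4–5); with
  demographic imbalance its F tests are anticonservative, which is a
  property of the procedure, not of the implementation.
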