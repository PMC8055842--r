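# pbem31p

Whole-brain **³¹P magnetic resonance spectroscopy** analysis of **phosphate
brain energy metabolism (p-BEM)** — from simulated free induction decays to
cohort-level statistics and classification.

In vivo ³¹P MRS at ultra-high field (7T) resolves thirteen phosphorus
resonances simultaneously: phosphocreatine (PCr), the three ATP phosphate
spins (α, β, γ), intracellular and extracellular inorganic phosphate (Pi),
the membrane phospholipid metabolites PE, PC, GPE and GPC, NAD, UDPG and a
broad macromolecule component. From the fitted signals one derives the
p-BEM markers used to probe mitochondrial (dys)function in normal aging,
amnestic mild cognitive impairment (aMCI) and Alzheimer's disease (AD):

| marker | definition |
|---|---|
| energy reserve index | PCr / t-ATP |
| energy consumption index | intracellular Pi / t-ATP |
| metabolic state indicator | intracellular Pi / PCr |
| membrane phospholipid index | (PE + PC) / (GPE + GPC) |
| intracellular pH | Henderson–Hasselbalch from δ(Pi): pH = pKₐ + log₁₀[(δ − δ_acid)/(δ_base − δ)] |
| free Mg²⁺ | 1:1 Mg–ATP binding isotherm from δ(α-ATP) − δ(β-ATP) |

with t-ATP the arithmetic *mean* of the α-, β- and γ-ATP signals, and all
chemical shifts referenced to PCr at 0 ppm.

The package implements, and tests end-to-end with known ground truth:

* **synthesis** — 13-resonance FIDs (2048 complex points, Voigt lineshapes,
  pH- and Mg²⁺-driven shifts, complex Gaussian noise, polynomial baseline)
  and full three-group cohorts (15 CN / 15 aMCI / 11 AD) with designed
  regional marker effects, covariate structure and cognition coupling;
* **preprocessing** — zero filling (2K → 4K), apodization, Fourier
  transform, manual and automatic (entropy-based) phase correction, region
  summation;
* **quantification** — baseline estimation plus constrained multi-peak
  *true* Voigt fitting (Faddeeva function, analytic Jacobian, bounded
  Levenberg–Marquardt) of all 13 resonances;
* **markers** — the table above, per brain region (frontal, temporal,
  parietal, occipital);
* **cohort statistics** — covariate adjustment (age, education, gender),
  shifted-log symmetrization, common-variance scaling, one-way ANOVA
  (α = 0.10 for BEM markers, 0.01 for cognition) with Tukey HSD (familywise
  α = 0.05) and BH-FDR across marker × region tests, and the six-coefficient
  group × marker interaction model for marker–cognition correspondence;
* **classification** — PCA to two components refit inside every training
  fold, quadratic discriminant analysis, stratified 10-fold
  cross-validation, confusion-matrix metrics.

## Worked example

Simulate one noiseless spectrum with known physiology, quantify it, and
read off the markers:

```r
library(pbem31p)

tr   <- ground_truth(ph = 7.05, mg = 0.25, seed = 1)
spec <- to_spectrum(zero_fill(simulate_fid(tr), 4096))
fit  <- fit_spectrum(spec)
bem_indices(fit, "temporal")
#>     region energy_reserve energy_consumption metabolic_state pi_ex_over_tatp
#> 1 temporal            1.1             0.3667          0.3333          0.1333
#>   pi_ex_over_pcr pme_pde   ph   mg t_atp
#> 1         0.1212       1 7.05 0.25     3
```

The fitted Pi shift (δ = 4.882 ppm) and α−β ATP shift difference
(8.670 ppm) return exactly the pH (7.05) and free Mg²⁺ (0.25 mM) that
generated the spectrum; every area is recovered to well under 1 %.

The full pipeline — simulate a cohort, run the statistics, classify:

```r
rep <- run_pipeline(pipeline_config(design = cohort_design(seed = 11)))
rep
#> p-BEM pipeline report
#>   41 participants, markers from the generator
#>   group differences at alpha = 0.10: 9 of 32 marker-region tests
#>   10-fold CV: error 0.0976 (SE 0.0463), accuracy 90.2%, 4 misclassified of 41
```

The temporal-lobe rows of `rep$group_differences` show the designed
pattern: energy reserve and consumption lower in aMCI and AD versus CN
(Tukey-adjusted p = 2.4e-05 and 1.2e-04 for aMCI–CN on this seed), the
metabolic state indicator elevated in AD (p = 2.3e-08), Mg²⁺ reduced in AD,
and the membrane phospholipid index essentially flat — while the frontal,
parietal and occipital regions stay null. Set
`pipeline_config(fit_spectra = TRUE)` to derive every marker by Voigt
fitting of the generated spectra instead of reading the generator's table
(slower; the two routes agree to < 1 % for noiseless spectra).

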