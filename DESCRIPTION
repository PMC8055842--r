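Package: pbem31p
Title: Whole-Brain 31P MRS Phosphate Brain Energy Metabolism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification of in-vivo phosphorus-31 magnetic
    resonance spectra and downstream phosphate brain-energy-metabolism (p-BEM)
    analysis. Generates 13-resonance 31P free-induction decays and three-group
    (cognitively normal, amnestic mild cognitive impairment, mild Alzheimer's
    disease) cohorts with known ground truth; preprocesses spectra (zero
    filling, apodization, Fourier transform, phase correction, region
    summation); quantifies metabolites by constrained multi-peak Voigt
    lineshape fitting with baseline estimation; derives intracellular pH from
    the inorganic-phosphate chemical shift and free magnesium from the
    alpha-beta ATP shift difference; computes energy reserve (PCr/t-ATP),
    energy consumption (Pi/t-ATP) and metabolic state (Pi/PCr) indices plus the
    membrane phospholipid index; runs covariate-adjusted one-way ANOVA with
    Tukey HSD and group-by-marker interaction models; and classifies
    participants with a quadratic discriminant on the first two principal
    components under stratified 10-fold cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
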