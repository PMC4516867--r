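---
title: "Quantifying denatonium by isotope dilution with an HDX-labeled standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying denatonium by isotope dilution with an HDX-labeled standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denaquant)
```

## The measurement problem

Denatonium (Bitrex) is the bitterest compound in common use; it is added to
denatured alcohols and household fluids at statutory levels around 10 µg/mL,
and verifying those levels calls for a robust LC-MS assay. The most reliable
quantification design in mass spectrometry is isotope dilution: spike the
sample with a known amount of an isotopically labeled copy of the analyte,
and read the analyte amount off the light/heavy signal ratio. The labeled
copy co-elutes with the analyte and ionizes identically, so matrix effects
and injection variability cancel in the ratio.

An economical way to obtain the labeled copy is hydrogen–deuterium exchange
(HDX). The denatonium cation (C~21~H~29~N~2~O^+^, monoisotopic m/z
`r round(monoisotopic_mz(parse_formula("C21H29N2O", 1)), 3)`) contains a
betaine moiety whose two α-CH~2~ hydrogens are acidic enough to exchange in
D~2~O under base catalysis (1% triethylamine). Crucially, the introduced
α-C deuterons are *acid-stable*: they survive aqueous and acidic LC
conditions indefinitely, while the amide N–H relabels instantly to match
the solvent. Base-catalysed exchange in D~2~O followed by an acidic
work-up therefore yields a clean α-d~2~ standard, shifted +2 Da from the
analyte.

The difficulty this package addresses is that a 2-Da separation is *not*
clean at the envelope level: the analyte's M+2 isotopic peak (two ^13^C,
^18^O, ...) lands on the standard's monoisotopic peak — about 6 mDa apart,
unresolvable at ESI-TOF resolving power. A naive two-peak ratio is biased;
the mixture must be deconvolved with the overlap modeled.

## The model

### Isotope patterns

`isotope_pattern()` computes the theoretical envelope of any formula by
per-element multinomial convolution over an embedded IUPAC 2013 isotope
table. Intermediate convolutions keep full fine structure (only
floating-point-identical masses are deduplicated); a single final pass
merges centroids closer than `merge_tol` (default 1 mDa) by
abundance-weighted mean, drops peaks below `abundance_floor` (default
10^-5^), and renormalizes. Charged species are electron-mass corrected
(m/z = (M − z·m~e~)/|z|), which matters at the sub-mDa level for cations.
Deuterium introduced by labeling is treated as isotopically pure ^2^H; the
exchange chemistry is what controls partial labeling, not the label's own
isotopic purity.

### Labeling states

A labeling state of the standard is the pair (number of α-C deuterons,
amide deuterated?). The two α-CH~2~ sites are chemically equivalent and
exchange independently, so after exchanging for time *t* at per-site rate
*k* the α count is binomial(2, 1 − e^−kt^) — `state_distribution()`. The
amide is modeled as instantaneous and complete in the matching solvent.
`apply_back_exchange()` encodes the selectivity that makes the label
usable: neutral or acidic water strips only the amide deuteron; base in
water strips the α-C deuterons too (binomial thinning at the same
first-order rate); D~2~O restores the amide label. `fit_rate()` recovers
*k* from an ESI-MS time course by least squares on the saturation curve.

No numeric exchange rate is available for this chemistry; the package
default *k* = 0.23/min is a modeling choice placing per-site deuteration
near 90% at 10 min and beyond 99.9% at 60 min, consistent with the
qualitative time course (substantial exchange visible at 10 min, complete
by 60 min). Fully labeled standards (`state_distribution(1, FALSE)`) are
the default study condition; partial labeling only changes the heavy basis
column, which becomes a state-probability-weighted mixture of labeled
envelopes.

### Envelope deconvolution

`build_basis()` lays the light envelope and the (possibly mixed) heavy
envelope on a common m/z grid, merging centroids closer than 0.01 Da so
the light-M+2 / heavy-M+0 pair shares one grid position. `match_envelope()`
projects an observed peak list onto the grid (tolerance 0.01 Da, about
30 ppm at m/z 325 — generous for TOF centroids yet far below the 1-Da
isotopic spacing) and reports unmatched nearby intensity as foreign.
`estimate_fractions()` solves the non-negative least-squares problem

observed ≈ a · light + b · heavy,   a, b ≥ 0

and reports fractions a/(a+b), b/(a+b) plus an L1 residual fraction. The
classical overlap-correction ratio for two species with complete labeling
is the special case of this NNLS on two grid points; the NNLS over the
full envelope is strictly more general (partial labeling states, more
peaks constraining the fit) and is validated in the tests against an
exhaustive grid search over the fraction simplex. Normalization happens
*after* the solve so the residual keeps its scale interpretation; absolute
scale lives in the chromatographic profile, not the fractions.

Collinearity — an "unlabeled standard" or any basis whose two columns are
numerically indistinguishable (condition number of the 2×2 normal matrix
above 10^8^) — is a hard error, not a silently regularized solve.

### Chromatography

`extract_xic()` slices per-scan intensity in a ± tol window; `find_peak()`
takes the apex, estimates baseline and noise robustly (median/MAD), and
bounds the peak where the trace falls below max(baseline + SNR·noise, 5%
of apex), padding two scans on each side so the trapezoidal area captures
more than 99% of a Gaussian peak (the 5% cut alone leaves ~1.4% in the
tails). No smoothing is applied by default: synthetic centroid data is
clean, and smoothing is a presentation choice, not a correctness one.

Co-elution is reported in whole scans (`coelution_delta()`), deliberately
avoiding any claim of sub-scan apex precision. Peak purity
(`peak_purity()`) deconvolves every scan across the peak and reports the
dispersion (standard deviation) of the per-scan light fraction: a pure,
co-eluting peak has a constant composition, so dispersion directly
operationalizes "the spectra look the same across the peak", and it reuses
the deconvolution core instead of introducing a second spectral-similarity
metric.

### Quantification, calibration, LOD

`quantify_run()` chains: XIC over the whole light+heavy envelope → peak
bounds → sum of all spectra across the bounds (the default; per-scan
estimates are available through `peak_purity()`) → grid projection → NNLS
fractions → amount = standard × light/heavy. `prep_amounts()` carries a
dilution chain (evaporation, reconstitution, aliquot, diluent, spike,
injection) in both directions, so an on-column amount back-calculates to a
sample concentration.

Calibration (`fit_calibration()`) is ordinary least squares of response
against amount, where the response is the internal-standard-normalized
area ratio — the quantity the isotope-dilution design makes robust. The
limit of detection uses the ICH-style estimator LOD = 3.3 σ~resid~/slope;
no claim is made that this reproduces any particular instrument's detection
floor, which depends on absolute sensitivity the synthetic model does not
attempt to emulate. Gravimetric unit conversion (ng ↔ pmol) uses the
*average* molecular weight of the benzoate salt C~28~H~34~N~2~O~3~
(≈ `r round(average_mw(parse_formula("C28H34N2O3")), 2)` g/mol), the scale
on which material is weighed: 0.68 ng ↔
`r signif(ng_to_pmol(0.68), 3)` pmol.

## The synthetic-data generator

`simulate_run()` emulates the features of the real experiment that the
analysis actually exercises:

- two isotopologue envelopes ~2 Da apart with the overlapping M+2/M+0
  centroid pair, rendered at resolving power 30,000 (FWHM-based centroid
  merging), typical of a benchtop ESI-TOF;
- a *shared* Gaussian elution profile (apex 18.83 min, σ 0.1 min by
  default, 1-s scans over a 17.5–20 min window) — co-elution of
  isotopologues is the generative assumption, and tests that need a
  retention shift impose one by recombining separately simulated channels;
- one shared response factor for light and heavy species (equal ionization
  efficiency of isotopologues, which is what the method presumes);
- multiplicative lognormal intensity noise with configurable CV, plus an
  optional flat additive baseline; with `noise_cv = 0` the generator is an
  exact linear model, so deconvolution must recover mixing weights to
  machine precision — and does;
- full determinism under a seed, without disturbing the caller's RNG
  stream.

What it deliberately does **not** emulate: matrix interferents beyond a
flat baseline, in-source fragmentation, detector saturation, retention
drift between runs, and absolute instrument response (intensities are
arbitrary units; injection volume defaults to 5 µL and cancels from every
ratio-based result). Passing tests therefore demonstrate the correctness
of the *computational* chain under the method's own assumptions, not the
performance of any instrument on real matrices.

Runs interchange as a documented CSV dialect (`scan`, `rt_min`, `mz`,
`intensity`; `write_run_csv()`/`read_run_csv()`), bit-stable under a fixed
seed.

## Numerical choices and degenerate inputs

- Intermediate convolution keeps fine structure and prunes only below
  10^-15^; merging once at the end makes the pattern identical (to 10^-9^)
  to exhaustive isotopologue enumeration with the same grouping rule.
- The basis is built from the same fine-tolerance patterns the generator
  uses, aggregated onto a 0.01-Da grid; this keeps the noiseless round
  trip exact instead of merely close.
- NNLS is solved by Lawson–Hanson (`pracma::lsqnonneg`); ties and
  degenerate cases surface as errors (all-zero observation, collinear
  basis, zero heavy fraction) rather than NaNs.
- `fit_rate()` uses a coarse log-grid bracket followed by golden-section
  refinement to 10^-12^; an all-zero time course returns k = 0 flagged
  degenerate instead of failing.
- Peak detection returns a no-peak result (`NULL`) on flat traces; blank
  runs propagate to a flagged non-detect in `quantify_run()`.

## Problem sizes in the validation suite

The test suite validates the stochastic claims at desk scale: 100 seeded
replicates for ratio recovery (noise CV 1%), 100 seeded end-to-end runs
with amounts log-uniform in 1–100 pmol (median relative error bounded at
2%), an 8-level calibration over 0.68–47.5 ng equivalents at 0.5% noise
(R² bound 0.9992), and 20 random small formulas against the enumeration
oracle. The whole suite runs in well under a minute.

## Known limitations

- Two species classes only (light analyte, labeled standard); co-eluting
  foreign compounds are flagged as residual/foreign intensity, not
  deconvolved.
- The exchange model is pseudo-first-order with equivalent sites; no
  pH-dependent rate law or site asymmetry.
- LOD is a calibration-residual construct; it tracks the simulation's
  noise model linearly and should not be read as an instrument detection
  limit.
- mzML ingestion is out of scope here; the CSV dialect is the interchange
  format, and converters from vendor formats to centroid CSV are routine.
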