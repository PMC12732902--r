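---
title: "Umami profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Umami profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umamikit)
```

This vignette is the package's account of the science it implements: the
scoring models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The scoring models

### Taste activity value

A compound's direct contribution to taste is scored as the ratio of its
tissue concentration to the human detection threshold, TAV = C/T, both in
mg per 100 g dry weight. TAV ≥ 1 is the conventional bound for a perceptible
contribution. The model is deliberately crude — a ratio, not a psychophysical
intensity function — so TAVs far above 1 rank compounds but do not claim
proportional perceived intensity (taste saturates).

The shipped threshold registry covers the standard sensory-literature list:
umami Glu 30 and Asp (see below); sweet Ala 6, Gly 13, Thr 26, Ser 15;
bitter Arg 50, His 20, Val 15; Lys 5 and Pro 30 carried under the
"unflavored" label their source lists use; nucleotides GMP 12.5 and AMP 50.
Taurine is registered class-only (tasteless per se): it belongs in
composition breakdowns but a TAV request for it is a defined error, never a
silent zero. The same holds for IMP, which has a potency but no established
threshold in the registry.

**The aspartate threshold.** Threshold compilations disagree on Asp: 10 and
100 mg/100 g both circulate. The bundled reference dataset's published TAVs
and EUC values are mutually consistent only with T(Asp) = 100 — with 10, the
reference EUC of *C. sinensis* recomputes to ~279.4 instead of the published
283.23 — so 100 is the shipped default and the 10 mg/100 g alternative is
kept, commented, in the YAML for users following the other lists.

### Equivalent umami concentration

Umami amino acids and 5′-nucleotides synergize at the T1R1/T1R3 receptor;
the Yamaguchi model expresses a mixture's umami intensity as the equivalent
MSG concentration:

$$\mathrm{EUC} = \sum_i a_i b_i \;+\; 1218 \left(\sum_i a_i b_i\right)
\left(\sum_j a_j b_j\right)$$

with concentrations in g/100 g and potencies relative to MSG (Glu 1.000,
Asp 0.077; AMP 0.18, IMP 1.0, GMP 2.3); 1218 is the empirical synergy
constant. Consequences the implementation embraces rather than hides:

- the score is unbounded and routinely exceeds 100 g/100 g; no cap is
  applied;
- it is nonlinear, so EUC-of-species-means differs from mean-of-replicate-
  EUCs. The headline per-species score is computed on species means (that is
  what published tables report); `euc_by_replicate()` gives the per-replicate
  mean ± SD separately, and the package never mixes the two;
- it scales as k in the additive term but k² in the synergy term, a property
  the tests enforce;
- IMP participates whenever present (potency 1.0); in the reference dataset
  it was not detected, and an absent compound contributes exactly 0.

Internally every module boundary uses mg per 100 g dry weight — the model's
g/100 g and the quantification chain's µg/g are converted at the edges. One
canonical unit avoids silent factor-of-ten errors across the three unit
conventions this literature mixes. Reporting rounds half-away-from-zero to
2 decimals (matching how the published tables round, e.g. 2.625 → 2.63);
internal math is full precision.

### HPLC quantification

Calibration is unweighted ordinary least squares of peak area on standard
concentration — the simplest model consistent with an R² acceptance
criterion; curves with R² ≤ 0.995 over the 0.1–50 µg/mL span are flagged
invalid. Inverse prediction floors trace-level negative estimates at zero
(with a warning) and warns beyond 1.2× the calibrated range. Tissue content
is C·V/W (µg/g), with the pooled extract entering as a single volume V; the
sample mass W is stored agnostically (the protocol's lyophilized-powder
detail is a prep fact, not a computation).

### Relative expression

The classic 2^−ΔΔCt chain: per-replicate ΔCt against the species-specific
reference gene, group ΔCt as the replicate mean, ΔΔCt against a calibrator,
fold = 2^−ΔΔCt. Efficiency is assumed 2.0 in the formula; measured
efficiencies from dilution-series curves (10^(−1/slope) − 1, acceptance
window 0.9–1.1) validate primers but are not folded into an
efficiency-corrected model. The calibrator default is "auto": per gene, the
species with the largest group ΔCt, which makes every displayed fold ≥ 1.
Because each species is normalized to its own reference gene, cross-species
folds compare relative levels, and the function logs that caveat.

### Group statistics and letters

Per-compound species differences use classical one-way ANOVA and Tukey HSD
(Tukey–Kramer for unbalanced groups), α = 0.05. The compact letter display
is computed from the pairwise p matrix by insert-and-absorb: start with one
letter covering all groups, split every letter containing a significantly
different pair, absorb subset letters. This guarantees the defining
invariant — two groups share a letter exactly when their pairwise p ≥ α —
though not minimal letter count. Letters are ordered so "a" goes to the
largest mean, the convention of descending-mean tables. The fully degenerate
case (all values identical) is reported as F = 0, p = 1 rather than NaN.

Expression–metabolite association uses Pearson's r with the two-sided
t-transform p on n − 2 df, **unadjusted** — the exploratory convention for
small candidate-gene panels, minimizing type-II errors at the cost of
family-wise control; the reporting filter compensates by highlighting only
|r| > 0.8 with p < 0.05.

## The synthetic-data generator

The generator emulates the study design the analysis assumes: six species
(units) × ten biological replicates, with per-species compound means/SDs
defaulting to the bundled reference table (where a published SD is missing, a
10% CV is used — a typical combined biological + analytical spread for these
assays).

- **Concentrations are lognormal**, moment-matched so each species×compound
  hits its target mean and SD in expectation; lognormality guarantees
  positivity, which a Gaussian would not.
- **Gene–compound coupling** uses a Gaussian copula at the unit (species)
  level: latent bivariate normals transformed to a lognormal expression fold
  (median 1, between-unit CV 0.5 by default) and a lognormal concentration
  whose mean/SD match the between-species spread of the configured table.
  Because Pearson correlation is not preserved by nonlinear margins, the
  latent correlation is back-calibrated through the bilognormal closed form
  $r = (e^{\rho_z\sigma_1\sigma_2}-1)/\sqrt{(e^{\sigma_1^2}-1)(e^{\sigma_2^2}-1)}$
  so the **observed-scale** Pearson r equals the configured ρ (default 0.90
  for GLUD1–Glu, the headline association). Bilognormal pairs have an
  asymmetric attainable range — strongly negative targets need comparable
  log-scale spreads on both margins — and an unattainable target fails
  loudly at generation rather than silently under-delivering.
- **Ct records** are derived from the folds (ΔCt = baseline − log₂ fold,
  reference Ct ≈ 18) with Gaussian technical noise (SD 0.15 cycles), so the
  2^−ΔΔCt chain recovers the latent folds exactly when the noise is switched
  off.
- **Determinism**: one master seed with per-generator substream derivation,
  so adding a generator never perturbs existing streams; identical config +
  seed gives byte-identical output.

What the generator does *not* emulate: seasonal/environmental covariates,
separate biological vs technical variance components (a single dispersion
term is used; the real split is unpublished), compound–compound covariance
within a species, and chromatographic artifacts. Passing tests on synthetic
data therefore demonstrate correctness of the computations and calibration
of the statistical machinery, not field validity of any biological claim.

## Numerical choices and degenerate inputs

- Reporting rounds half-away-from-zero at 2 dp; all comparisons against
  published values happen at that precision.
- Missing threshold, missing potency, negative concentration, mixed basis,
  duplicate (species, replicate, compound) rows: all defined errors that
  name the offender, never silent coercions.
- Zero within-group variance: ANOVA/Tukey short-circuit to "no separation"
  (F = 0, p = 1) when means are also equal; zero-variance correlation pairs
  return NA with a warning.
- Sample SD uses the n − 1 denominator throughout (the "mean ± SD"
  convention of replicate tables); a single replicate reports SD = NA.

## Problem sizes

The test suite and drivers run the study-scale design (6 × 10) everywhere a
published quantity is reproduced, and scale the stochastic calibration
checks to where their Monte-Carlo error is decisive: 10⁵ draws for
moment-matching and the default-coupling recovery (MC error on r ≈ 6×10⁻⁴),
2×10⁴ for the ρ-sweep, 4×10³ permutations for the ANOVA cross-check.

## Known limitations

- EUC is a chemical index of umami *potential*; it does not model taste
  saturation or mixture suppression, so species rankings, not absolute
  intensities, are the meaningful output.
- Three of the six reference species lack a recoverable Asp mean, so their
  EUCs are computed from partial inputs and flagged as such in the driver
  output; they are not reproduction targets.
- The reconstruction of amino-acid means from TAVs printed at 2 decimals
  carries ±0.005·T rounding, which propagates to roughly ±0.1 g MSG/100 g in
  EUC — the resolution limit of desk reproduction from printed values.
- Letter assignments for the reference tables cannot be regression-tested
  (raw replicates unpublished); only the CLD invariant is enforced.
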