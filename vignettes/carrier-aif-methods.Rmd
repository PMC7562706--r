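---
title: "Non-radiometric arterial input functions from carrier mass: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-radiometric arterial input functions from carrier mass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaif)
```

## The problem

Quantitative brain PET with a carbon-11 tracer usually needs the arterial
input function (AIF): the time-course of unmetabolized tracer radioactivity
in arterial plasma. The conventional measurement counts plasma radioactivity
in a γ-counter and corrects for radiometabolites by radio-HPLC — all inside
the few half-lives (t~1/2~ = 20.4 min) the decaying signal allows.

A ^11^C tracer is, by mass, almost entirely *carrier*: the non-radioactive
^12^C and ^13^C isotopologues that accompany it, typically a thousandfold
molar excess over the ^11^C species. If the molar activity

$$A_m = \frac{\text{radioactivity}}{\text{total amount (radioactive + carrier)}}
\qquad \text{(GBq/µmol)}$$

of the injected dose is known, a carrier concentration curve measured by
LC–MS/MS converts directly into an AIF in radioactivity units — with no
radioactivity measurement, no decay deadline, and absolute traceability
through the decay law $A = \lambda N$. This package implements that
pipeline and a synthetic-study generator for validating it end to end.

## Molar activity from isotopologue peak areas

The theoretical ceiling is the carrier-free molar activity
$A_m^* = (\ln 2 / t_{1/2})\, N_A \approx 3.41\times10^{20}$ Bq/mol
(341,000 GBq/µmol), computed — never hard-coded — from the configured
half-life. A dose analysis monitors the MRM channels of the ^11^C, ^12^C
and ^13^C isotopologues of a product ion. With peak areas $A_{11}, A_{12},
A_{13}$,

$$A_m = \frac{A^*}{A + A^*}\,A_m^*, \qquad
A = A_{12} + A_{13}, \qquad A^* = A_{11}\,(1 + r_\text{nat}/100),$$

where $r_\text{nat}$ is the natural M+1/M ratio of the fragment (the
^11^C molecules carrying a natural heavy isotope elsewhere fall outside the
monoisotopic ^11^C channel). In *pair mode* — used when the abundant ^12^C
channel would saturate the detector — $A_{12}$ is reconstructed from
$A_{13}$ via the carrier's measured ^13^C/^12^C ratio $r$:
$A_{12} = A_{13}\cdot 100/r$. The two modes are algebraically identical
whenever the areas are consistent, and the package tests pin that identity
at 1e−12.

Two conventions had to be fixed where the assay description leaves them
open:

* The $A^*$ heavy-isotope correction uses the *natural* ratio of the
  reference compound, not the enriched carrier ratio: the enrichment sits
  at the labeled position, which in the radioactive species is ^11^C, so
  only the remaining atoms (at natural abundance) can shift its channel.
  The difference is below 0.1% of $A_m$ either way; both are configurable.
* Replicate injections are summarized as mean ± SD with no outlier
  rejection.

## Cyclotron ^13^C enrichment

Proton irradiation of nitrogen makes ^11^C by ^14^N(p,α)^11^C, but the
^14^N(p,2p)^13^C channel has a similar cross section (74.2 vs 68.9 mb at
13.2 MeV), so stable ^13^C is co-produced in proportion to beam exposure.
The generator models this with saturation kinetics: production rate
$R = A_{EOB}/(1 - e^{-\lambda T})$, linear ^13^C accumulation
$n_{13} = R\,(\sigma_{13}/\sigma_{11})\,T$, and ^11^C decay through the
synthesis. The carrier's ^13^C/^12^C ratio therefore rises with $A_m$ and
extrapolates to the natural ratio at $A_m = 0$ — the behaviour the
enrichment-line fit (`fit_enrichment_line()`) checks. Two caveats are
deliberate:

* A first-principles evaluation of this model at 75 GBq / 40 min gives
  ~0.43 nmol of ^13^C, not the ~10 nmol sometimes quoted as a rough
  estimate; the generator therefore parameterizes the yield through the
  cross-section ratio and beam settings rather than asserting a mass.
* The ratio-vs-$A_m$ relation is *exactly* linear only in the
  carrier-dominated limit. Because the true $A_m$ denominator includes the
  beam-derived ^13^C and ^11^C amounts (it must, or the zero-noise
  estimator round trip would not be exact), the relation is very slightly
  hyperbolic. With realistic defaults the fitted intercept lands within
  ~0.2% of the configured natural ratio and $r > 0.9999$ — not within
  1e−9. The test suite asserts the achievable guarantee and leaves the
  idealized exact-linearity assertion failing by design rather than
  weakening either the model or the round-trip exactness.

## Plasma quantification and the isotope skew

Carrier in plasma is quantified against a stable-isotope-labeled internal
standard on a linear calibration curve of area ratio versus concentration.
Because the calibration uses the natural-abundance reference compound while
the dose carrier is ^13^C-enriched, quantification on the ^12^C channel
underestimates total carrier; the correction is

$$c' = \frac{100 + x}{100 + y}\,c,$$

with $x$ the carrier and $y$ the reference ^13^C/^12^C ratio. For the
enrichment actually observed ($x - y \lesssim 0.9$ points) this is a
sub-1% adjustment, and the package asserts that bound.

**Calibration weighting.** The generic `fit_calibration()` default is
unweighted OLS, matching the simple linear curve of the motivating assay.
The *pipeline* default (`study_config()`) is `1/x²` weighting: with
multiplicative MS noise over the three-decade concentration range of an
AIF, the unweighted intercept error (tens of pM) would swamp the late-time
tail and corrupt AUCs by ~50–100%. This is the one place the package
deviates from its own "simplest model" rule, because the end-to-end
simulation proved the simple choice numerically wrong; weighting remains a
single config key. Relatedly, the generator's plasma calibration series
spans 7.8–8000 pM so that standards actually bracket the samples; values
below the lowest standard are flagged (`below_lloq`), not censored, since
late AIF points matter.

## AIF construction and the γ-counter correction

The LC–MS/MS AIF is the corrected carrier curve times $A_m$
(pM × GBq/µmol = Bq/mL, reported in kBq/mL). The radiometric AIF is the
γ-counter total-activity curve times the radio-HPLC parent fraction, with
fractions interpolated linearly onto the activity grid and never
extrapolated. γ-counters calibrated against surrogate isotopes read ^11^C
with a roughly constant multiplicative bias (~1.3×); the per-preparation
correction factor is estimated as the geometric mean of γ/LC–MS/MS
ratios — the maximum-likelihood estimator for a shared factor under
lognormal noise — and applied as a division. The estimator choice is a
package decision; the source assay does not state one.

Method agreement is summarized by trapezoidal AUCs (no extrapolation
beyond the sampled range), the "percent lower than reference" convention,
the mean-based test–retest form $100\,|a-b|/\bar{ab}$, Pearson's $r$,
paired $t$ (two-sided, $n-1$ df), and the intraclass correlation. The ICC
variant is two-way, absolute-agreement, single-measures — ICC(A,1) — the
only variant consistent with a correlation that survives a constant
multiplicative offset while agreement does not (the 0.07 → 0.91 pattern).
It is implemented directly from the mean-squares decomposition and tested
against an independent `aov()`-based oracle.

## What the generator emulates — and what it does not

One synthetic study comprises: productions spanning $A_m$ ≈ 140–1100
GBq/µmol (beam scaling at fixed contamination); a calibration series; and
one subject per production with

* the 23-point arterial schedule (15-s draws to 2.5 min, then 3, 4, 6, 8,
  10, 15, 20, 30, 40, 50, 60, 75, 90 min);
* a bi-exponential parent carrier curve, defaults 8800·e^(−1.2t) +
  47·e^(−0.025t) pM at the reference condition (≈2000 pM at 1.25 min to
  ≈5 pM at 90 min, the observed plasma range), scaled inversely with
  $A_m$ at fixed injected dose (10.1 MBq/kg) as physiology dictates;
* a parent fraction $f(t) = f_\infty + (1-f_\infty)e^{-k_{met}t}$
  (defaults 0.05, 0.05 min⁻¹);
* a preparation-specific γ bias drawn around 1.32 (SD 0.03), matching the
  distinct constant per-preparation ratios seen in practice;
* between-subject lognormal variability of the curve amplitudes (CV 0.2,
  reproducing the ~21% across-subject AUC RSD) — without it, subject-level
  correlation statistics would be noise-driven and meaningless;
* multiplicative lognormal noise (unit mean) on all peak areas and γ
  counts. Poisson counting noise is omitted: γ counts at kBq levels are
  high enough that the multiplicative term dominates.

All randomness flows from explicit seeds; identical seed and configuration
reproduce tables byte-identically. With every noise term at zero, each
pipeline estimate ($A_m$, ratio, concentrations, correction factor, AUCs)
equals its generator truth to better than 1e−9 relative — by construction,
since the generator emits areas under the same first-order isotope
conventions the estimators invert.

A green synthetic test therefore establishes internal consistency and
statistical behaviour under the stated noise model. It does **not**
establish: matrix effects and extraction recovery, chromatographic
interference, detector saturation, dispersion or delay of the arterial
signal, whole-blood/plasma partitioning, or the unexplained residual ~8%
AUC gap that remains between methods after correction in real data — the
pipeline reports such a gap but does not model its cause.

## Numerical and policy choices

* Units: $A_m$ in GBq/µmol (1 GBq/µmol = 10¹⁵ Bq/mol); activities kBq,
  concentrations pM, times minutes post-injection; decay references in
  seconds relative to end of synthesis.
* Isotope abundance defaults: ^13^C/^12^C 1.082%, ^2^H 0.0115%,
  ^15^N 0.365%, ^17^O 0.038% per atom; all configurable. The M+1 model is
  first-order (no M+2), adequate below ~10%.
* Half-life default 20.4 min; $A_m^*$ accepted against the conventional
  3.413 × 10²⁰ Bq/mol at 0.2% (the precision of the underlying half-life
  is not better specified).
* Degenerate inputs: identical series give ICC = 1 and t = 0/p = 1;
  zero-variance-with-offset differences are an error; below-blank
  concentrations clamp to 0 with a warning and flag.
* p-values are reported as computed; 0.05 is the conventional threshold.

## Known limitations

The production model uses single effective cross sections rather than
energy-resolved excitation functions; the subject model has no rising
(injection/dispersion) phase before the first sample, so AUCs are
internally consistent but not calibrated to any particular printed study
mean; and the CLI's `aif` subcommand assumes one preparation per subject
unless an explicit subject map is provided.
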