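# msaif

Non-radiometric arterial input functions (AIFs) for carbon-11 PET tracers
by LC–MS/MS quantification of the tracer carrier.

## Why

Kinetic modeling of brain PET data needs the AIF — the time-course of
unmetabolized radiotracer in arterial plasma. For ^11^C tracers
(t<sub>1/2</sub> = 20.4 min) the conventional radiometric measurement
(γ-counting + radio-HPLC metabolite correction) must race the decay. But a
^11^C tracer is, by mass, almost entirely non-radioactive *carrier*
(^12^C/^13^C isotopologues). Knowing the dose's molar activity

> *A*<sub>m</sub> = radioactivity / total amount  (GBq/µmol),
> with ceiling *A*<sub>m</sub>\* = (ln2/t<sub>1/2</sub>)·N<sub>A</sub> ≈ 3.41 × 10²⁰ Bq/mol,

a carrier concentration curve measured by LC–MS/MS converts directly into
an AIF in radioactivity units — no radioactivity measurement, no decay
deadline. `msaif` implements the full pipeline:

* **Isotopologue molar activity** — *A*<sub>m</sub> = *A*\*/(*A* + *A*\*) ·
  *A*<sub>m</sub>\* from ^11^C/^12^C/^13^C peak areas (triad mode) or from
  ^11^C/^13^C alone plus the carrier's ^13^C/^12^C ratio (pair mode,
  avoiding detector saturation).
* **Plasma quantification** — internal-standard calibration, with the
  (100 + x)/(100 + y) correction for the cyclotron-induced ^13^C
  enrichment of the carrier.
* **AIF construction and comparison** — carrier→activity conversion,
  metabolite-corrected radiometric AIFs, geometric-mean estimation of the
  systematic γ-counter bias (~1.3×), trapezoidal AUC, test–retest
  variability, Pearson r, absolute-agreement ICC(A,1), paired t.
* **Synthetic studies** — a generator with full ground truth (cyclotron
  ^11^C/^13^C co-production, carrier contamination, bi-exponential plasma
  clearance, declining parent fraction, detector bias, lognormal noise)
  so every stage is validated end to end.

## Worked example

```r
library(msaif)

nuclide_constants()
#> <nuclide_constants> t1/2 = 20.4 min, lambda = 0.000566297 /s, Am* = 3.41e+20 Bq/mol (341031.9 GBq/umol)

# pair-mode molar activity from a dose analysis
am_from_pair(area_11c = 1.101, area_13c = 100,
             carrier_ratio = 10.08, natural_ratio_pct = 9.16)
#> <molar_activity> Am = 374.9 GBq/umol (pair mode)

# carrier amount x Am = radioactivity (pmol x GBq/umol = kBq)
radioactivity_from_carrier(15.2, 200.4)
#> [1] 3046.08

# a complete synthetic study: simulate -> quantify -> compare -> verify
run_end_to_end(study_config(seed = 1))
#> <end_to_end> 8 subjects; max |rel error| of recovery: 0.034
#> AIF method comparison (AUC, kBq x min/mL)
#>   n subjects: 8
#>   mean AUC  LC-MS/MS: 1.01e+03   radiometric: 1.34e+03   corrected: 1.02e+03
#>   LC-MS/MS lower than radiometric by 24.8% (uncorrected), 0.9% (corrected)
#>   VAR 28% / 1%, Pearson r 0.99 / 1.00, ICC 0.50 / 1.00 (uncorr / corr)
#>   paired t: -11.1 (p = 1.08e-05) uncorrected, -2.55 (p = 0.0379) corrected
```

Reading the comparison: the uncorrected radiometric AIF overshoots the
mass-based AIF by the configured γ bias (1.32× → AUCs ~25% lower for
LC–MS/MS); after the per-preparation correction the two methods agree to
~1%, Pearson r is essentially unchanged, and the absolute-agreement ICC
jumps — the signature of removing a purely systematic offset. The
recovery line confirms every estimate sits within 3.4% of its simulation
ground truth at the default noise level (and within 1e−9 at zero noise).

## Command line

```sh
Rscript -e 'msaif::msaif_cli()' simulate --seed 4 --subjects 8 --out study/
Rscript -e 'msaif::msaif_cli()' am  --dose study/dose_areas.csv --ratios study/carrier_ratios.csv --out study/
Rscript -e 'msaif::msaif_cli()' aif --plasma study/plasma.csv --calibration study/calibration.csv \
    --gamma study/gamma.csv --parent-fraction study/parent_fraction.csv \
    --am-report study/am_report.csv --out study/
Rscript -e 'msaif::msaif_cli()' report --seed 1 --out report/
```

All tabular interchange is CSV with versioned column names; configuration
is a flat JSON file (`study_config()` documents the keys); every run
writes a provenance record (config hash, seed, schema version).

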