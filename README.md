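# putatrophy

Age-normative analysis of putamen volume in relapsing-remitting multiple
sclerosis (RRMS), for neuroimaging researchers who have per-subject
volumetry (e.g., FreeSurfer `aseg.stats` output) for patients and
healthy controls and want to quantify each patient's putamen atrophy
beyond normal aging — and model when it starts and how it progresses.

## The method

Head size is removed by the proportion method,

    APV = left putamen + right putamen            [mm³]
    RPV = APV / ICV × 100                         [% of intracranial volume]

and age by a normative regression fitted on healthy controls only,

    RPV_HC(Age) = β₀ + β₁ · Age

Each subject is then scored by the age-corrected deviation

    ΔRPV  = RPV_observed − RPV_HC(Age)            [percentage points of ICV]
    ΔRPV% = ΔRPV / mean(RPV_HC) × 100             [% of mean control RPV]

where negative ΔRPV% means atrophy. For patients, ΔRPV% is regressed on
disease duration D (months) under two competing forms — linear
`a·D + b` (constant loss; its root −b/a extrapolates atrophy onset) and
logarithmic `a·log₁₀(D) + b` (degressive loss) — compared by residual
sum of squares with normal-probability-plot correlations as secondary
evidence. Group contrasts use pooled t-tests, Yates-corrected
chi-squared, ANCOVA, and Pearson correlations with lesion burden.

A synthetic-cohort generator (`generate_study()`) reproduces the assumed
statistical structure (demographics, normative line, logarithmic
decline, lesion copula) so the whole pipeline runs and is testable with
no external data.

## Worked example

```r
library(putatrophy)

study  <- generate_study(synth_config(seed = 5))
report <- run_pipeline(study$cohort, out_dir = "results")
report
```

```
<analysis_report> 26 HC, 68 MS
  normative: RPV_HC(Age) = 0.9283 -0.00408 x Age (residual SD 0.0573)
  APV reduction 19.0%, RPV reduction 18.9%; deviation t = -9.81 (df 92, p = 5.62e-16)
  patients below age expectation: 67/68
<trajectory_fit:linear> deviation = -0.0565 x D -14.599 (n = 68, SSE = 4503.4, QQ-r = 0.990)
<trajectory_fit:log10> deviation = -11.421 x log10(D) +1.250 (n = 68, SSE = 4408.1, QQ-r = 0.991)
  onset (linear extrapolation): -258 months; preferred model: log10
  deviation ~ lesion_t1_ml: r = -0.70 (n = 68, p = 2.88e-11)
  deviation ~ lesion_flair_ml: r = -0.76 (n = 68, p = 5.84e-14)
```

Reading this: the controls' relative putamen volume declines by about
0.004 percentage points of ICV per year; patients sit on average ~19%
below age-matched expectation (67 of 68 below it); the linear trajectory
extrapolates atrophy onset to well before first symptoms, while the
logarithmic model — preferred on residual sum of squares — reads the
same data as steep early loss that flattens later; and more lesion
burden goes with more negative deviation. `results/` receives
`report.json`, the demographics and deviation CSV tables, and the two
deviation-versus-duration figures.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","putatrophy.R",package="putatrophy"))')" \
  synth --seed 5 --out data/
Rscript "$(Rscript -e 'cat(system.file("cli","putatrophy.R",package="putatrophy"))')" \
  analyze --cohort data/cohort.csv --out results/
```

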