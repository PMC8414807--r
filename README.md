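# ffrscore

Multi-factor risk weighting and scoring for predicting low fractional flow
reserve (FFR ≤ 0.8) in coronary stenosis.

Invasive FFR is the reference standard for judging whether a stenosis is
hemodynamically significant, but screening on angiographic diameter
stenosis (DS) alone predicts it poorly. `ffrscore` is for biostatisticians
and clinical researchers who want to combine the published independent risk
factors — gender, BMI, stenosis location, coronary dominance, LVEF, left
ventricular mass, DS and others — into a single quantitative screening
score, and to evaluate how well that score discriminates.

## What it computes

The core is an analytic hierarchy process (AHP). Factors sit in a
three-layer hierarchy (target → evidence domains → variables), each layer
weighted by a pairwise importance-degree matrix *A* on the Saaty 1–9 scale
(built directly, or from odds ratios via the monotone map
`clamp(round(ORᵢ/ORⱼ), 1, 9)`). For each matrix the package solves the
normalized principal right eigenvector **w** (the local weights) and the
maximum characteristic root *MCR*, and diagnoses judgment consistency with

    CI = (MCR − n) / (n − 1),   RCR = CI / K(n),   acceptable iff RCR ≤ 0.1

where K(n) is the random-consistency constant (0.58, 0.96, 1.12, 1.24 for
n = 3..6). Global factor weights are products down the hierarchy; the top
seven factors are flattened into a 10-point scoring form (one-decimal
items, rounding residual to the smallest item) with an inclusive ≥ 6.2
decision cutoff. Evaluation is rank-based AUC (DeLong or bootstrap CIs),
Youden-index cutoff selection, and confusion-matrix metrics with Wilson
CIs, against a DS-alone baseline. A seeded synthetic cohort generator,
calibrated to the published marginals and operating point, exercises the
whole pipeline without access to the original clinical cohort.

## Worked example

```r
library(ffrscore)

gw <- propagateWeights(ffrHierarchy())
head(globalWeights(gw), 7)
#>    factor            criterion criterionWeight factorWeight globalWeight rank
#> 8      ds coronary angiography            0.51        0.387      0.19737    1
#> 7      ls coronary angiography            0.51        0.288      0.14688    2
#> 9    tcad coronary angiography            0.51        0.242      0.12342    3
#> 1  gender  clinical statistics            0.32        0.350      0.11200    4
#> 12   lvef   cardiac ultrasound            0.17        0.590      0.10030    5
#> 6     bmi  clinical statistics            0.32        0.256      0.08192    6
#> 13    lvm   cardiac ultrasound            0.17        0.280      0.04760    7
```

DS carries the largest global weight (0.51 × 0.387 = 0.197, rank 1). The
top seven factors become the 10-point form:

```r
form <- ffrScoringForm()
form
#> ScoringForm: 10 points total, predict low FFR when score >= 6.2
#>   ds       ds >= 60 : 2.4
#>   ls       stenosis_location = LAD : 1.8
#>   tcad     tcad = right : 1.5
#>   gender   gender = male : 1.4
#>   lvef     lvef <= 58 : 1.2
#>   bmi      bmi >= 23.5 : 1.0
#>   lvm      lvm >= 148 : 0.7

scorePatient(list(gender = "male", stenosis_location = "LAD", ds = 72,
  tcad = "right", lvef = 62, lvm = 138, bmi = 26), form)$total
#> [1] 8.1
```

That patient scores 8.1 ≥ 6.2, so the form predicts FFR ≤ 0.8. End to end
on a synthetic cohort:

```r
coh <- generateCohort(defaultCohortSpec(n = 2000, seed = 1))
evaluateCohort(coh)
#> Evaluation on 2000 records (prevalence of low FFR: 0.517)
#>   scoring form AUC: 0.849 (95% CI 0.833-0.866)
#>   DS-alone AUC:     0.684 (95% CI 0.660-0.708)
#>   cutoff >= 6.2 points: sens 0.902, spec 0.602, PPV 0.708, NPV 0.852
#>   mean total score: 6.8 +/- 1.8 points
```

The multi-factor form clearly out-discriminates DS alone (AUC 0.849 vs
0.684 here). A command-line wrapper covering the same pipeline
(`weights`, `form`, `score`, `evaluate`, `simulate`) is installed under
`exec/ffrscore`.

See `vignettes/ffr-risk-weighting.Rmd` for the model, the calibration of
the synthetic cohort, and the package's design decisions.

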