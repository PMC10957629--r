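# postprandial

Analysis of postprandial amino acid responses in crossover intervention
trials: who digests which protein, how completely, and how fast?

In a typical study, volunteers consume different protein meals
(interventions) in successive periods, one of them an easily digestible
reference; blood amino acid concentrations are sampled repeatedly for a
few hours after each meal.  This package implements the full analysis
chain for such data, for nutrition scientists and biostatisticians:

1. **Curve fitting.**  Every participant x intervention x analyte time
   course is fitted with a baseline-extended Wood curve
   *y(t) = d + a·t^b·e^(−ct)* (b = m·c), by multi-start bounded
   nonlinear least squares.  The parameters are interpretable: *d* is
   the fasting baseline, *m* the peak time, *c* the decay rate.
2. **Parameters of interest**, analytically from the fit:
   Time2Max = m; Height = a(b/c)^b e^(−b); and
   AUC(t_f) = a·γ(b+1, c·t_f)/c^(b+1) above baseline, with γ the lower
   incomplete gamma function.
3. **Curation**: PoIs and curve parameters outside plausible ranges
   (defaults: AUC > 0, Height in (0, 1000), Time2Max in (15, 200) min)
   become `NA` with a full audit trail.
4. **Non-responder imputation**: low AUC/Height estimates predicted
   from the 0.2/0.8-quantile spread of the raw series; Time2Max is
   never imputed.
5. **Comparison**: per analyte and PoI, a linear mixed model
   `PoI ~ Intervention + Period + (1 | Participant)` with
   test-vs-reference contrasts — AUC as a back-transformed ratio,
   Height and Time2Max as differences — Kenward–Roger (or
   Satterthwaite) degrees of freedom, and Holm-adjusted p-values.

A synthetic-study generator with known ground truth, visualization
(time-course panels, PCA score plots, curation dot plots, forest
plots), a scripted pipeline (`run_pipeline()`), and a command-line
front end (`exec/postprandial`) round out the package.

## Worked example

Simulate a default crossover study (12 participants, 3 interventions,
10 sampling times within 3 h, 9 essential amino acids) in which the
first test intervention has a true AUC ratio of 0.7 against the
reference, then run the analysis:

```r
library(postprandial)

design <- simulate_effect_scenario(null_design(sim_design(seed = 42)),
                                   auc_ratio = 0.7)
sim <- simulate_study(design)
sim$table
#> Study table: 12 participants, 3 interventions (reference: REF), 9 analytes, 3240 records

fits <- fit_all(sim$table, n_starts = 25, seed = 42)
pois <- curate_pois(extract_pois(fits), fits)$pois
res  <- compare_pois(pois, reference = "REF")
head(as.data.frame(res)[c("Analyte", "PoI", "contrast", "type",
                          "estimate", "ci_low", "ci_high", "p_adjusted")])
#>   Analyte      PoI     contrast       type estimate  ci_low ci_high p_adjusted
#> 1     His      AUC TESTA vs REF      ratio    0.741   0.552   0.995   0.511767
#> 2     His      AUC TESTB vs REF      ratio    0.993   0.739   1.332   1.000000
#> 3     His   Height TESTA vs REF difference   -8.996 -12.500  -5.492   0.000397
#> 4     His   Height TESTB vs REF difference   -2.580  -6.084   0.924   1.000000
#> 5     His Time2Max TESTA vs REF difference    0.707  -4.531   5.945   1.000000
#> 6     His Time2Max TESTB vs REF difference   -2.078  -7.188   3.033   1.000000
```

Reading the output: the estimated histidine AUC ratio for TESTA is 0.74
(truth: 0.70) with a 95 % CI just excluding 1, while the null
intervention TESTB sits at 0.99; the height differences follow the
amplitude scaling (TESTA absorbs less), and peak times do not differ —
exactly the generating truth.  `p_adjusted` is Holm-corrected within
each PoI across all analytes and contrasts, so single-analyte findings
are damped appropriately.

A single series can be inspected directly:

```r
one <- subset(sim$table, Participant == "P01" & Analyte == "His")
fit <- fit_wood(one$Time[1:10], one$Value[1:10], n_starts = 50, seed = 42)
summary(fit)
#> Wood curve fit (10 points, 50 starts)
#>       a       m       c       d       b
#>  0.1763 36.3925  0.0516 95.0641  1.8796
#> RSS: 134  residual sd: 4.726
#> Parameters of interest (t_f = 180 min):
#>       AUC    Height  Time2Max
#> 1601.1023   23.1237   36.3925
```

`fit_wood()` returns a classed model object with `print`, `summary`,
`coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate`
methods.

The full pipeline — read or simulate, validate, fit, extract, curate,
impute, compare, plot, with every intermediate table and report written
to a run directory — is one call:

```r
run_pipeline(pipeline_config(input = "study.csv", reference = "WP",
                             outdir = "run1", seed = 1))
```

or, from a shell, `exec/postprandial run --input study.csv --reference WP`.

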