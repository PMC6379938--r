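# svloop — left ventricular strain–volume loop analysis

`svloop` analyses left ventricular (LV) **strain–volume loops** from
frame-by-frame 3D speckle-tracking traces: per cardiac cycle, principal
strain (PS, %, negative on shortening) is plotted against cavity volume
(mL), and the loop's single linear fit `strain = k·volume + c` yields two
characteristics — the **slope k** (%/mL, the strain response per unit
volume change) and the **coefficient of determination R², read as
systolic–diastolic (S/D) coupling**. R² near 1 means shortening during
ejection and relengthening during filling track one line; low R² means
the two limbs diverge, the loop opens up, and part of the deformation does
no volume work ("wasted work"). Low baseline coupling of the *mid-septal*
PS–global volume loop marks reversible wasted septal work and predicts
reverse remodelling after cardiac resynchronization therapy (CRT); the
published classification cut-off R² < 0.55 ships as the default constant.

The package is aimed at echocardiography researchers working with exported
strain/volume curves (one CSV/TSV per subject-cycle: `time_ms`,
`strain_seg01..16`, `volume_global`, `volume_seg01..16`, optional JSON
sidecar). It provides:

* the five loop families per subject (global–global, mid-septal/mid-lateral
  vs global volume, mid-septal/mid-lateral vs segmental volume) with
  systolic/diastolic limb partitioning at the end-systolic frame;
* loop fits, peak strain, ejection fraction, strain delay index (SDI),
  TpPS-SD% and Tmsv-SD% dyssynchrony indices, and responder
  classification (ΔLVESV ≥ 15% at follow-up);
* the cohort statistics layer: pooled/Welch t-tests, paired wall
  comparisons, chi-square/Fisher, univariate→multivariate logistic
  screening, ROC with the sensitivity+specificity-maximizing cut-off,
  DeLong paired AUC comparison, Pearson correlation, Bland–Altman
  agreement;
* a seeded 16-segment **waveform simulator** with healthy, responder-like
  (early septum + rebound stretch + late lateral loading),
  non-responder-like and post-CRT phenotypes, used for validation and
  power studies.

## Worked example

Simulate one responder-like cycle, build its loops and fit them:

```r
library(svloop)
rec   <- simulate_cycle(phenotype_preset("responder_like", seed = 42))
loops <- build_loops(rec)
fit_loop(loops$midseptal_global)
#> <loop_fit> midseptal_global
#>   slope k = 0.1265 %/mL, intercept c = -27.28 %
#>   R2-S/D coupling = 0.4456 over 32 points
fit_loop(loops$midlateral_global)
#> <loop_fit> midlateral_global
#>   slope k = 0.354 %/mL, intercept c = -72.58 %
#>   R2-S/D coupling = 0.8180 over 32 points
```

The septal wall is severely uncoupled (R² 0.45: the open loop of wasted
septal work) while the lateral wall still tracks volume (R² 0.82). At
cohort scale, with the clinical group sizes (27 responders, 13
non-responders):

```r
recs <- c(simulate_cohort(27, "responder_like",    seed = 1),
          simulate_cohort(13, "nonresponder_like", seed = 1001))
tab  <- add_response(cohort_metrics(recs))   # pairs baseline/follow-up ESV
compare_groups(tab, "r2_midseptal_global", "group")
#> <group_comparison> r2_midseptal_global --  Two Sample t-test
#>   nonresponder_like: 0.691 +/- 0.125 (n = 13)
#>   responder_like: 0.389 +/- 0.215 (n = 27)
#>   t = 4.689, p = 3.493e-05
roc_analysis(tab$r2_midseptal_global, tab$responder, direction = "low")
#> <roc_result> AUC = 0.875 (27 positive / 13 negative)
#>   optimal cut-off 0.5999 (low scores predict positives): sensitivity 85%, specificity 92%
```

Baseline septal coupling is markedly lower in the subjects that go on to
respond (0.39 vs 0.69), and discriminates response (AUC 0.875) with an
optimal cut-off close to the published 0.55.

See `vignettes/strain-volume-loops.Rmd` for the model, the simulator's
assumptions and every numerical/statistical choice.

## Command line

```sh
Rscript inst/cli/svloop.R simulate --preset responder_like --n 20 --seed 7 --out traces/
Rscript inst/cli/svloop.R analyze  --in traces/ --out reports/
Rscript inst/cli/svloop.R cohort   --in reports/metrics.csv --out reports/
```
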