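---
title: "Strain-volume loop analysis of the dyssynchronous left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-volume loop analysis of the dyssynchronous left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(svloop)
```

## The model

Three-dimensional speckle-tracking echocardiography measures left
ventricular (LV) principal strain (PS, %, negative on shortening) and
cavity volume (mL) simultaneously, frame by frame, over one cardiac cycle,
for the standard 16-segment model. Plotting strain (y) against volume (x)
per frame yields a **strain-volume loop** with a systolic limb (R wave to
end-systole, ES) and a diastolic limb (ES back to end-diastole).

A single regression line $y = kx + c$ is fitted by ordinary least squares
over *all* points of the loop, both limbs pooled. Two characteristics
summarise the loop:

* the **slope** $k$ (%/mL) — the strain response per unit volume change.
  For a perfectly synchronous ventricle with strain $s(t) = -A\,w(t)$ and
  volume $V(t) = EDV - \Delta V\,w(t)$ sharing one activation waveform
  $w$, the loop collapses onto a line of slope exactly $A/\Delta V$;
* the **coefficient of determination**, read as the degree of
  **systolic-diastolic (S/D) coupling**: $R^2 \approx 1$ means shortening
  during ejection and relengthening during filling trace the same line,
  while low $R^2$ means the two limbs diverge — at a given volume the
  segment carries different strain in systole and diastole, the loop
  opens up, and part of the segment's deformation does no volume work
  ("wasted work").

Five loop families are built per subject: global PS against global
volume; mid-septal and mid-lateral PS against global volume; and
mid-septal / mid-lateral PS against the corresponding *segmental* volume.
Mechanical dyssynchrony is summarised by the strain delay index
(SDI, $\sum_{i=1}^{16}(\text{peak PS}_i - \text{PS}_i(ES))$, $\le 0$ by
construction), and by the segmental dispersions of time to peak strain
(TpPS-SD%) and time to minimum segmental volume (Tmsv-SD%), both as
percentages of the R-R interval. A patient is a **CRT responder** when the
end-systolic volume falls by at least 15% at follow-up; the baseline
mid-septal PS-global volume $R^2$ below the published cut-off 0.55
predicts response (the cut-off ships as an applied constant — re-deriving
it needs the original patient data, which are not public).

The phase-shift interpretation of S/D coupling has a useful closed form:
for strain and volume that are sinusoids of the cycle with relative phase
$\varphi$, densely sampled over exactly one period,
$R^2 = \cos^2(2\pi\varphi/RR)$; a quarter-period shift gives $R^2 = 0$.
The test suite pins the implementation to this limit.

```{r sinusoid}
t <- (0:719) / 720
sapply(c(0, 0.125, 0.25), function(phi) {
  fit_loop(data.frame(volume = sin(2 * pi * (t - phi)),
                      strain = sin(2 * pi * t)))$r2_sd_coupling
})
```

## What the simulator emulates

No patient-level traces are published, so the package ships a
phenomenological 16-segment generator used for validation, calibration
studies and the acceptance checks.

Each segment's shortening follows a raised-cosine activation kernel
(`waveform()`): zero until its activation onset, peak shortening at
end-systole, relaxation back to zero at the next R wave. The kernel is
smooth ($C^1$), pluggable, and was chosen for its simplicity — no
electromechanical or pressure modelling is attempted. Segmental volume
uses the same kernel scaled between the segment's share of EDV and ESV;
global volume is the sum of the 16 segmental volumes at every frame (an
exact invariant of the generator).

Dyssynchrony enters through three per-segment parameters:

* **activation delay** (ms) — onset shift of shortening, with a left
  bundle branch block-like wall gradient (septum first, lateral wall
  last) in the heart-failure presets;
* **rebound fraction** (0-1) — the fraction of a segment's shortening
  returned as positive stretch: a raised-cosine pulse that starts at the
  segment's mid-upstroke, peaks *at* end-systole and decays during early
  diastole. Early-activated septum shortens against low load, is then
  stretched by the late-contracting lateral wall, and ends systole with
  little net shortening; the pulse produces exactly this morphology (an
  early strain minimum, a positive-going deflection within systole, and
  reduced end-systolic shortening). A pulse that returned to zero at ES
  was tried first and cannot open the loop far enough: it pins
  end-systolic strain back to the full amplitude, bounding the septal
  $R^2$ well above the severely uncoupled values seen in responders, so
  the ES-peaked form was adopted;
* **amplitude** (%) — peak shortening magnitude per wall.

Measurement noise is i.i.d. Gaussian per frame and channel (no
autocorrelation), with defaults of 0.8 % strain and 0.3 mL per segmental
volume channel.

Four presets encode the cohort's group structure. Their defaults are
calibrated once, a priori, against the published group means: end-diastolic
/ end-systolic volumes of 60/22 mL (controls), 204/159 mL (responder-like),
271/220 mL (non-responder-like) and 152/104 mL (post-CRT); amplitudes such
that noise-free preset metrics land on the reported loop characteristics
(controls' global loop slope ~1.1 %/mL with $R^2 \approx 1$; responders'
mid-septal-global $R^2 \approx 0.46$ against a mid-lateral $R^2 \approx
0.81$); responder-like rebound 0.8 confined to the septal wall versus 0.25
(with a 1.5x delay gradient) in non-responders, so that the time-based
dyssynchrony indices and SDI do *not* separate the two patient groups
while septal coupling does — the defining feature of the clinical finding
being emulated. Between-subject variability uses one seeded substream per
subject (log-normal subject-level factors on amplitude, delay and rebound
severity, plus independent per-segment jitter), so cohorts are exactly
reproducible and extending a cohort never perturbs earlier subjects.

```{r presets}
rec <- simulate_cycle(phenotype_preset("responder_like",
                                       noise_sd_strain = 0,
                                       noise_sd_volume = 0))
loops <- build_loops(rec)
fit_loop(loops$midseptal_global)
fit_loop(loops$midlateral_global)
```

```{r loopfig, fig.alt = "Mid-septal strain-volume loop of a responder-like cycle"}
plot(loops$midseptal_global, fit = fit_loop(loops$midseptal_global))
```

What passing tests on this generator do **not** show: the simulator has no
translation/rotation artefacts, no dropout or tracking failure, no
respiratory gating error, no beat-to-beat variability, and its noise is
white — real speckle-tracking error is spatially and temporally
correlated. Results on synthetic cohorts demonstrate that the *pipeline*
recovers the structure it was built to detect, not that the clinical
effect sizes generalise.

## Numerical and statistical choices

* **Frames and grids.** Default 32 frames per cycle over an 800 ms R-R
  interval (volume-rate territory of 3D acquisitions, ~40 vps); frame 1
  is the R wave (end-diastole) and end-systole defaults to the frame
  nearest 0.4 RR. On file ingestion the ES frame comes from the JSON
  sidecar when present, else from the global volume minimum — the
  standard surrogate when no ECG annotation survives export (exact for
  the simulator). Traces on different grids are linearly interpolated
  onto the strain grid; grids equal within 1e-6 ms are treated as
  identical. The systolic limb includes the ES frame itself.
* **Mid-wall identity.** "Mid-septal" and "mid-lateral" default to the
  single mid septal (9) and mid lateral (12) segments of the 16-segment
  model. The identity is configurable (`select_midwall_segments()`);
  multi-segment selections form composites by mean strain and summed
  volume. The underlying anatomical ambiguity (mid inferoseptal vs mid
  anteroseptal averaging) is deliberately left to the caller.
* **Degenerate loops.** Zero strain variance returns slope 0 and $R^2$
  0 (a non-deforming segment is maximally uncoupled); zero volume
  variance is an error (unphysiological input). Peak strain searches the
  full cycle by default (`window = "systole"` restricts it); ties take
  the earliest frame. All SDs use the sample ($n-1$) denominator.
* **SDI sign.** SDI is reported signed ($\le 0$), matching the negative
  values tabulated clinically; `abs = TRUE` gives the magnitude.
* **t-tests.** Pooled-variance Student's t by default (the convention of
  the era's SPSS-based reporting); Welch via `var_equal = FALSE`. Paired
  comparisons with zero difference variance are flagged degenerate, not
  tested.
* **2x2 tables.** Pearson chi-square without continuity correction when
  all expected counts are at least 5 (Cochran's criterion), Fisher's
  exact test otherwise; `method` forces either.
* **Logistic screening.** One univariate fit per candidate; univariate
  $p < 0.05$ (two-sided throughout) enters a single multivariate model —
  entry only, no stepwise elimination. P-values are likelihood-ratio
  tests: at $n \approx 40$ with a strong predictor the fit sits near
  separation, where Wald statistics collapse (the Hauck-Donner effect)
  while the LRT remains calibrated — the package's null-calibration test
  verifies the ~5% entry rate empirically. Odds ratios are Wald-based,
  reported per 1 unit and per 1 SD (the univariate-OR scale of a
  unit-bounded variable like $R^2$ is otherwise incomparable with
  millisecond-scale indices), and flagged non-estimable under separation.
* **ROC.** Empirical curve over midpoints between consecutive distinct
  scores; AUC by the trapezoidal rule (equal to the normalized
  Mann-Whitney U, which the tests verify exhaustively at small n);
  optimal cut-off maximizes sensitivity + specificity with ties broken
  toward higher sensitivity; `direction = "low"` declares markers whose
  *low* values predict the positive class, as for S/D coupling. Paired
  AUCs are compared with DeLong's covariance estimator.
* **Problem sizes.** The validation cohort mirrors the clinical group
  sizes (27 responders, 13 non-responders, 20 controls); the
  null-calibration study uses 1000 replicates at n = 40, and oracle
  equivalences use 100 random loops — sizes chosen so the full suite
  exercises every path at meaningful power while remaining quick to run.

## Limitations

* The generator is phenomenological: kernels, delays and rebound pulses
  are descriptive shapes, not electromechanics; pressure, afterload and
  the Frank-Starling response are not modelled.
* Only the 16-segment model is supported (no 17/18-segment variants), and
  only mid-level septal/lateral loop families are built, matching the
  analysis it implements.
* The 0.55 classification cut-off is applied, not re-derived; on
  synthetic cohorts the ROC-optimal cut-off lands near but not exactly on
  it, as expected for any finite sample.
* Vendor file formats (TomTec/Philips) are not parsed; the trace-file
  dialect (`time_ms`, `strain_seg01..16`, `volume_global`,
  `volume_seg01..16` + JSON sidecar) is this package's own documented
  convention.
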