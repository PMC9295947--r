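---
title: "Normative modeling of placental T2* across gestation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of placental T2* across gestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placenorm)
```

## The problem

Placental T2*, the effective transverse relaxation time measured by
multi-echo gradient-echo (MEGE) MRI, is sensitive to the balance of oxy-
and deoxyhemoglobin in maternal placental blood (the BOLD effect). In
healthy pregnancy it falls continuously with gestational age: a high
plateau early in gestation, an accelerating decline through an inflection
near 30 weeks, and a lower plateau near term. Pregnancies heading toward
adverse outcomes — hypertensive disease, severe growth restriction,
stillbirth — show systematically depressed T2* well before clinical
disease. That makes a *normative model* of T2* against gestational age a
candidate screening instrument: score each scan against the
uncomplicated-pregnancy reference, and ask how well a low percentile
predicts adversity.

`placenorm` implements that pipeline end to end: voxelwise relaxometry,
candidate-model regression with BIC selection, z-score/percentile
scoring, and ROC evaluation, together with seeded synthetic cohorts and
imaging phantoms that reproduce the statistical structure the analysis
assumes, so every stage is testable without clinical data.

## Relaxometry

A MEGE acquisition samples the signal at six echo times (defaults 4.92,
9.84, 19.68, 29.52, 36.90, 49.20 ms; voxels 1.75 x 1.75 x 3.5 mm). Each
voxel follows the mono-exponential decay

$$S(TE) = S_0 \, e^{-TE/T_2^*}.$$

`fit_t2star_voxel()` inverts this by Levenberg–Marquardt nonlinear least
squares, initialized from the log-linear regression of $\log S$ on $TE$.
Pure log-linear inversion is bias-prone at low SNR because the log
transform distorts the noise; the nonlinear refit is the standard remedy
in quantitative mapping. Voxels with fewer than three positive echoes, a
non-negative log-linear slope (no decay to invert), or a divergent or
non-positive fit are flagged invalid rather than clamped — such voxels
are noise-dominated and carry no relaxometry information. The relative
measurement uncertainty of a voxel is the delta-method SD of its $T_2^*$
estimate, $\sqrt{[\mathrm{RSS}/(n-2)\,(J^\top J)^{-1}]_{22}}\,/\,T_2^*$.

`map_t2star()` aggregates a placental ROI with the **median** (the
intra-placental T2* distribution is markedly non-Gaussian) after
excluding voxels whose *fitted* value is 250 ms or more — a strict
$\ge$ threshold; such long values indicate amniotic-fluid contamination.
The exclusion is applied before both the median and the uncertainty
summary. An open question in the aggregation is whether to pool voxels
across slices or aggregate per slice first; the package pools all valid
voxels over the entire placenta, matching how whole-organ medians are
reported. `placental_volume()` sums per-slice voxel counts times voxel
volume; slices lost to motion are filled by linear interpolation of the
nearest present slices (edge gaps copy their single nearest neighbor).

## Trajectory models and selection

Six closed forms are available (`model_spec()`): constant, linear,
quadratic, cubic, the logistic sigmoid

$$y(t) = \frac{p_1}{1 + e^{p_2 (t - p_3)}} + p_4,$$

and its analytic time derivative (3 parameters) for rate-of-change data.
With $p_2 < 0$ the sigmoid decreases from the early plateau $p_4$ to the
late plateau $p_1 + p_4$ with inflection at $p_3$. Evaluation goes
through `plogis`, so arbitrarily large $|p_2(t - p_3)|$ cannot overflow.

`fit_model()` fits polynomials exactly by ordinary least squares and the
sigmoid families by Levenberg–Marquardt with analytic Jacobians.
Logistic fits are local-minimum-prone, so the sigmoid start is
data-driven ($p_4$ = mean of early observations, $p_1$ = late mean minus
$p_4$, $p_2 = -0.2$, $p_3 = 30$) plus a deterministic grid of 20
alternative $(p_2, p_3)$ starts; the best residual sum of squares wins.
A deterministic grid rather than random jitter keeps fitting off the
user's RNG stream. In testing, the multistart reproduces a 50-start
Nelder–Mead refit to better than $10^{-3}$ relative.

Conventions, chosen once and used everywhere:

* parameter covariance $s^2 (J^\top J)^{-1}$ with $s^2 =
  \mathrm{RSS}/(n-k)$; a numerically singular $J^\top J$ (e.g. a sigmoid
  degenerating to a line) falls back to the pseudoinverse so the fit is
  reported with very large uncertainties instead of failing;
* reported RMS residual $\sqrt{\mathrm{RSS}/n}$ (the residual variance
  inside the covariance still uses $n-k$; both conventions are stated
  because reference tables rarely say which they print);
* $\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$ — the Gaussian
  log-likelihood form with the additive constant dropped, since it is
  shared by all candidates on the same data. `select_model_bic()` picks
  the minimum, breaking ties toward fewer parameters and excluding
  non-converged candidates with a warning.

`confidence_band()` produces pointwise bands by the delta method: curve
variance $g(t)^\top C\, g(t)$ with $g$ the parameter gradient, plus
$s^2$ for the prediction interval. Normal quantiles are used (the bands
derive from modeled covariance, not small-sample t intervals). Group
differences are declared where the two 95% confidence bands fail to
overlap (`band_separation()`), reported as contiguous week intervals on
a 10–40 week grid with 0.1-week steps.

Within-subject rates of change are the centered finite differences of
consecutive scans (`rate_pairs()`); `fit_rate_model()` fits the
3-parameter derivative form to the pooled pairs. Because typical
scan spacing is 5–15 weeks, the finite differences smooth the derivative
bump; the fitted inflection is therefore less precise than the one from
the T2* curve itself, and in degenerate subgroups (nearly constant
rates) the fit is legitimately reported with enormous uncertainties.

## Scoring and discrimination

`zscore()` standardizes a scan against the uncomplicated (UN) reference
fit: $z = (y - \hat\mu(t)) / \sigma_{pred}(t)$ where $\sigma_{pred}$ is
the **prediction**-interval SD (residual variance plus delta-method
curve variance). The narrower curve-CI SD would inflate reference
z-scores far past unit variance; only $\sigma_{pred}$ makes the
reference population come out with SD $\approx 1$, which is what a
z-score chart requires. Percentile is $100\,\Phi(z)$. Gestational ages
outside 10–40 weeks are refused rather than extrapolated. Group
comparisons use the two-tailed two-sample Kolmogorov–Smirnov test,
Cohen's d with pooled SD, and the 2x2 chi-square without continuity
correction with a Wald log-scale CI on the relative risk; no
multiple-testing correction is applied because raw p-values are the
convention for these descriptive contrasts. Percentile histograms use
twenty 5%-wide bins, left-closed except the final closed bin
$[95, 100]$. Analysis windows are $[10,20)$, $[20,30)$, $[30,40]$ weeks
— every scan falls in exactly one.

`roc_curve()` evaluates the percentile as a classifier with the
low-score-positive orientation (a scan is called adverse when its
percentile is at or below the cutoff). Thresholds sit at midpoints
between distinct scores with infinite sentinels; the trapezoidal AUC
then equals the Mann–Whitney pairwise concordance with ties counted
half, a property the test suite enforces by exhaustive enumeration.
Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$ locates the optimal
cutoff `c_opt`, reported in percentile units. The primary contrast is
primary-adverse (PA) versus UN; secondary-abnormal (SA) scans are
excluded from the primary ROC. Scan-level ROC is the default — each
completed study is one point — with subject-level aggregation (worst
percentile per subject) available via `windowed_roc(level = "subject")`.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the study conditions the analysis assumes:

* 316 subjects; outcome groups UN/PA/SA with probabilities
  0.626/0.222/0.152; two sites at 0.566/0.434. (The source tables print
  the PA share both as 22.2% and 21.8%; the generator uses 22.2%.)
* 1–3 completed scans per subject with probabilities 0.14/0.20/0.66,
  assigned to distinct gestational windows 10–20/20–30/30–40 weeks with
  equal weights, and gestational age uniform within the window — study
  enrollment was spread across these windows roughly uniformly after the
  protocol expanded to continuous coverage.
* per-scan median T2* from the group-specific sigmoid plus Gaussian
  residuals (UN: parameters $(-59.2, -0.24, 29.3, 84.6)$, SD 9.6 ms; PA
  and SA analogous), and linear gestational trends with Gaussian
  residuals for hemoglobin, SpO2, placental volume and T1
  (`default_group_models()`). Hemoglobin units are carried opaquely
  because the source mixes mg/dl and mmol labels for the same numbers.

Numerical care points: residuals are Gaussian *truncated to positive
T2*** — the deep-decay tail near term would otherwise produce a
physically impossible non-positive T2* roughly once per thousand late
scans; those draws are redrawn, which leaves Kolmogorov–Smirnov
normality checks passing at $n \approx 10^4$. Each subject draws from
its own L'Ecuyer-CMRG random substream derived from the single config
seed, so runs are exactly reproducible, enlarging the cohort appends
subjects without reshuffling existing ones, and cross-subject draws
carry no seeding artifacts (naive `set.seed(seed + i)` schemes
measurably bias the first draws and were rejected).

Deliberate simplifications, hence what passing tests do *not* show about
real data: no subject-level random effects (all scans are pooled, as the
reference analysis pools them — within-subject correlation beyond the
shared group curve is absent); no fetal or maternal motion, B0
inhomogeneity, or coil effects; sites differ only by label, not by
altitude physiology; outcome groups are drawn independently of the
ancillary variables. Recovery of printed parameters from these cohorts
validates the estimation machinery, not the biology.

`simulate_multiecho_phantom()` plays the same role for the imaging
stage: an ellipsoidal placenta on a voxel grid, a T2* field with smooth
sinusoidal modulation at lobule scale (15 mm default, 20% amplitude),
mono-exponential decay over the six echoes, and additive Gaussian noise.
Additive Gaussian (not Rician) noise is a deliberate choice: at the
SNR regimes simulated the distinction is negligible, and magnitude-bias
modeling is out of scope. Voxels can be assigned T2* $\ge$ 250 ms to
mimic amniotic fluid and must be caught by the exclusion rule.

## Problem sizes and reproducibility

The validation suite chooses sizes that make the statistics decisive:
500-scan cohorts for sigmoid recovery (200 replicates when calibration
of the replicate scatter is the question), 300-subject / 2–3-scan
cohorts for the rate model, $10^4$-scan cohorts for distributional
checks, $10^5$ subjects for group-proportion convergence, and phantoms
of a few thousand masked voxels for mapping accuracy. A full
`run_pipeline()` at the 316-subject study scale takes well under a
second apart from phantom mapping. `scripts/acceptance.R` re-runs the
headline recovery experiments from scratch at a caller-supplied seed and
writes the recovered quantities as JSON.

## Known limitations

* The normative reference is refitted from whatever cohort it is given;
  the package ships no frozen clinical reference curve.
* Band non-overlap is a conservative pointwise criterion, not a formal
  test of curve difference, and no AUC confidence intervals or
  cross-validation are provided (the ROC is in-sample by design).
* The rate-model fit inherits the finite-difference smoothing bias
  described above; its inflection estimate is reliable to roughly a week
  at study scale, not better.
* T1 mapping itself (variable flip angle reconstruction, B1 correction)
  is out of scope; per-scan median T1 enters only as a scalar.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- run_config(cohort = cohort_config(n_subjects = 316),
                  output_dir = "run1", seed = 1)
report <- run_pipeline(cfg)
report$group_fits$UN$form     # which family BIC selected for UN
report$roc$overall$auc        # scan-level PA-vs-UN discrimination
render_diagnostics("run1")    # fit bands, percentile histogram, ROC
```
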