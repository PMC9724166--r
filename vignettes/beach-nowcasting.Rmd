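---
title: "Methods: censoring-aware nowcasting of fecal-indicator concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censoring-aware nowcasting of fecal-indicator concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibcast)
```

## The problem

Recreational beach advisories hinge on fecal-indicator concentrations —
cultured *E. coli* and enterococci, F+ and somatic coliphage, and
qPCR-based genetic markers — that are expensive to measure and arrive a day
late. Nowcasting replaces the wait with a statistical forecast from
covariates available at sampling time: water temperature, turbidity,
dissolved oxygen, conductivity, pH, dissolved organic carbon, UV254
absorbance, wind, waves, rainfall accumulations, sunlight, humidity and
counts of humans, birds and dogs. `fibcast` implements the full statistical
machinery for building and judging such site-specific models, including the
qPCR quantification chain that produces the genetic-marker responses in the
first place.

## The regression core

For one site and one indicator, the response is the log10 concentration
(`log10(C)` for cultured and qPCR indicators, `log10(C + 1)` for coliphage,
whose counts can fall below 1). Non-detects are replaced by half the
detection limit (or half the lower limit of quantification for qPCR) on the
linear scale before transforming; the substitution of the full limit is
available as a switch, but the half-limit convention is the default because
it is the standard convention for left-censored environmental data and
matches how the summary statistics are defined. Covariates are standardized
to mean zero and unit variance per site-season dataset — models are
site-specific, so pooling standardization across sites would leak one
site's scale into another's model.

The fit is least-angle regression with the lasso modification, written from
scratch in `lars_fit()`. From the null model, the covariate most correlated
with the residual enters the active set; coefficients move along the
equiangular direction until an inactive covariate's correlation catches up
(entry) or an active coefficient crosses zero (exit, the lasso
modification). The path is piecewise linear, and when `n > p` with a
full-rank design its final step is exactly the OLS solution — both
properties are tested, the latter to 1e-8 and the path itself against an
independent coordinate-descent lasso solver at matched penalties.

Model selection tracks Mallows' Cp along the path,

$$C_p(k) = \mathrm{RSS}_k / \hat\sigma^2 - n + 2\,df_k,$$

with `df_k` the active-set size plus one for the intercept, and selects the
first step attaining the minimum (ties break toward the sparser model). The
error variance `sigma2_hat` is the classical full-OLS estimate
`RSS_full / (n - p - 1)`, under which the full model has `Cp = p + 1`
exactly — a convenient algebraic check that the suite asserts. The
intercept is handled by centering the response only; the response is not
rescaled, so coefficients are in log10 concentration units per standard
deviation of covariate.

Two numerical choices deserve note. Entry ties (two covariates reaching the
tying correlation within tolerance) are broken by column order and logged
in the path's `notes`. An entrant whose addition would make the active Gram
matrix numerically singular (reciprocal condition below 1e-12) is skipped
with a warning and the path continues without it; in exact arithmetic a
covariate inside the active span always ties exactly at the end of the
current direction, so this guard fires only for near-collinear designs.
The step count is capped at `min(n - 1, 8p)` so degenerate inputs cannot
cycle.

## What minimum-Cp selection does and does not do

Minimum-Cp selection on a lasso path reliably *retains* strong true
covariates but routinely carries one or more weak noise covariates along:
the `2*sigma2` penalty is cleared by the best of several noise columns
about half the time, and path shrinkage pushes the Cp minimum past the
step where the true support is complete. On strong-signal synthetic data
(three true covariates of ten, coefficients of one, noise sd 0.2, n = 200)
the selected set contains the true support in every replicate, but equals
it exactly only in a small minority — a property shared by an independent
LARS implementation and documented here because sparsistency should not be
read into the selected models. The influence scores below are aggregates
across models precisely because single selected sets are noisy.

## Predictive evaluation

`kfold_predict()` splits the events into ten nearly equal random folds; for
each fold the other nine are used to fit a complete sub-model — including
re-standardization of the training covariates, so no information leaks from
the withheld fold — and the withheld fold is predicted once. Whether the
original study re-standardized within folds is not stated anywhere we could
check; we do, because it is the defensible choice. Two scores summarize the
predictions:

* **SRMSEP** — root mean squared error of prediction divided by the mean
  log10 concentration of the modeled indicator, computed over the full
  substituted response (the definition references the modeled metric, not
  the withheld folds).
* **R²pred** — the coefficient of determination of the regression of
  observed on predicted values, i.e. their squared Pearson correlation.

Across a set of models the two metrics are standardized by dividing by the
maximum over the set, and the composite **Overall Performance** is
`standardized R²pred + (1 - standardized SRMSEP)`, in [0, 2]. The
standardization is defined over whatever model set is supplied to
`build_board()`, so the set must be explicit for the scores to be
reproducible.

## Censored correlations

Associations between indicator pairs are Pearson correlations of the log10
values, with left-censored entries replaced independently in each of 100
repetitions by a Uniform(0, limit) draw on the linear concentration scale,
then transformed with the indicator's own transform (including the `+1`
offset for coliphage — the imputed value passes through the same transform
as the response). The reported correlation is the mean over repetitions;
significance uses `t = r\sqrt{n-2}/\sqrt{1-r^2}` on the averaged r with
`n - 2` degrees of freedom, applied once to the mean rather than averaged
over per-repetition p-values. A uniform draw on the log scale is exposed as
an option (`impute_scale = "log"`). Because the log of a uniform draw has a
heavy left tail, the repetition spread of r grows with censoring intensity;
at 20% censoring of both series and n = 65 it sits around 0.03–0.06.

## Covariate influence

One minimum-Cp model per site-indicator pair is fitted on all available
events, and each covariate is scored across models by (1) the sum of
absolute coefficients, (2) the proportion of models with a non-zero
coefficient, and (3) the Total Score, their sum. Related covariates can be
aggregated — 24 h and 72 h rainfall into "Rainfall", the two wind
components into "Wind Speed/Direction" — with summed magnitudes and *union*
occurrence counting: a group occurs in a model if any member does, so a
proportion can never exceed one. A covariate measured only at some sites is
scored over the models where it was available (its own denominator), and
heatmap matrices mark unavailable cells `NA`, never zero — a zero means the
lasso shrank the coefficient out of a model that could have used it.

## qPCR quantification and acceptance gates

Genetic-marker responses come from a quantification chain implemented in
full. A composite standard curve is a weighted linear regression of Ct on
log10 copies per reaction over a dilution series composited across
instrument runs; the default weight of a level is its replicate count
(identical to per-replicate OLS), with inverse-variance weighting optional,
because the weighting scheme is a workbook convention rather than a
published constant. The amplification efficiency is `10^(-1/slope) - 1` and
the per-cycle amplification factor `amp_base` is `efficiency + 1`.

Delta-delta-Ct quantification anchors a sample to calibrator samples:
`ddCt = (sample target Ct - calibrator mean target Ct) - (sample Sketa22 Ct
- calibrator mean Sketa22 Ct)`, and copies are the median calibrator copies
times `amp_base^(-ddCt)`. We use the curve's own `amp_base` rather than an
assumed 2 — consistent with assay efficiencies near 0.9 — which also makes
the ddCt and direct-curve methods agree exactly on noiseless data (a tested
identity). The median calibrator copies are the median over calibrator
wells of curve-derived estimates, the most direct reading of a
calibrator-anchored unit. Direct curve quantification
(`10^((Ct - intercept)/slope)`, Sketa22 delta-Ct recovery adjustment,
volume scaling) serves the *E. coli*-style workflow. The sample-level lower
limit of quantification follows from the lowest standard and the extract
fraction: 6 copies per reaction at 1/120 of the extract per reaction gives
720 copies per sample. The conversion from calibrator sequence equivalents
to cell equivalents is a configurable multiplicative factor (default 1),
since the workbook constant is not public.

Run acceptance applies six automatic gates: ANCOVA parallelism of per-run
standard curves (both nested-F p-values above 0.05 — with numerically
identical lines the F statistic is 0/0 and the p-value is 1 by convention);
calibrator target and Sketa22 means within ±3 reference standard deviations;
test-sample Sketa22 within 3 Ct of the calibrator mean; test-sample IAC
within 1.5 Ct of the negative-control mean; negative-control copy estimates
below the sample-level LLQ prior to any Sketa22 adjustment; and duplicate
test-well Ct standard deviation within 1.414. Undetected reactions are a
distinct `NA`/`"ND"` state, never the number 40 — 40 is substituted only
inside the averaging steps of the gates, as the acceptance rules specify. A
gate whose controls are absent reports "not evaluable" rather than passing
silently.

## The synthetic-data generator

Because the study's raw beach data are not deposited, every stage is
exercised on synthetic seasons whose structure matches the analysis
assumptions: a Gaussian copula imposes target Pearson correlations on
covariates with gaussian, lognormal, negative-binomial-count or circular
marginals; the default suite carries the three collinear pairs observed in
Great Lakes covariate data (UV254–DOC r = 0.81, 24–48 h rainfall r = 0.84,
48–72 h rainfall r = 0.89, plus an implied 24–72 h r = 0.75 required for
the three-way block to be jointly attainable). The response is a sparse
linear signal in the standardized covariates plus Gaussian noise in log10
units, back-transformed and left-censored at the configured limit *after*
the noise, since detection limits act on measurements. Wind direction is
simulated independently of speed unless a correlation is configured; wind
speed/direction pairs are decomposed into alongshore and onshore components
using the meteorological "direction from" convention with the shore-normal
pointing from water to land. Events are exchangeable — no within-season
autocorrelation is modeled, since none is quantified in the source
material — and there is no spatial structure within a beach. Passing tests
on these data therefore demonstrate correctness of the statistical
machinery, not calibration to any real beach: real seasons have serial
dependence, covariate measurement error and non-Gaussian noise the
generator does not emulate.

Lognormal marginals attenuate a latent copula correlation slightly (a
latent 0.81 yields about 0.80 in Pearson terms at these dispersions), which
is why the collinearity screen in the default pipeline flags the configured
pairs but empirical correlations sit just under their targets.

All randomness flows from named integer seeds through a deterministic
splitting scheme (`child_seed`), so identical configurations give
bit-identical artifacts; the pipeline manifest records an MD5 hash per
output file to make this checkable.

## Problem sizes and defaults

Default simulated seasons use 70 events per site (the per-site scale of a
five-day-per-week beach season), ten cross-validation folds, 100 imputation
repetitions, a collinearity threshold of 0.8 with UV254 and 48 h rainfall
preferentially excluded, and six-level dilution series in triplicate across
two instrument runs for qPCR. Property suites use 100-replicate Monte
Carlo batches at n = 200 for selection behavior and n = 5000 for
copula-moment convergence. The coliphage linear-scale detection limit is a
configuration parameter (default 1.6 PFU/L in the demo suite) rather than a
constant, because the published log-scale value is not derivable from a
stated linear limit under the `log10(C + 1)` transform.

## Known limitations

* Minimum-Cp selected models overselect; use the influence aggregates, not
  single active sets, for interpretation.
* The SRMSEP standardization divides by the mean log10 concentration and is
  undefined (and refused) when that mean is zero; indicators whose mean
  log10 concentration is near zero (low-abundance coliphage) produce large,
  unstable SRMSEP values.
* The censored-correlation p-value treats the averaged r as a single
  estimate; it does not propagate imputation uncertainty.
* Missing covariates are handled by row-wise deletion (reported in the
  model frame), not imputation.
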