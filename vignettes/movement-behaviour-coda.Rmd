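---
title: "Compositional analysis of 24-hour movement behaviours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movecoda)
```

## The problem and the geometry

Device-measured daily time use partitions 1440 minutes into sleep,
sedentary time (ST), light physical activity (LPA) and moderate-to-vigorous
physical activity (MVPA). The constant-sum constraint means the four
durations are not four free numbers: all information is in their ratios,
the parts are negatively correlated by construction, and Euclidean
statistics applied to raw minutes (means, covariances, regression slopes)
can be misleading. `movecoda` works in Aitchison geometry instead.

A composition is any strictly positive 4-vector considered equivalent up to
scale; `close_comp()` fixes the representative that sums to the closure
constant κ (1440 min by default, but any κ > 0 and any number of parts
D ≥ 2 are supported). An isometric log-ratio (ilr) map sends the simplex
isometrically to ℝ^(D−1):

$$ z = V^\top \ln x, \qquad x = \mathcal{C}\!\left(\exp(Vz)\right)\cdot\kappa, $$

where the contrast matrix $V$ (D × (D−1), orthonormal columns, each summing
to zero) is built from a sequential binary partition (SBP) by the standard
balance formula: a step separating $r$ numerator parts from $s$ denominator
parts contributes $+\sqrt{s/(r(r+s))}$ and $-\sqrt{r/(s(r+s))}$
respectively.

**Default SBP.** Many SBPs exist and all induce the same geometry; every
quantity this package reports (compositional means, fitted values, ANOVA
tables, substitution differences) is invariant to the choice, which the
test suite verifies against a structurally different partition at 1e-8.
We still must fix a default for coefficient reporting: pivot balances in
the order (sleep, ST, LPA, MVPA), where coordinate k contrasts part k with
the geometric mean of the later parts. The first coordinate is then the
familiar "sleep versus waking behaviours" balance, and the last isolates
LPA versus MVPA.

**Centre and dispersion.** The compositional mean is the arithmetic mean of
ilr coordinates mapped back to the simplex, which equals the closure of
per-part geometric means; `comp_mean()` computes it by the geometric-mean
route and the tests confirm the equivalence on random data. Dispersion is
summarised by the variation matrix $T_{ij} = \mathrm{var}\,\ln(x_i/x_j)$
(sample variance, denominator n−1 — the conventional unbiased choice; the
matrix is closure- and perturbation-invariant). The variation matrix, the
centred log-ratio covariance $S$ and the ilr covariance $\Sigma_z$ are
equivalent parameterisations connected by
$S = -\tfrac12 G T G$ (with $G = I - J/D$ the double-centring projector)
and $\Sigma_z = V^\top S V$; `variation_to_ilr_cov()` and
`ilr_cov_to_variation()` implement the round trip (tested to 1e-9). This
bridge is what lets a published variation matrix drive the simulator.

## The outcome models

`fit_outcome_model()` regresses an outcome on the D−1 ilr coordinates plus
covariates by OLS. Covariate conventions, fixed for reproducibility:

* **sex** — two-level factor, reference level first alphabetically
  (`boy`);
* **age** — years, entered linearly and uncentred;
* **IMD decile** — unordered factor on the observed deciles, reference =
  lowest (most deprived) observed decile. A single linear slope would force
  1 df; deprivation effects need not be monotone, and the factor coding
  matches the multi-df tests reported in this literature;
* **zBMI as an extra covariate** for the fitness outcome, to separate
  composition-related fatness from other paths to fitness;
* missing data: complete cases per model, with the dropped count reported.

**Type II tests.** `anova_marginality()` tests each term after all others:
the Type II sum of squares is the residual-SS increase when the term alone
is removed, with the ilr coordinates treated as a single (D−1)-df block —
testing individual ilr coordinates would make inference basis-dependent,
the block test is not. The F statistic is primary; the Wald chi-squared for
the same coefficient block (equal to df·F under OLS) is reported alongside
because both appear in applied work and readers should be able to compare
either. The implementation is by explicit model refitting and is
cross-checked in the tests against `car::Anova()` with the ilr block bound
as a matrix term.

**Diagnostics.** `model_diagnostics()` reports Shapiro–Wilk on residuals
(normality), studentised Breusch–Pagan (homoscedasticity), Ramsey RESET
with squared and cubed fitted values (linearity), and flags observations
with |externally studentised residual| > 3, leverage > 2p/n or Cook's
distance > 4/n. Thresholds are arguments, the report is always produced,
and nothing is dropped automatically — flagging is information, not policy.

## Compositional isotemporal substitution

`reallocate()` moves t minutes from one behaviour to another, leaving the
remaining parts bit-identical, so the day still sums to κ exactly. The
donor must retain strictly positive time; a move that exhausts it is an
explicit infeasibility (an error for a single reallocation, a flagged
missing cell inside `difference_grid()`, so full grids can always be
written). The predicted difference is

$$ \Delta\hat y(t) = \beta^\top\left(z(x_t) - z(x_0)\right), $$

evaluated at a fixed covariate profile that cancels in the subtraction
(verified by a profile-independence test). The default profile for
*absolute* predictions sets numeric covariates to their sample means and
averages factors over observed proportions, so the prediction at the
training compositional mean equals the mean fitted value.

Three structural properties follow from linearity in log-ratios rather
than minutes, and each is asserted in the tests: Δŷ(0) = 0 exactly;
direction asymmetry (|Δŷ(a→b)| ≠ |Δŷ(b→a)|, large when the move involves
the smallest part, MVPA); and baseline dependence
(`group_baseline_grids()` evaluates the *same* fitted model at each
weight-status group's own mean composition — only the baseline changes).

Delta-method standard errors and t-intervals for Δŷ are computed from the
ilr-block coefficient covariance. These are an extension beyond the
substitution tables this methodology usually prints, included because the
covariance is already available and uncertainty should not be discarded;
they are labelled as such in the output.

Display conventions follow the field: square substitution tables are
oriented rows-receive / columns-donate, the default grid runs 0–25 min in
5-min steps with a 2.5-min fine option, and CSV output keeps full
precision (rounding is left to presentation).

## The synthetic cohort generator

`synthetic_config()` / `generate_records()` emulate the study conditions
under which the method is meant to operate, so the whole pipeline is
testable without access to individual-level cohort data. The generator is
first-class, tested code.

* **Compositions** are logistic-normal: ilr coordinates drawn multivariate
  normal around each group's mean composition with a shared covariance.
  This is the natural distribution under the geometry and matches the
  modelling assumption surface — the analysis itself assumes linearity in
  ilr space, nothing more.
* **Defaults are the reference cohort's published summaries**
  (`cohort_reference`): group sizes 15/115/39 (underweight, normal-weight,
  overweight/obese; 169 in all), group compositional means in minutes, and
  the ilr covariance implied by the published full-sample variation matrix
  through the conversion bridge. Covariates: sex ≈ 50/50, age ~
  N(10.3, 0.3²) years, IMD deciles concentrated on 1–3 (85% of the cohort;
  probabilities chosen to give mean ≈ 2.5), height ~ N(141.2, 6.2²) cm.
* **Outcome coefficients are calibrated, not invented.** For each outcome
  the three published 15-min MVPA-donor substitution differences at the
  full-sample mean composition form a linear system
  $\beta^\top \Delta z_k = d_k$, k = 1..3, which
  `calibrate_ilr_effects()` solves exactly for β. Because the model is
  linear in ilr coordinates, those three entries determine the entire
  published substitution table — all twelve cells per outcome and all four
  baselines — and the acceptance tests confirm the package reproduces every
  published entry from this calibration (zBMI within 0.02; %WHtR and VO2
  peak within 0.15, the printed precision of 0.1 plus the rounding the
  published 1-dp inputs propagate through the solve). Intercepts anchor the
  mean-composition prediction to the published outcome means (zBMI 0.43,
  %WHtR 46, VO2 peak 47.0). Covariate effects (e.g. small sex effects, an
  age slope) and residual SDs (0.9 zBMI units, 4.5 %WHtR points,
  2.8 ml·kg·min⁻¹) are implementer defaults chosen to give realistic total
  outcome variance; they are fixture parameters for testing, not estimates
  of any cohort's true effects. VO2 peak additionally loads on the
  generated zBMI (−1.5 per unit), so adjusting fitness for fatness is
  meaningful on synthetic data.
* **What it does not emulate:** measurement error in accelerometer
  processing, non-wear artefacts, zero MVPA days, within-person day-to-day
  variation (one composition per child), non-normal outcome tails, or the
  circular definition of weight status from zBMI (groups differ only
  through their composition means, and the weight-status label is the
  generating group). Passing tests therefore demonstrate the statistical
  machinery is correct under its own assumptions, not that those
  assumptions hold in any particular real dataset.

A degenerate-but-instructive corner: with all residual SDs set to zero,
zBMI becomes an exact linear function of the ilr coordinates and
covariates, so adding it as a covariate to the fitness model is perfectly
collinear (and the package refuses the rank-deficient fit). Tests of the
adjusted model keep zBMI's own noise.

## Numerical choices and degenerate inputs

* Tolerances: 1e-9 relative for algebraic identities (closure, ilr round
  trip, variation/covariance round trip), 1e-8 for identities that pass
  through a regression fit (basis invariance of ANOVA, predictions,
  grids). These reflect accumulation through `lm`'s QR path.
* Zeros: log-ratios are undefined at zero, so zero durations are rejected
  by default. `replace_zeros()` (or `zero_policy = "replace"` in the
  reader) offers explicit multiplicative replacement — zeros set to δ
  (default 0.5 min), non-zero parts shrunk to preserve the row total —
  and reports every affected row. Replacement is never silent or
  automatic.
* Validation errors name the offending part and row; rank deficiency names
  the collinear columns; infeasible reallocations name the donor part and
  its available minutes.
* Orthonormality of a user-supplied SBP is verified numerically (1e-10) at
  basis construction, which catches non-hierarchical sign matrices.
* Determinism: every generator call is seeded from its config; the
  pipeline writes no timestamps into data outputs, so identical
  configurations produce byte-identical CSV/JSON bundles (timestamps go to
  the log only).

## Problem sizes in the test suite

The suite favours many small, sharply targeted cases: algebraic properties
run on dozens of random compositions; law-of-large-numbers checks on the
generator use n = 10⁴ (1% tolerance on means, 10% on variation entries);
coverage of the ilr coefficient CIs uses 500 replicate cohorts at the
study's n = 169 (±3 Monte-Carlo SEs around 95%); the Type II null-size
check uses 300 replicates at α = 0.05. The acceptance script repeats the
calibration summaries at 200 replicates. These sizes make the Monte-Carlo
bands tight enough to detect real miscalibration while keeping the whole
suite fast.

## Known limitations

* Cross-sectional predictions only: a substitution difference is a
  comparison between children with different compositions, not a
  within-child effect of changing behaviour.
* Pairwise one-to-one reallocation only; no proportional or one-to-many
  schemes.
* No interactions, mixed effects, survey weights or variable selection in
  the outcome models.
* The delta-method interval for Δŷ treats the baseline composition as
  fixed; when the baseline is itself estimated (a group mean), its
  sampling variability is ignored.
* Spreadsheet input requires the optional `readxl` package; delimited text
  is the first-class path.
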