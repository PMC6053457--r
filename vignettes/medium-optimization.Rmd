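---
title: "Methods: statistical medium optimization with rsmga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical medium optimization with rsmga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmga)
```

This vignette is the package's account of its statistical methods: the
models and their assumptions, the conventions and defaults chosen where the
field leaves room, the numerical choices, and what the bundled fixtures and
synthetic generators can and cannot demonstrate.

## The three-stage pipeline

A fermentation medium has many candidate components; running a full
factorial experiment over all of them is infeasible. The classical
statistical route — implemented end to end here, and illustrated with a
bundled cholesterol oxidase (COD) production study on *Streptomyces
rimosus* — is:

1. a saturated two-level **Plackett–Burman screening design** to find the
   few components with large main effects,
2. a **central composite design** (CCD) and second-order **response
   surface** fit over the survivors, and
3. bound-constrained **maximization** of the fitted polynomial, here with
   a real-coded genetic algorithm (GA).

All concentrations are in g/100 ml; the response is enzyme activity in
U/ml.

## Plackett–Burman screening

The 12-run design is built by cyclic rotation of the standard generator row
`+ + − + + + − − − + −` plus a final all-minus row. All 11 columns are
balanced and pairwise orthogonal; columns not bound to a factor serve as
*dummy* columns whose apparent effects estimate the experimental error.

**Effect convention.** The concentration effect is the difference of level
means, `E = (Σ y_high − Σ y_low)/(N/2)`. Some write-ups print the formula
with `N` in the denominator while tabulating values consistent with `N/2`;
this package implements the level-mean difference (the DOE convention), and
the screening fixture reproduces the study's printed effects under it. On
any balanced orthogonal two-level design this equals exactly twice the
least-squares slope of the response on the coded column — a property the
test suite checks against `lm()`.

**Error variance.** `V_eff = Σ E_d²/n` over dummy-column effects, and
`S.E. = √V_eff`. Which columns served as dummies is often unrecoverable
from a published table, so `dummy_variance()` and `pbd_screen()` accept a
printed `v_eff` verbatim as an override; the bundled screening fixture
carries `v_eff = 0.001494`.

**Degrees of freedom and tails.** The bundled study's printed p values are
reproduced by a one-tailed t test (upper tail of |t|) with `df = N − 2 =
10`; that is the default (`tails = 1`, `df = n_runs − 2`), with both
configurable. The conventional alternative `df = n_dummies` is available by
passing `df = length(design$dummies)`. The significance rule defaults to
90 % confidence (`p ≤ 0.10`), the usual screening threshold; at that rule
the fixture selects yeast extract, dextrose, starch and ammonium carbonate.
Ties in the |t| ranking are broken by input factor order.

## Central composite design and the quadratic model

For k factors the CCD combines 2ᵏ⁻¹ (or 2ᵏ) factorial points at coded ±1,
2k axial points at ±α (α = 2 in the bundled study, giving five levels per
factor), and replicated centers. Coded and natural units are linked by the
exact affine map `natural = center + coded·step`; `code_points()` /
`decode_points()` are exact inverses, and a warning is raised when
`center − α·step` would require a negative concentration.

The bundled 27-run CCD's eight factorial points are *not* a regular
half-fraction (their sign products are not constant), so `ccd_design()`
accepts an explicit factorial point list; its generator default is the
regular 2ᵏ⁻¹ fraction. The printed table parses to 11 center replicates
(its text says ten); the fixture stores the table as printed.

**Fitting.** `rsm_fit()` expands points into the 15-column basis
(intercept, 4 linear, 4 quadratic, 6 pairwise interactions, in documented
order) and fits by OLS via `lm()`. Natural units are the default — the
bundled study's published equation is in natural units — with coded units
optional; predictions from either fit of the same data agree to numerical
precision, which the suite verifies. Rank deficiency is detected at a
smallest/largest singular value ratio of 1e−10 and reported with the
collinear columns. A constant response yields R² = 0 by convention.

**ANOVA.** The fit reports the standard decomposition with
`df_regression = p − 1` and `df_residual = n − p` (14/12 for the bundled
design). Published tables sometimes use other df conventions (the bundled
one prints 4/22, inconsistent with a 15-coefficient model on 27 runs);
`anova_from_ss()` therefore recomputes MS, F, p, R² and R from *given*
SS/df, so any printed table is reproducible as arithmetic. On the bundled
study's printed sums of squares it returns F = 48.672 and R² = 0.89847.

**Known discrepancies in the bundled model fixture.** The study's equation
text and coefficient table disagree on the intercept sign; −0.1801
reproduces the printed center-point prediction 1.698545 (evaluation gives
1.6985583) and is used. Its non-center predicted column deviates from the
printed coefficients by up to ~0.025 — the coefficient set behind that
column is unrecoverable — so fixtures anchor on the center-point
prediction. The printed residual SS (0.5024) likewise exceeds the sum of
squared printed residuals (~0.11); both are preserved as separate
fixtures, never reconciled in data.

## Genetic-algorithm maximization

`ga_maximize()` implements the classical toolbox configuration: uniform
random initial population within bounds, rank fitness scaling (selection
weight ∝ 1/√rank), stochastic universal sampling, scattered crossover
(per-gene random mask between two parents), elitism, and termination on a
stall window or generation cap. Defaults mirror the bundled study's printed
configuration — population 200, elite 2, crossover fraction 1, 100
generations, 50 stall generations. The stall tolerance is 1e−6 absolute.
Migration/subpopulation settings of that configuration are deliberately not
implemented (single population); the printed initial-range and
mutation-handle entries are uninterpretable and replaced by uniform
initialization within bounds and a configurable mutation operator.

Two properties follow by construction and are tested: the per-generation
best trace is non-decreasing (elitism), and a seeded run is
bit-reproducible.

**Mutation and convergence.** With crossover fraction 1 the standard child
accounting produces no mutation children, so search is pure recombination
of initial gene values — faithful to the printed configuration, and
adequate on the bundled surface, but it cannot refine an optimum beyond the
initial population's resolution. For the oracle-agreement tests the package
therefore uses crossover fraction 0.8 with Gaussian shrink mutation
(per-gene sd a fraction of the factor range, decaying linearly to zero at
the generation cap), which converges to ~1e−3 on smooth concave
quadratics. Uniform reset mutation (rate 0.01) is the default operator.

**Bounds.** The bundled study never states its optimizer bounds, and its
reported optimum (0.99, 0.8, 0.1, 0.05 g/100 ml) lies *outside* the CCD
ranges for yeast extract and ammonium carbonate. Bounds are therefore an
explicit input; `ga_bounds_preset()` ships `"ccd-box"` (the axial box —
the defensible choice, since the polynomial is an interpolation and
extrapolating it is unsupported) and `"extended-box"` (contains the
reported optimum). The study's predicted 5.41 U/ml cannot be reproduced by
evaluating its printed coefficients at its printed optimum; the package
treats that figure as non-reproducible and anchors GA acceptance on
oracles instead: the analytic stationary point
(`quadratic_stationary_point()`, which solves `2Bx = −a`, classifies by
Hessian eigenvalue signs with a relative tolerance of 1e−10, and falls
back to dense grid + L-BFGS-B polish inside the box when the stationary
point is infeasible or not a maximum) and an independent dense grid search
in the tests. On the surface fitted to the bundled CCD observations, the
GA over the ccd-box finds ~4.4 U/ml at high yeast extract, high dextrose,
minimal starch and high ammonium carbonate — the same qualitative corner
the study reports, despite the unreproducible headline number.

## Enzymology helpers

**Purification tables.** Specific activity = activity/protein; yield = %
of the first row's total activity; fold = ratio of specific activities to
the first row's. Full precision is the default. The bundled study's
printed table derives folds from its 2-decimal specific-activity column,
which is *truncated*, not rounded (12.375 tabulates as 12.37; 5.2273 as
5.22): `rounded = TRUE` reproduces that arithmetic (folds 2.22, 4.35,
10.31 versus 2.22, 4.34, 10.29 at full precision). One printed yield
(61.62 %) is inconsistent with its raw values (61.66 %) under any rounding
and is treated as a typo.

**Kinetics.** `fit_kinetics()` estimates Km and Vmax either by the
classical unweighted Lineweaver–Burk line on (1/S, 1/v) — back-transformed
via `Vmax = 1/intercept`, `Km = slope·Vmax`, flagged invalid if either is
non-positive — or by direct nonlinear least squares (`nls()`, initialized
from the LB estimate; `scaleOffset` handles the zero-residual case so
noiseless data converge). Both are exact on noiseless Michaelis–Menten
data. Their relative merit under noise depends on the error model, and the
package's own simulations quantify it on the bundled study's conditions
(5 points, 0.02–0.1 mM, Km 0.043 mM, Vmax 2.21): under additive noise
(sd 0.05, ~5 % of the mid-range velocity) the direct fit clearly beats LB
on Km RMSE (the classical reciprocal-transform pathology: reciprocals
amplify errors at small velocities), and the acceptance suite asserts
exactly that. Under 5 % *multiplicative* noise the two are statistically
indistinguishable — the reciprocal transform is variance-stabilizing for
constant-CV errors — so no superiority claim is made or tested there.

## Synthetic-data generators

The generators emulate the statistical structure each stage assumes, not
fermentation biology:

* `simulate_pbd_response()` — additive main effects on the coded design
  (effect convention matching the screener, so zero-noise round trips are
  exact) plus iid Gaussian noise. Baseline default 1.98 U/ml (the mean
  activity of the bundled screening table); noise default sd 0.05 U/ml,
  the scatter of the bundled CCD's center replicates.
* `simulate_ccd_response()` — a known quadratic surface plus iid noise;
  zero noise makes `rsm_fit()` the exact inverse.
* `simulate_mm_kinetics()` — Michaelis–Menten velocities with additive or
  multiplicative noise.

All are pure functions of (arguments, seed) and restore the caller's RNG
state. What passing tests on them shows: the estimators invert their
generative models, with the sampling variances the closed forms predict
(e.g. sd of a screening effect = 2σ/√N). What they do not show: behavior
under real fermentation data's replicate structure, heteroscedasticity,
run-order drift, or model misspecification — a CCD's quadratic is an
approximation, and no generator here produces lack-of-fit.

## Problem sizes and determinism

The test suite uses the study-scale problems directly (12-run PBD, 27-run
CCD), Monte-Carlo sizes of 500–2000 replicates for sampling-distribution
checks, 20 seeded problems for GA-oracle agreement (populations 60–80,
≤200 generations, dimensions 2–3 with 41–201 points/axis grids), and 500
seeded replicates for the kinetics RMSE comparison. Every stochastic step
takes an explicit seed; `run_pipeline()` given the same seed writes
byte-identical outputs.

## Known limitations

* Only the 12-run PB construction is provided (no 20-/24-run catalogues,
  fold-over, or aliasing analysis).
* No lack-of-fit decomposition into pure error; no stepwise selection or
  ridge/canonical analysis beyond the stationary point.
* Single-population GA; no hybrid local search, no migration.
* Lineweaver–Burk is unweighted (the classical plot); no inhibition or
  stability model fitting beyond relative-activity tables.
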