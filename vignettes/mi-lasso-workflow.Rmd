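---
title: "Bounded-interval imputation and two-round LASSO/stepwise selection"
author: "milasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-interval imputation and two-round LASSO/stepwise selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milasso)
```

## The problem

Compiled datasets on microalgal growth — here, studies of the fatty-acid
(FA) profile of *Nannochloropsis oculata* — combine observations from many
laboratories. Each source reports a different subset of culture variables
(nutrients, pH, light, aeration, temperature, with or without daily
profiles), so the combined table has pervasive missingness, and the sources
themselves introduce fixed "data origin" effects. The analysis goal is
variable selection: among on the order of a hundred candidate predictors
and their pairwise interactions, which growth conditions actually shape
each FA response (its percentage of total FAs, its ratio to C16:0, and its
content per ash-free dry weight)?

`milasso` implements that selection pipeline end to end:

1. **Model-based imputation bounds.** Each missing cell gets a
   `[lower, upper]` interval from a mechanistic argument rather than a
   statistical model of the observed cells (see below).
2. **Multiple imputation.** `m` completed copies are drawn with independent
   uniform draws inside the bounds (`draw_imputations()`).
3. **Round-1 LASSO screening** per imputation under three penalty-selection
   criteria (minimum CV error, one-standard-error, and "NoBlocking"),
   combined across imputations by trimmed absolute coefficients.
4. **Round-1 stepwise regression** on the selected mains plus all their
   pairwise interactions, on raw (non-normalized) data.
5. **Round-2 LASSO** over every term surviving round 1, again under
   NoBlocking, followed by a final stepwise pass.
6. **Rubin's-rule pooling** of the final per-imputation fits.

## Imputation bounds

The bound calculators are deliberately simple, unit-explicit rules:

* **AFDW from dry weight** (`afdw_bounds_from_dw`): ash content between 1%
  and 20%, so AFDW lies in `[0.80 dw, 0.99 dw]`.
* **Biomass from cell counts** (`biomass_bounds_from_cells`): the single-cell
  weight is at least 10 pg early in the culture; the lower trajectory ramps
  the cell weight linearly from 10 pg to the final per-cell weight, the
  upper holds the final weight constant.
* **Nitrate** (`nitrate_bounds`): consumption is a second-order polynomial
  in the biomass change (and initial nitrate); the *upper* biomass
  trajectory gives the *lower* nitrate bound and vice versa, clamped to
  `[0, initial]`. The polynomial coefficients are configuration
  (`default_config()$chem$nitrate_poly`), defaulting to a linear term of
  60 mg N per g AFDW — a typical nitrogen quota of ~6% w/w.
* **Phosphate** (`phosphate_bounds`): biomass phosphorus content between
  0.5% and 2.5% (luxury uptake).
* **pH and inorganic carbon** (`carbonate_equilibrium`): see below.
* **Illumination geometry** (`illumination_bounds`): for a cylinder of
  unknown diameter lit from one side, light availability is `2 I0 / d`, so
  a 5–10 cm diameter assumption brackets it. No ray tracing is attempted;
  surface intensity and the illuminated-surface/volume ratio are the only
  geometry inputs used anywhere.

### The carbonate solver

Missing pH values are bounded with an equilibrium speciation calculation.
Rather than depending on an external geochemistry code, the package solves
the one-dimensional proton condition of the open CO~2~ system directly:

$$[\mathrm{H^+}] + Z - [\mathrm{OH^-}] - [\mathrm{HCO_3^-}] -
  2[\mathrm{CO_3^{2-}}] = 0,$$

with $[\mathrm{CO_2(aq)}] = K_H\,p_{\mathrm{CO_2}}$ and $Z$ the net
strong-ion charge of the medium. $K_H$ follows Weiss (1974), $K_1$/$K_2$
Millero et al. (2006) (valid for salinity 0–50 and reducing to the
freshwater limits at S = 0), and $K_w$ Millero's seawater fit. The left
side is strictly increasing in $[\mathrm{H^+}]$, so the root is unique; a
bracketing search on pH ∈ [2, 12] is polished with Newton steps until the
charge imbalance is at numerical zero (far below the 10⁻¹⁰ eq L⁻¹ the
package asserts). Ion pairing and activity corrections are *not* modelled:
the equilibrium value is only the anchor of a bound, and the residual model
(`fit_ph_residual_model`) absorbs systematic bias by regressing
proton-activity residuals `10^(-pH_real) - 10^(-pH_eq)` on nutrient
consumption and aeration rate. Media records for testing come from
`generate_chem_fixture()`, which scales standard-seawater major ions to a
target salinity and adds f/2 nutrient loads.

### Why uniform draws

The bound models assert nothing beyond the interval itself, so the draw
distribution is the maximum-entropy choice on a bounded interval: i.i.d.
uniform, cell by cell. No joint imputation model across variables is
fitted — that would inject structure the bounds do not claim. The number of
imputations defaults to `m = 10`, conventional for moderate missingness;
the stack stores its seed and distribution tag so alternative draw shapes
could be added without a format change.

## The regression core

Predictors are z-scored (sample SD, n − 1) and the response centred, which
keeps the intercept out of the penalty. The LASSO objective

$$\frac{1}{2n}\sum_i\Bigl(y_i - \beta_0 - \sum_j \beta_j x_{ij}\Bigr)^2 +
  \lambda \sum_j |\beta_j|$$

is minimized by cyclic coordinate descent with exact soft-threshold
updates. The convergence criterion is a full sweep moving no coefficient by
more than `lasso.tol` (default 10⁻⁷), and every single-penalty fit carries
its KKT residual as a global-optimality certificate. Because the temporal
k-day averages are nearly collinear with their day-of-harvest values
(correlations above 0.98), the path solver adds an active-set acceleration:
once a support stabilizes, the exact minimizer for that support and sign
pattern is computed from the Gram matrix and accepted only when it lowers
the penalized objective, with ordinary sweeps verifying convergence either
way. This changes nothing about the solution, only how fast the slow,
ill-conditioned tail of the path is traversed.

The penalty grid is log-spaced over 100 values from $\lambda_{max} =
\max_j |x_j^\top y|/n$ down to $10^{-3}\lambda_{max}$, with warm starts.
Cross-validation (10-fold, seeded) re-estimates standardization on the
training folds only; the SE of the CV curve is the SD of fold MSEs over
√folds.

### Three penalty criteria

* **min_mse** — smallest mean CV error; ties go to the larger penalty.
* **one_se** — largest penalty within one SE of the minimum.
* **noblocking** — the smallest grid penalty at which *every* data-origin
  dummy has a zero coefficient: the most permissive model that still
  excludes all origin fixed effects. This reading retains the most
  candidate predictors for the stepwise stage, matching the criterion's
  screening role. The criterion works off the coefficient path only. If
  origin coefficients re-enter non-monotonically along the path, only the
  chosen penalty itself must be blocking-free (a message notes the
  non-monotonicity); if they are active everywhere below the top of the
  path, the all-zero fit is returned with a warning.

## Stepwise refinement

Stepwise selection runs on raw-scale data with F-tests: start from the full
candidate model, drop the worst in-model term with p > `premove` (0.10),
else add the best out-of-model term with p < `penter` (0.05), one move per
step, removal considered first, ties broken lexicographically, with a
visited-model cycle guard. Interactions are raw column products and are
*not* forced to keep their main effects — final models may legitimately
contain an interaction without its mains.

Two numerical choices deserve note. First, when the candidate pool exceeds
the sample (hundreds of pairwise interactions against ~121 observations),
the full-model start is screened by a ridge prefit: mains are kept
preferentially, then the strongest interactions, down to a design with at
least half the observations left as residual degrees of freedom, with one
pivoted QR removing any remaining collinear columns. A bare full-rank start
(residual df ≈ 1) makes every F-test powerless and lets the procedure
wander into saturated models, so the df floor is applied to additions too:
a term may not enter once it would push residual df below n/2. Second,
with `penter = premove` the retention probability of a single null
candidate equals the nominal level exactly, which is how the package's
type-I-error simulations are run.

## Pooling and reporting

Per term, across `m` imputations: a term absent from an imputation's model
contributes estimate 0, SE 0 and p-value 1 — the only convention under
which presence-weighted means are well defined, and consistent with the
trimmed-mean exclusion logic. Rubin's rule gives the total variance
`T = W + (1 + 1/m) B`; the reported spread is `sqrt(T)`. p-value summaries
are the plain mean ± SD plus the 80% trimmed mean (sort, drop the outer
10% from each tail); significance markers are `mean p <= 0.05` (bold in
the rendered tables) and `trimmed p <= 0.05` (dagger). Cross-imputation
term selection uses the trimmed mean of *absolute* coefficients — many
genuinely important terms are negative, so a sign-literal reading would
discard them — and a term survives only if it is retained in enough
imputations that trimming cannot zero it out. No multiplicity correction is
applied beyond these marker conventions; the type-I-error consequences are
quantified by the package's own null simulations rather than hidden.

In round 2, any column involving an origin dummy (as a main effect or
inside a product) counts as a blocking column for the NoBlocking criterion,
so the surviving set — and hence every final model — provably contains no
origin effects. When no blocking column reaches round 2 at all, the
criterion is vacuously satisfied and the most permissive (smallest) grid
penalty is used. Round-2 interaction columns are products of *raw* columns,
z-scored afterwards: standardizing before multiplying would change what the
interaction measures. Responses are modelled independently, one pipeline
per response.

## The synthetic-data generator

`generate_study()` emulates the structure of the compiled dataset, not its
values: 121 observations; 40 numeric predictors of which 4 carry daily
series (log-normal marginals for concentration-like variables, uniform
levels 10–30 for temperature-like temporal variables, AR(1) daily wander
with ρ = 0.8 so the 2/3/4-day averages are as collinear as in real data); a
4-level origin categorical encoded as 3 blocking dummies with offsets
(0, 0.8, −0.5, 0.4) on the response; a 3-level nitrogen-source categorical;
5 true mains and 2 true pairwise interactions among them; Gaussian noise
SD 0.25; 15% missingness, completely at random, on predictor cells only;
and bounds `truth ± max(0.2 |truth|, 0.05)` so the truth always lies inside
its interval. These defaults are the package's study conditions; tests that
need other shapes construct their own designs explicitly.

What the generator does *not* emulate: informative missingness (real
source-specific reporting gaps are anything but MCAR), model-based bounds
(bounds here are built around the truth; the chemistry calculators are
tested separately), non-Gaussian response noise, and between-variable
correlation beyond the temporal collinearity. Passing the recovery tests
therefore demonstrates that the pipeline's machinery selects correctly
under its own assumptions — not that those assumptions hold for any
particular compiled dataset.

## Problem sizes and determinism

The recovery studies in the test-suite and acceptance script run the full
default design over 10 seeds with `m = 10`; unit tests use compact designs
(60–80 observations, ≤ 10 predictors, `m = 3`) that finish in seconds.
Every random stage — generation, imputation draws, CV fold splits — derives
its stream from one master seed, and two runs with identical data, config
and seed produce byte-identical report files. Reports are written as CSV
and markdown tables (estimate ± pooled SD in two-significant-digit
scientific notation, p mean ± SD, trimmed p, markers) plus a YAML manifest
recording seed, m and the full configuration.

## Known limitations

* Bounds-only uniform imputation ignores relationships between variables;
  it is honest about what the bound models claim but weaker than a joint
  imputation model where one is defensible.
* The stepwise stage inherits the usual pathologies of p-value stepping
  (selection bias, post-selection inference); the pipeline mitigates but
  does not eliminate them, via LASSO pre-screening and trimmed-mean
  aggregation across imputations.
* The carbonate solver omits ion pairing, borate and phosphate speciation;
  its role is bound-setting, with the residual model absorbing bias.
* With `m = 10`, between-imputation variance estimates (B) are themselves
  noisy; pooled SDs should be read as order-of-magnitude uncertainty.
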