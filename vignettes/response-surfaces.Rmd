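---
title: "Hill-type response surfaces for mixture synergy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill-type response surfaces for mixture synergy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riccsurf)
```

## The surface family

A single agent's dose-response is the four-parameter Hill curve
$E(d) = E_0 + (E_{max}-E_0)/(1+(EC_{50}/d)^{\alpha})$, which in log-dose
coordinates is the solution of a logistic (for $E_0 = 0$) or Riccati
ordinary differential equation. The package generalizes this to mixtures:
a response surface $u(\vec d)$ over the doses of $n$ agents is required to
solve the corresponding Riccati partial differential equation

$$\sum_{i=1}^n \frac{\partial u}{\partial x_i}
  = \gamma(\vec x)\,\frac{(u-u_{min})(u_{max}(\vec x)-u)}{u_{max}(\vec x)-u_{min}},
  \qquad x_i = \log d_i,$$

with the boundary conditions that the single-drug Hill curves are recovered
on the axes and that splitting one drug's dose over fictitious components
changes nothing (sham compliance).

With scaled doses $m_i = d_i/EC_{50,i}$, the *null-interaction* solution is

$$u_{null} = u_{min} + \frac{u_{max}-u_{min}}{1+\left(\sum_i m_i\right)^{-\gamma}},$$

where $u_{max}$ and $\gamma$ are the $m$-weighted averages of the compound
maxima and slopes. The *full-interaction* surface keeps this shape and adds
two parameter families:

* **perturbations** per compound — additive shifts of $E_{max}$
  (`d_emax`) and slope (`d_slope`), and a multiplicative $EC_{50}$ factor
  (`d_m50`, the inactive value is 1). They deform the pure-compound limits
  of the surface.
* **interactions** per subset $S$ of $2..n$ compounds — a position term
  `d_m` entering the dose bracket via $(\prod_{i\in S} m_i)^{1/|S|}$, and
  maximum-effect (`d_emax`) and slope (`d_slope`) terms entering the
  numerators of $u_{max}$ and $\gamma$ with the same root terms. They
  vanish automatically whenever any member of $S$ is undosed.

Any subset of active parameters still solves the PDE — the package's
`pde_residual()` checks this numerically, and the test suite asserts it on
randomized models. The total parameter budget is $3(2^n-1)$: 9 for binary,
21 for ternary, 45 for quaternary mixtures (`parameter_count()`).

Two printed-form ambiguities in the surface family were resolved as
follows. The bracket exponent is $-\gamma$ throughout (required for effects
that increase with dose at positive slope, and for consistency between the
binary and the general form). The slope-perturbation numerator pairs each
compound's `d_slope` with its own dose term (the symmetric form, matching
the ternary pattern). Both choices are fixed, not options.

### Conventions and degenerate inputs

* Evaluation is in the dose domain; the log-dose form appears only inside
  `pde_residual()`.
* $u_{min}$ is constant by default (the baseline response cannot depend on
  absent drugs); a dose-weighted `umin_mode = "mixed"` variant exists for
  completeness.
* The $m$-weighted averages are 0/0 at the all-zero dose point; the surface
  is defined there by its continuous limit $u_{min}$.
* In the full model the shifted scaled doses $m_i = d_i/(EC_{50,i}\,
  d_{m50,i})$ are used in **all** terms (including the unperturbed first
  terms of $u_{max}$ and $\gamma$); the strict null evaluation path
  (`u_null()`) never applies shifts and ignores every perturbation or
  interaction.
* The dose bracket must stay positive: a sufficiently negative `d_m`
  (below $-2$ for a pair at equal scaled doses) makes the bracket negative,
  and evaluation stops with an error naming the offending subset. A floor
  of `1e-300` guards exponentiation at zero dose. Outputs are never
  clamped; contract violations are surfaced, not hidden.

## Fitting

`fit_pure()` estimates each compound's Hill curve from its single-drug rows
($EC_{50}$ on the log scale plus slope; baseline and maximum fixed at 0 and
1 unless freed), using a deterministic grid of starting values. Mixture
fits never re-estimate the pure curves.

`fit_mixture()` estimates the active parameters of a mask by bounded
Levenberg-Marquardt least squares (`minpack.lm::nls.lm`), restarted from a
seeded Latin hypercube of 16 points over the default bounds
(`d_emax` $\in [-1, 1]$ clipped so every $E_{max,i}+\delta \le 1$;
`d_slope` $\in [-20, 20]$; `d_m50` $\in [0.01, 100]$;
`d_m` $\in [-1.9, 50]$; interaction `d_emax` $\in [-1,1]$ and `d_slope`
$\in [-20, 20]$), plus the all-inactive start. The best residual sum of
squares wins; the whole procedure is deterministic given the seed.
Standard errors come from the numerical Jacobian at the optimum with
$\hat\sigma^2 = RSS/(N-k)$.

**Fit scope.** A mixture model is fitted to the *complete* table of its
compounds — single-drug rows and mixture rows together. The perturbation
parameters enter the pure-compound limits of the surface, so they are only
identifiable when the pure rows are in the objective; for interaction-only
masks the estimates are unchanged by the pure rows (their residuals do not
depend on interaction terms), but the reported RMSE then describes the
whole table. The ternary model is fitted jointly to all rows, consistent
with the near-transferability of the pairwise interaction coefficients.

**Null-model prediction error.** When quoting the predictive RMSE of the
null surface on a fixed-ratio mixture ray, the package's analyses use the
ray's *transition* rows — up to and including the first fully saturated
(effect = 1) observation. Beyond saturation every sensible model predicts
1, so trailing saturated rows carry no discriminating information and
would only dilute the prediction error. Fits, by contrast, always use all
rows: the saturated tail is exactly what prevents the interaction
parameters from overfitting the transition.

**Fit statistics.** `fit_statistics()` reports RSS, $RMSE = \sqrt{RSS/N}$,
adjusted $r^2$ with the $(N-1)/(N-k-1)$ correction, and
$AIC = 2k - 2\ln L$ under a Gaussian likelihood with the
maximum-likelihood variance $\hat\sigma^2 = RSS/N$; $k$ counts model
parameters only (not the variance). The likelihood convention is a
documented package choice — AIC values are therefore comparable within
this package, and model comparison uses AIC *differences* only. The
Wilcoxon-Mann-Whitney test (`mw_test()`; exact enumeration for combined
$N \le 12$, tie-corrected normal approximation otherwise) checks that
observed and modeled effects share a distribution, and the Shapiro-Wilk
test checks residual normality.

## Parameter elimination

`reduce_model()` performs backward elimination: at each step every active
parameter is removed in turn, the model refitted (warm-started from the
current solution plus a fresh Latin-hypercube), and the removal with the
lowest AIC accepted while it improves on the current AIC; ties are broken
by the smallest $|estimate|/SE$. Removed `d_m50` factors pin at 1, all
other parameters at 0. The full trail of candidate AICs is kept.

Strict AIC minimization is greedy and, like all AIC selection, mildly
permissive: on rich synthetic designs (50+ rows) it typically retains one
to three weakly significant noise-fitting parameters alongside the true
ones — their estimates stay within about two standard errors of
insignificance. On the anesthetics data the nine-parameter
midazolam+propofol model reduces to exactly the three interaction terms;
for the other two pairs the elimination continues into the interaction
triple itself (midazolam+alfentanil keeps only the position interaction,
propofol+alfentanil the position and slope interactions), because those
weakly determined terms do not pay their AIC rent on five-point rays. The
three-interaction binary model is nevertheless the package's reference
reduced model, mirroring the shared structure of the three pairs.

## Synergy analysis

`synergy_surface()` evaluates $u_{Ricc}-u_{null}$ on per-compound dose
axes: by default 201 log-spaced points from one tenth of the smallest
non-zero observed dose to the largest observed dose, plus an exact-zero
node (the ternary analyses in the tests and the acceptance script use 61
points per axis; the refined extrema agree to far better than the
grid-doubling tolerance of $10^{-6}$ asserted in the tests).
`find_extrema()` takes the global grid extrema and refines them by
Nelder-Mead in log-dose space, reflected at the search box (the
experimental dose range — extrapolating the fitted surface beyond the data
is not meaningful). Synergies are reported as effect fractions; the CLI
renders percent. `iso_levels()` extracts iso-effect and iso-synergy level
sets: contour polylines for two compounds, marching-tetrahedra triangle
meshes for three; for the null model the 50% iso-effect set is the
classical linear isobole ($\sum m_i = 1$), which the tests verify.

## The synthetic-data generator

`synthetic_spec()` + `generate_table()` simulate studies with a known
ground-truth surface: a default design of six log-spaced single-drug doses
per compound spanning two decades around each $EC_{50}$ plus a four-level
full-factorial mixture grid, i.i.d. Gaussian effect noise (optionally
clipped to $[0,1]$), and a stored truth for recovery scoring. This
emulates the dose layouts and noise scale of designed mixture studies
(typical effect noise 0.01–0.05). It deliberately does **not** emulate
several features of real data: binomial quantal responses (fractions of
responding subjects take discrete values), heteroscedastic or correlated
errors, dose-measurement error, and high-dose response declines. Passing
recovery tests therefore demonstrates the estimator's correctness and
calibration under clean conditions, not robustness to those real-world
complications.

## Known limitations

* The surface family assumes Hill-type monotone responses; non-monotone
  dose-response (e.g. receptor-level decline at extreme doses) is outside
  its range, which is also why extrema are searched only within the
  experimental dose ranges.
* AIC values are convention-dependent (see above) and not comparable with
  other software's likelihoods.
* With very short mixture rays (five points) the slope- and
  maximum-effect interaction terms are weakly identified; their standard
  errors, not their point estimates, carry that information.
* `u_max + du_max` can exceed 1 transiently for positive maximum-effect
  interactions; the fitting bounds constrain only the per-compound maxima
  ($E_{max,i} + \delta \le 1$), matching the family's boundary conditions.
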