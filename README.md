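# riccsurf

Hill-type response surfaces for drug-mixture synergy analysis.

## The problem

Whether a drug combination is synergistic, antagonistic or merely additive
depends entirely on the reference model of "null interaction". `riccsurf`
implements a response-surface framework in which both the reference and the
observed mixture response are generalized Hill functions — closed-form
solutions of the logistic/Riccati partial differential equation that
underlies the Hill dose-response law. It is aimed at pharmacologists and
toxicologists who have dose-effect tables for single agents and their
mixtures (two or more components) and want to quantify *where in dose space*
a mixture deviates from non-interaction, rather than compressing the
interaction into a single index.

## The model

Each pure compound follows a four-parameter Hill curve

    E(d) = E0 + (Emax - E0) / (1 + (EC50 / d)^alpha).

With scaled doses `m_i = d_i / EC50_i`, the **null-interaction surface** for
an n-component mixture is

    u_Hill = u_min + (u_max - u_min) / (1 + (sum_i m_i)^(-gamma)),

where `u_max` and `gamma` are the dose-weighted averages of the compound
maxima and slopes. This surface solves the n-dimensional Riccati PDE

    sum_i du/dx_i = gamma (u - u_min)(u_max - u) / (u_max - u_min)

(x_i = log-doses), is sham-compliant, and reduces to the single-drug Hill
curves on the axes.

The **full-interaction surface** `u_Ricc` keeps this functional form and
adds, per compound, perturbations of Emax, slope and EC50, and, per subset S
of 2..n compounds, interaction terms entering through |S|-th roots of
products of scaled doses, e.g. for two drugs

    u_Ricc = u_min + (u_max + du_max - u_min) /
             (1 + (m_a + dm_ab sqrt(m_a m_b) + m_b)^-(gamma + dgamma)).

That makes 3(2^n - 1) candidate parameters (9 binary, 21 ternary, 45
quaternary); every parameter subset still solves the PDE. Parameters are
estimated by bounded multistart least squares with the pure-compound curves
held fixed, then pruned by AIC-guided backward elimination. The **synergy
surface** is the difference `u_Ricc - u_Hill`; its extrema over the
experimental dose ranges are the dose combinations of peak synergism and
antagonism.

## Worked example

The packaged dataset contains hypnosis responses (fraction of subjects
hypnotized) for midazolam, propofol and alfentanil alone, in pairwise
fixed-ratio combinations and as a ternary mixture (doses in mg/kg).

```r
library(riccsurf)
tab <- load_anesthetics()
curves <- list(hill_curve("midazolam", ec50 = 0.144, slope = 4.8),
               hill_curve("propofol",  ec50 = 1.078, slope = 11.1))
keep <- tab$alfentanil == 0 & (tab$midazolam > 0 | tab$propofol > 0)
pair <- dose_table(tab[keep, c("midazolam", "propofol", "effect")],
                   compounds = c("midazolam", "propofol"))
fit <- fit_mixture(pair, curves, interaction_mask(curves), seed = 1)
summary(fit)
#> Full-interaction response-surface fit
#>
#>                            estimate std_error t_value
#> d_m.midazolam:propofol       1.1091    0.1244  8.9117
#> d_emax.midazolam:propofol    0.1444    0.1121  1.2890
#> d_slope.midazolam:propofol -12.7757    1.5073 -8.4758
#>
#> n = 20, k = 3, RSS = 0.03762, RMSE = 0.0434, adj. r2 = 0.9791
#> AIC = -62.76, MW p = 0.654, Shapiro-Wilk p = 0.901

surface <- synergy_surface(fit, n_grid = 201)
extrema <- find_extrema(surface)
print(extrema$maximum)
#> Surface maximum: +0.6514 (65.1%) at (midazolam = 0.02916, propofol = 0.6683)
```

Reading: the three interaction parameters (position, maximum-effect and
slope interaction of the pair) describe the mixture data with an RMSE of
0.043 effect units, an order of magnitude better than the null surface
(RMSE 0.39 on the mixture rays), and the fitted surface predicts up to a
65% stronger hypnotic effect than non-interaction would, at 0.029 mg/kg
midazolam plus 0.67 mg/kg propofol. `reduce_model()` starting from all nine
binary parameters eliminates the six perturbations and retains exactly
these three interaction terms.

A thin command-line interface over the same functions ships in
`inst/cli/riccsurf` (subcommands `fit-pure`, `fit-mixture`, `reduce`,
`synergy`, `simulate`).

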