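---
title: "Density-structured transition models for ordinal weed coverage surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-structured transition models for ordinal weed coverage surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weeddyn)
```

## The model

weeddyn analyses longitudinal surveys in which weed abundance at a site is
scored once a year on an ordinal coverage scale: 0 "absent" (0% ground
cover), 1 "low" (<20%), 2 "medium" (20–50%), 3 "high" (>50%). The state of
a field in year $t$ depends on its state in year $t-1$ (through the seed
bank) and on the management applied in year $t$, so the natural model is a
density-structured Markov chain: a $4\times4$ column-stochastic transition
matrix $\mathbf{P}_{ts}$ whose entry $p_{ji}$ is the probability of coverage
level $j$ this year given level $i$ last year,

$$\mathbf{q}_{ts} = \mathbf{P}_{ts}\,\mathbf{q}_{t-1,s},$$

with $\mathbf{q}$ the state-probability vector over the four levels.

The transition probabilities come from a cumulative-link (proportional-odds)
regression with a site-level random intercept. Writing $F$ for the logistic
CDF, the cumulative probability of staying at or below level $j$ is

$$\Pr(Y_{ts} \le j \mid Y_{t-1,s}=i)
  = F\!\big(\beta_{j|j+1} - (\alpha_i + \boldsymbol\beta^\top\mathbf{x}_{ts}
  + \varepsilon_s)\big),$$

where $\beta_{0|1} < \beta_{1|2} < \beta_{2|3}$ are the thresholds,
$\alpha_i$ (with $\alpha_0 = 0$) carries the dependence on the previous
year's level, $\mathbf{x}_{ts}$ holds the management covariates of the
*destination* year (farmland use as five treatment dummies against a wheat
baseline; summer irrigation and delayed sowing as 0/1 indicators;
December–April mean temperature in °C, raw and uncentered), and
$\varepsilon_s \sim \mathrm{N}(0, \sigma^2)$ is shared by all transitions of
site $s$. Cell probabilities are differences of adjacent cumulative
probabilities, and each observed transition is one multinomial draw from its
column.

Attaching covariates to the destination year is a modelling commitment, not
a convenience: farmland use in year $t$ and irrigation during the preceding
summer are what act on the seed bank between the two surveys.

## Estimation

The likelihood of a site is the integral of its product of multinomial cell
probabilities over the random intercept; the package maximizes the sum of
the log marginal likelihoods (`marginal_loglik()`, `fit_transition_model()`).
Numerical choices:

* **Quadrature.** Adaptive Gauss–Hermite with 15 nodes by default. The
  integrand is log-concave, so the per-site mode is found by a vectorized
  Newton iteration (guarded steps, tolerance $10^{-10}$) and the rule is
  centred and scaled there. A Laplace option (`quadrature = "laplace"`) is
  the one-node special case. Against brute-force trapezoid integration over
  $\varepsilon \in [-8, 8]$ with $10^5$ points, 15-node AGQ agrees to
  better than $10^{-6}$ on test fixtures, and 15 vs 31 nodes agree to the
  same precision.
* **Parameterization.** Thresholds are optimized as
  $(\beta_{0|1}, \log\Delta_2, \log\Delta_3)$, so their strict ordering
  holds at every iterate; $\sigma$ is optimized as $\log\sigma$.
* **Optimizer.** L-BFGS-B with an analytic gradient obtained by
  differentiating under the same adaptive quadrature rule, from three
  deterministic starts (a warm start at the $\sigma=0$ fixed-effects
  optimum, a frequency-based null start, and a jittered copy); a
  finite-difference polish runs whenever the interior gradient norm exceeds
  $10^{-3}$. Fits are reproducible bit for bit. The gradient-norm
  convergence check uses central differences with step $10^{-4}$, whose
  noise floor (~$10^{-5}$ on these likelihoods) is why the declared
  tolerance is $10^{-3}$ rather than something stricter; at an active box
  bound the projected gradient need not vanish, so only interior
  coordinates count.
* **Separation.** Management categories that deterministically clear the
  weed (paddy rice, typically) drive their coefficient toward $-\infty$.
  Coefficients are bounded at $\pm 25$, values beyond $\pm 10$ are flagged
  as quasi-separated, and no penalization is applied: projections only need
  the saturated probabilities, which are indistinguishable beyond that
  magnitude.
* **$\alpha$ ordering.** The previous-level effects are fitted as three
  free treatment contrasts, not constrained monotone; ecological
  expectation says they should be ordered, so a violation is reported as a
  warning rather than imposed. This keeps the likelihood surface smooth and
  makes the check visible.
* **Model selection.** `backward_select()` drops one term at a time by AIC
  ($-2\ell + 2k$, with $\sigma$ counted as one parameter), resolving ties
  within $10^{-6}$ toward fewer parameters, and keeps the full candidate
  ladder so the comparison table can be printed.

The $\sigma = 0$ special case reduces exactly to the conditional likelihood
at $\varepsilon = 0$; the test suite verifies the fixed-effects fit against
`MASS::polr` to $10^{-6}$ in log-likelihood on data with an interior
maximum. `polr` is used only as this cross-check oracle, never inside the
fitter.

## Projection

`transition_matrix()` evaluates the four columns for one management profile
with $\varepsilon$ fixed at 0 — the population-average site; a flag allows
nonzero values for sensitivity analyses. `project_trajectory()` iterates
$\mathbf{q}_t = \mathbf{P}_t\mathbf{q}_{t-1}$ through a cyclic matrix
sequence; the 20-year horizon and the $\delta$(level 0)/$\delta$(level 3)
initial states of `default_scenarios()` are the standard comparison setup.

Equilibria: for a constant environment the stationary vector is the right
eigenvector at the dominant eigenvalue $\lambda = 1$ (dense 4×4
eigen-decomposition, eigenvalue chosen by minimal $|\lambda - 1|$; power
iteration as fallback for numerically complex or negative vectors and the
documented test oracle). For a two-use rotation, the coverage distribution
oscillates between two phase states: the state in use-1 years is the
stationary vector of $\mathbf{P}_1\mathbf{P}_2$ and the state in use-2
years that of $\mathbf{P}_2\mathbf{P}_1$, linked by
$\mathbf{q}_1^* = \mathbf{P}_1\mathbf{q}_2^*$ and vice versa. In the printed
equilibrium table the row labelled with a farmland use is the distribution
observed in the years when that use is grown, i.e. *after* the transition
into that use — which is why the paddy-rice row of a wheat–paddy rotation
is the near-certain level-0 state. Convergence years are reported at
$L_\infty < 0.01$, matching two-decimal reporting granularity; tables round
to two decimals only on request.

## The synthetic generator and the survey reconstruction

`simulate_survey()` generates data with exactly the structure the estimator
assumes: one Gaussian intercept per site, covariates drawn i.i.d. across
years from a configurable management mix, levels stepped forward through
the model's own multinomial columns, then independent thinning of
site-years. Per-site RNG substreams are derived deterministically from the
seed, so enlarging a study leaves existing sites' data untouched. Real
rotations are of course serially structured rather than i.i.d.; i.i.d.
management is the right null for estimator testing, and fixed rotation
scripts can be imposed through `year_ranges` and custom configs where
scenario-level realism matters.

`simulate_ibaraki_survey()` is a stand-in for the monitoring dataset the
models were designed for: 41 winter-cereal fields in Ibaraki, Japan,
observed 1997–2009, 425 site-year records. The site-by-year skeleton and
each site's December–April temperature mean/SD are public summary
information and are reproduced exactly (the spans sum to 425); coverage
levels, management sequences and yearly temperatures are simulated. The
generating coefficients are the reported projection-model estimates rounded
to one decimal, with $\sigma = 1$ — the original study reports no
random-intercept SD, so this is a deliberate, configurable default. The
reported paddy-rice magnitude (−18.8) is kept even though it is
quasi-separated, because weakening it would reverse the management ranking
the model exists to capture; the small unit-test fixture (`toy_model()` in
the test helpers) caps it at −8 instead to keep tiny likelihoods
non-degenerate.

What analyses of the reconstruction can and cannot show: structure-level
quantities (record and site counts, pair enumeration, design encoding) are
exact; estimator-level properties (bias, CI coverage, quadrature accuracy,
selection behaviour) are meaningful because the generator matches the
model; but likelihood-level values refit from it — AIC values, coefficient
point estimates — describe the simulated outcomes, not the original
observations, and are not expected to match published values computed from
data this package does not redistribute. The reported coefficients also
imply near-deterministic dynamics (level 3 is close to absorbing under
continuous wheat), so refits on the reconstruction inherit widespread
quasi-separation; that is a property of the published point estimates, not
of the fitter.

## Parameter recovery

`parameter_recovery()` wraps the simulate–refit loop. The default
`recovery_config()` uses 300 sites × 12 years (~3300 transitions),
moderate effects (thresholds −1/0.5/2, previous-level effects 1.5/3/4.5,
irrigation −1, land-use effects between 0.3 and −3), $\sigma = 1$, and
7-node AGQ for the refits; 20 replicates run in a few minutes on one core.
Under this design the absolute bias of thresholds and the irrigation
coefficient stays well under 0.1 and 95% Wald intervals for the irrigation
coefficient cover at their nominal rate — the package's core guarantee that
the marginal-ML machinery is consistent for data generated from its own
assumptions.

## Known limitations

* No category-specific (non-proportional) covariate effects, no crossed or
  nested random effects, no Bayesian fitting.
* Transitions are formed between consecutive observations only
  (`max_gap = 1` by default); records separated by missing years are never
  silently bridged, and larger gaps must be requested explicitly — the gap
  then still uses a single one-year transition kernel, which is an
  approximation, which is why it is off by default.
* Missing temperatures are allowed in the data but refused (not imputed) by
  any specification that includes the temperature term.
* The ordinal scale is treated as observed without error; mis-scored
  coverage classes propagate directly into the transition counts.
* Projections fix $\varepsilon = 0$, i.e. describe the average site;
  between-site spread at equilibrium is larger than the projected
  distributions suggest.
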