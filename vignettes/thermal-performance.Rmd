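---
title: "Thermal performance of insect development: models, thresholds and degree-days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal performance of insect development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaldev)
```

## The problem

Insects are ectotherms: the speed of their development is set largely by
ambient temperature. A standard laboratory design rears cohorts at a series
of constant temperatures and records each individual's egg-to-adult
development time. Converting times to rates, $D(T) = 1/\text{dev time}$
(1/day), yields a thermal performance curve from which three quantities of
applied interest are derived: the lower developmental threshold $T_b$ below
which development stops, the degree-day requirement (thermal constant) $DD$
needed to complete the stage, and the optimum temperature $T_{opt}$ at which
development is fastest. For biological-control practitioners these numbers
determine where and when a natural enemy such as a pupal parasitoid can
establish, and feed directly into degree-day phenology forecasts.

`thermaldev` implements this workflow end to end: life-table input,
two rate models, threshold/degree-day/optimum derivation, degree-day
emergence prediction, and a seeded simulator for validating the whole chain
by parameter recovery. The packaged example data are published mean
development times of two pupal parasitoids of the fall webworm,
*Chouioia cunea* and *Psychophagus omnivorus*, reared at 10-30 °C
(`parasitoid_devtimes()`).

## The two rate models

**Linear (degree-day) model.** $D(T) = a + bT$, fit by ordinary least
squares (`devrate(..., model = "linear")`, internally `stats::lm`). Its
x-intercept gives the lower threshold, and its slope the thermal constant:

$$T_b = -\frac{a}{b}, \qquad DD = \frac{1}{b}.$$

Both are reported only when $b > 0$; a flat or decreasing rate profile has
no meaningful threshold, and the fit then carries `NA` with a warning. The
linear model ignores the curvature near the thermal limits and cannot
express an optimum.

**Brière model.** A nonlinear curve that rises from a lower threshold,
peaks asymmetrically, and falls to zero at an upper threshold:

$$D(T) = n\,T\,(T - T_b)\,(T_L - T)^{1/m}, \qquad T_b \le T \le T_L,$$

with $D(T) = 0$ outside $[T_b, T_L]$ (`briere_rate()`). $n$ and $m$ are
empirical shape parameters without direct biological meaning. The optimum
has a closed form, obtained by differentiating $T(T-T_b)(T_L-T)^{1/m}$ and
taking the larger root of the resulting quadratic:

$$T_{opt} = \frac{2mT_L + (m+1)T_b +
  \sqrt{4m^2T_L^2 + (m+1)^2T_b^2 - 4m^2T_bT_L}}{4m + 2}$$

(`briere_optimum()`; tested against brute-force grid maximisation at
$10^{-3}$ °C resolution).

Both fits minimise the (optionally weighted) sum of squared rate residuals,
and both report the plain coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$ (`r_squared()`); no adjusted $R^2$ and no
information criteria, since a single $R^2$ per fit is the convention in
this literature.

## Numerical strategy for the Brière fit

The least-squares surface of the Brière model is multimodal in
$(T_b, T_L, m)$. `devrate(..., model = "briere")` therefore:

1. profiles out $n$ analytically — for fixed $(T_b, T_L, m)$ the model is
   linear in $n$, so its optimum is a closed-form ratio;
2. refines the remaining three parameters with box-constrained
   quasi-Newton (`optim`, L-BFGS-B) from every node of a deterministic
   $5 \times 5 \times 5$ grid of starts (cell midpoints over the bounds);
3. keeps the lowest residual sum of squares, breaking ties by grid order,
   so repeated fits are bit-for-bit reproducible — no randomness anywhere
   in fitting.

Default bounds, all overridable via `briere_bounds()`: $T_b \in [0,
\min T_{obs})$, $T_L \in (\max T_{obs}, 45]$, $m \in [0.3, 6]$. The
thresholds must bracket the observed developing window for the profiled
model to stay real-valued, and 45 °C is a biologically safe ceiling for
temperate insects. A solution on a bound raises a warning and sets the
`at_boundary` flag. Standard errors come from the local Gauss-Newton
approximation $\sigma^2 (J^\top W J)^{-1}$ and are labelled approximate;
with as many parameters as temperatures they are undefined and reported as
`NA`.

The model has four free parameters, so four distinct temperatures are the
minimum for a determined fit. With exactly three the fit still runs —
published life tables sometimes offer no more, as with *P. omnivorus*
here — but warns that the parameters are not uniquely identified; with
fewer it errors.

## What counts as an observation

Cells with zero emergence contribute *no* rate observations: a temperature
where nothing developed is informative about survival, not about
development speed, and injecting zero rates would drag both fits towards
the non-developing range. Such cells are kept as `"non_developing"`
metadata. This choice matters: for *P. omnivorus* the published mean rates
*decrease* from 20 to 30 °C, so without injected zeros the OLS slope is
negative (threshold undefined) and the straight line describes those three
means better than any Brière curve confined to $T_L \le 45$ °C — an exact
Brière interpolation of that decreasing triple would need $T_L$ in the
hundreds of degrees. The per-group $R^2$ comparison computed by
`fit_groups()` on the packaged means reflects exactly this: the Brière
model wins for both *C. cunea* groups and loses for both *P. omnivorus*
groups. Reported fits elsewhere that show the Brière model winning for
this species are only reproducible if zero rates at non-developing
temperatures were included, which this package deliberately does not do.

Because only cell means are published for the example data, the reader
expands each cell into $n$ identical pseudo-individuals (or one record
weighted by $n$); fits on either representation are identical. Whether the
original analyses used individuals or means is not stated anywhere we can
check, so both input modes are first-class.

## Degree-day phenology

`accumulate_degree_days()` implements rectangle-method thermal summation
on daily means: day $i$ adds $\max(T_i - T_b, 0)\,\Delta t$ degree-days,
with $\Delta t = 1$ day by default. Days at or below $T_b$ add exactly
zero — negative increments are never allowed to subtract. There is no
upper cutoff by default, since the plain form subtracts only $T_b$; a
horizontal cutoff (`t_cap`) is available but off. `predict_emergence()`
returns the first day the running sum reaches the degree-day requirement,
`NA` if never. Under constant temperature this reduces to the closed form
$\lceil DD / ((T - T_b)\Delta t) \rceil$, which the tests verify over a
random sweep. No within-day temperature profile (e.g. single-sine) is
modelled; inputs are daily means, or daily min/max collapsed to their
midpoint.

## The life-table simulator

`simulate_lifetable()` emulates the constant-temperature rearing design:
2 species × 2 sexes × 5 temperatures (10, 15, 20, 25, 30 °C) × 50
individuals per cell by default, with sex-specific true Brière curves
taken from the fitted parasitoid values (`default_species_params()`).
Each individual:

* emerges with probability given by a logistic survival window
  $p_{max}\,\mathrm{logit}^{-1}((T - t_{lo})/s)\,
  \mathrm{logit}^{-1}((t_{hi} - T)/s)$, forced to zero outside the sex's
  $(T_b, T_L)$ window where development is impossible;
* if emerged, gets $\text{dev time} = D(T)^{-1} e^{\varepsilon}$ with
  $\varepsilon \sim N(0, \sigma^2)$, $\sigma = 0.05$ by default.

Noise is multiplicative on *time* (lognormal), not additive on rate: times
stay positive and right-skewed, as real development data are. The survival
windows (e.g. emergence from ~15-30 °C for *C. cunea* but only ~20-30 °C
for *P. omnivorus*) and the female shares (0.97 vs 0.2) are round-number
choices reproducing the qualitative rearing pattern; true
between-individual variance is unknowable from published standard errors
of means, so $\sigma = 0.05$ is a convention, clearly labelled. The
default "fixed" design gives deterministic cell sizes (the unit on which
recovery is assessed); a "bernoulli" mode draws each individual's sex from
the female share instead, for studying progeny sex ratios. One seeded
stream per call; replicate $r$ of `recovery_experiment()` reuses
`seed + r`, so replicates are independent yet reproducible.

What the simulator does **not** emulate: host-parasitoid dynamics, clutch
size, fluctuating temperatures, diapause, and any thermal-injury dose
model for cold storage. Passing recovery tests therefore show that the
estimators invert the generative model faithfully — not that field data
satisfy that model.

## Validation and problem sizes

The test suite checks, among others: exact identities ($-a/b$, $1/b$,
curve roots at the thresholds, $a + b T_b = 0$ to machine precision);
closed-form versus grid maximisation of $T_{opt}$ (100 random curves);
noiseless self-consistency of the Brière fit (20 points, all four
parameters recovered to $10^{-4}$ relative error, objective no worse than
at the generating truth or than a $12^3$ brute-force grid); and a
Monte-Carlo recovery study (100 replicates, 50 individuals per cell,
$\sigma = 0.05$) in which the median absolute error of the recovered lower
threshold must stay below 1 °C. These sizes keep the default suite around
two minutes on one core while leaving the Monte-Carlo bounds comfortably
away from their thresholds. The linear model's threshold, estimated from
data observed only at 15-30 °C, is biased low by about 1 °C relative to
the generating Brière threshold — an extrapolation artifact the recovery
report quantifies, not a bug.

## Known limitations

* Only the linear and Brière rate functions are provided; no Lactin,
  Logan or Sharpe-Schoolfield alternatives, and no model selection beyond
  $R^2$.
* Survival and fecundity are simulated but not modelled as functions of
  temperature; the package fits development rate only.
* Degree-day accumulation assumes daily means are representative
  (rectangle method); under strongly fluctuating regimes this
  underestimates development on days straddling the threshold.
* Approximate standard errors from the local quadratic are optimistic for
  near-underdetermined fits (3 temperatures), where they are suppressed.
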