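---
title: "Bayesian concentration-response analysis of bottle bioassays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian concentration-response analysis of bottle bioassays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottlebioassay)
```

## The problem

Insecticide resistance in mosquito populations is monitored with
susceptibility bioassays: adult mosquitoes are exposed inside glass bottles
coated with a known mass of active ingredient, and mortality (or, for
sterilizing compounds such as juvenile hormone mimics, the inhibition of
egg-laying among surviving females) is recorded after a fixed holding
period. Establishing a discriminating concentration (DC) for a new compound
requires estimating the full concentration-response relationship of
susceptible colonies -- in particular the concentrations killing 50% and 99%
of the test population (LC50, LC99), or inhibiting oviposition in 50% and
99% of exposed females (OI50, OI99) -- and doing so comparably across many
laboratories.

This package implements that analysis end to end: data QC, a Bayesian
binomial concentration-response model, endpoint inversion, a within-bioassay
variability statistic, multi-laboratory aggregation, and DC derivation,
together with a synthetic campaign generator that provides ground-truth
curves for validation.

## The model

Counts are binomial at the level of one exposure unit (one bottle of one
replicate at one concentration):

$$y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
p_i = D + \frac{A - (D - Z)}{\left[1 + e^{B(\ln x_i - C)}\right]^E},$$

with the asymptotes fixed at $A = 0$, $D = 1$, so

$$p_i = 1 - \frac{1 - Z}{\left[1 + e^{B(\ln x_i - C)}\right]^E}.$$

* $B > 0$ is the slope on the log-concentration scale;
* $C$ locates the curve ($e^C$ is the LC50 when $E = 1$);
* $E > 0$ skews the approach to the upper asymptote;
* $Z \in [0, 1)$ is the background response rate: control bottles
  ($x = 0$) enter the likelihood with $p = Z$, which is the model-based
  analogue of Abbott's control-mortality correction. The fitted curve with
  $Z$ divided out represents insecticide-attributable response, and all
  LC/OI quantiles are defined on that corrected scale:
  $\mathrm{LC}_q = \exp\!\left(C + \ln\!\big[(1-q)^{-1/E} - 1\big]/B\right)$.

Priors are $B \sim N(3,1)$, $C \sim N(3,5)$, $E \sim N(3,5)$,
$Z \sim N(0,5)$. The printed prior forms are unconstrained normals while the
parameters are constrained ($B, E$ strictly positive, $Z$ a probability);
we reconcile the two by truncating each prior to its parameter's support.
The same likelihood serves the oviposition endpoint with $y$ = females not
laying among $n$ = chambered survivors and $Z = 1 - $ (control laying
rate).

Sampling uses JAGS (four chains, 5000 iterations, 50% warm-up). Convergence
is declared when the potential scale reduction factor of every free
parameter is below 1.05 -- the threshold is our choice, as the study design
this follows states only a qualitative convergence requirement -- and a
non-converged first run triggers exactly one refit at 10,000 iterations,
after which the fit is reported with its diagnostics either way. Under a
componentwise slice sampler the $C$--$E$ pair mixes slowly (they trade off
along a ridge whenever the data inform mostly one flank of the curve), so
borderline $\widehat{R}$ values just above 1.05 occur on clean data;
escalation usually, but not always, resolves them. The `converged` flag is
deliberately strict and downstream summaries carry it rather than hiding
it.

## Fitting scopes and uncertainty conventions

One pooled curve is fitted per (institution, species, insecticide) scope to
all accepted bioassays, every exposure record entering as its own data
point. Endpoint point estimates are posterior medians of the per-draw
LC$_q$ (inverting each draw, then summarising, so joint parameter
uncertainty propagates; inverting the median curve instead is a close but
not identical alternative, and per-draw is the default). The uncertainty
range around an institution's estimate is the minimum and maximum of the
per-bioassay posterior-median LC$_q$ -- a deliberate design echo of
multi-centre reporting practice, where between-replicate spread, not the
pooled credible interval, conveys reproducibility. With a single bioassay
the pooled 95% credible interval is substituted and flagged
(`single_curve`). Species-level statistics are the arithmetic mean of
institution values with the envelope (min of lows, max of highs) as range.

## QC rules

Applied per bioassay on controls pooled across the bioassay's control
bottles (per-replicate control rates are not used, mirroring the pooled
mortality definition):

* control mortality $\ge$ 20%: discarded;
* strictly between 5% and 20%: accepted, correction carried by $Z$ in the
  fit (reported `accepted_with_correction`);
* at or below 5%: accepted as is. Exactly 5% is left uncorrected -- the
  band is read literally as open at both ends, and the report's reason text
  records the convention;
* oviposition series: discarded when the control *laying* rate falls below
  30% (the rule is on laying, i.e. one minus the control non-laying
  proportion);
* a bioassay without control rows cannot be evaluated and is excluded as
  `unevaluable` rather than silently accepted.

## Within-bioassay variability

For each retained draw $m$, the deviation
$\frac{1}{I}\sum_i |y_i/n_i - p_i^{(m)}| \times 100$ is computed over the
data points of the scope; the statistic is the median across draws, with
the central 95% of draw deviations as its interval. Across institutions,
the species-level value is the mean, with a min-max interval once more than
one institution contributes. Whether the within-iteration aggregation over
points should be a mean or a median is ambiguous in the source convention;
the mean (an *average* within-bioassay deviation) is the default and a
median mode is exposed via `point_summary`. Deviations are computed on the
raw probability scale, because the fitted $p_i$ includes $Z$ and is
therefore on the same scale as the observed proportions.

## The synthetic campaign generator

`campaign_design()` defaults encode the standard Step-2 layout: six serial
concentrations (default 0.1--30 µg/bottle in half-log steps, the shape of a
ten-fold dilution series bracketing an LC50 of 1), four replicate bottles
of 25 mosquitoes per concentration, two control bottles of 25, and three
bioassays per laboratory, i.e. ~300 mosquitoes per concentration per
laboratory. Outcomes are binomial draws from a known `curve_params` truth;
three optional realism features are:

* **between-replicate overdispersion** -- bottle-level probabilities drawn
  from a beta distribution with mean $p(x)$ and intra-class correlation
  `overdispersion_rho` (a beta-binomial mechanism; the default 0 matches
  the pure-binomial model assumption);
* **between-laboratory heterogeneity** -- independent Gaussian
  perturbations of $(\log B,\ C,\ \mathrm{logit}\, Z)$ with user-set scale
  (`perturb_curves`), reproducing between-laboratory LC spread without
  asserting a cause; $E$ is left shared because the data rarely identify
  its lab-to-lab variation;
* **oviposition campaigns** -- survivors are chambered with probability
  `chambering_rate` (default 0.9, a typical survival to chambering for a
  sterilizing compound at sub-lethal doses) and non-laying counts follow
  the same logistic form with $Z = 1 -$ control laying rate.

Seed discipline: a master seed deterministically yields per-laboratory and
per-bioassay substreams (`sample.int` under the master seed), so campaigns
are byte-reproducible and no global random state leaks.

What the generator does *not* emulate: bottle-coating degradation and
volatility loss, temperature effects, day or operator effects beyond the
symmetric overdispersion, non-logistic curve shapes, and correlation
between mortality and fecundity within a bioassay. Passing recovery tests
on these simulations therefore validates the estimation machinery, not the
biological adequacy of the 5PL form for any particular compound.

## Numerical choices

* The curve is evaluated as $1 - (1-Z)\exp(-E\,\mathrm{log1p}(e^\eta))$
  with a large-$\eta$ guard, so it neither overflows nor loses the upper
  asymptote; inside JAGS the probability is clamped to
  $[10^{-12}, 1-10^{-12}]$ so dispersed initial values cannot render an
  observed count impossible.
* Structurally impossible data ($Z = 0$ with control deaths) yield a
  log-likelihood of $-\infty$ by contract, not an error.
* The grid-posterior oracle enumerates likelihood $\times$ prior over a
  rectangular grid with log-sum-exp rescaling; truncation constants of the
  priors are parameter-free and cancel in the normalisation. It is the
  independent reference for the sampler on reduced models ($E$, $Z$
  fixed), where a 2-D grid is affordable and exact to grid resolution.
* Chain initial values are drawn from the priors (per-chain substreams), so
  the convergence diagnostic sees genuinely dispersed starting points.
* DC reporting rounds to 2 significant figures, the precision at which DCs
  are conventionally published; the LC basis (0.99 by default, 0.999
  optionally) and the multiplier (2) are parameters of `compute_dc`.

## Problem sizes used in the validation suite

The test suite and acceptance analyses run the full default schedule where
the behaviour under study depends on it (parameter recovery over 20 seeded
campaigns, overdispersion contrasts over 10 seed pairs, the escalation
rule), and deliberately smaller schedules (1000--2000 iterations) where the
property under test -- determinism, constraint satisfaction, serialisation
-- is invariant to chain length. Law-of-large-numbers checks of the
generator use $10^6$ mosquitoes per concentration. The acceptance script
analyses a three-laboratory mortality campaign (~5850 mosquitoes) plus a
single-laboratory oviposition campaign at the default design.

## Known limitations

* No hierarchical pooling across laboratories: each institution is fitted
  independently and aggregation is by unweighted means and envelopes.
  Replicate numbers in typical campaigns are too small to identify
  between-laboratory variance components, so a random-effects extension is
  deferred.
* The min-max range convention understates uncertainty when replicate
  fits are few and overstates it under outlier replicates; it is kept for
  comparability with multi-centre reporting practice.
* The binomial likelihood has no overdispersion term; simulated
  overdispersed campaigns therefore inflate the variability statistic
  rather than widening parameter intervals -- which is exactly the
  behaviour the within-bioassay variability statistic is designed to
  surface.
* Componentwise slice sampling converges more slowly than gradient-based
  samplers on this posterior; the escalation rule compensates but strict
  convergence at the 1.05 threshold is not guaranteed on every dataset.
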