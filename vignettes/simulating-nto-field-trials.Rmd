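---
title: "Simulating non-target-organism field trials for prospective power analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating non-target-organism field trials for prospective power analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntopower)
```

## The problem

Environmental risk assessment (ERA) of genetically modified (GM) crops
requires comparative field trials in which counts (or presence/absence) of
non-target organisms — aphids, beetles, parasitoids — are compared between
the GM plant and its conventional comparator, often alongside additional
treatments and a set of reference varieties with a history of safe use.
Two statistical questions are asked of such trials: *is there a
difference?* (difference testing; rejection is proof of difference) and
*is any difference smaller than the limit of concern?* (equivalence
testing by the two one-sided tests / TOST construction; rejection of
non-equivalence is proof of safety). Before a trial is planted one wants
to know the power of both tests at realistic effect sizes — and for
overdispersed, zero-inflated, blocked, repeated-measures count data there
is no usable closed form. `ntopower` answers this with a hierarchical
simulation model plus a Monte-Carlo power engine.

## Count and presence/absence families

The elementary generator is a distribution for one experimental unit.
Counts are Poisson with mean $\mu$ mixed, optionally, with a unit-level
rate variable $Z$:

* **Overdispersed Poisson** — gamma mixing with $\mathrm{var}(Z) =
  (\phi - 1)\mu$, marginal variance $\phi\mu$, $\phi \ge 1$.
* **Negative binomial** — gamma mixing with $\mathrm{var}(Z) =
  \omega\mu^2$, marginal variance $\mu + \omega\mu^2$, $\omega \ge 0$.
* **Poisson-lognormal** — lognormal mixing, equivalent to a normal random
  effect of variance $\sigma^2$ on the log-linear predictor; marginal
  variance $\mu + (e^{\sigma^2} - 1)\mu^2$, i.e. the negative-binomial
  variance function with $\omega = e^{\sigma^2} - 1$. We accept the
  dispersion on either scale (`dispersion_scale`), keeping $\sigma^2$ as
  the canonical internal scale to avoid repeated `log1p` round trips.

Presence/absence responses out of $n$ plants are binomial with success
probability $\pi$, beta-mixed (**beta-binomial**, variance
$n\pi(1-\pi)[1 + (n-1)\varphi]$), or logit-normal-mixed
(**binomial-logitnormal**), whose moments have no closed form and are
evaluated by Gauss–Hermite quadrature. `match_logitnormal()` calibrates
$(\eta, \sigma^2)$ to target moments $n\pi$ and $\omega n\pi(1-\pi)$ by
nested root finding; because the variance of this family is bounded by the
factor $\omega = n$, unreachable targets fail loudly rather than return a
pseudo-solution.

Every family takes a structural-zero probability $\delta$: the
zero-inflated response equals the count with probability $1-\delta$ and
zero otherwise, giving $P(Y=0) = \delta + (1-\delta)P_c(X=0)$. Sampling
applies $\delta$ as an independent Bernoulli mask — simpler than inverting
the mixture CDF and the same law. The degenerate settings $\phi = 1$,
$\omega = 0$, $\sigma^2 = 0$, $\varphi = 0$, $\delta = 0$ all reduce
exactly to the base family instead of erroring; boundary cases are where
sensitivity analyses live.

```{r pmf-example}
dist_pmf(count_dist("poisson", mu = 5, delta = 0.2), 0)   # 0.2 + 0.8 e^-5
dist_moments(count_dist("negbin", mu = 10, dispersion = 0.5))
```

**Quadrature order.** Probabilities of the two log/logit-normal mixtures
integrate the normal random effect with a fixed-order Gauss–Hermite rule,
order 50 by default (configurable). Over the parameter grids exercised in
the tests ($\mu \le 40$, $\omega \le 1$, $n \le 16$) the rule is accurate
to well below $10^{-8}$ once the support is truncated where the tail mass
falls under $10^{-12}$; note the Poisson-lognormal tail is heavy, so
"far enough" can be thousands of counts for large $\mu\omega$.

## The trial hierarchy

All structural effects act additively on the log scale for counts and the
logit scale for probabilities ($\pi$ and $\delta$), which keeps means
positive and probabilities in $(0,1)$. For unit $(i,j,k)$ at time $t$,

$$\log \mu = \underbrace{a_{v(k)}}_{\text{variety}}
 + \underbrace{u_i}_{\text{trial/site/year}}
 + \underbrace{b_{ij}}_{\text{block}}
 + \underbrace{f_p(t)}_{\text{time pattern}}
 + \underbrace{v_t}_{\text{time random effect}}$$

with an entirely parallel predictor for $\operatorname{logit}\delta$; the
count-part and zero-part effects are drawn independently (the worked
example in the package tests draws them separately, and no cross-
correlation parameter is supported).

* **Varieties.** Exactly one GM and one comparator; any number of
  *additional* varieties with fixed effects; *reference* populations whose
  members are drawn from $N(\text{mean}, \text{var})$ — they represent
  natural variation among varieties with a history of safe use. In
  multi-trial settings reference draws are two-stage: a trial-level
  reference mean $M \sim N(m, s_1^2)$ (`ref_trial_var` in
  `trial_structure()`), then member effects $\sim N(M, s_2^2)$
  (`effect_var` in `variety()`); the marginal variance is $s_1^2 + s_2^2$
  by the law of total variance, which the tests verify by simulation. We
  mirror the same two-stage structure for the zero part, the natural
  symmetric choice.
* **Design.** Randomized complete blocks with normal block effects; a
  completely randomized design is the same code path with zero block
  variance and replicates relabelled as plots. All varieties appear in
  every block.
* **Trials.** Unstructured multiple environments (random trial main
  effects) or a site-by-year grid (site, year, and site-by-year
  components). Genotype-by-environment interaction replaces a fixed
  variety effect by a per-trial draw $N(\text{effect}, \text{gxe\_var})$,
  so GM-vs-comparator differences keep a common basis across trials.
* **Repeated measures.** Equidistant time points; the time pattern is
  constant, linear or quadratic on the transformed scale. The quadratic
  uses the peak parameterization
  $f_2(t) = \beta_{\max} - (t - \beta_{\mathrm{opt}})^2 / (2\beta_{\mathrm{tol}})$
  (positive tolerance: maximum; negative: minimum), converted internally
  by `quad_coefficients()`. Coefficients are interpreted on the
  user-facing time labels (e.g. days $-14 \dots 14$), since both
  conventions are common. The correlated random vector
  $v \sim \mathrm{MVN}(0, \sigma_v^2 V)$ supports no extra variability,
  compound symmetry ($V_{kl} = \rho$) and AR1 ($V_{kl} = \rho^{|k-l|}$),
  with the matrix square root taken by eigendecomposition so the singular
  $\rho = 1$ case works. Compound symmetry with $\rho = 0$ on a Poisson
  family is exactly one lognormal mixing layer — i.e. the
  Poisson-lognormal — which the acceptance suite confirms with a
  two-sample test on $10^5$ draws.

Per the published model's own restrictions we keep one dispersion
parameter shared across varieties and trials, equal time dependence across
varieties, and no split-plot randomization; Taylor's power law is a
variance-mean relationship without an associated distribution and is
therefore not a generator.

**Seeding.** `simulate_dataset(scen, seed)` is bit-reproducible;
`simulate_batch()` derives one sub-seed per dataset from the master seed so
the $k$-th dataset is stable across runs. Within a draw, per-variety
effects are realized in sorted-name order, so permuting the variety list
of a scenario leaves the simulated joint law (in fact the realized draws)
unchanged. Zero-variance components are exactly zero and consume no
random numbers.

## Inference layer

The analyses are those used in practice on such trials:

* `fit_count_model()` / `lrt_difference()` — Poisson or negative-binomial
  maximum likelihood with one mean per variety and common dispersion,
  with or without the restriction mean(GM) = mean(comparator); the
  difference test is twice the log-likelihood gap against
  $\chi^2_1$. For group-saturated mean structures the ML means equal the
  group sample means *for any* common dispersion (the score in each mean
  factorises), so the fit reduces to a one-dimensional profile
  maximisation over $\log\omega$ (`optimize`, tolerance $10^{-8}$, search
  interval $\log\omega \in [-30, 10]$) — deterministic, fast, and exact.
  At the boundary $\hat\omega < 10^{-10}$ the Poisson likelihood is used.
  An all-zero variety floors its mean at $10^{-8}$ and flags the fit.
* `quasi_poisson_test()` — the Poisson LRT scaled by the full-model mean
  deviance whenever that exceeds 1. (Pearson-based scaling is the other
  classical choice; the deviance form is the one used by the sensitivity
  analyses this package replicates.)
* `loganova_test()` — ANOVA of $\log(y + 0.5\cdot I[\text{any zero}])$;
  the reported statistic is the GM-vs-comparator contrast *t*-test with
  pooled residual variance rather than the omnibus F, because the power
  question is about that single pairwise difference.
* `profile_ci_ratio()` — the profile-likelihood interval for
  $\theta = \mu_{GM}/\mu_{comp}$, i.e.
  $\{\theta : 2(\hat\ell - \ell(\theta)) \le \chi^2_{1,0.95}\}$. Under
  the Poisson the nuisance mean has the closed-form maximiser
  $(S_C + S_G)/(n_C + \theta n_G)$, so the profile is exact; under the
  negative binomial the nuisance mean and dispersion are profiled
  numerically (Nelder–Mead, relative tolerance $10^{-10}$). Endpoints are
  found by bracketed root search on $\log\theta$ to $10^{-6}$.
* `tost_equivalence()` — non-equivalence is rejected when the interval
  lies strictly inside the limits of concern $(L, U)$. We use a single
  95% interval, the operational TOST at one-sided 2.5%; this is the
  construction that pairs with a plotted 95% interval, and it is mildly
  conservative relative to the 90%-interval TOST at nominal 5%.

Zero-inflated *fitting* is deliberately out of scope: the interesting
question replicated here is what happens when excess-zero data are
analyzed by a plain negative binomial (the dispersion estimate explodes to
absorb the zero spike and power collapses at large means — the acceptance
suite quantifies the drop).

## Power engine

`estimate_power()` simulates `n_sims` datasets at every replication level
of the grid $N = 4, 6, 8, 10, 15, 20, 30, 40$ (the customary grid for
these studies), applies an analysis, and reports rejection fractions with
standard error $\sqrt{p(1-p)/n}$. Common random numbers across $N$ are
not used, mirroring the original studies; analysis failures are excluded
from the denominator and counted. `required_replications()` first applies
isotonic regression (power is monotone in $N$; Monte-Carlo noise need not
be), then interpolates linearly in $N$ and reports the smallest level
reaching the target, rounded to the nearest integer; values outside the
grid are censored and rendered `"<=4"` / `">=40"`. Rounding to nearest —
rather than ceiling — is the rule consistent with interpolating a
discrete published table; at 1000 simulations the two differ by at most
one replicate, inside the tables' own Monte-Carlo uncertainty.

`reproduce_table()` sweeps the three canonical studies: the
negative-binomial difference-test table over $(\omega, \mu)$ at
$\theta = 2$; the Poisson difference/equivalence pair over $(\theta, \mu)$
with limits $(1/2, 2)$; and the repeated-measures equivalence table
(Poisson-lognormal, $\omega = 0.25$, quadratic peak with
$\beta_{\mathrm{opt}} = 0$, $\beta_{\mathrm{tol}} = 47.96$ — i.e. 60% of
the peak at $\pm 7$ days — AR1 $\rho = 0.8$), comparing a single
observation at the peak against summed counts over five sampling dates,
with limits $(1/3, 3)$.

```{r power-example, eval = FALSE}
sc <- single_trial_scenario("negbin", mu = 40, theta = 2, dispersion = 0.25)
pc <- estimate_power(sc, "nb_lrt", n_sims = 1000, seed = 1)
required_replications(pc)   # 9 replicates for 80% power
autoplot(pc)
```

## What the generator does and does not emulate

The synthetic data reproduce the statistical skeleton of ERA field
trials: overdispersion, zero inflation, blocking, environment and G-by-E
variance components, autocorrelated seasonal abundance curves. They do
not emulate spatial correlation between neighbouring plots, measurement
or identification error beyond the stated families, unbalanced or missing
observations, or dispersion heterogeneity across varieties. Passing power
targets on these simulations therefore validates the statistical
machinery under the stated model, not the fit of that model to any
particular field dataset.

## Problem sizes and reproducibility

The default study conditions are the published ones: 1000 simulated
datasets per parameter combination and replication grid point, two-sided
$\alpha = 0.05$, target power 0.80, one additional variety at the
comparator mean. The package's own test suite runs most properties at
500–1000 simulations and verifies Monte-Carlo moment identities at
$10^5$ draws with $4\sigma$ tolerances; `scripts/acceptance.R` recomputes
six required-replication cells at the full 1000 simulations per grid
point. Every stochastic quantity in the package is reproducible from a
single integer seed.
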