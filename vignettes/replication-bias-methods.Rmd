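---
title: "Methods: expected power, posterior probability and publication bias from a replication rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expected power, posterior probability and publication bias from a replication rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubbias)
```

## The model

A body of research is modelled as repeated binary hypothesis testing. A
fraction $\theta$ of tested hypotheses is true a priori. A study testing a
true hypothesis reports a positive (significant) finding with probability
equal to its statistical power $1-\beta$; a study testing a false hypothesis
reports one with probability $\alpha$, its type-1 error rate. Three
identities follow:

$$P_\text{true} = \theta\,(1-\beta), \qquad
  P_\text{false} = \alpha\,(1-\theta), \qquad
  P_\text{total} = \theta\,(1-\beta) + \alpha\,(1-\theta).$$

Bayes' theorem gives the probability that a published positive finding is
true,

$$\hat\theta \;=\; \frac{\theta\,(1-\beta)}{\theta\,(1-\beta) +
  \alpha\,(1-\theta)},$$

and a positive finding replicates in an independent study exactly when that
study comes out positive, so the replication probability is the positive
rate evaluated at the posterior:

$$R \;=\; \hat\theta\,(1-\beta_r) + \alpha_r\,(1-\hat\theta),$$

with subscripts $o$/$r$ separating original from replication studies
($\alpha_o = 0.05$; $\alpha_r = 0.025$ by default, because replications of a
directional finding are in effect one-sided tests run at half the two-sided
level).

Run forwards, these formulas answer "what literature does research with given
$\theta$ and power produce?". The package's main purpose is the inverse
problem: given an *observed* replication rate $R$ (for experimental
psychology, the Open Science Collaboration's estimate $R = 0.36$, $n = 97$,
95% CI 27–46%), solve for the power of the original studies under any
assumed prior, and from it derive the expected rate of positive evidence and
the publication bias needed to turn that rate into the ~90% positive
literature actually observed.

## Variance in power across studies

Treating all studies as sharing one power value is the zero-variance special
case (`solve_naive()`). In general power varies between studies, and because
the posterior is concave in power, variance matters: the package integrates
the posterior over a distribution $f$ of per-study power,

$$E[\hat\theta] = \int \frac{\theta p}{\theta p + \alpha_o (1-\theta)}
  f(p)\,dp, \qquad
  E[R] = E[\hat\theta]\,\bar p_r + \alpha_r\,(1 - E[\hat\theta]),$$

where $\bar p_r$ is the mean replication power implied by the power linkage
(below). `repro_fit()` finds the mean original power $\mu$ at which $E[R]$
equals the observed rate.

### The power scale is floored at $\alpha$

A two-sided test rejects with probability at least its level, so per-study
power cannot fall below $\alpha_o$. The distribution families therefore live
on $[\alpha, 1]$: power $= \alpha + (1-\alpha)X$ with $X$ on $[0,1]$. This
choice is not cosmetic — the bimodal component means used throughout
(`0.145`/`0.905`, and `0.0975`/`0.9525` for the extreme-variance preset) are
exactly the images of $X = 0.10/0.90$ and $X = 0.05/0.95$ under this map,
and with the floor in place the single-shape Beta family at $s = 1/2$
reproduces the variance band ($0.09$–$0.12$ at mean power 30–39%) that
meta-meta-analytic surveys of published literatures report. An unfloored
scale is available via `power_dist(..., floor = 0)`. The point-mass family
carries no floor: it is an atom, not a rescaled density, and the
zero-variance solver must agree with the naive closed form on its full
domain.

### Families and their single shape parameter

$X$ is a point mass, a Beta variable, or a two-component Beta mixture. The
free shape $s$ is attached to the *type-2-error* side: the density of
$1 - X$ has first shape $s$, and its second shape is derived from the mean
(`second_shape()`), so $X \sim \mathrm{Beta}(s\,m/(1-m),\, s)$ at mean $m$.
Mixture components have fixed means; the weight follows from the overall
mean (`mixture_weight()`), and a mean outside the component means is an
infeasibility, not an error. Presets name the standard variance choices:

| preset | family | role |
|---|---|---|
| `zero` | point mass | zero variance |
| `alt_small` | Beta, $s=1$ | smaller alternative variance |
| `likely` | Beta, $s=1/2$ | matches the meta-survey variance band |
| `alt_large` | bimodal, means 0.145/0.905, shapes 1 and 2 | larger alternative variance |
| `extreme` | bimodal, means 0.0975/0.9525, shapes 1 and 1 | extreme variance |

At any fixed mean these are ordered by variance (point $<$ $s{=}1$ $<$
$s{=}1/2$ $<$ bimodal $<$ extreme), which the tests assert across means
0.3–0.7.

### Power linkage

Replication studies in a direct-replication project are designed at least as
large as the originals, so three linkages bracket replication power: equal
to original power (`identical`, lower bound), perfect (`perfect`, upper
bound), and an additive offset (`offset:` $\delta$). The likely range uses
$\delta \in [0.06, 0.10]$ — the power a median-sized replication adds over a
median original for true correlations between 0.2 and 0.4, by the Fisher-z
calculation in `correlation_power()` — with $\delta = 0.08$ as midpoint. The
offset applies to the *solved mean*: $\bar p_r = \mu + \delta$, mirroring
the scalar replication power in the $E[R]$ identity; $\delta$ is not applied
inside the integral. An offset implying $\bar p_r > 1$ makes the scenario
infeasible rather than being clamped.

## Numerical choices

*Quadrature.* Expectations against a Beta component use the
probability-integral substitution $u = F(x)$, turning the integral into a
smooth one on $[0,1]$ evaluated with 512 Gauss–Legendre nodes; the
substitution absorbs the endpoint singularities that shapes below 1 put in
the density. Every expectation is recomputed at 1024 nodes, and if doubling
moves the result by more than $10^{-8}$ the adaptive integrator
(`stats::integrate`, rel. tol. $10^{-10}$) takes over in the same
$u$-domain, where the integrand stays bounded even for near-degenerate
shapes.

*Root-finding.* $E[R]$ is strictly increasing in $\mu$; the solver verifies
the sign pattern on the bracket (and monotonicity on a coarse probe) before
calling Brent's method (`uniroot`, tol. $10^{-12}$). Feasible solutions
reproduce $R$ to $10^{-8}$, which the tests assert. The admissible bracket
is $(\alpha_o, 1]$, clipped by the link ($\mu \le 1-\delta$) and by mixture
component means; the cause of any infeasibility is recorded in the fit.

*Grids.* Sweeps default to 200 log-spaced priors on $[0.025, 0.975]$,
matching the log-scaled prior axis of the standard displays. The bundled
tests run sweeps on 25–60 point grids and the timing check on a 40-point
grid; the Monte-Carlo cross-validation uses $10^6$ studies per cell of a
$3\times 3$ (prior $\times$ distribution) design, and the correlation-power
simulation uses $4\times 10^4$ bivariate-normal samples (Monte-Carlo SE
$\approx 0.002$ against a $\pm 0.02$ tolerance).

*Rounding.* Reported percentages and odds round half-up to the printed
precision (integer percent, integer odds) when compared against published
values.

## Publication bias

If research produces positive findings at rate $P$ but the literature
displays a share $L$ of them, the odds that an observed negative result was
suppressed rather than published are

$$B = \frac{(1-P)/P}{(1-L)/L},$$

i.e. negative evidence is observed $B$ times per negative result published;
$B = 1$ means no suppression, and against the customary $L = 0.9$ the
formula reduces to $9(1-P)/P$. This is an odds rescaling, not a new model:
$P$ comes from the linear identity $P = \theta\mu + \alpha_o(1-\theta)$,
which needs only the mean power because it is linear in $p$.
`studies_needed()` divides a published positive count by $P$ to give the
implied number of studies run. The exact binomial test
(`binomial_bias_test()`) asks whether $k$ of $n$ replications could come
from a literature with reproducibility $p_0$; the only direction of interest
is "less", so the p-value is the lower tail $P(X \le k)$. The default
$k = 35$ is $\mathrm{round}(0.36 \times 97)$, since the replication project
published the rate rather than the count; `k` stays exposed.

## The simulator and what it validates

`simulate_studies()` draws the full process — truth, per-study power,
outcome, publication (negatives thinned by `1/suppression_odds`),
replication — with a documented RNG order (truth uniforms, mixture-component
uniforms then one `rbeta` call, outcome, publication, replication uniforms)
so seeded runs are portable.

One structural point deserves emphasis. $E[\hat\theta]$ above is the
*per-study* (unweighted) expectation of the posterior. A generative
literature, however, shows you positive findings, and conditioning on a
positive finding weights each study by its probability of producing one; the
share of positive findings that are true is therefore the *pooled* posterior
$\theta\mu/(\theta\mu + \alpha_o(1-\theta))$ — the posterior at the mean,
which by Jensen exceeds the mean of the posterior. No generative process can
make its empirical true-positive share converge to $E[\hat\theta]$, so the
simulator carries two prediction sets: `predicted` (pooled posterior,
positive rate, and the replication rate the chosen coupling implies — all
computable by quadrature, and the quantities the empirical rates are tested
against at $3$ binomial SE) and `closed_form` (the per-study expectations
the solver matches to an observed $R$). Keeping both visible quantifies the
gap instead of hiding it.

Replication coupling defaults to mean-field (a scalar replication power at
the linked mean, mirroring the affine $E[R]$ identity). A
`replication = "per_study"` mode couples each study's own drawn power into
its replication; with an additive offset and a continuous power
distribution, some drawn power always exceeds $1-\delta$, and that mode then
errors — the same rule the solver applies to infeasible links.

What the generator does *not* emulate: effect sizes, sample sizes or
p-value distributions (the framework operates on power directly), correlated
repeat observations within a study, or selection on anything other than the
sign of the finding. Passing the simulation cross-checks therefore shows the
closed forms are internally consistent with their own generative reading —
not that real literatures satisfy the model's assumptions.

## Design choices made where the design was open

* **Replication identity as printed, not jointly integrated.** $E[R]$
  multiplies $E[\hat\theta]$ by a scalar replication power. A joint
  integration (replication power varying with the study inside the integral)
  is a different estimand; the simulator's `per_study` mode exposes the
  difference empirically, and the affine form remains the estimator because
  it is the form whose inverse the package exists to compute.
* **One-sided binomial test.** Reproducibility below $p_0$ is the only
  alternative of scientific interest here.
* **Fisher-z for correlation power.** The standard approximation in power
  calculators; it wobbles by about a percentage point against the exact
  noncentral distribution, which is why the 6–10 point offset range is
  carried as a range rather than a point.
* **Presets as first-class values.** The named bands (`likely`,
  `alternative`, `extreme`, `zero_variance`, `outer`) and scenario presets
  (`likely_low` … `outer_upper`) are plain (link, distribution) pairs, so
  any alternative reading costs one constructor call, not a code change.

## Limitations

The method yields expectations after many trials, not credible intervals; it
inherits binary NHST (a hypothesis is true or false); it consumes summary
statistics, not raw study records; and the prior is assumed independent of
power. Sweeps across priors, replication rates and variance assumptions are
the package's substitute for formal uncertainty quantification: the outer
envelope is valid under any variance from zero to extreme and any
replication power between original and perfect.
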