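# pubbias

Expected statistical power, posterior probability and publication bias of a
published literature, inferred from its observed replication rate.

## The problem

Large-scale direct-replication projects give a number the literature itself
never shows: the probability **R** that a published positive finding holds up
in an independent replication (for experimental psychology, the Open Science
Collaboration estimated R = 0.36, n = 97, 95% CI 27–46%). Under binary
null-hypothesis significance testing, Bayes' theorem ties that number to
everything else about the research:

- prior probability **θ** that a tested hypothesis is true,
- statistical power **1−β** of the studies,
- type-1 error rates (α_o = 0.05 originals; α_r = 0.025 replications of a
  directional finding),
- posterior probability **θ̂** of a published positive finding,

via

```
P_total = θ(1−β) + α(1−θ)                        positive-evidence rate
θ̂       = θ(1−β) / [θ(1−β) + α(1−θ)]             posterior (Bayes)
R       = θ̂(1−β_r) + α_r(1−θ̂)                    replication probability
```

Given an observed R and an assumed prior, the package solves these
identities backwards for the expected power of the original studies —
integrating the posterior over a distribution of per-study power, since
power varies between studies and the posterior is concave in it — and then
asks the publication-bias question: research with that power and prior
produces positive findings at rate `P = θμ + α_o(1−θ)`, typically 8–14%, yet
the literature displays ~90% positive findings. The odds that an observed
negative result was suppressed rather than published are
`B = [(1−P)/P] / [(1−L)/L]`, i.e. tens of negative observations per negative
publication.

It is intended for meta-researchers, methodologists and anyone who wants to
turn a replication-project estimate into quantitative statements about
power, truth rates and selection in a literature.

## Worked example

Assume one in ten tested hypotheses was true a priori (θ = 0.1), the
observed replication rate R = 0.36, replication studies 8 points better
powered than originals, and per-study power following the Beta (s = 1/2)
distribution whose variance matches meta-meta-analytic surveys:

```r
library(pubbias)
fit <- repro_fit(theta = 0.1)
fit
#> Replication-rate fit (R = 0.36, theta = 0.1)
#>   link: offset:0.08   power distribution: beta:0.5 (mean 0.594)
#>   expected power, original studies       59.4%
#>   expected power, replication studies    67.4%
#>   expected posterior of findings         51.6%
#>   expected positive-evidence rate        10.4%
#>   bias odds (vs 90% positive literature)   77.2
```

Read: to be consistent with 36% reproducibility, such research would have
had about 59% expected power, its published positive findings would be true
about half the time (the low replication rate is then explained by 67%
replication power, not by mass false positives alone), it would produce
positive evidence in only ~10% of studies — and turning that 10% into a 90%
positive literature requires observing negative evidence ~77 times per
negative result published.

The observed rate is itself strong evidence of bias: in an unbiased
literature with 90% positive findings, reproducibility should be at least
~90%,

```r
binomial_bias_test()
#> Exact binomial test of literature bias
#>   35/97 replicated vs null reproducibility 0.90
#>   one-sided p-value: 7.89e-38
```

Other entry points: `solve_naive()` (zero-variance closed form),
`repro_sweep()` / `envelope()` (bands over a grid of priors, the
machine-readable figures), `feasibility_bound()` (the smallest prior that
does not imply better-than-perfect power), `simulate_studies()` (seeded
generative simulation validating the closed forms), and
`run_figure2()` / `run_figure3()` (CSV sweep tables). A thin command-line
wrapper lives at `inst/cli/pubbias.R`:

```sh
Rscript inst/cli/pubbias.R solve --theta 0.1 --R 0.36 --link offset:0.08 --dist likely
Rscript inst/cli/pubbias.R bias-test --k 35 --n 97 --p0 0.9
```

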