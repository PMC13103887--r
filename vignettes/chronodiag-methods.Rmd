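---
title: "Diagnosing dated phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing dated phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodiag)
```

## The problem

A dated (time-calibrated) phylogeny places every node of a rooted tree at a
calendar date, so that branch lengths are durations in years. In microbial
population genetics such trees are usually obtained by *dating the nodes* of
an undated phylogeny whose branch lengths count substitutions (per genome),
given the known sampling dates of the tips. Every dating method makes
assumptions — a molecular clock model, a tree prior, the absence of
contaminating outliers — and when an assumption fails the resulting dates can
be badly wrong while still looking plausible. `chronodiag` asks the absolute
question: *is there evidence that this particular dated tree should not be
trusted?* It answers it with three complementary diagnostics (outlier
detection, posterior predictive checking, residual analysis), together with
the machinery needed to exercise them end to end: four clock models, a
Bayesian dating engine, a pseudo-posterior sampler for point estimates, and
coalescent simulators.

Throughout, `D` denotes a dated tree with branch durations $d_i$ (years) and
`L` the undated tree with branch substitution counts $l_i$. Branches of `D`
are matched to branches of `L` by the leaf bipartition they induce. The two
branches $a, b$ adjacent to the root of `D` induce the same bipartition and
correspond to a single unrooted branch $x$ of `L`; its substitutions are
divided proportionally to the durations,
$l_a = l_x d_a / (d_a + d_b)$ and $l_b = l_x d_b / (d_a + d_b)$
(a 50/50 split when both durations are zero, a case the definition leaves
open). When the two trees disagree topologically beyond the root we raise an
error rather than guess a partial matching.

## Molecular clock models

The clock model gives the distribution of $l_i$ given $d_i$ and is the basis
of everything else. Four models are provided (`clockModel()`):

| family    | kind                | law |
|-----------|---------------------|-----|
| `poisson` | strict, discrete    | $l \sim \mathrm{Poisson}(d\mu)$ |
| `gamma`   | strict, continuous  | $l \sim \Gamma(\text{shape}=d\mu,\ \text{scale}=1)$ |
| `negbin`  | relaxed, discrete   | $l \sim \mathrm{NegBin}(\text{size}=d\mu/\omega,\ \text{prob}=1/(1+\omega))$ |
| `argamma` | relaxed, continuous | $l \sim \Gamma(\text{shape}=d\mu/(1+\omega),\ \text{scale}=1+\omega)$ |

All four have mean $d\mu$, with $\mu$ the clock rate in substitutions per
year; the variance is $d\mu$ for the strict families and $d\mu(1+\omega)$ for
the relaxed ones, so the additive relaxation parameter $\omega \ge 0$ is an
overdispersion multiplier ($\omega = 0$ recovers the strict model as a
limit). The negative binomial convention above was chosen because it is the
one that reproduces these moments; the package verifies both moments by exact
summation and Monte Carlo in its test suite. A branch of zero duration
carries zero substitutions with probability one. Non-integer substitution
values presented to a discrete family — which arise from the proportional
root split, or from expected-substitution branch lengths — are evaluated
under the moment-matched continuous counterpart.

## Residual analysis

For each branch, the uniform residual is the probability integral transform
$u_i = F_i(l_i) = P(L_i \le l_i \mid d_i)$ under the clock model used for
dating. If the inference is valid, $u_i \sim \mathrm{Uniform}(0,1)$, and the
normal residuals $n_i = \Phi^{-1}(u_i)$ are standard normal — directly
analogous to regression residuals.

For the discrete families the plain transform is not uniform; the standard
remedy is the *randomized* PIT, drawing
$u_i \sim \mathrm{Uniform}(F_i(l_i - 1),\ F_i(l_i))$, an interval whose width
is the probability mass of the observed count. This provably restores exact
uniformity and is what `uniformResiduals()` implements; the randomization is
redrawn independently for every posterior draw. (An alternative convention
writes the interval as $(F(l), F(l+1))$; that interval carries the mass of
$l+1$ and demonstrably fails the calibration the method relies on, which the
test suite checks by simulation, so the mass-of-$l$ interval is used.)
Residuals are clipped to $[10^{-12}, 1-10^{-12}]$ before the normal quantile
transform for numerical safety.

Normality of the residuals is then assessed with the Anderson–Darling
*simple-hypothesis* test — the null is the fully specified Normal(0,1), not
the composite family, which is why Shapiro–Wilk would be the wrong test here.
Testing $n_i$ against Normal(0,1) is exactly equivalent to testing $u_i$
against Uniform(0,1). The p-value uses the asymptotic null distribution of
the statistic (the Marsaglia–Marsaglia series), with no small-sample
correction; its calibration is verified in the tests by simulating the null.
Samples smaller than 8 trigger a warning but are still tested.

A Bayesian dating run yields many posterior draws; `posteriorResidualPvalues()`
repeats the residual analysis per draw (each with its own dates and clock
parameters, capped at 1000 draws, evenly subsampled) and summarizes the
posterior distribution of p-values by its median — which can be read roughly
as a p-value — and the proportion below 0.05.

## Posterior predictive checks

`ppCheck()` simulates undated trees from posterior draws (tree plus clock
parameters, drawn with replacement; a point estimate conditions all
replicates on itself) and compares four branch-length summary statistics of
the observed tree with their simulated distributions: mean, sample variance,
maximum, and stemminess (internal branch length over total branch length;
the root-adjacent branches count as internal when their child is an internal
node, since the definition distinguishes only internal vs total). The sample
variance divisor ($n-1$) is applied identically to observed and simulated
trees, so the choice cannot affect the p-values. Each statistic gets a
two-sided empirical p-value with the add-one rule,
$p = \min\!\big(1,\ 2\min\big(\tfrac{1+\#\{s \le o\}}{S+1},
\tfrac{1+\#\{s \ge o\}}{S+1}\big)\big)$,
which is strictly positive and super-uniform; the default is $S = 1000$
replicates. The four p-values are Benjamini–Hochberg adjusted and the
combined p-value is the minimum adjusted value (a harmonic-mean combination
is available via `combine = "harmonic"`); a combined value below 0.05 is
reported as an issue. Two-sidedness and the add-one correction are design
choices: the alternatives are one-sided or unadjusted counts, and the
two-sided add-one form is the calibrated, conservative default.

## Outlier detection

`rootToTipRegression()` regresses root-to-tip substitution distance on
sampling date; the slope estimates the clock rate and the x-intercept the
root date. `rttEnvelope()` draws, for each tip, the central 95% interval of a
Poisson distribution with mean `slope * (date - xIntercept)` — the envelope
construction is not prescribed anywhere, and Poisson matches the strict-clock
generative model this regression presumes. `dateRandomizationTest()`
permutes the tip dates (without replacement) and compares the observed $R^2$
(slope optionally) with its permutation distribution. `branchOutlierTest()`
computes, for every matched branch, a two-sided tail probability of the
observed substitutions under a fitted clock model,
$p = \min(1, 2\min(P(L \le l), P(L \ge l)))$, adjusts by Benjamini–Hochberg
and flags branches at $q < 0.05$. This tail-probability form is an explicit
stand-in for the per-branch likelihood-distribution comparison popularized by
ML dating tools, whose exact statistic is not public; it has the virtues of
being exact under the model and FDR-controlled.

## Bayesian dating engine

`mcmcDate()` is a deliberately minimal node-dating engine: fixed topology,
constant-size heterochronous coalescent prior on node dates, one of the four
clock models for the substitution counts, and Metropolis–Hastings over the
internal node dates, $\mu$, $\omega$ and the coalescent time scale `Ne` (in
years, i.e. effective size times generation duration). Priors:
$\mu \sim \mathrm{Exp}(\text{mean} = \text{root-to-tip slope})$ (floored at
$10^{-6}$), $\omega \sim \mathrm{Exp}(1)$, and the improper scale prior
$1/N_e$. One iteration is a sweep — every internal node date once in random
order (normal random-walk proposals, rejected when they violate the time
ordering), then each free parameter (multiplicative log-normal walks).
Proposal steps adapt towards 25% acceptance during burn-in only. Defaults:
2000 sweeps, 50% burn-in, retained draws thinned to at most 1000. Any subset
of $\{\mu, \omega, N_e, \text{root date}\}$ can be fixed. The sampler is
validated against a numerical grid posterior on a three-tip tree (total
variation below 0.05) and by parameter-recovery coverage in the test suite.
`dic()` computes the deviance information criterion from the clock
log-likelihood trace, using the variance form
$p_D = \mathrm{var}(\text{deviance})/2$ (the deviance-at-the-mean variant
would need a point estimate that the fixed-topology engine does not
privilege).

Closed forms used throughout: the rate estimator
$\hat\mu = \sum_i l_i / \sum_i d_i$ (`mleMu()`); the coalescent scale
estimator $\hat\alpha = \sum_i k_i(k_i-1)(t_i - t_{i+1}) / (2(n-1))$ over the
inter-event intervals of the lineages-through-time curve (`mleAlpha()`),
which is the exact maximizer of the coalescent likelihood; and the conjugate
posterior $\alpha \sim \mathrm{InvGamma}(n-1,\ W)$ with
$W = \sum_i k_i(k_i-1)(t_i-t_{i+1})/2$ under the improper inverse-gamma prior
(`alphaPosteriorSample()`). The inverse-gamma scale is written here as $W$:
the two printed conventions in the field disagree by the factor that makes
the prior-free estimator $\hat\alpha = W/(n-1)$ the natural center, and only
this parametrization is dimensionally consistent with it; the two-tip closed
form (median $1/\ln 2$ when $W = 1$) pins the choice down in the tests.

## Point estimates and the pseudo-posterior

`mlDate()` produces a point-estimate dated tree by cyclic one-dimensional
optimization of the node dates. Two facts shape its design, both
rediscoverable with this package. First, the *unpenalized* clock likelihood
is maximized by collapsing every low-count branch to zero duration and
inflating the rate — a degenerate overfit; `mlDate()` therefore includes the
coalescent log-density (at its profiled scale) as a penalty by default, and
reaches the unpenalized optimum (`penalized = FALSE`) only by polishing from
the penalized solution. Cyclic ascent from a regression-based start can also
wedge whole subtrees in poor local optima that single-node moves cannot
escape, so the optimization warm-starts from the highest-density draw of a
short MCMC by default. Second, the profile
likelihood over $\mu$ is nearly flat along the ridge where all durations
scale as $1/\mu$ and is only weakly anchored by the spread of tip dates, so
by default the rate is not profiled but fixed at the root-to-tip regression
slope, the standard practice for point-estimate dating.

Residuals computed directly against a point estimate are *underdispersed*:
the fitted durations track $l_i/\hat\mu$ too closely, the signature of
overfitting. The idealized iid case makes this exact: with
$d \sim \Gamma(k, \theta)$ and $l \mid d \sim \mathrm{Poisson}(d\mu)$, the
posterior is $\Gamma(k + l,\ \theta/(1+\theta\mu))$ by conjugacy
(`conjugateToy()`), residuals of $l$ against posterior draws of $d$ are
exactly uniform, and residuals against $\hat d = l/\mu$ are visibly
underdispersed. `pseudoPosterior()` transfers this reasoning to trees: the
point-estimate tree is rescaled to substitution units ($d_i \hat\mu$, floored
at $10^{-3}$ to keep the continuous likelihood proper), and a short MCMC is
run over node dates only, under the continuous strict clock, with the rate
fixed at $\hat\mu$ (by default the $\sum l/\sum d$ estimator on the point
tree, which is the rate the tree itself is consistent with — an externally
supplied rate that disagrees with the tree systematically shifts all
residuals and destroys the calibration) and the coalescent scale fixed at
$\hat\alpha$. Residuals are then computed per pseudo-draw exactly as in the
Bayesian case, using the clock family of the original dating. The default
chain length (3000 sweeps) errs long: an under-mixed pseudo-posterior stays
too close to the overfitted point estimate and pushes p-values down.

## Simulators

All test data are generated internally. `simCoalescent()` implements the
standard backward-in-time heterochronous coalescent with constant scale
`ne`: with $k$ active lineages the next coalescence is exponential with rate
$k(k-1)/(2N_e)$, interleaved with sampling events. `simCoalescentNt()`
generalizes to a time-varying $N(t)$ by time rescaling, accumulating the
integrated rate backwards with trapezoid steps (default step: span/1000) and
bisecting at the crossing; `logisticTrajectory()` supplies the clonal
expansion law $N(t) = M (t-s)^2 / (h^2 + (t-s)^2)$ for $t \ge s$ (zero
before $s$, half of the carrying capacity $M$ at $s + h$), whose
non-integrable divergence at $s$ guarantees all component lineages coalesce
after the expansion started. `simStructured()` simulates several components
independently and joins their root lineages at specified divergence dates —
an explicit, simple stand-in for a full structured-coalescent simulation,
sufficient to reproduce the confounding phenomenon. `injectOutliers()` adds a
fixed number of substitutions to selected terminal branches.

`simulateDataset()` bundles the study scenarios. The default conditions are
100 tips sampled uniformly over 2010–2020 with $N_e g = 1$ year and
$\mu = 10$ substitutions per year (strict), $\omega = 5$ for the relaxed
variant — small enough in expected counts that discreteness matters, large
enough that diagnostics have power. The structured scenario uses three
components of equal size, each sampled in a single year (2000, 2010, 2020) —
the reading of "sampled in three different years" that creates the
date–structure association driving confounding — with logistic trajectories
($M = 10$, $h = 5$, onset 30 years before each component's sampling year)
joined at 1965 and 1946, so the true root sits in 1946 while the
date–structure association pulls the apparent root decades later. The exact
component layout is not prescribed anywhere; these values reproduce the
qualitative confounding (inflated regression slope, far-too-recent apparent
root) in a substantial fraction of replicates without fine tuning.

What the simulations do *not* emulate: real genomes have finite sites,
recombination, sequencing error and non-coalescent demographic structure.
Passing diagnostics on these simulations shows the methods are calibrated and
powerful under their own assumptions; it does not certify behaviour on data
violating the infinite-sites assumption (very high rates, very deep
ancestors) or with recombination, which distorts branch lengths in ways only
partially captured by the relaxed clock.

## Numerical choices and problem sizes

Uniform residuals are clipped at $10^{-12}$; discrete CDFs evaluate
$P(L \le \lfloor l \rfloor)$; time-rescaling inversion bisects to $10^{-10}$;
the MCMC recomputes its cached clock likelihood every 200 sweeps to cancel
floating-point drift; zero-duration root splits fall back to 50/50. The
replicate studies in the test suite are run at reduced sizes chosen to keep
the full suite fast while leaving each check well powered — e.g. 20
replicates of 40–50 tips for false-positive and coverage studies, with
single full-size (100-tip) datasets for the headline calibration and power
checks; the acceptance script runs the full-size analyses. The
deep-tree point-estimate illustration uses 100 tips sampled 1980–2020 with
$N_e g = 5$ years (root around the early 1970s), the geometry in which
point-estimate dating is practically used and in which the regression slope
is a precise rate estimate.

## Known limitations

- The dating engine fixes the topology and the root; it will not detect a
  wrong root, only the damage a wrong root does to the fit.
- The coalescent prior is constant-size only; strong demographic structure
  appears as misfit (by design — that is what the diagnostics are for).
- The pseudo-posterior is an approximation without full theoretical
  justification; it is validated empirically against full posteriors.
- P-values from the posterior distribution of residual p-values are
  summaries, not frequentist error rates; the median is interpretable as a
  p-value only informally.
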