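---
title: "Flexible Bayesian latent class analysis: model, priors, and Monte Carlo design"
author: "flexlca authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible Bayesian latent class analysis: model, priors, and Monte Carlo design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Classical latent class analysis (LCA) for binary items assumes *conditional
independence*: given class membership, the indicators are uncorrelated.
`flexlca` relaxes this to *approximate independence*. Each class $m$ has a
latent multivariate normal response

$$Y^* \mid X = m \sim N(\mu_m, \Sigma_m), \qquad y_j = \mathbf{1}[y_j^* \ge 0],$$

so the endorsement probability of item $j$ in class $m$ is $\Phi(\mu_{jm})$
and the off-diagonal entries of the correlation matrix $\Sigma_m$ are the
within-class tetrachoric correlations. Instead of fixing these correlations
to zero, they receive a zero-mean prior whose variance is chosen by the
analyst: small variance recovers (approximately) the classical model, large
variance lets residual dependence be detected and estimated.

A note on the probit sign convention: the latent response is dichotomized
at zero with $y = 1$ on the non-negative side, so $P(y_j = 1 \mid X = m) =
\Phi(\mu_{jm})$ and $\mu = +1$ describes a high-endorsement class. This is
the only convention under which thresholds of $+1$ and $-1$ produce a
class separation of two latent standard deviations.

## The prior ladder

The prior on each class's latent covariance is inverse-Wishart $IW(I, f)$
with an identity scale matrix. Standardizing a draw to a correlation matrix
induces, on every off-diagonal correlation, the symmetric distribution
$r = 2B - 1$ with $B \sim \mathrm{Beta}(s, s)$, $s = (f - J + 1)/2$, hence

$$\operatorname{Var}(r) = \frac{1}{f - J + 2}.$$

At $f = J + 1$ the marginal is exactly uniform on $(-1, 1)$. The package
ships a frozen five-rung ladder for $J = 10$ items (see `prior_ladder()`):

| name | `iw_df` | variance | 95% halfwidth (normal approx.) |
|---|---|---|---|
| strongly informative | 33341 | 3.0e-5 | ±0.011 |
| informative | 408 | 0.0025 | ±0.098 |
| weakly informative | 108 | 0.0100 | ±0.196 |
| weakly non-informative | 52 | 0.0227 | ±0.295 |
| strongly non-informative | 11 | 0.3333 | ±1.132 |

Two design decisions are worth recording. First, the strongly informative
rung is *defined by its variance* (3e-5, i.e. 95% of prior mass within
about ±0.01), and its degrees of freedom are derived from the variance via
`iw_df_for_variance()`; the variance is what drives every downstream
result, and a user who wants to pin the degrees of freedom instead can pass
`prior_spec(n_items, iw_df = ...)` directly. Second, the ladder reports two
95% interval half-widths: the conventional normal approximation
$1.96\sqrt{v}$ (which exceeds the support for the uniform rung, ±1.13) and
the exact symmetric-beta quantile (±0.95 for the uniform rung). Both are
exposed because the normal approximation is the one commonly quoted.

Remaining prior components follow common software defaults and are not the
object of study: thresholds $\mu_{jm} \sim N(0, 5)$ on the standardized
probit scale, class proportions $q \sim \mathrm{Dirichlet}(10, 10)$.

## The sampler

`fit_blca()` runs a data-augmented Gibbs sampler for the multivariate
probit mixture. A sweep updates

1. the latent responses $y^*_{ij}$ by systematic-scan univariate truncated
   normal conditionals (one pass per sub-iteration), using a numerically
   stable tail sampler (normal rejection in the bulk, translated
   exponential rejection in the tail);
2. class memberships from the categorical full conditional
   $\propto q_m\, \phi(Y_i^*; \mu_m, W_m)$;
3. class proportions from the conjugate Dirichlet;
4. thresholds from the conjugate multivariate normal;
5. each class's latent covariance from the conjugate inverse-Wishart
   $W_m \mid \cdot \sim IW(I + S_m, f + n_m)$, where $S_m$ is the centered
   cross-product of the class's latent responses;
6. a Metropolis "group move" along the non-identified scale direction
   $(W, \mu, y^*) \to (sW, \sqrt{s}\,\mu, \sqrt{s}\,y^*)$, whose
   closed-form target (a generalized inverse-Gaussian) follows from the
   prior terms alone.

### Why the latent covariance is *not* standardized inside the chain

Only the correlations and standardized thresholds $\mu_{jm}/\sqrt{W_{jj,m}}$
are identified by binary data; the latent variances are free. This freedom
is essential, not a nuisance: if the chain is forced onto the unit-variance
section (sampling latents from the standardized correlation matrix), the
conjugate update sees $S_m \approx n_m \hat R$, which swamps the identity
prior scale, and the degrees of freedom $f$ lose all influence on the
posterior — every prior rung then returns the empirical tetrachoric
correlation. Keeping $W_m$ as the state lets the latent scale adapt to the
prior ($W \approx I/(f - J - 1)$ a priori), which is precisely what makes
$f$ act on the identified correlations, with posterior centre approximately
$\hat\rho\, n_m / (n_m + f - J - 1)$ — linear shrinkage controlled by the
prior. The sampler *stores* only identified quantities: standardized
thresholds and correlations, relabeled per draw so class 1 is the
high-endorsement class (unambiguous at the two-standard-deviation class
separation studied here). In prior-only mode (zero rows of data) the stored
correlations are exactly standardized $IW(I, f)$ draws, which pins the
realized prior against the closed form; this equivalence is asserted in the
test suite.

The threshold prior is stated on the standardized probit scale; internally
it is mapped to the raw latent scale with the prior's equilibrium variance
factor so conjugacy is retained exactly. Chains start from a total-score
split of the units with probit-transformed class item means, jittered per
chain, rather than from uniformly random memberships: with free
correlation matrices the model admits a spurious mode in which one diffuse,
strongly correlated class absorbs the whole sample, and symmetric random
starts frequently fall into its basin; the jittered data-informed starts
remain overdispersed (the Gelman-Rubin diagnostic retains its meaning)
while starting the chains in the basin of the mixture mode.

### Mixing and the `n_inner` knob

The conjugate covariance update inherits autocorrelation roughly
$n_m/(n_m + f - J - 1)$ from the latent responses: under weak priors (small
$f$) correlation parameters mix slowly — an intrinsic property of probit
data augmentation, since binary data constrain the latent field only
through its signs. `mcmc_config(n_inner = NULL)` therefore advances the
coupled (latent response, covariance) pair one extra sub-iteration per
sweep when this ratio is large (two sub-iterations above 0.8). This
matters mainly for the uniform rung; with informative priors the
correlation posterior is close to the prior and mixes essentially
independently. Even so, at 2 chains × 2,000 iterations the worst
correlation parameters under the uniform prior reach potential scale
reduction (PSR) values of roughly 1.1–1.4 in some replications; runs an
order of magnitude longer (the full-scale design uses 50,000 iterations)
bring them below the 1.05 cut. Convergence summaries at short desk-scale
chain lengths should be read with that in mind; this is a known limitation
of the sampler at small $f$, reported honestly by the convergence rate.

Point estimates are posterior medians of the pooled post-burn-in chains
(first half of each chain discarded); the PSR is the classical
between/within-chain variance ratio on the retained draws, floored at 1,
and a fit "converges" when every scalar parameter (proportions, thresholds,
correlations) has PSR below `psr_threshold` (default 1.05, the common software choice; configurable).

## Posterior predictive model checking

`compute_ppp()` implements the posterior predictive p-value with the
likelihood-ratio chi-square over full response patterns,

$$D(Y; \theta) = 2 \sum_{c\,:\,n_c > 0} n_c \log \frac{n_c}{N \pi_c(\theta)},$$

comparing the observed discrepancy with that of a replicated dataset of the
same size at each of 100 evenly spaced post-burn-in draws;
$\mathrm{PPP} = \Pr(D_\text{rep} \ge D_\text{obs})$, with values near 0.5
indicating good fit.

The model-implied pattern probabilities $\pi_c(\theta)$ are mixtures of
multivariate normal orthant probabilities. Two estimators are provided.
The default (`method = "simulation"`) simulates 30,000 latent response
vectors per draw and tabulates all $2^J$ patterns at once, with a symmetric
smoothing count of 0.5 per cell so no observed pattern has estimated
probability zero; the same estimate is used for the observed and the
replicated discrepancy, preserving their exchangeability under the model,
and the Monte Carlo noise largely cancels in the comparison. The
alternative (`method = "orthant"`, also behind `mvn_orthant()` and
`pattern_probabilities()`) evaluates each orthant by quasi-Monte Carlo
sequential conditioning on a randomly shifted square-root lattice; it is
deterministic to about 1e-4 at a few thousand lattice points and anchors
the simulation estimator in the test suite, but costs roughly a third of a
second per draw at $J = 10$ and is therefore not the default inside the
Monte Carlo study. Beyond 15 items full-pattern enumeration is refused and
a margin-based discrepancy (univariate plus bivariate Pearson chi-squares)
takes over with a message.

Classification entropy is computed at the posterior medians from the
pattern probabilities, scaled so 1 means perfect assignment; a single-class
model reports 1 by convention.

## The synthetic population and the study harness

`build_population(corr_size)` reconstructs the two-class study population:
equal class sizes, ten binary items, thresholds $+1$ (class 1) and $-1$
(class 2), and conditional dependence injected at pairs (1,2), (3,9), (5,7)
in class 1 and (4,6) in class 2, all at a common size 0, 0.20, 0.50 or
0.80. What this generator emulates is exactly this study design — and
nothing more: it has no missing data, no polytomous items, no covariates,
equal thresholds within class, and at most mild dependence sparsity.
Passing tests therefore demonstrate correct behavior under these
conditions, not robustness to the messier features of real survey data.

`run_study()` executes a condition grid with per-replication seeds derived
deterministically from the master seed and the cell coordinates, so every
cell is independently reproducible and results are independent of
execution order; finished cells can be checkpointed as CSV and are skipped
on re-run. Aggregation produces the study's summary outputs: %
significant per monitored pair (Type I error at true zero, power
otherwise), mean PPP, mean posterior-median estimates for the bias table
trio (pairs (1,2), (1,3), (3,8) in class 1), convergence rate, and the
$\eta^2$ decomposition of replication-level PPP over the factors sample
size (N), correlation size (C) and prior variance (P) from a full-factorial
fixed-effects ANOVA (`stats::aov` on the balanced grid).

Desk-scale defaults are 50 replications per cell, 2 chains × 2,000
iterations, and a three-point sample-size grid {100, 500, 1000}; the full-scale
design (400 cells × 200 replications × 50,000 iterations) is
available behind `flexlca study --full` but is cluster work. The bias
table aggregates over whichever sample sizes the study actually ran and
records them in an attribute, making the aggregation set explicit.

## Numerical choices and degenerate inputs

* Truncated normal sampling switches to the translated-exponential tail
  sampler at standardized truncation point 0.45, keeping bounded expected
  cost for extreme thresholds.
* Inverse-Wishart draws use the Bartlett decomposition with triangular
  solves only; draws that fail a Cholesky positive-definiteness check are
  redrawn and counted.
* An emptied class (50+ consecutive iterations) raises a warning but
  sampling continues — the Dirichlet prior keeps the proportions proper.
* Equal-tailed credible intervals use `stats::quantile` type 7; a
  correlation is "significant" at level $\alpha$ when its $1 - \alpha$
  interval excludes zero (the equivalent of the two-tailed posterior
  decision rule common in commercial software).
* Underidentified requests (more free parameters than response-pattern
  degrees of freedom, e.g. two classes with two items) are refused with an
  explanatory error.
* All randomness flows through R's RNG; `set.seed` plus the configuration
  seed make fits, studies and the command-line tools bit-reproducible.

## Problem sizes used by the shipped checks

The package's own test suite runs the study conditions at reduced
replication counts (25–50 replications for rate and mean targets, 8 per
rung for monotonicity patterns, a 4-cell × 20-replication smoke grid for
convergence), with 2 chains × 2,000 iterations throughout; the acceptance
script uses 100 replications for the error-rate and power conditions. The
reduced grid for the PPP variance decomposition spans the full dependence
range (correlation sizes 0, 0.5, 0.8 and three prior rungs at two sample
sizes): the dominance of the correlation-size factor is a property of the
full 0–0.8 range, and a grid truncated at moderate dependence would
understate it.
These counts are the package's choice of desk scale; the study's effect
directions are stable at this scale, while precise estimates of every
aggregate require the full-scale design.

## Known limitations

* Under the uniform correlation prior the correlation parameters mix
  slowly (see above); convergence rates at short chain lengths
  under-report what longer chains achieve.
* The PPP's simulation estimator introduces Monte Carlo noise of a few
  hundredths into individual PPP values; averaged over replications this
  is negligible relative to the between-replication spread.
* Polytomous indicators, missing data, covariates, asymmetric priors on
  correlations, and information-criterion model comparison are out of
  scope.
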