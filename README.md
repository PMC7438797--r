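# flexlca

Flexible Bayesian latent class analysis (LCA) for binary indicators that
replaces the exact conditional-independence assumption with **approximate
independence**: the tetrachoric correlations among indicators within each
latent class are estimated freely under zero-mean priors of chosen
variance, so residual dependence can be *detected* instead of assumed
away. The package is aimed at methodologists and applied researchers in
psychology, epidemiology and the social sciences who fit latent class
models to questionnaire-style binary data and want to check — or relax —
local independence.

## The model

Each unit belongs to one of $M$ latent classes; given class $m$, a latent
response vector follows

$$Y^* \mid X = m \sim N(\mu_m, \Sigma_m), \qquad y_j = \mathbf{1}[y^*_j \ge 0],$$

so item $j$ is endorsed with probability $\Phi(\mu_{jm})$ and the
off-diagonal entries of the correlation matrix $\Sigma_m$ are within-class
tetrachoric correlations. Each class's latent covariance gets an
inverse-Wishart prior $IW(I, f)$; standardizing induces on every
correlation a symmetric distribution on $(-1, 1)$ with mean zero and
variance $1/(f - J + 2)$ — a prior "ladder" from strongly informative
(variance 3e-5, correlations pinned near zero) to strongly non-informative
($f = J + 1$, uniform on $(-1,1)$). Estimation is by a data-augmented
Gibbs sampler (RcppArmadillo); model fit is checked with the posterior
predictive p-value (PPP) based on the likelihood-ratio chi-square over
response patterns, and convergence with the Gelman-Rubin potential scale
reduction (PSR). A Monte Carlo study harness reproduces, at desk scale,
the Type I error / power / model-fit / bias behavior of the approach
across the prior ladder.

## Worked example

```r
library(flexlca)

pop  <- build_population(corr_size = 0.5)      # two classes, 10 items,
                                               # rho = 0.5 at (1,2), (3,9), (5,7) / (4,6)
dat  <- generate_dataset(pop, n = 500, seed = 42)
fit  <- fit_blca(dat, n_classes = 2,
                 prior  = prior_from_ladder("weakly informative"),
                 config = mcmc_config(seed = 7))
s <- summary(fit, data = dat)
s
#> flexlca summary: M = 2 , J = 10 , N = 500
#>   convergence: max PSR = 1.028 (converged)
#>   posterior predictive p-value: 0.05
#>   classification entropy: 0.952
#>   significant correlations (95% CI excludes 0): 4
#>     rho[1,1,2]
#>     rho[1,3,9]
#>     rho[1,5,7]
#>     rho[2,4,6]

test_correlation_significance(fit, class_index = 1, pair = c(1, 2))
#> [1] TRUE
#> attr(,"interval")
#> [1] 0.08091694 0.38092831
#> attr(,"median")
#> [1] 0.2356202
```

Reading the output: both chains pass the Gelman-Rubin cut (max PSR 1.03 <
1.05); the four truly dependent item pairs — and only those — have 95%
credible intervals excluding zero; the posterior median for the (1,2)
correlation is 0.24, i.e. the true 0.5 shrunk toward the zero-mean prior
by roughly $n_1/(n_1 + f - J - 1) \approx 0.7$ at this prior
(`weakly informative` = variance 0.01, $f = 108$); and the PPP of 0.05
flags the misfit that imposing approximate independence on substantially
dependent data produces. With the strongly non-informative prior the same
data give a median near 0.5 and a PPP near 0.5; with the strongly
informative prior the correlation is pinned at zero and the PPP collapses
— the trade-off the prior ladder is designed to explore. `prior_ladder()`
prints the five rungs with their variances and 95% limits.

The simulation harness runs the full factorial study design at a chosen scale:

```r
grid  <- condition_grid(sample_sizes = c(100, 500), corr_sizes = c(0, 0.5),
                        priors = c("weakly informative", "strongly non-informative"),
                        n_replications = 10, master_seed = 1)
study <- run_study(grid)
study$cells          # % significant, mean PPP, convergence rate per cell
bias_table(study)    # mean estimates of the monitored true-zero trio
eta_squared(study)   # PPP variance decomposition over N, C, P
```

A thin command-line tool wraps the same functions (installed under the
package's `exec/` directory; put it on your PATH or call it as
`"$(Rscript -e 'cat(system.file("exec", "flexlca", package = "flexlca"))')"`):

```sh
flexlca priors --df 11 --items 10      # induced marginal prior report
flexlca simulate --corr 0.5 --n 500 --seed 1 --out data/example
flexlca fit --data data/example.csv --prior "weakly informative" --out out/fit
flexlca study --sizes 100,500 --reps 10 --out study_out
```

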