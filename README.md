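# pbclk

Estimating the **absolute probability of species presence** from
presence-background data.

## The problem

Presence-background (PB) data — a list of sites where a species was
observed plus a background sample of unlabelled sites — are the most
plentiful kind of occurrence data in species distribution modelling, but
they identify the probability of presence $\Pr(y=1\mid x)$ only up to an
unknown multiplicative constant.  The popular LK estimator maximizes the
partial likelihood

$$L(\beta) = \sum_{x\in P}\ln p(x;\beta) - n_1\,\ln\Big(\tfrac{1}{n_0}\sum_{x\in B}p(x;\beta)\Big),$$

which is *exactly* invariant to rescaling $p$, so it identifies the scale
only through the curvature of the assumed parametric family — and fails,
sometimes spectacularly, when that assumption carries no information.

`pbclk` implements the constrained alternative: maximize the same
likelihood subject to the background mean of the fitted probabilities
equalling a prevalence $\pi_0$ (**CLK**), and — the centrepiece — a
**refined CLK** pipeline that estimates $\pi_0$ from the data themselves:

1. train a classifier for the sample-membership probability
   $\Pr(s=1\mid x)$ on the pooled presence/background rows;
2. aggregate the top-ranked scores into an estimate of the labelling
   frequency $c$, and convert it to a prevalence
   $\hat\pi = q\,(p_1/n_0)\,(1-\hat c)/\hat c$, where $q$ is the known
   probability of presence at the best sites (**local certainty** $q=1$,
   or partial **local knowledge** $q<1$);
3. fit CLK with $\pi_0=\hat\pi$.

The package ships the full simulation laboratory around these estimators:
a catalogue of 13 generating probability functions (logistic, exponential,
cloglog links; including the classic full/scaled logistic pair that defeats
LK), a presence-background simulator with latent truth retained, and an
experiment engine measuring RMSE curves and nonconvergence rates over
replicates.

Audience: quantitative ecologists and statisticians working with
presence-only/use-availability data, and anyone studying class-prior
estimation in positive-unlabelled learning.

## Worked example

```r
library(pbclk)

m <- catalog_model("cat1_linear")       # truth: 1/(1+exp(-0.606+3.64x)) on [-1,1]
d <- simulate_pb(m, n1 = 1000, n0 = 10000, seed = 42)
print(d)
#> Presence-background dataset: n1 = 1000 , n0 = 10000 , d = 1
#>   latent truth kept: p2 = 5797 (implied c = 0.1471)

true_prevalence(m)
#> [1] 0.5787389

rf <- fit_refined_clk(d, fit_family("logistic", 1),
                      lkn = local_knowledge(q = 1),
                      classifier = classifier_config(seed = 3), seed = 11)
print(rf)
#> Refined CLK fit
#> Prevalence estimate: pi_hat = 0.5727 (c_hat = 0.1487, q = 1)
#> CLK fit (logistic link, degree 1)
#>   beta      = -0.488649, 3.11415
#>   loglik    = 180.8262
#>   converged = TRUE  (grad_norm 8.48e-09)
#>   constraint: pi0 = 0.572717, residual 0.00e+00

rmse_curve(rf, m)
#> [1] 0.02702183
```

Reading the output: the classifier puts the membership probability at the
top-decile sites at $\hat c = 0.1487$ (the implied truth is 0.1471), which
converts to a prevalence estimate of 0.573 against a true 0.579; the
constrained fit then recovers the generating curve to RMSE 0.027 while
satisfying its prevalence constraint to machine precision.  An
unconstrained LK fit on the same dataset reaches RMSE 0.062.

A command-line interface covers the same pipeline
(`inst/scripts/pbclk`): `simulate`, `fit-lk`, `fit-clk`, `fit-refined`,
`prevalence`, `replicate`, `report`, `catalog`.

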