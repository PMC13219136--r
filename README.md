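# robez — robust hierarchical Bayesian EZ-diffusion modeling

`robez` is an R package for fitting the hierarchical Bayesian EZ-diffusion
model to two-choice response-time (RT) data, and for studying what happens
to it when the data contain contaminant trials.

The EZ-diffusion model maps three summary statistics of a cell of trials —
accuracy rate *P<sub>c</sub>*, mean RT, RT variance — to the three Wiener
diffusion parameters (drift rate ν, boundary separation α, non-decision
time τ) in closed form; with *k* = αν/*s*²:

> *P<sub>c</sub>* = 1/(1+e<sup>−k</sup>),
> MRT = τ + (α/2ν)(2*P<sub>c</sub>*−1),
> VRT = (α*s*²/ν³)(*P<sub>c</sub>* − ½ − k *P<sub>c</sub>*(1−*P<sub>c</sub>*)).

Embedding the *sampling distributions* of these statistics as a proxy
likelihood turns the point estimator into a hierarchical Bayesian model with
a within-subject meta-regression on drift, ν<sub>p,k</sub> ~ N(μ<sub>ν</sub>
+ β X<sub>k</sub>, σ²<sub>ν</sub>), where β — the condition effect — is the
parameter under test. Because sample means and variances break down under a
single aberrant trial, the package also implements a **robust variant** that
substitutes the median for the mean and the interquartile-range variance
estimate

> Var<sub>IQR</sub> = ((Q₃ − Q₁)/1.349)²

for the variance, leaving the proxy-likelihood structure unchanged. The
package provides the full validation pipeline: closed-form forward/inverse
moment equations, trial-level Wiener sampling (Rcpp), a hierarchical
two-condition data generator with a delayed-startup/guess contaminant
mixture, JAGS-based inference, ROC/AUC + RMSE/bias evaluation, and a
factorial simulation-study runner with a CLI (`exec/robez`).

## Worked example

Forward and inverse EZ equations are exact inverses:

```r
library(robez)
p <- ddm_params(nu = 1, alpha = 2, tau = 0.3)
m <- forward_moments(p)
unlist(m)
#>        pc       mrt       vrt
#> 0.8807971 1.0615942 0.3416198
unlist(inverse_ez(m$pc, m$mrt, m$vrt)[1:3])
#>    nu alpha   tau
#>   1.0   2.0   0.3
```

Generate a two-condition hierarchical dataset under a high-drift regime
(true β = 0.4), contaminate 5% of each participant's trials, and fit both
summary methods to the *contaminated* data:

```r
set.seed(3)
pop <- draw_population("high-nu/low-alpha", beta = 0.4)
ind <- draw_individuals(pop, P = 40)
clean <- generate_dataset(ind, T = 40)
contam <- contaminate(clean, ind, rate = 0.05)
table(contam$contaminant)
#> delayed   guess    none
#>      69      91    3040

for (meth in c("standard", "robust")) {
  cells <- summarize_dataset(contam, method = meth, rt_scope = "all")
  ft <- fit_model(build_model(cells, model_spec(method = meth, rt_scope = "all")),
                  mcmc_control(chains = 2, adapt = 300, warmup = 300, draws = 500),
                  seed = 7)
  cat(sprintf("%-8s beta = %.3f (sd %.3f), z = %.2f\n", meth,
              ft$beta_mean, ft$beta_sd, decision_statistic(ft, "z_abs")))
}
#> standard beta = 0.022 (sd 0.098), z = 0.22
#> robust   beta = 0.299 (sd 0.172), z = 1.74
```

The 5% contamination (160 of 3200 trials) drags the standard fit's effect
size nearly to zero — delayed startups inflate the mean and variance, which
the model reconciles by lowering drift — while the robust fit stays near the
generating β = 0.4. On clean data the two methods agree (see the tests and
the methods vignette). `run_study()` scales this comparison over a factorial
grid of participant counts, trial counts and effect sizes, aggregating AUC,
RMSE and bias per design cell.

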