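# mixboost

Searching for interaction effects among many correlated exposures --
environmental contaminant mixtures measured in a cohort, typically --
with stochastic gradient boosted regression trees.  Instead of guessing
which product terms to put into a regression, `mixboost` fits a flexible
tree ensemble and then asks, for any subset of exposures, how much of
their joint fitted effect is non-additive, using the Friedman--Popescu
H statistic

```
H²(j,k) = Σᵢ [F̂ⱼₖ(xᵢⱼ, xᵢₖ) − F̂ⱼ(xᵢⱼ) − F̂ₖ(xᵢₖ)]² / Σᵢ F̂ⱼₖ²(xᵢⱼ, xᵢₖ)
```

where the `F̂`s are centered partial-dependence functions of the
ensemble.  H runs from 0 (additive) to 1 (pure interaction), extends to
three- and four-way subsets by inclusion--exclusion, and -- crucially --
is calibrated against a parametric-bootstrap null: artificial outcomes
`ỹᵢ = F_A(xᵢ) + y_p(i) − F_A(x_p(i))` (additive fit `F_A` plus permuted
residuals) are refit with the full model to show how large H gets when
no interaction exists at all.  Detection = observed H above the null's
95th percentile; repeated split-sample validation grades how stable each
detection is.  The package is aimed at epidemiologists and
toxicologists screening mixtures for synergism/antagonism and at
methodologists studying interaction detection; its output is a ranked
shortlist of plausible interactions for follow-up, not confirmatory
p-values.

It includes:

* `gbt()` -- stochastic gradient boosting with best-first regression
  trees (squared or absolute loss), an Rcpp core, staged prediction,
  and split-improvement variable importance (`relative_influence()`);
* `partial_dependence()` -- exact recursion-based partial dependence
  (verified against the brute-force definition to 1e-8);
* `h_stat()`, `h_null()`, `split_stability()` -- the interaction
  machinery;
* `tune_gbt()` -- bootstrap grid tuning with the one-standard-error
  rule;
* `simulate_mixture()` -- a 27-contaminant log-normal panel (correlated
  PCB block, binary sex) whose outcome hides a four-way interaction, a
  sinusoidal non-linearity and a BPA-by-sex interaction at configurable
  signal-to-noise ratios;
* `power_boosted()` / `power_parametric()` -- a power benchmark of the
  H rule against FDR-screened product-term regression;
* `run_workflow()` and a thin CLI (`inst/cli/mixboost.R`) tying the
  steps together with manifests and figures.

## Worked example

Simulate the mixture panel at a strong signal-to-noise ratio, fit the
ensemble, rank exposures, and test an interacting pair against two
non-interacting ones:

```r
library(mixboost)
sim <- simulate_mixture(mixture_config(n = 1000, snr = 2), seed = 42)
#> Simulated contaminant mixture: 1000 subjects, 27 exposures + sex
#>   target SNR 2, realized SNR 1.87, noise SD 1.32

x   <- as.matrix(sim$panel)
fit <- gbt(x, sim$y, n.trees = 600, depth = 6, shrinkage = 0.01, seed = 42)
head(relative_influence(fit), 8)
#>       OCDD     PCB170     pp_DDE        MMP         Cd        BPA         Cu
#> 100.000000  50.979052  50.528843  40.542468  29.103704   9.370368   5.011994
#>        TNC
#>   4.897821

set.seed(42)
h_null(x, sim$y,
       list(c("pp_DDE", "PCB170"), c("BPA", "sex"), c("OCDD", "Hg")),
       params = list(n.trees = 600L, depth = 6L, shrinkage = 0.01),
       n_rep = 50, rows = 400)
#> H statistics against a parametric-bootstrap null (50 replicates)
#>          subset order   h_obs null_q5 null_q50 null_q95 significant p_advisory
#> 1 pp_DDE:PCB170     2 0.28454 0.02653  0.05228   0.1094        TRUE       0.00
#> 2       BPA:sex     2 0.00971 0.00000  0.00807   0.0280       FALSE       0.42
#> 3       OCDD:Hg     2 0.02740 0.00403  0.01083   0.0297       FALSE       0.12
```

The six variables driving the outcome head the importance ranking (OCDD
through its strong non-linearity, the four product-term variables
through their joint effect).  The p,p'-DDE x PCB 170 pair -- part of the
simulated four-way interaction -- produces H = 0.28 against a null 95th
percentile of 0.11: detected.  OCDD x Hg, a nothing pair, stays inside
its null.  BPA x sex is a *true* interaction this desk-scale fit fails
to flag: under the rank-based exposure transform that term carries only
~3% of the signal variance (the methods vignette quantifies this), a
useful reminder that absence of a flag is not absence of an effect.
Four-way subsets work the same way (`h_stat(fit, c("pp_DDE", "PCB170",
"Cd", "MMP"), x)`), and `split_stability()` reports how often a
detection survives repeated half-sample refits.

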