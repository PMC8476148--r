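# jointdfe

Inference of the **joint distribution of fitness effects (DFE)** of new
deleterious mutations between two diverged populations, from the
two-dimensional allele frequency spectrum (AFS).

When populations split, a mutation's selection coefficient may differ
between them (`s1` in the ancestral/first population, `s2` in the second).
`jointdfe` models the bivariate distribution of population-scaled effects
`(γ1, γ2) = (2·Na·s1, 2·Na·s2)` and estimates its correlation **w** — the
weight of a perfectly correlated component in a mixture joint DFE

    G(γ1, γ2) = w · G1d(γ) δ(γ1 − γ2)  +  (1 − w) · G1d(γ1) G1d(γ2),

with lognormal (or gamma) marginals `G1d`. Because both components share
the marginal, `w` *is* the correlation of the joint DFE. Expected spectra
come from a two-population Wright–Fisher diffusion solver (drift,
selection with dominance, size change, migration); fitting is by Poisson
Random Field composite likelihood, staged as in standard SFS practice:
demography from neutral (synonymous) variants, then the DFE from selected
(nonsynonymous) variants over a cache of spectra on a grid of selection
coefficients. Composite-likelihood uncertainties use the Godambe
information matrix with block-bootstrap spectra.

For users who fit DFEs from site frequency spectra (dadi/fitdadi-style
workflows) and want to ask how *transferable* fitness effects are between
populations, rather than fitting each population separately.

## Worked example

Simulate data under a known joint DFE, then recover it:

```r
library(jointdfe)

demo  <- default_truth_demography()        # IM: growth + asymmetric migration
truth <- default_truth_dfe(w = 0.9)        # lognormal mixture, mu 3.6, sigma 5.1

# cache expected spectra over a grid of selection coefficients (theta = 1)
cache <- build_cache(demo, n1 = 10, n2 = 10,
                     grid = build_gamma_grid(12, c(1e-4, 2000)))

expected <- expected_selected_afs(cache, truth, theta_sel = 13842.5, p_misid = 0.01)
obs      <- poisson_sample_afs(expected, seed = 11)

fit <- fit_dfe(obs, cache, lognormal_mixture_dfe(1, 2, 0.5),
               theta_sel = 13842.5, n_starts = 2, seed = 1)
print(fit)
#> dfe fit: logLik = -383.0767, converged = TRUE
#>       mu    sigma        w  p_misid
#> 3.810189 5.337266 0.908920 0.010035

boots <- bootstrap_set(lapply(1:20, function(b)
  poisson_sample_afs(expected, seed = 100 + b)), obs)
se <- godambe_se(fit, obs, boots)
round(se, 5)
#>      mu   sigma       w p_misid
#> 0.07699 0.16302 0.00949 0.00140

w_significance(fit$params[["w"]], se[["w"]])
#> # A tibble: 1 × 6
#>   label w_hat      se     z  p_value p_adjusted
#>   <chr> <dbl>   <dbl> <dbl>    <dbl>      <dbl>
#> 1 1     0.909 0.00949 -9.60 8.05e-22   8.05e-22
```

The truth (`mu = 3.6`, `sigma = 5.1`, `w = 0.9`, `p_misid = 0.01`) is
recovered within sampling error; the z-test correctly rejects perfect
correlation (`w = 1`). The Godambe standard error of `w` (0.0095) matches
the spread of direct bootstrap refits (0.0098 on the same replicates).

Other entry points: `fit_demography()` (neutral-spectrum demographic fits
with `theta_neu` profiled), `expected_joint_afs()` /
`wright_fisher_oracle()` (diffusion engine and its finite-population
validation oracle), `run_precision_experiment()` /
`run_robustness_suite()` (simulation studies), `read_afs()` /
`write_afs()` (frequency-spectrum text files), `project()`,
`misid_transform()`, `partition_theta()`. A thin command-line wrapper
lives at `inst/cli/jointdfe`. The methods vignette
(`vignettes/joint-dfe-methods.Rmd`) documents the model, the numerics and
their accuracy limits.

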