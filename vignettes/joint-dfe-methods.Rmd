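---
title: "Methods: inferring the joint DFE between two populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring the joint DFE between two populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jointdfe)
```

## The model

When two populations diverge, a new mutation may affect fitness differently
in each: selection coefficient `s1` in the ancestral and first contemporary
population, `s2` in the second. The *joint distribution of fitness effects*
(joint DFE) is the bivariate distribution of the population-scaled pair
`(gamma1, gamma2) = (2 Na s1, 2 Na s2)` across new mutations, and its
correlation summarises how conserved mutation fitness effects are between
the populations. This package infers the joint DFE of deleterious mutations
from the joint allele frequency spectrum (AFS) of a two-population sample.

The observed data are two `(n1+1) x (n2+1)` count matrices: a neutral
(synonymous) spectrum `N` and a selected (nonsynonymous) spectrum `S`.
Under the Poisson Random Field assumption (unlinked sites, independent
Poisson entry counts),

* `E[N] = theta_neu * F(0, 0 | demo)`,
* `E[S] = theta_sel * ∬ F(gamma1, gamma2 | demo) G(gamma1, gamma2) d gamma`,

where `F(gamma1, gamma2)` is the expected spectrum at mutation rate
`theta = 1` under the fitted demography and `G` is the joint DFE density.
Inference is staged: demography (plus `theta_neu`, profiled analytically)
is fit to the neutral spectrum; the DFE parameters are then fit to the
selected spectrum with the demography held fixed and `theta_sel` fixed at a
known multiple of `theta_neu` (`ratio_NS`; presets 2.31 for human
nonsynonymous/synonymous, 2.85 for *D. melanogaster*, 2.5 for wild tomato,
5.21 for GC-conservative human mutations). Joint optimisation of demography
and DFE is intentionally unsupported: each DFE likelihood evaluation needs
`F` on a whole grid of selection coefficients, so the two stages are
separated by the selection cache.

### DFE families

The workhorse model is a mixture: with probability `w` a mutation has
*identical* effects in the two populations (`gamma1 = gamma2`, a singular
component supported on the diagonal), otherwise the two effects are
independent draws from the same marginal. Because both components share the
marginal, the correlation of the mixture equals `w`, which is why `w` is
reported as *the* DFE correlation. Marginals are lognormal
(`mu`, `sigma` of `log |gamma|`) or gamma (`alpha`, `beta`). A bivariate
lognormal with log-scale correlation `rho` (possibly asymmetric marginals)
is also provided; note `rho` is the correlation of the *logs* — the
raw-scale correlation of a bivariate lognormal is smaller — and all
comparisons of `w` with `rho` in this package are on the log scale.
Only deleterious effects are modelled (`gamma <= 0`); beneficial mutations
are out of scope.

The singular diagonal component is never represented as a pointwise 2D
density: the expected selected spectrum is assembled as
`w ×` (1D integral along the diagonal of the cache) `+ (1 − w) ×`
(2D product integral), which is both exact for the mixture semantics and
numerically stable as `w -> 1` (where a pointwise bivariate density
concentrates on the diagonal and 2D quadrature degrades — the documented
caveat of the bivariate-lognormal family).

## The diffusion engine

`expected_joint_afs()` computes `F` by integrating the Wright-Fisher
diffusion forward in time: the ancestral population is brought to
mutation-selection-drift equilibrium by a direct steady-state solve (an
optional pre-split epoch of instantaneous ancestral growth is integrated
transiently), the 1D density is lifted onto the 2D diagonal at the split,
and the two populations then evolve under drift (`V = x(1-x)/nu`),
selection with dominance (`M_sel = 2 gamma x(1-x)(h + (1-2h)x)`, genotype
fitnesses `1 : 1+2hs : 1+2s`) and migration (`M_mig = m12 (y - x)`). Units
follow the diffusion convention throughout: sizes relative to the ancestral
size `Na`, time in `2 Na` generations, migration as `2 Na m`,
`theta = 4 Na mu`. Supported histories: `equilibrium`, `split_mig` /
`split_no_mig` (instantaneous post-split sizes), `IM` (founding fractions
`s_frac`, `1 - s_frac` with exponential growth to `nu1`, `nu2`), and
`IM_pre` (`IM` preceded by an instantaneous ancestral size change).

Numerics: a conservative finite-volume discretisation on a tanh-stretched
grid crowded at the frequency boundaries; Chang-Cooper exponential-fitting
interface weights (so steep selection boundary layers remain stable);
fully implicit time stepping (default target step 2e-3 time units, at
least 100 steps per epoch); alternating implicit sweeps along the two axes
for the 2D operator; new mutations injected each step at the lowest
interior frequency of each population's axis. The sample spectrum is a
binomial-kernel integral of the density, computed on three grids
(`max(n1, n2) + 10` points plus refinements of 10 and 20) and Richardson-
extrapolated to zero spacing. Tiny negative extrapolation artefacts are
clipped to zero; clipping beyond 1% of the spectrum maximum warns.

Boundary handling deserves emphasis. In a single-population integration,
density reaching a frequency boundary is removed (the variant stopped
segregating). In the 2D integration that would be wrong: a variant lost or
fixed in one population may still segregate in the other, and those
variants populate the spectrum edges (private and fixed-difference
classes). The 2D sweeps therefore conserve flux into the boundary nodes —
the lost/fixed measures accumulate there and keep evolving along the other
axis — and the advective part of the two boundary-adjacent interfaces is
purely upwinded so that accumulated boundary mass re-enters the interior
only where drift genuinely points inward (e.g. migration re-introducing a
lost allele).

### Validation and known accuracy limits

The engine is validated against an independent discrete Wright-Fisher
oracle (`wright_fisher_oracle()`): explicit transition matrices over the
joint count lattice of two finite populations with the same
selection/dominance/migration conventions, mutation influx `theta/2` per
generation per unit relative size, equilibrium by direct linear solve, and
binomial downsampling. Because the chain's deviation from the diffusion
limit is first order in `1/N_sim`, oracle answers at `N_sim` and
`2 N_sim` are Richardson-extrapolated where sharp comparisons are needed.
Agreement on standard scenarios (neutral with migration, selected
isolation, long-isolation private-variant limits) is at the 1-3% level per
unmasked entry for `|gamma| <= 10` and `n <= 8`. Two known soft spots,
documented deliberately: (i) migration-coupled rare and edge entries —
private singleton classes and the shared-singleton entry `(1,1)` — are
overestimated by a few percent, growing with divergence time (about 2.5%
on the edges and 6% at `(1,1)` by `T = 0.3` in a neutral
migration model, cross-checked against both the Wright-Fisher oracle and
coalescent branch-length expectations); the effect is grid- and
timestep-converged, i.e. a property of the discretised 2D operator
(boundary retention plus migration re-entry), not of resolution; (ii) accuracy degrades for
`|gamma| > ~500`, where the boundary layer at `x = 0` is thinner than any
practical grid — cached strong-selection spectra are dominated by the
(well-resolved) rare-variant classes, and oracle comparisons are run at
moderate `|gamma|` only. Self-consistency of simulation studies is
unaffected by either (the same engine generates and fits), but absolute
comparisons to other software at those entries should expect differences
of that order.

## The selection cache and DFE integration

`build_cache()` evaluates `F` on a log-spaced grid of `|gamma|` magnitudes
(default 50 points on `[1e-4, 2000]`, hence 2500 ordered pairs) plus the
neutral spectrum; for a symmetric demography the transpose identity halves
the engine work. The cache is a single self-describing RDS container
(grid, demography, sample sizes, dominance, engine settings, version), and
`check_cache()` refuses caches whose demography differs from the current
fit. `|gamma| = 1e-4` is numerically neutral (within 1% of the neutral
spectrum — a cache invariant under test), which motivates the tail rule
below.

`expected_selected_afs()` integrates a DFE over the cache with the
trapezoid rule on the raw (non-uniform, log-spaced) magnitude abscissae.
Two deliberate numerical choices:

* **Mass renormalisation.** Raw trapezoid weights on a 50-point log grid
  misstate the in-domain probability mass by 1-2% for a wide lognormal
  (sigma ~ 5). The in-domain node weights are therefore rescaled so that
  their sum equals the analytic in-domain mass (CDF difference); the full
  weight accounting — in-domain plus tails — is then normalised by
  construction, which is asserted (to 1e-3) on every integration via the
  `weight_total` attribute. Accuracy against dense on-the-fly quadrature
  improves monotonically with grid size: ~12% worst-entry error at 8
  points, ~2.5% at 16, ~1% at 25, sub-percent at 50.
* **Tail assignment.** DFE mass outside the cached domain is assigned to
  the nearest boundary spectra: the `gamma -> 0` side to the *neutral*
  spectrum for the fully-neutral direction (diagonal and the both-small
  corner) and otherwise to the smallest-magnitude row/column (the two
  differ by under 1%); the `-Inf` side to the largest-magnitude
  row/column/corner. Edge strips of the 2D decomposition are distributed
  along the in-domain axis proportionally to the (conditional) marginal
  weights; for the bivariate lognormal, strip and corner masses are exact
  bivariate-normal rectangle probabilities computed by deterministic 1D
  quadrature of the conditional CDF.

Misidentification: with probability `p_misid` the ancestral state of a
variant is mistaken, reflecting the spectrum through
`F'(i,j) = (1-p) F(i,j) + p F(n1-i, n2-j)`. Separate parameters are carried
by neutral and selected fits (misidentification rates depend on selection).
The transform is applied after DFE integration and theta scaling — the
order is mathematically irrelevant for fixed `p`, fixed here for
reproducibility.

## Fitting, uncertainty, significance

Both fits maximise the Poisson composite log-likelihood over unmasked
entries (absorbing corners `(0,0)` and `(n1,n2)` always masked, no
folding). Optimisation is Nelder-Mead on transformed parameters — log for
positive quantities, logit for `w`, `s_frac` and `p_misid`, `atanh` for
`rho`, identity for log-scale means — with `n_starts` perturbed restarts
(jitter SD 0.5 on the transformed scale) and relative convergence tolerance
1e-8; equal-likelihood ties break toward the lexicographically smallest
transformed vector. `theta_neu` is profiled in closed form; `theta_sel` is
never free. Estimates of `w` within 1e-4 of 0 or 1 are flagged as
boundary-pinned.

Composite likelihoods understate uncertainty, so `godambe_se()` computes
the sandwich variance `H^-1 J H^-1`: `H` is the central finite-difference
Hessian of the log-likelihood on the original data at the MLE (relative
step 1e-2 on the transformed scale, cross-checked at 1e-3 with a warning
when SEs shift by more than 20%), and `J` is the empirical covariance of
per-bootstrap score vectors, each bootstrap spectrum evaluated with
`theta_sel` scaled by its segregating-sites ratio. The delta method maps
the variance back to natural scale. Because conventions differ on whether
published `±` values are standard errors or 95% half-widths, `tidy()`
reports both `std.error` and `1.96 * std.error`.

`w_significance()` turns `(w_hat, SE)` pairs into two-tailed z-tests of
`w = 1` with Benjamini-Hochberg adjustment across exactly the family of
estimates passed in — pooling across data subsets is the caller's decision.
`partition_theta()` splits a selected-class mutation rate between
deleterious and tolerated site classes by rate-weighted proportions
`sum(u_i d_i) / sum(u_i (d_i + t_i))`, the form under which the two
proportions sum to one (the variant with denominator
`sum(u_i) * sum(d_i + t_i)` does not normalise and is not used).

## The simulation harness

`run_precision_experiment()` reproduces the precision study design:
expected selected spectrum under a truth demography and DFE, independent
Poisson replicates, refit of the DFE per replicate. Defaults are the study
conditions: lognormal-mixture truth `mu = 3.6`, `sigma = 5.1`, `w = 0.9`;
selected-class rate `theta_NS = 13842.5`; 20 chromosomes per population;
10 replicates; a 25-point cache (the full-scale 50-point grid and
216/198 samples remain available through the arguments). The truth
demography is an isolation-with-migration history with divergence, growth
and asymmetric migration (`s_frac = 0.8`, `nu1 = 3.0`, `nu2 = 3.2`,
`T = 0.1`, `m12 = 1.0`, `m21 = 0.5`) — this package's documented choice
of a realistic human-like history of divergence, growth and gene flow.
The smallest precision
configuration ("two chromosomes") is interpreted as two chromosomes *per
population*. Per-replicate seeds derive deterministically from the base
seed, so experiments rerun bit-identically.

`run_robustness_suite()` reproduces the bias studies on noise-free
expected data (bias, not variance, is the question): refitting with a
misspecified no-migration demography; truth dominance `h = 0.25` or
`0.75` fitted as additive; a gamma-mixture truth (`alpha = 0.4`,
`beta = 1400`) fitted with the lognormal mixture; and symmetric
(`mu = 3.6`, `sigma = 5.1`) or asymmetric (`mu2 = 4.5`, `sigma2 = 6.8`)
bivariate-lognormal truths fitted with the symmetric mixture. The expected
pattern — reproduced in the acceptance checks — is that `mu` and `sigma`
absorb the misspecification while `w` stays within 0.05 of truth (within
0.1 of `rho` for the bivariate truths at high correlation). Misidentified
ancestral states can optionally be injected into simulated data through
the forward transform before Poisson sampling.

### What the generator does and does not emulate

Synthetic data are unlinked Poisson counts from the model's own expected
spectra. They emulate sampling noise, misidentification, dominance and
demographic/DFE misspecification; they do not emulate linkage
(background selection), positive selection, inbreeding, or annotation
error in classing sites as neutral versus selected. Passing the precision
and robustness checks therefore demonstrates statistical correctness of
the estimator under its own assumptions, not robustness to linked
selection — in the source study that required external forward simulation,
out of scope here.

## Scale of the shipped checks

The test and acceptance runs use desk-scale configurations chosen to keep
the full suite in minutes: 6-14 chromosomes per population for
engine/oracle cross-checks (oracle cost grows with the squared lattice),
20 per population with a 25-point cache for parameter recovery, 14 per
population with a 15-point cache for the robustness suite, and a 12-point
cache for the uncertainty comparison. Each scaled-down setting is a
parameter, not a limit: the full-scale configuration is one argument away.
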