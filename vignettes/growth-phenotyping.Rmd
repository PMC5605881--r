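---
title: "GP functional ANOVA for growth phenomics: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GP functional ANOVA for growth phenomics: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the test suite
does and does not demonstrate about real plate-reader data.

## The observation model

A plate-reader cohort crosses strains (a parent plus knockouts) with
experimental conditions (standard growth plus stressors), reads OD600
every 30 minutes for 48 h, and replicates each cell biologically and
technically. After normalization (below), a reading of strain $i$ under
condition $j$ at grid time $t$ is modeled as

$$y_{ij}(t) = \mu(t) + \alpha_i(t) + \beta_j(t) + (\alpha\beta)_{ij}(t)
  [+ \gamma_b(t)] + \varepsilon,$$

with a shared mean function $\mu$, functional main effects of strain and
condition, their interaction, optionally a batch function $\gamma_b$, and
i.i.d. Gaussian noise with one shared variance. `fanova_spec()` declares
which effects and interactions a given design needs: the joint
multi-condition screen uses strain, condition and their interaction (plus
batch when experiments span batches); a temperature-shock run, fit
separately, uses a strain effect only; complementation designs add
two-level vector/plasmid factors and, where the question demands it, a
condition-plasmid interaction. The fitter is generic over any such
declaration.

Effects are not identifiable as written — adding a function to $\mu$ and
subtracting it from every $\alpha_i$ changes nothing — so each effect set
is constrained to sum to zero across its levels at every time, and
interactions over both margins. The package enforces this *by
construction*: the $n$ effect functions of a factor are
$\alpha = C\,\alpha^{*}$ where $C$ (`contrast_basis()`) is the
deterministic orthonormalized-Helmert basis of the sum-to-zero subspace
and $\alpha^{*}$ are $n-1$ unconstrained contrast functions. Orthonormal
columns matter: a shared (exchangeable) GP prior on the contrasts then
induces an exchangeable prior over the effects, so no strain is privileged
by the parameterization. Interaction functions use the Kronecker product
of the parents' bases, which zeroes both margins. Every posterior draw
therefore satisfies the constraints to round-off (the suite checks 1e-8;
observed violations are ~1e-16).

## Priors and hyperparameters

Each latent group (mean, each effect set, each interaction set, batch)
carries a GP prior with the RBF covariance
$\kappa(t_1,t_2) = \sigma^2 \exp(-(t_1-t_2)^2/\ell)$. Note the
parameterization: $\ell$ divides the *squared* distance directly, so its
units are hours²; the correlation between readings $d$ hours apart is
$e^{-d^2/\ell}$. This differs from the common $2\ell^2$ convention, and is
deliberate — it is the form the rest of the package's math and defaults
assume, and it is stated on `rbf_kernel()` so users porting lengthscales
from other toolkits convert correctly.

Hyperparameter priors are proper bounded log-uniforms, which keep slice
sampling well defined without injecting shape information:

* signal variance $\sigma^2 \in [10^{-4}, 10^4]$ — generous on both
  sides of the ~0.1–1 (log2-OD)² scale of real effects;
* lengthscale $\ell \in [(\text{grid step})^2, (4\,\text{grid span})^2]$,
  derived from the data grid: nothing rougher than the sampling interval
  can be resolved, and nothing smoother than several spans can be
  distinguished from a constant;
* noise variance $\sigma^2_\varepsilon \in [10^{-6}, 10^2]$.

Initial values ($\sigma^2 = 1$, $\ell = (\text{span}/3)^2$, noise at 10%
of the data variance) only affect burn-in.

## Sampling

The sampler alternates:

1. **Gibbs updates of every latent function block.** Conditional on
   everything else, a block $f$ on the grid has the conjugate multivariate
   normal full conditional with precision $K^{-1} + W/\sigma^2_\varepsilon$,
   where $W$ accumulates the squared contrast coefficients of the
   observations attributed to $f$ at each grid time. Blocks within a group
   share one Cholesky factorization of $K$ per sweep.
2. **Slice sampling of hyperparameters** (`slice_sample()`, step-out plus
   shrinkage) in log space, one univariate update per parameter per sweep,
   where the bounded log-uniform priors are flat. The noise variance is
   updated the same way from the residual sum of squares.

Defaults are 1,000 burn-in and 1,000 retained draws (thinning 1),
configurable via `mcmc_control()`. Chains are bit-reproducible given
(data, spec, control, seed). Numerical safety: kernel diagonals get a
jitter of $10^{-6}\sigma^2$, escalated tenfold on Cholesky failure up to
$10^{-2}\sigma^2$ before a diagnostic error.

Correctness is anchored two ways rather than by eyeballing traces: with
hyperparameters fixed the model is linear-Gaussian, and the test suite
compares MCMC means and variances of every latent coordinate against the
exact conjugate posterior computed by independent dense matrix algebra
(agreement within 3 batch-means Monte-Carlo SEs at 2,000 draws); and fits
to data simulated from the model's own prior recover the true effect
functions (correlation > 0.99, pointwise 95%-band coverage ≈ 0.94
averaged over 20 cohorts at the sizes below).

## Normalization

`normalize_growth()` applies three steps, in this order:

1. log2 transform (exponential growth becomes linear; one unit is one
   doubling);
2. drop readings earlier than 4 h — instrument and condensation
   variability dominates before the cultures complete a generation. The
   boundary is half-open: $t < 4$ is dropped, $t = 4$ retained, which
   keeps a round grid start and is deterministic;
3. subtract one scalar per condition so the condition's mean log2 OD at
   its earliest retained grid point is exactly zero, absorbing
   inoculum-density differences between experimental designs.

Zeroing is computed *after* trimming (the trimmed points should not
influence the anchor). A consequence worth knowing: multiplying all raw
ODs of a condition by any constant changes nothing downstream — the log2
shift is absorbed by the offset — so unit mismatches between runs are
harmless within a condition. Times are snapped to the nearest multiple of
the sampling interval (default 0.5 h); a time farther than 25% of the
interval from the grid is an error rather than an interpolation, because
the model assumes a shared grid and silent interpolation would mask
plate-layout problems.

## Phenotype metrics

**OD_delta.** Under the standard condition the mutant-parent difference is
$\alpha_i - \alpha_p + (\alpha\beta)_{i,\mathrm{std}} -
(\alpha\beta)_{p,\mathrm{std}}$ per draw. Under a stress condition it is
the strain-parent contrast under stress *minus the same contrast under
standard*, so a mutant that differs from the parent identically in both
environments shows no stress phenotype. Any model terms the spec does not
include contribute zero, which makes the same function valid for the
strain-only shock model.

**Significance.** The 95% interval is the pointwise 2.5%/97.5% posterior
sample quantile band — per-time-point, with no simultaneous-band
correction; that matches the per-time-point decision rule the metric is
defined by. The cost is multiplicity: scanning ~90 grid points for *any*
exclusion inflates the family-wise false-positive rate well above 5%.
The package's stance is to measure and report that rate rather than hide
it — `null_calibration()` fits a no-effect cohort and reports the
any-exclusion fraction (0 at the default desk-scale sizes, where
replicate averaging keeps the bands honest) — and the magnitude cutoff
(below) exists precisely to filter incidental one-point exclusions.

**Magnitude.** $\|\mathrm{OD}_\Delta\| = \sum_t \mathrm{OD}_\Delta(t)^2$,
computed per draw and summarized by the posterior median and quartiles.
Two deliberate literalisms: there is no square root, and no grid-step
weighting — so the value depends on grid density (halving the spacing
about doubles it). The analysis grid is fixed at 30-minute steps by
default, making values comparable across strains and conditions fit on
the same grid; comparing magnitudes across differently gridded fits is
not meaningful and is documented as such. The median (not the mean) is
the ranking summary because the per-draw distribution is right-skewed.

**Heat shock.** Shock-run metrics start at the shock-onset grid point
(default 16 h), and each draw's trajectory has its own value *at* the
onset subtracted — the minimal reading of "subtract the pre-shock
difference", which removes any constant divergence accumulated before the
shock without modeling the pre-shock period further. The trajectory is
thus pinned to zero at onset and the first significant time is always
strictly after it.

**Direction** labels come from the posterior-mean sign over the
significant runs: `faster` above the parent, `slower` below, `mixed` when
runs of both signs occur.

**Universal cutoff.** `select_cutoff()` returns the smallest magnitude
that (i) exceeds every strain-condition pair whose extremal posterior-mean
value (argmax and argmin over time) sits inside its own 95% band — pairs
whose largest excursions are not credibly nonzero — and (ii) exceeds the
90th percentile of standard-condition magnitude medians. Both bounds are
closed at the boundary, so the implementation adds a vanishing relative
epsilon and significance tests use `>= cutoff`; whether the comparison
summary is the median was an open choice, settled on the median for
consistency with the ranking and network-weight summaries.

## Downstream phenomics

* **Clustering** (`cluster_trajectories()`): Euclidean distance and
  complete linkage by default — the plain choice for trajectories on a
  common grid — with a correlation distance available when shape matters
  more than magnitude. The cut height is a required user choice; there is
  no universal default for a dendrogram cut and pretending otherwise
  would hide a real decision.
* **Correlation enrichment** (`correlation_enrichment()`): Pearson
  correlations of posterior-mean trajectories against a focal strain
  (Spearman by flag), hits at $\hat\rho \ge 0.4$, membership tested by
  the upper-tail hypergeometric. Affine rescaling of any trajectory
  leaves the result unchanged.
* **Classification** (`classify_phenotypes()`): growth & stress if
  significant under standard and ≥ 1 stress; else cross-stress if under
  ≥ 2 stress conditions; else stress-specific if under exactly one
  condition; else none. Every condition other than the declared standard
  counts as stress. The rule is a partition by construction.
* **Enrichment universes** are always explicit arguments — there is no
  silent genome-size default, because the tail probability is meaningless
  without knowing $N$. Raw p-values are reported; Benjamini-Hochberg is
  an optional, clearly separate column.
* The **network** is bipartite (strain and condition nodes), one edge per
  significant call, weighted by the magnitude median and signed by the
  extremal posterior-mean value; exported as GraphML (attributes intact)
  or SIF (`strain faster|slower condition` lines).

## The synthetic-data generator

`simulate_dataset()` generates cohorts with exactly the generative
structure the model assumes: a modified-Gompertz baseline
($A e^{-e^{\mu_\max e (\lambda - t)/A + 1}}$, a realistic lag /
exponential / stationary shape on the log scale), sum-to-zero effects
drawn from the model's own GP prior (or planted shapes decomposed into
mean/main/interaction components so the constraints still hold exactly),
replicate structure, and i.i.d. noise. The default noise SD of 0.05
log2-OD units was chosen once so that planted effects of 0.3–1.0 span
marginal-to-obvious significance at typical replication; the default grid
is 4–48 h at 0.5-h steps, matching the 30-minute instrument cadence after
the 4-h trim.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: heteroscedastic or autocorrelated instrument
noise, evaporation and condensation drift, blank-well offsets, plate
position effects, and model misspecification generally. Recovery results
on simulated cohorts are evidence the *inference machinery* is correct,
not that the model fits any particular instrument's quirks.

Benchmark presets (`make_benchmark_cohort()`): `null` (no effects, for
calibration), `small` (3 strains × 2 conditions, 30 grid points, 4
replicate curves per cell — the recovery-study shape), `cross_stress_demo`
and `heatshock_demo` (planted qualitative phenotypes for end-to-end
checks), and `full_shape` (28 strains × 5 conditions at full replication,
for demos and load testing; its planted strains emulate the headline
phenotype shapes qualitatively only).

## Problem sizes in the test suite

The statistical checks run at sizes one CPU handles in minutes, chosen as
the smallest sizes at which each property is informative: the conjugate
comparison on a 10-point grid with 2 × 2 factors and 2,000 draws; the
recovery study over 20 seeds of the `small` preset at 500 retained draws;
demos at 400 draws. These sizes are the package's definition of its
desk-scale benchmark, and `scripts/acceptance.R` reruns all of them from
scratch.

## Known limitations

* Pointwise credible bands imply multiplicity over the grid; the null
  exceedance rate is reported, not corrected away. A simultaneous-band
  option would be a natural extension.
* The magnitude statistic is grid-dependent by definition; fits to be
  compared must share a grid.
* One shared noise variance across all strains, conditions and times;
  real variance often grows near stationary phase.
* The Gibbs sweep is single-chain and single-threaded; very large cohorts
  (hundreds of latent functions on dense grids) are outside the intended
  desk scale.
* Serialization of posteriors is JSON (`write_fanova_json()`), favoring
  portability and inspectability over compactness.
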