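---
title: "Hierarchical inference of mouth-form plasticity and its transgenerational memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical inference of mouth-form plasticity and its transgenerational memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouthform)
```

## The problem

*Pristionchus pacificus* worms develop one of two mouth forms: the
wide-mouthed, predatory eurystomatous (Eu) morph or the narrow-mouthed
stenostomatous (St) morph. The decision is made once per animal and is
influenced by diet: inducing diets or supplements push genetically
identical animals toward the Eu morph, and after the inducer is removed
the elevated Eu frequency can persist for one or more generations —
intergenerational or transgenerational inheritance of the phenotype.

The raw data of such an experiment are plate counts: for each experimental
condition and each generation (labelled `F1, F2, ...` during induction and
`F5R1, F5R2, ...` after reversal), about 10-60 agar plates are scored, each
with roughly 20 animals, and the number of Eu animals per plate is
recorded. Plates are genuine biological replicates and vary more than
binomial sampling alone allows, so the analysis has to separate
within-plate (binomial) noise from between-plate heterogeneity.

## The model

Each (condition, generation) group is fitted independently. Animal
$i$ on plate $r$ is a Bernoulli trial with that plate's own Eu
probability $\theta_r$; equivalently (and as implemented, since the
per-plate count is the sufficient statistic) the plate count is binomial.
The plate-level probabilities are linked by a generation-level mode
$\omega$ and concentration $\kappa$ through the mode-concentration
parameterization of the Beta distribution:

$$
\begin{aligned}
k_r &\sim \mathrm{Binomial}(n_r,\ \theta_r) \\
\theta_r &\sim \mathrm{Beta}\!\left(\omega(\kappa-2)+1,\ (1-\omega)(\kappa-2)+1\right) \\
\omega &\sim \mathrm{Beta}(\alpha,\ \beta) \\
\kappa &\sim 2 + \mathrm{Gamma}(3,\ 1)
\end{aligned}
$$

With shapes $a = \omega(\kappa-2)+1$ and $b = (1-\omega)(\kappa-2)+1$ we
have $a + b = \kappa$ and, for $\kappa > 2$, the Beta mode equals
$\omega$: $\omega$ is "the typical plate's" Eu probability and $\kappa$
measures how tightly plates cluster around it ($\kappa = 2$ is the
uniform distribution; large $\kappa$ means homogeneous plates).

Two hyperprior choices are deliberately explicit:

* **$\alpha = \beta = 1$** (default): a uniform prior on the mode. It is
  uninformative and preserves the model's symmetry under relabelling
  Eu $\leftrightarrow$ St, a symmetry the test-suite exploits.
* **The shifted concentration prior.** A literal
  $\kappa \sim \mathrm{Gamma}(3,1)$ admits $\kappa < 2$, where the mode
  parameterization breaks down (shapes can turn non-positive and the
  "mode" interpretation is lost). The package therefore places the
  Gamma(3, 1) law on $\kappa - \kappa_\mathrm{offset}$ with offset 2 by
  default, guaranteeing valid shapes; `kappa_offset = 0` restores the
  unshifted form. The Gamma is parameterized by shape 3 and *rate* 1
  (mean 3).

The shifted prior is informative about $\kappa$: its mass lies below
$\kappa \approx 12$. With 10-30 plates of 20 animals the data carry
little information about $\kappa$ (binomial noise dominates the
between-plate signal), so the $\kappa$ posterior stays prior-dominated
and pooled intervals are conservative — wide — for very homogeneous
plates. This matters for the classifier design below.

## Sampling

The posterior is explored with a seeded Metropolis-within-Gibbs sampler
(compiled, using R's RNG so results are reproducible from a single
integer seed):

1. $\theta_r \mid \omega, \kappa, k_r$ — exact conjugate draw from
   $\mathrm{Beta}(a + k_r,\ b + n_r - k_r)$, independent across plates;
2. $\omega$ — random-walk Metropolis on $\mathrm{logit}(\omega)$;
3. $\kappa$ — random-walk Metropolis on $\log(\kappa - \mathrm{offset})$;

both random walks carry the change-of-variable Jacobians in the
acceptance ratio. Step sizes adapt by Robbins-Monro toward 44%
acceptance during warmup only and are frozen afterwards, so the kept
draws target the exact posterior. Chains start from a moment-style
estimate jittered per chain (overdispersed starts, which split-$\widehat{R}$
needs to be meaningful).

Defaults are 4 chains $\times$ 25000 kept draws after 2000 warmup
iterations. Because the $\theta_r$ are refreshed by exact conjugate
draws, almost all autocorrelation sits in $\omega$ and $\kappa$; the
default budget gives every parameter an effective sample size (ESS)
comfortably above the convergence contract of 10000, in about two
seconds for a 10-plate group. A fit failing the contract (any ESS below
`target_ess`, any split-$\widehat{R}$ above 1.01) is returned flagged with a
structured warning — never silently, and never as an error, so partial
results stay inspectable.

**Diagnostics.** ESS is the autocorrelation-based estimator on
rank-normalized split chains with Geyer's initial positive-sequence
truncation (plus monotone smoothing) of the paired autocorrelations.
Split-$\widehat{R}$ is the classical potential scale reduction factor over
half-chains; the raw estimator is reported, which can undershoot 1 by
$O(1/n)$ sampling noise.

## Summaries: one point and one error bar per group

The figure-style summary of a group pools the $\theta_r$ draws of all
plates and chains into one vector — the distribution of "a replicate's
Eu probability" — and reports its mean and 95% highest-density interval
(HDI). The HDI is computed directly from samples: over the sorted draws,
the narrowest window containing $\lceil 0.95\,N \rceil$ of them, ties
broken toward the lowest start index (a fixed, reproducible rule; no
density estimation, no support for disjoint intervals). Pooling per-plate
posteriors (rather than, say, summarizing $\omega$) keeps genuine
between-plate heterogeneity visible in the error bar. The per-plate
alternative is available via `summarize_group(..., per_plate = TRUE)`.

## The memory classifier

The qualitative labels used for inheritance phenotypes are formalized as
a deterministic rule on the per-generation summaries:

* a **baseline band** stands in for the control-diet response range;
  either configured explicitly (default upper bound 0.5, which a ~30% Eu
  baseline plus plate noise stays below) or fitted as the 95% HDI of
  pooled baseline-generation $\theta$ draws;
* a reversal generation is **elevated** iff its HDI lower bound lies
  *strictly* above the band's upper bound (a tie is not elevated);
* **duration** is the number of consecutive elevated generations
  starting at R1 — a rebound after a lapse does not extend memory;
* **category**: duration 0 is *none*, 1-2 is *intergenerational*,
  $\geq 3$ is *transgenerational* (TEI), following the field's usage of
  these terms.

Raising the band's upper bound can only shorten the duration
(monotonicity, tested as a property).

## The synthetic generator

`scenario_spec()` encodes the experimental design the generator
emulates: a baseline mode (default 0.3 — the study strain is
preferentially non-predatory, about 30% Eu, on the control diet), a
near-complete induced mode (default 0.995; a Beta mode of exactly 1 is
outside the parameterization, so "complete induction" is capped), a
concentration `kappa_true` (> 2), a design of plates $\times$ animals
per generation (default 10 $\times$ 20, the laboratory floor), and two
dynamic parameters:

* **`induction_lag`** — induction ramps linearly from baseline to the
  induced mode over `lag` generations, then holds. Lag 0 reproduces the
  immediate, generation-1 induction seen on inducing diets; a positive
  lag mimics inducers whose effect builds over several generations.
* **`retention`** — after reversal, generation $m$ has
  $\omega_m = \mathrm{baseline} + (\mathrm{induced} -
  \mathrm{baseline})\cdot \mathrm{retention}^m$. No decay law for
  phenotypic memory is established in this system; geometric decay is
  adopted as the simplest monotone one-parameter family able to span
  immediate loss (retention 0), short memory, and long memory
  (retention near 1). It is a modelling choice of this package, not an
  empirical claim.

Seeding contract: one integer seed reproduces a whole table bitwise, and
per-generation sub-streams derive from it, so appending generations never
perturbs earlier ones.

**Presets.** Three canned scenarios span the qualitative outcomes:
`fast_decay` (retention 0.72 — reversal modes $\approx$ 0.80, 0.66,
0.56, ...), `slow_decay` (retention 0.95) and `no_retention` (retention
0), all with `kappa_true = 50` and 30 plates per generation. Thirty
plates (within the design envelope of up to 60 per condition) rather
than the 10-plate floor, and an R1 mode of ~0.8, are needed because the
prior-dominated $\kappa$ posterior keeps the pooled HDI's lower arm
about 0.2 wide: scenarios with R1 modes near 0.75 at 10 plates straddle
the 0.5 decision boundary and classify unreliably. Geometric decay also
bounds how fast the mode can drop between adjacent generations, so the
presets target robust *categories* (duration 1-2 vs $\geq 3$ vs 0), not
an exact duration.

## Calibration

`sbc_coverage()` closes the loop: data are drawn from the model's own
prior predictive (mode from Beta($\alpha,\beta$), concentration from the
shifted Gamma, plate thetas, binomial counts), refitted, and the
fraction of nominal-95% plate-theta HDIs containing the generating
truth is recorded. For an exact sampler this coverage is 95% by
construction, so deviations expose sampler or summary bugs. Replicates
whose fit fails the (reduced) convergence contract are excluded and
counted, never hidden. At 500 replicates the binomial error band is
roughly $\pm 3$ percentage points on the per-replicate scale.

## Numerical choices and edge cases

* Complete induction is encoded as mode 0.995, never 1.0.
* `kappa_true` $\leq 2$ and probabilities outside (0,1) are rejected at
  construction; `log_posterior()` raises a domain error outside the
  support, while the sampler-facing `log_posterior_or_inf()` returns
  $-\infty$ (proposals are rejected, never crash a chain).
* Conjugate $\theta$ draws are clamped to $[10^{-12}, 1-10^{-12}]$ to
  guard against underflow at extreme shapes.
* The sample-based HDI requires $\geq 100$ draws for masses below 1;
  mass 1 returns the sample range. Width ties are resolved to the lowest
  start index, with a $10^{-8}$-relative tolerance so exact grids do not
  tie-break on floating-point noise.
* All CSV emission is locale-independent (UTF-8, "." decimal) and
  byte-stable for identical inputs; the pipeline manifest records the
  config, its MD5 hash, the seed, the package version and per-group
  convergence flags.

## Problem sizes used by the shipped analyses

The bundled analysis scripts and the test-suite are sized for a desk
run: single-group fits use the shipped defaults (4 $\times$ 25000
draws); multi-group stages and resampling studies (simulation-based
calibration, coverage and scenario-recovery checks) use a reduced budget
of 2 chains $\times$ 2500 draws with a correspondingly reduced ESS
target of 300, at which HDI endpoints are stable to well under the
decision margins involved. Calibration uses 500 prior-predictive
replicates in the acceptance script and 200 in the analysis driver.

## Limitations

* The generator emulates replicate heterogeneity, binomial sampling and
  generation-indexed mode trajectories; it does not emulate dose-response
  across inducer concentrations (conditions are just named trajectories),
  batch effects between biological replicates run on different days, or
  scorer error in phenotyping. Passing tests therefore validate the
  inference machinery, not those aspects of real data.
* Groups are fitted independently; no information is shared across
  generations or conditions, and no dose-response or decay-curve model is
  fitted to the trajectory itself.
* The memory call depends on the baseline band; with a fitted band the
  call inherits the band's sampling variability.
* The concentration prior is informative at realistic plate counts, so
  pooled intervals for very homogeneous groups are conservative.
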