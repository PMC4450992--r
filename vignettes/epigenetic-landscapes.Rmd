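---
title: "Epigenetic landscapes and collective cell-fate decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic landscapes and collective cell-fate decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(epiland)
library(dplyr)
```

## Overview

`epiland` implements two complementary views of early embryonic cell-fate
decisions.

The first is *descriptive*: from single-cell expression profiles annotated
with developmental stage it constructs a Waddington-style epigenetic
landscape — a surface over (cell state, developmental time) whose valleys
are cell types and whose hills are the barriers between them.

The second is *mechanistic*: it models a single lineage bifurcation as a
small gene circuit of auto-activating, mutually inhibiting transcription
factors (TFs), in two variants — the classical two-TF toggle circuit and a
two-*cluster* circuit in which each side of the bifurcation is carried by a
pair of cooperating TFs. Phase-space analysis and a stochastic population
simulation quantify how much more robust the collective (two-cluster)
decision is when one protein's degradation rate is perturbed.

## The landscape construction

### Cell-state axis

Expression values are on the qRT-PCR scale `28 - Ct` (0 = undetected, ~18 =
maximal; `read_expression_table(..., input_is_ct = TRUE)` performs the
transform and clips at the detection floor). Each gene is centred across
cells and the cells are projected onto the first two principal components
of the covariance PCA. Because a PCA axis is defined only up to sign, each
component's sign is fixed so that its largest-magnitude loading is
positive; without this the angular coordinate below would not be
reproducible across platforms.

The one-dimensional cell-state coordinate is the *angular* position
`theta = atan2(pc2 - o2, pc1 - o1)` of each cell around an origin `(o1,
o2)` placed in a cell-free region of the PC plane. The origin placement is
what makes `theta` meaningful: it must see each cell fate in its own
angular sector, and no fate may straddle the branch cut at `±pi`. For data
on the scale of the reference qRT-PCR dataset the default `c(-0.5, 0)` is
appropriate; for other data `origin = "auto"` places the origin below the
whole point cloud at `(0, min(pc2) - 0.2 * range(pc2))`, which confines
`theta` to `(0, pi)` so the branch cut can never bisect a fate, while
preserving the angular separation of the fates. Cells within `1e-6`
radians of the cut are reported.

### Per-stage mixtures

Within one developmental stage, each cell type is assumed to distribute
normally along `theta` — an assumption `validate_normality()` lets you
check per stage or per segment with a Shapiro–Wilk test and exported Q–Q
quantile pairs. A stage with `m` cell types is therefore a 1-D Gaussian
mixture

\[ f(x) = \sum_{k=1}^{m} \tau_k \, \Phi(x \mid \mu_k, \Sigma_k), \qquad
   \sum_k \tau_k = 1, \]

fitted by EM (model-based clustering with unequal component variances, via
mclust). The component count is selected among `1:max_components` by BIC,
with three safeguards that matter in practice:

* **Initialisation.** EM only finds local optima, and the default
  hierarchical initialisation can strand a component across an empty gap
  between well-separated groups. Each candidate count is therefore also
  started from a multi-restart k-means partition and the better likelihood
  kept. Fitting stays deterministic: the internal restarts use a fixed,
  locally scoped RNG stream.
* **A reliability floor.** A count `m` is only entertained if the stage
  has on average at least 25 cells per component (`min_per_component`).
  Each unequal-variance component costs three parameters, and below a few
  dozen cells per component, chance gaps in a unimodal sample are
  routinely mistaken for extra cell types.
* **Parsimony margin.** Among counts whose BIC lies within 2 units of the
  optimum — the conventional positive-evidence margin — the smallest count
  wins, so an extra cell type must earn genuine evidence.

Degenerate stages (all `theta` identical) return a single component with
the variance floored at `1e-6` rad².

### Pseudo-potential and surface

True gradient potentials do not exist for these dynamics, so the landscape
height is the Boltzmann-form pseudo-potential of the state density,

\[ U(x) = -\rho \ln f(x) + \omega , \]

with `rho > 0` and `omega` pure scale/offset gauges (shifting `omega`
shifts every height identically). The density is floored at
`floor_density = 1e-12` before the logarithm so `U` stays finite where
`f` underflows. Stages sit at ordinal times `t = log2(stage)`
(`0 ... 6` from zygote to 64-cell, evenly spacing the stage axis); rows
between consecutive stages (10 by default) are filled by linear
interpolation of `U` in `t`, and an optional cosmetic tilt
`tilt_rate * t` is added *after* interpolation to depict the loss of
differentiation potency. All quantitative checks in the package run with
`tilt_rate = 0`. The default grid is 200 `x`-points.

```{r landscape, message = FALSE}
cells <- generate_synthetic(synthetic_config(seed = 1))
proj <- pca_project(cells, origin = "auto")
mixes <- fit_all_stages(proj)
vapply(mixes, function(m) m$m, integer(1))   # cell types per stage
surface <- build_landscape(mixes, cells = proj)
autoplot(surface)
```

## The synthetic-data generator

`generate_synthetic()` emulates the structure of the reference experiment:
442 cells over stages 1–64 (8/16/24/48/80/120/146 per stage), 48 genes of
which three clusters of 17 (TE-like), 10 (PE-like) and 12 (EPI-like) genes
mark the lineages, the remaining 9 genes being uninformative. Stages up to
16 cells draw from a single progenitor state with every cluster at an
intermediate mean; the 32-cell stage splits 1:1 into an ICM-like and a
TE-like state; the 64-cell stage mixes TE-high, PE-high and EPI-high
states 2:1:1 (roughly a blastocyst's composition). Gene noise within a
cluster shares a per-cell latent factor (`within_cluster_corr = 0.15`) so
cluster members correlate even within one cell type; values are clipped at
the detection floor 0.

The expression scale (`mean_high = 14`, `mean_low = 2`, `noise_sd = 1.5`)
keeps the off state about one standard deviation above the floor. These
defaults were chosen so that the planted structure is the truth of the
data: with an off state sitting on the floor, clipping skews each
lineage's angular distribution and a mixture criterion legitimately reads
the skew as an extra component — a property of badly scaled simulation,
not of the method.

What the generator does *not* emulate: embryo-of-origin structure
(cells are i.i.d. given their type), signalling-coupled proportions,
dropout patterns beyond floor-clipping, and the curved "horseshoe"
PC geometry of real developmental series. Passing tests on synthetic data
therefore demonstrate correctness of the machinery on data satisfying the
model's assumptions, not performance on any real dataset.

## The bifurcation circuits

Both circuits use Hill kinetics with shared parameters `alpha = 1.5`
(auto-activation), `beta = 1` (cross-inhibition), `n = 4`, `s = 0.5`, and
per-protein degradation `gamma = 1` (a perturbed protein gets
`gamma* = 1.5`). The two-TF model is

\[ \frac{du}{dt} = \alpha\frac{u^n}{s^n+u^n} + \beta\frac{s^n}{s^n+v^n}
   - \gamma_u u, \]

with the mirrored equation for `v`. The two-cluster model tracks four
proteins `u1, u2` (cluster 1) and `v1, v2` (cluster 2); each obeys the
pooled rate law

\[ \eta(a,b,c,d,\gamma_a) = \alpha\frac{a^n+b^n}{s^n+a^n+b^n}
   + \beta\frac{s^n}{s^n+c^n+d^n} - \gamma_a a , \]

and the biologically meaningful observables are the cluster totals
`x = u1 + u2`, `y = v1 + v2`. Within a cluster the difference `u1 - u2`
decays exactly at rate `gamma`, which justifies plotting the force field
on the symmetric slice `u1 = u2, v1 = v2`; fixed-point finding nevertheless
runs in the full 4-D space because perturbed circuits have asymmetric
roots.

```{r circuits}
fp <- find_fixed_points("two_tf", circuit_params())
fp
count_stable(fp)
```

### Numerical choices

Fixed points come from damped Newton iteration (numerical Jacobian by
central differences, step `1e-6`) started on a 40×40 lattice over
`[0, 3]^2` (2-D) or a 12×12 symmetric-slice lattice plus a coarse 6⁴ full
lattice (4-D); roots are deduplicated at `max(10 * tol, 1e-7)` with
`tol = 1e-10`, and stability is read off the Jacobian eigenvalues. Real
parts within `1e-8` of zero are flagged marginal and classified as
saddles rather than silently as attractors — at a bifurcation point that
is the conservative call. States are clipped to the non-negative orthant
throughout: concentrations are physical, and with an even Hill exponent a
negative excursion would spuriously activate.

One substantive finding is worth recording here because it contradicts a
naive reading of the phase portraits: with the parameters above, raising
`gamma_u` to 1.5 moves the balanced (progenitor) attractor toward the
`v`-dominant attractor but does **not** eliminate it — the perturbed
two-TF system still has three stable fixed points, as confirmed by an
independent dense-grid descent oracle. The barrier between the progenitor
and the `v`-dominant attractor becomes very shallow (the two slow regions
visually merge), and the *fusion* proper happens once auto-activation is
annealed below roughly `alpha ≈ 1.2`. The population-level consequence —
near-extinction of the `u`-lineage — is exactly reproduced by the
simulation below.

## The population simulation

`simulate_population()` follows the stated protocol literally rather than
as a formal SDE discretisation: 1000 cells, 100 steps, update
`state <- state + 0.2 * rhs(state; alpha_t) + noise_t * N(0, 1)` per TF,
with `alpha_t = 1.5 * 0.98^(t-1)` and `noise_t = 0.5 * 0.98^(t-1)`
(first step unannealed), initial concentrations `N(1.5, 1)` clipped at 0,
and clipping at 0 after every step. Annealing `alpha` destabilises the
progenitor attractor, forcing commitment; each cell is then assigned to
the nearest stable attractor of the terminal
(`alpha = 1.5 * 0.98^99 ≈ 0.199`) system — by cluster totals in the
4-D model — with exact ties broken toward the lower label. In the
terminal bistable regime this nearest-attractor rule coincides with the
sign of `u - v`.

```{r simulation}
res <- simulate_population("two_tf", circuit_params(gamma = c(1.5, 1)),
                           sim_config(seed = 1))
glance(res)
```

Because the original report quotes single stochastic runs with an
unstated seed, lineage fractions are judged in expectation over ten seeds
with a ±5 percentage-point band; the qualitative ordering — the perturbed
two-cluster circuit commits several-fold more cells to the disfavoured
lineage than the perturbed two-TF circuit — holds seed by seed.

## Coexpression modules

`spearman_matrix()` computes gene–gene Spearman correlations over the
cells of one stage (64-cell by default; average ranks for ties, constant
genes zeroed with a warning), and `cluster_genes()` cuts a
complete-linkage tree on `1 - rho` into `k = 3` clusters. Complete
linkage is the default of the heatmap tooling this reproduces, and the
linkage is exposed because the exact 17/10/12 split can depend on it;
`k` is fixed at 3 by the two blastocyst bifurcations rather than chosen
automatically. Clusters are labelled TE/PE/EPI by which of *Cdx2*,
*Gata4*, *Nanog* they contain.

```{r coexpression, fig.height = 5.5}
panel <- generate_synthetic(synthetic_config(seed = 1, n_genes = 39))
cm <- spearman_matrix(panel, stage = 64)
cl <- cluster_genes(cm, k = 3)
count(cl, label)
cluster_separation(cm, cl)
autoplot(cm, clusters = cl)
```

On a panel where every gene belongs to a planted module, the three-way cut
recovers the modules exactly. With lineage-uninformative genes present
(the 48-gene default), a `k = 3` cut spends one cluster on the
uncorrelated genes and may merge the PE and EPI modules, whose members
are positively coexpressed across the TE-versus-ICM contrast — the same
behaviour visible in real blastocyst panels; inspect the dendrogram (the
`dendrogram` attribute) or raise `k` in that situation.

## Open choices made by this package

* PCA on the covariance (not correlation) matrix of mean-subtracted
  values: only mean-subtraction is part of the preprocessing contract,
  and all genes share one measurement unit.
* Mixtures and Q–Q diagnostics operate on `theta` throughout; segmenting
  the PC plane instead would require a supervised step this package
  deliberately avoids.
* Missing values are rejected rather than imputed; the supported input is
  a complete qRT-PCR panel.
* The reader accepts either raw Ct or pre-transformed expression via
  `input_is_ct`, since delivered tables come in both conventions.

## Known limitations

* The angular coordinate is treated as linear, not periodic; the origin
  placement must keep fates clear of the branch cut (use
  `origin = "auto"` when in doubt).
* Fixed-point search is multi-start local root finding, not continuation;
  counts are reliable for the lattice densities used here but an
  adversarially placed root could in principle be missed.
* The valley depth of the landscape reflects sampling proportions of cell
  types, so the input must be an unbiased sample of the population at
  each stage.
* Test and example problem sizes (e.g. ten simulation seeds, the reduced
  populations in unit tests) are the package's choices for routine
  verification; all headline quantities are also reproduced at the full
  1000-cell scale by `scripts/acceptance.R`.
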