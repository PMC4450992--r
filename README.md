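# epiland

Waddington epigenetic landscapes from single-cell expression profiles, and
ODE models of the gene circuits that decide early lineage bifurcations.

`epiland` is aimed at developmental/systems biologists with stage-annotated
single-cell expression tables (e.g. single-cell qRT-PCR panels of
preimplantation embryos) who want to

* visualise development as an epigenetic landscape — valleys are cell
  types, hills are the barriers between them;
* model a lineage bifurcation as a tristable dynamical system of
  auto-activating, mutually inhibiting transcription factors (TFs); and
* quantify why a bifurcation decided by two *clusters* of TFs resists
  perturbations that break the classical two-TF toggle circuit.

## The models

**Landscape.** Cells are projected onto the first two principal components
of their mean-subtracted expression profiles; each cell's state coordinate
is its angle `theta` around an origin placed in a cell-free region. Each
stage is fitted with a 1-D Gaussian mixture over `theta`
(`f(x) = Σ τ_k Φ(x | μ_k, Σ_k)`, component count chosen by BIC), and the
landscape height is the Boltzmann pseudo-potential
`U(x) = −ρ ln f(x) + ω`, linearly interpolated between stages along
developmental time `t = log2(stage)`.

**Circuits.** The two-TF toggle is
`du/dt = α uⁿ/(sⁿ+uⁿ) + β sⁿ/(sⁿ+vⁿ) − γ_u u` (and symmetrically for `v`);
the two-cluster circuit generalises it to four proteins via the pooled rate
law `η(a,b,c,d,γ) = α (aⁿ+bⁿ)/(sⁿ+aⁿ+bⁿ) + β sⁿ/(sⁿ+cⁿ+dⁿ) − γa`, observed
through the cluster totals `x = u1+u2`, `y = v1+v2`. Defaults: `n = 4`,
`s = 0.5`, `α = 1.5`, `β = 1`, `γ = 1`, perturbed `γ* = 1.5`. A stochastic
population simulation (1000 cells, 100 steps, force coefficient 0.2, noise
`0.5·0.98^t`, auto-activation annealed `1.5·0.98^t`) forces cells out of
the progenitor state and reads off the fraction committing to each lineage.

## Worked example

```r
library(epiland)

# synthetic 442-cell qRT-PCR panel with the stage structure of mouse
# preimplantation development
cells <- generate_synthetic(synthetic_config(seed = 1))

proj  <- pca_project(cells, origin = "auto")
mixes <- fit_all_stages(proj)
vapply(mixes, function(m) m$m, integer(1))
#> [1] 1 1 1 1 1 2 3

surface <- build_landscape(mixes, cells = proj)
autoplot(surface)   # one valley through 16 cells, two at 32, three at 64

# tristability of the two-TF toggle
fp <- find_fixed_points("two_tf", circuit_params())
count_stable(fp)
#> [1] 3

# perturb one TF's degradation rate and simulate commitment
res <- simulate_population("two_tf", circuit_params(gamma = c(1.5, 1)),
                           sim_config(seed = 1))
res$fractions
#>     1     2     3
#> 0.048 0.000 0.952

res4 <- simulate_population("two_cluster",
                            circuit_params(gamma = c(1, 1.5, 1, 1)),
                            sim_config(seed = 1))
res4$fractions
#>     1     2     3
#> 0.198 0.000 0.802
```

The component counts 1/1/1/1/1/2/3 are the cell types per stage (one
progenitor population through the 16-cell stage, the ICM/TE split at 32
cells, the EPI/PE/TE trichotomy at 64 cells). The simulation output shows
the robustness contrast: with one degradation rate raised by 50 %, only
~5 % of two-TF cells still reach the disfavoured lineage, against ~20 %
when the same perturbation hits one member of a two-TF *cluster* —
collective decision-making buffers the insult.

A coexpression view of the gene modules behind the bifurcations (on a
panel where every gene belongs to a planted module):

```r
panel <- generate_synthetic(synthetic_config(seed = 1, n_genes = 39))
cm <- spearman_matrix(panel, stage = 64)
cl <- cluster_genes(cm, k = 3)
dplyr::count(cl, label)
#> 1 EPI      12
#> 2 PE       10
#> 3 TE       17
autoplot(cm, clusters = cl)  # clustered correlation heatmap
```

The three complete-linkage clusters of the 64-cell-stage Spearman matrix
recover the planted TE (17 genes, containing *Cdx2*, *Eomes*, *Gata3*),
PE (10, *Gata4*/*Gata6*/*Sox17*) and EPI (12, *Nanog*/*Fgf4*/*Sox2*)
modules exactly.

A thin command-line launcher wrapping the same functions is installed at
`system.file("exec", "epiland", package = "epiland")`, with subcommands
`synth`, `landscape`, `phase`, `fixedpoints`, `simulate` and `clusters`;
every output TSV is accompanied by a provenance JSON that suffices to
re-run the computation.

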