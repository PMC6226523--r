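# basisdeconv

Bulk gene expression from blood or tissue is a weighted average over the cell
populations in the sample. Cell-mixture deconvolution inverts that averaging:
given a mixture profile **s** over a set of signature genes and a reference
*basis matrix* **M** (signature genes × cell types, each column the mean
expression profile of one purified population), it estimates the proportion
vector **p** from the linear-mixing model

```
s ≈ M p ,   p ≥ 0 ,   Σ p = 1
```

`basisdeconv` is for researchers who want to *build* such basis matrices from
heterogeneous sorted-cell expression compendia — not just apply a published
one — and to quantify how technical (microarray platform) and biological
(disease state) heterogeneity in the compendium affects downstream
deconvolution. Everything runs on synthetic data generated in-package, so the
whole pipeline is testable without external cohorts.

## What the package does

**Basis construction** (`build_basis()`). For every gene *g* and cell type
*i* within a lineage *l*, the one-vs-rest Hedges' g effect size `E_gil`
(pooled-SD standardized mean difference with the small-sample correction
`J = 1 − 3/(4(n₁+n₂) − 9)`) is computed, and genes are ranked by the
min-delta separation statistic

```
ΔE_gil = min over j ≠ i in l of ( E_gil − E_gjl )
```

— high ΔE marks genes separating the target from its *closest* relative.
A stepwise search then walks down each ranked list, scoring samples by the
mean of per-gene z-scores and recording the AUROC of classifying the target
against the rest of its lineage at each prefix length; the signature is the
smallest prefix within ε = 0.005 of the maximal AUROC, with at least 5
genes. Stage 1 separates cell types within lineages; stage 2 removes all
stage-1 genes and repeats the procedure to separate the lineages themselves.
Basis values are per-cell-type means over the quantile-normalized compendium.

**Deconvolution** (`deconvolve_dataset()`). Four interchangeable solvers
behind one preprocessing contract (dataset-level quantile normalization plus
z-scoring of sample and basis): ordinary least squares, simplex-constrained
quadratic programming (fast active-set non-negative least squares),
Huber-robust IRLS, and linear-kernel ν-SVR over ν ∈ {0.25, 0.5, 0.75}.
Goodness of fit is the Pearson correlation between **s** and the
reconstitution **M p̂**, with an optional permutation p-value (random gene
subsets re-solved under the same pipeline).

**Bias evaluation** (`mad_heterogeneity()`, `separation_auroc()`,
`fisher_combine()`, `proportion_agreement()`). Platform heterogeneity is the
median absolute deviation of per-platform median goodness of fit, tested
one-sided against a platform-label permutation null via a Z-test; gof
p-values score blood-versus-tissue discrimination by AUROC; estimated
proportions are compared with measured ones by pooled Pearson r and RMSE in
percentage points.

**Synthetic compendium generator** (`sim_config()`,
`simulate_sorted_compendium()`, `simulate_mixtures()`, ...) and three
scripted experiments (`run_platform_bias_experiment()`,
`run_disease_bias_experiment()`, `run_concordance_experiment()`) that
reproduce, directionally, the three phenomena motivating multi-platform
mixed-state basis construction: single-platform bases are more
platform-heterogeneous, healthy-only bases lose blood-vs-tissue
discrimination on disease samples, and the choice of basis matrix drives
estimate discordance more than the choice of solver.

## Worked example

```r
library(basisdeconv)

# a sorted-cell compendium: 20 immune cell types, 10 replicates each
cfg <- sim_config(n_genes = 1500, n_samples_per_type = 10, n_markers = 10,
                  n_platforms = 1, platform_tau = 0, seed = 7)
sim <- simulate_sorted_compendium(cfg)

# hierarchical signature selection + mean-expression assembly
basis <- build_basis(sim$expr)
glance(basis)
#> # A tibble: 1 x 6
#>   name  n_genes n_cell_types n_lineages n_cell_type_stage n_lineage_stage
#> 1 basis     132           20         10                80              52

# 20 blood-like mixtures with known proportions, deconvolved four ways
# (recovery is assessed in the raw linear space; see the methods vignette)
mix <- simulate_mixtures(sim$truth, n = 20, seed = 8)
res <- deconvolve_dataset(mix$expr, basis, methods = c("linear", "qp", "robust", "svr"),
                          qn = FALSE, rescale = FALSE)
glance(res)
#> # A tibble: 4 x 5
#>   method basis_id n_samples median_gof  iqr_gof
#> 1 linear basis           20      0.999 0.000717
#> 2 qp     basis           20      0.999 0.000787
#> 3 robust basis           20      0.999 0.000866
#> 4 svr    basis           20      0.999 0.000746

est <- tibble::as_tibble(res)[res$method == "qp", ]
cor(as.numeric(as.matrix(est[, proportion_cols(res)])),
    as.numeric(mix$truth$proportions[est$sample_id, proportion_cols(res)]))
#> pooled Pearson r (qp estimates vs true proportions): 0.944
```

The `glance(basis)` row says the two-stage selection kept 132 signature
genes (80 separating cell types within their lineages, 52 separating the
lineages) for 20 cell types — about 7 genes per target, reflecting the
minimal-signature stopping rule. Median goodness of fit of 0.999 on these
low-noise mixtures says each mixture is reconstituted almost perfectly from
the estimated proportions; the pooled r of 0.944 compares all 400 estimated
proportions against the simulation ground truth. (`build_basis()` warns that
four singleton-lineage cell types have no within-lineage stage — their
markers enter at the lineage stage instead; that is expected for this
hierarchy.)

Each result type has `tidy()`/`glance()` and `autoplot()` methods; a thin
command-line wrapper with `simulate`, `build-basis`, `deconvolve`,
`evaluate-bias`, `agreement` and `experiments` subcommands is installed
under `inst/cli/basisdeconv`.

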