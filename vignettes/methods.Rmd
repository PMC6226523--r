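---
title: "Models, assumptions and design choices in basisdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in basisdeconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(basisdeconv)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each component, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices that matter. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The mixing model and its assumptions

A bulk expression profile is modeled as a non-negative linear combination of
cell-type-specific mean profiles on the **linear** intensity scale:
`s = M p + noise` with `p` on the probability simplex. Everything downstream
assumes linearity, which holds for transcript abundance but not for
log-transformed data; the package therefore never log-transforms and treats
all inputs as linear-scale. The basis matrix `M` must contain genes whose
expression differs strongly *between* cell types and is stable *within*
them — that is what the construction stage optimizes for.

## Basis construction

**Effect sizes.** Differential expression of gene `g` in cell type `i`
against the remaining types of its lineage is measured by Hedges' g: the
mean difference standardized by the pooled SD, times the small-sample
correction `J = 1 − 3/(4(n₁+n₂) − 9)`. The correction is applied always —
it is within rounding of 1 for large groups and materially less biased for
the 3–10-replicate groups typical of sorted-cell compendia. Groups need at
least `min_samples = 3` observations per side (the pooled SD, and with it
the correction, degenerates below that). A gene with zero pooled SD but
unequal means receives a signed sentinel of magnitude 1e6: a perfect
separator must outrank every finite effect without introducing `Inf` into
later arithmetic.

**Ranking.** Candidate markers for target `i` are ranked by the min-delta
statistic `ΔE_gil = min_{j≠i} (E_gil − E_gjl)` — the margin of the target's
effect over its *strongest* competitor, so a gene shared by two related cell
types scores near zero even if both are far from the rest. Ties are broken
lexicographically by gene id for determinism.

**Stepwise selection.** The multi-gene score of a sample is the mean of
per-gene z-scores over the current prefix of the ranked list (gene-wise
standardization over the comparison population). This is the simplest
monotone aggregate that reduces to the single-gene AUROC at prefix length
one and requires no fitted weights. The selected signature is the smallest
prefix whose AUROC is within `epsilon = 0.005` of the maximum over the
searched horizon, raised to `min_genes = 5`. The search horizon is capped at
`max_genes = 50` prefixes: signatures in this family of methods are tens of
genes at most, and the cap bounds runtime without binding in practice. The
AUROC itself is the rank-based (Mann–Whitney) statistic with half-credit for
ties.

**Two stages.** Stage 1 selects signatures separating each cell type within
its lineage; stage 2 removes *all* stage-1 genes from the candidate pool
(their within-lineage specificity would confound between-lineage
separation — removal is global, not per lineage) and repeats selection to
separate lineages from one another. Lineages with a single cell type have no
stage-1 comparison and are skipped with a warning; their identity is carried
entirely by the lineage stage. Basis values are per-cell-type means over the
quantile-normalized compendium, with stage provenance recorded per gene.

## Preprocessing contracts

**Quantile normalization** forces every sample to the per-rank mean of the
sorted columns; tied values receive the mean of the reference values their
rank span covers. This dialect is idempotent to machine precision on
tie-free data. It is implemented in-package because the tie convention is
part of the contract; on tie-free input it agrees with the standard
implementations to 1e-12 (asserted in the tests against limma).

**Rescaling.** The deconvolution pipeline optionally z-scores the mixture
vector by its own mean/SD and the basis by its matrix-wide mean/SD. Global
(not per-column) standardization of the basis preserves between-cell-type
contrasts. This uniform contract exists so that solver comparisons are not
confounded by preprocessing differences. Two consequences matter:

* For solvers that re-normalize their coefficients (OLS, robust, SVR),
  estimates with and without rescaling agree closely (correlation > 0.95 in
  the tests) — rescaling is innocuous for them.
* For the simplex-constrained QP solver it is *not* innocuous: after
  z-scoring, a mixture is `s_z ≈ α M_z p + β1` with `α = sd(M)/sd(s) ≠ 1`,
  and the hard constraint `Σp = 1` cannot absorb `α`. Recovery benchmarks
  therefore run in the raw linear space (`qn = FALSE, rescale = FALSE`),
  where the mixing model holds exactly; the z-scoring contract is a
  comparability device for heterogeneous real data, not part of the
  estimand. The ν-SVR solver standardizes internally in either mode because
  support-vector fitting is scale-sensitive.

## Solvers

* `linear` — OLS without intercept; negatives clipped, renormalized.
* `qp` — `argmin ‖s − Mp‖²` s.t. `p ≥ 0, Σp = 1`. Solved as non-negative
  least squares with a heavily weighted sum-to-one augmentation row (the
  fully-constrained trick familiar from spectral unmixing), using a fast
  active-set solver on the 20×20 normal equations, then refined to the
  exact KKT solution on the identified support. Exact recovery on noiseless
  mixtures is at machine precision.
* `robust` — Huber IRLS, tuning constant 1.345, scale re-estimated from the
  residual MAD each iteration, stopping when the relative coefficient change
  drops below 1e-6. Convergence is linear and slow on strongly collinear
  bases (all columns share the housekeeping baseline), so the iteration cap
  is a generous 500; each iteration is a small weighted solve, so the cap is
  cheap. Non-convergence is an error, never a silent result.
* `svr` — linear-kernel ν-SVR (C = 1, tolerance 1e-4) over
  ν ∈ {0.25, 0.5, 0.75}; the fit minimizing the reconstruction RMSE of the
  raw coefficient vector is kept, then clipped and renormalized.

Goodness of fit is `cor(s, M p̂)` in the space the solver actually fitted.
Because Pearson correlation is affine-invariant, the value is identical
whether or not the pair was z-scored.

**Permutation significance.** The null distribution for a sample's gof draws
uniform random gene subsets (of the size actually used) from the sample's
full profile, assigns them to the basis gene slots, and re-solves; the
p-value uses the add-one estimator, so it is never zero and is
(discretely) uniform when the sample has no relation to the basis — the
calibration is asserted in the acceptance suite. Note that for a fixed basis
the p-value is a monotone transform of the gof, so rank-based summaries
(like the blood-versus-tissue AUROC) see the same ordering either way, up to
ties at the resolution floor `1/(n_perm+1)`.

## The platform-heterogeneity MAD test

The observed statistic is the raw median absolute deviation of per-platform
median gof, methods pooled — raw, without the 1.4826 consistency constant,
because it is used as a descriptive heterogeneity score rather than a robust
SD estimate. The null is generated by permuting platform labels across
samples (group sizes preserved), and significance is a one-sided upper-tail
Z-test against that background; the normal approximation of the permutation
distribution is adequate at the replicate counts used (null rejection rate
at α = 0.05 measured at 0.065–0.08 over 200 replicates in the acceptance
suite). A `per_sample` variant — median absolute deviation of each sample's
gof from the mean of per-platform means — is available behind a flag; the
per-platform-median form is the primary definition. Power at a platform
dispersion of τ = 0.5 was the basis for sizing the calibration cohort at
8 mixtures per platform (a smaller cohort of 5 gave 16% lower power).

## The synthetic compendium

The generator emulates a multi-platform sorted-cell compendium:

* one shared log-normal baseline expression profile (location 6, scale 1 on
  the log scale — a realistic microarray-like dynamic range);
* per cell type, a disjoint set of planted marker genes multiplied by a
  fold change (default 4× — the weakest contrast that still behaves like a
  canonical marker);
* sorted replicates = cell-type mean × per-gene log-normal biological
  variability (`bio_cv = 0.2`) + additive Gaussian noise truncated at zero
  (default SD 5% of the mean signal). The biological CV term matters: with
  purely additive noise, within-sample gene ranks are deterministic, and
  quantile normalization then maps a rank-stable gene to the *identical*
  value in every replicate of a group — genes whose rank shifts between
  groups acquire artificial zero within-group variance and saturate the
  effect-size sentinel. Real replicates, especially across studies, vary
  per gene; 20% CV is conservative for cross-laboratory compendia. The
  truncation is a proper left-truncated Gaussian (inverse-CDF sampling),
  not clamping: clamping would put an atom of exact-zero ties into the data,
  which microarray intensities do not show and which breaks the idempotence
  of quantile normalization.
* platform distortion: per platform, a shared per-gene multiplicative factor
  `exp(N(0, τ²))` plus an optional dynamic-range exponent; platform
  assignment is balanced within cell types so single-platform bases remain
  constructible.
* disease: a shared perturbed gene set with per-gene log-normal factors,
  modulated by a lineage-structured response (half the lineages respond),
  plus — the component that actually breaks healthy-only bases — an
  *aberrant disease program*: an out-of-basis expression state (think blast
  expansion in leukemia) that displaces up to `disease_program_mass` of a
  disease sample's transcriptome. Gene-wise factors alone are a per-gene
  reweighting that leaves the cell-type contrast structure intact, so a
  healthy basis often still fits perturbed mixtures perfectly; displacement
  by an unseen expression state is the mechanism by which severe disease
  makes blood samples partially out-of-basis. Disease mixtures carry a
  per-sample severity spanning 0.4–1 as an evenly spaced spectrum (a
  designed cohort from mild to fully displaced).
* tissue-like out-of-basis samples: an independent parenchymal profile plus
  a 4–15% immune infiltrate (evenly spaced across the cohort) — real
  biopsies contain resident leukocytes, and that partial fit is exactly what
  makes separating biopsies from blood by fit quality non-trivial. The
  biopsy cohort's own state is held at baseline; the disease axis the
  generator models is the derangement of circulating cells.

What the generator does **not** emulate: probe-level microarray artifacts,
background correction, RNA-seq count noise, correlated gene modules beyond
the shared baseline, or covariance between marker identity and expression
level. Passing tests on this generator therefore demonstrate the internal
consistency and statistical behavior of the machinery under the stated
model, not performance on any real cohort.

## The scripted experiments

All three experiments run at a desk-scale default (20 cell types, 1500
genes, 12 sorted samples per cell type; 20 replicates), chosen so each
completes in a few minutes on one CPU while keeping every group above the
effect-size sample floor.

* **Platform bias**: basis from the best-represented single platform versus
  a basis from all platforms, scored by the MAD statistic on
  platform-distorted mixtures (τ = 0.5, the dispersion at which the MAD test
  has ≥ 90% power). The single-platform basis inherits one platform's gene
  factors and misfits the others.
* **Disease bias**: healthy-only basis (`H`) versus healthy+disease basis
  (`HD`), scored by the blood-versus-tissue AUROC of gof p-values,
  separately on healthy-state and disease-state cohorts. `HD` wins on
  disease because its column space contains the disease program; both bases
  discriminate well on healthy cohorts. The QP solver is used here: its few
  effective degrees of freedom keep the permutation null tight, so fit
  differences remain visible in the p-values (an unconstrained solver with
  20 free coefficients on ~150 genes fits even random data to r ≈ 0.4,
  compressing the p-value scale).
* **Concordance**: all four solvers crossed with two distinct bases
  (all-platform versus single-platform, so gene selection and values both
  differ); per-sample proportion estimates are correlated pairwise and
  grouped as same-matrix / different-matrix. The same-matrix group's median
  correlation exceeds the different-matrix groups' in every replicate of the
  acceptance run — the basis matrix, not the solver, is the dominant source
  of discordance.

## Degenerate inputs and tie-breaks

Duplicate gene or sample ids, negative or non-finite expression, annotations
referencing unknown samples, promiscuous probes, empty gene intersections,
single-class AUROC labels, p-values outside (0, 1], and sub-floor group
sizes all raise immediate errors (or warnings with exclusion where the spec
of the operation calls for it). Single-sample quantile normalization returns
its input with a warning. Per-sample failures inside `deconvolve_dataset()`
are collected, not fatal. Ranking ties break lexicographically; AUROC ties
count one half; the permutation p-value is add-one-corrected. All
generators, selections and permutation tests are pure functions of their
seed arguments; derived child seeds stay within the 32-bit integer range.

## Known limitations

* The generator's marker model (disjoint marker sets, shared baseline) makes
  signature selection easier than on real compendia, where markers overlap
  and co-vary; recovery rates here are upper bounds.
* Fisher's combination of per-method p-values assumes independence, which
  pooled methods on the same samples do not satisfy; treat combined values
  as approximate.
* The MAD Z-test relies on a normal approximation of a permutation
  distribution; its measured null rejection rate (0.065–0.08 at α = 0.05)
  is slightly liberal.
* The blood-versus-tissue AUROC saturates when every mixture's p-value hits
  the permutation floor; the number of permutations bounds the resolution.
* Deconvolution output is relative proportions over the basis cell types;
  absolute cell counts and populations missing from the basis are out of
  scope.
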