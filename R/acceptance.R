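# Benchmark scenarios behind the package's headline claims. They are exported
# so that the test suite and scripts/acceptance.R reproduce the same
# quantities from the same study conditions.

#' Exact-recovery benchmark scenario
#'
#' A 20-cell-type compendium with 15 planted markers per type and a 317-gene
#' reference basis (all planted markers plus filler genes), with 50 Dirichlet
#' mixtures. `noiseless = TRUE` switches all stochastic terms after the mean
#' profiles off, so mixtures are exact simplex combinations of the basis
#' columns.
#'
#' @param seed RNG seed.
#' @param noiseless Generate noise-free mixtures and compendium?
#' @param n_mixtures Number of mixtures.
#' @return List with `basis`, `mixtures` (an `expr_matrix`), and `true_p`
#'   (mixtures x cell types).
#' @export
acceptance_recovery_scenario <- function(seed = 1, noiseless = TRUE, n_mixtures = 50) {
  cfg <- sim_config(n_genes = 2000, n_samples_per_type = 10, n_markers = 15,
                    fold_change = 4, n_platforms = 1, platform_tau = 0,
                    noise_sd = if (noiseless) 0 else NULL,
                    bio_cv = if (noiseless) 0 else 0.2, seed = seed)
  sim <- simulate_sorted_compendium(cfg)
  markers <- unlist(sim$truth$markers, use.names = FALSE)
  filler <- setdiff(rownames(sim$expr$values), markers)
  genes <- c(markers, sort(filler)[seq_len(317 - length(markers))])
  basis <- basis_from_gene_list(sim$expr, genes, name = "reference_317")
  mx <- simulate_mixtures(sim$truth, n_mixtures,
                          noise_sd = if (noiseless) 0 else NULL,
                          seed = child_seed(seed, 17))
  list(basis = basis, mixtures = mx$expr, true_p = mx$truth$proportions)
}

#' Noisy pipeline-recovery benchmark scenario
#'
#' Same scale as [acceptance_recovery_scenario()], but the compendium carries
#' 5 percent additive noise, the basis is constructed end-to-end with
#' [build_basis()], and the mixtures are noisy.
#'
#' @param seed RNG seed.
#' @param n_mixtures Number of mixtures.
#' @return As [acceptance_recovery_scenario()].
#' @export
acceptance_noise_scenario <- function(seed = 1, n_mixtures = 50) {
  cfg <- sim_config(n_genes = 2000, n_samples_per_type = 10, n_markers = 15,
                    fold_change = 4, n_platforms = 1, platform_tau = 0, seed = seed)
  sim <- simulate_sorted_compendium(cfg)
  basis <- suppressWarnings(build_basis(sim$expr, name = "pipeline"))
  mx <- simulate_mixtures(sim$truth, n_mixtures, seed = child_seed(seed, 17))
  list(basis = basis, mixtures = mx$expr, true_p = mx$truth$proportions)
}

#' Recover proportions in a benchmark scenario and score against truth
#'
#' Deconvolution runs in the raw linear space (`qn = FALSE, rescale = FALSE`):
#' the linear-mixing model holds on that scale, so parameter recovery is
#' well-posed for the simplex-constrained solver too (the SVR solver
#' standardizes internally either way). See the methods vignette for why the
#' z-scoring contract is kept out of recovery benchmarks.
#'
#' @param scenario Output of an `acceptance_*_scenario()` function.
#' @param methods Solvers to score.
#' @return List with per-method named vectors `max_abs_err`, `pearson`
#'   (pooled), `rmse_pp` (percentage points), plus all `gof` values and
#'   `n_mixtures`.
#' @export
acceptance_recover <- function(scenario, methods = c("linear", "qp", "robust", "svr")) {
  res <- deconvolve_dataset(scenario$mixtures, scenario$basis, methods = methods,
                            qn = FALSE, rescale = FALSE)
  stopifnot(nrow(attr(res, "failures")) == 0)
  cts <- colnames(scenario$true_p)
  out <- list(max_abs_err = c(), pearson = c(), rmse_pp = c())
  for (m in methods) {
    sub <- tibble::as_tibble(res)[res$method == m, ]
    est <- as.matrix(sub[, cts])
    tru <- scenario$true_p[sub$sample_id, cts]
    out$max_abs_err[m] <- max(abs(est - tru))
    out$pearson[m] <- stats::cor(as.numeric(est), as.numeric(tru))
    out$rmse_pp[m] <- 100 * sqrt(mean((est - tru)^2))
  }
  out$gof <- res$gof
  out$n_mixtures <- ncol(scenario$mixtures$values)
  out
}

#' Planted-marker recovery benchmark
#'
#' For each seed, builds a basis from a 12-cell-type / 4-lineage compendium
#' with 6 planted markers per type (fold change 4, 10 samples per type) and
#' checks that every cell type's signature recovers at least 80 percent of
#' its planted markers, that signatures respect the 5-gene floor, and that
#' the two selection stages stay disjoint.
#'
#' @param n_seeds Number of independent seeds.
#' @param seed Master seed.
#' @return Tibble with one row per seed: `seed_ok` (all cell types >= 80
#'   percent marker recovery), `min_recovery`, `signature_size_ok`,
#'   `stages_disjoint`.
#' @export
acceptance_marker_recovery <- function(n_seeds = 20, seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_genes = 800,
      cell_types = stats::setNames(rep(paste0("lineage", 1:4), each = 3), paste0("ct", 1:12)),
      n_samples_per_type = 10, n_markers = 6, fold_change = 4,
      n_platforms = 1, platform_tau = 0, seed = child_seed(seed, i))
    sim <- simulate_sorted_compendium(cfg)
    b <- suppressWarnings(build_basis(sim$expr))
    ct_sigs <- b$signatures[names(cfg$cell_types)]
    recovery <- vapply(names(cfg$cell_types), function(ct) {
      sig <- ct_sigs[[ct]]
      if (is.null(sig)) return(0)
      mean(sim$truth$markers[[ct]] %in% sig$genes)
    }, 0.0)
    sizes_ok <- all(vapply(b$signatures, function(s) s$chosen_k >= 5 || s$flagged, TRUE))
    s1 <- names(b$stage_of)[b$stage_of == "cell_type_stage"]
    s2 <- names(b$stage_of)[b$stage_of == "lineage_stage"]
    tibble::tibble(seed_ok = all(recovery >= 0.8), min_recovery = min(recovery),
                   signature_size_ok = sizes_ok,
                   stages_disjoint = length(intersect(s1, s2)) == 0)
  })
  dplyr::bind_rows(rows)
}

# Shared scenario for the MAD calibration study: a clean basis and truth,
# mixtures spread over platforms.
mad_calibration_scenario <- function(seed) {
  cfg <- sim_config(
    n_genes = 600,
    cell_types = stats::setNames(rep(paste0("lineage", 1:4), each = 3), paste0("ct", 1:12)),
    n_samples_per_type = 8, n_markers = 6, fold_change = 4,
    n_platforms = 1, platform_tau = 0, seed = seed)
  sim <- simulate_sorted_compendium(cfg)
  basis <- suppressWarnings(build_basis(sim$expr))
  list(cfg = cfg, truth = sim$truth, basis = basis)
}

#' Calibration and power of the platform-heterogeneity MAD Z-test
#'
#' Null replicates draw mixtures spread evenly over 8 platforms with no
#' platform effect and record the Z-test rejection rate at alpha = 0.05;
#' power replicates inject a per-platform gene-factor dispersion of
#' `tau = 0.5` into the mixtures (the basis stays clean) and record the
#' rejection rate.
#'
#' @param n_null,n_power Replicate counts.
#' @param seed Master seed.
#' @param n_platforms,n_per_platform Mixture layout per replicate.
#' @param n_perm Label permutations per test.
#' @return List with `null_rejection_rate`, `power`, `n_null`, `n_power`.
#' @export
acceptance_mad_calibration <- function(n_null = 200, n_power = 50, seed = 1,
                                       n_platforms = 8, n_per_platform = 8,
                                       n_perm = 150) {
  sc <- mad_calibration_scenario(child_seed(seed, 1))
  plats <- paste0("platform_", seq_len(n_platforms))
  run_rep <- function(i, tau) {
    mx <- simulate_mixtures(sc$truth, n_platforms * n_per_platform,
                            seed = child_seed(seed, 100 + i))
    ann <- mx$expr$annotations
    ann$platform <- rep(plats, each = n_per_platform)
    expr <- expression_matrix(mx$expr$values, ann)
    if (tau > 0) {
      expr <- apply_platform_effect(expr, tau = tau, seed = child_seed(seed, 7000 + i))
    }
    res <- deconvolve_dataset(expr, sc$basis, methods = "linear")
    res <- dplyr::left_join(res, ann[c("sample_id", "platform")], by = "sample_id")
    het <- mad_heterogeneity(res, n_perm = n_perm, seed = child_seed(seed, 3000 + i))
    het$pvalue < 0.05
  }
  null_rej <- vapply(seq_len(n_null), run_rep, TRUE, tau = 0)
  power_rej <- vapply(seq_len(n_power), function(i) run_rep(i + n_null, tau = 0.5), TRUE)
  list(null_rejection_rate = mean(null_rej), power = mean(power_rej),
       n_null = n_null, n_power = n_power)
}

#' Null calibration of the goodness-of-fit permutation p-value
#'
#' Generates samples with no relation to the basis (independent log-normal
#' profiles over a larger gene universe) and returns their permutation
#' p-values; under this null-generation process the p-values should be
#' (discretely) uniform.
#'
#' @param n_samples Number of null samples.
#' @param n_perm Permutations per p-value.
#' @param seed Master seed.
#' @return Numeric vector of p-values.
#' @export
acceptance_gof_null_pvalues <- function(n_samples = 100, n_perm = 99, seed = 1) {
  sc <- mad_calibration_scenario(child_seed(seed, 2))
  universe <- rownames(sc$truth$mean_profiles)
  vapply(seq_len(n_samples), function(i) {
    prof <- withr::with_seed(child_seed(seed, 400 + i),
                             stats::setNames(rlnorm(length(universe), 4, 1), universe))
    gof_significance(prof, sc$basis, method = "linear", n_perm = n_perm,
                     seed = child_seed(seed, 800 + i))
  }, 0.0)
}
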