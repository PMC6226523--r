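#' Default scenario for the bias experiments
#'
#' A desk-scale multi-platform sorted-cell scenario: the full 20-cell-type /
#' 9-lineage immune panel, 1500 genes, 12 sorted samples per cell type spread
#' over 4 platforms. Platform dispersion defaults to `tau = 0.5`; the disease
#' variant perturbs half the transcriptome with a log-SD comparable to the
#' marker contrast (`log(4) ~ 1.4`) and adds two out-of-basis tissue
#' populations.
#'
#' @param kind `"platform"`, `"disease"`, or `"concordance"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
experiment_config <- function(kind = c("platform", "disease", "concordance"), ...) {
  kind <- match.arg(kind)
  base <- list(n_genes = 1500, n_samples_per_type = 12, n_markers = 10,
               fold_change = 4, n_platforms = 4, platform_tau = 0.5)
  if (kind == "disease") {
    base$platform_tau <- 0
    base$n_platforms <- 1
    base$disease_fraction <- 0.5
    base$disease_gene_fraction <- 0.5
    base$disease_scale <- 0.8
    base$disease_program_mass <- 1.0
    base$n_out_of_basis <- 3
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

subset_samples <- function(m, keep) {
  expression_matrix(m$values[, keep, drop = FALSE],
                    m$annotations[m$annotations$sample_id %in% colnames(m$values)[keep], ])
}

# Platform-distorted mixtures: n_per_platform mixtures per platform, sharing
# the compendium's platform factors.
platform_mixtures <- function(sim, n_per_platform, seed) {
  plats <- colnames(sim$truth$platform_factors)
  pieces <- lapply(seq_along(plats), function(i) {
    mx <- simulate_mixtures(sim$truth, n_per_platform, seed = child_seed(seed, i),
                            prefix = sprintf("mix_p%d_", i))
    ann <- mx$expr$annotations
    ann$platform <- plats[i]
    expr <- expression_matrix(mx$expr$values, ann)
    expr <- apply_platform_effect(expr, factors = sim$truth$platform_factors,
                                  gamma = sim$truth$platform_gamma)
    list(expr = expr, true_p = mx$truth$proportions)
  })
  vals <- do.call(cbind, lapply(pieces, function(p) p$expr$values))
  ann <- dplyr::bind_rows(lapply(pieces, function(p) p$expr$annotations))
  list(expr = expression_matrix(vals, ann),
       true_p = do.call(rbind, lapply(pieces, function(p) p$true_p)))
}

new_experiment_report <- function(experiment, cfg, n_reps, seed, per_rep, summary, verdicts) {
  structure(list(experiment = experiment, config = cfg, n_reps = n_reps,
                 seed = seed, per_rep = per_rep, summary = summary,
                 verdicts = verdicts), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: %d replicates (seed %d)\n",
              x$experiment, x$n_reps, x$seed))
  print(x$summary)
  for (v in names(x$verdicts)) {
    cat(sprintf("  [%s] %s\n", if (isTRUE(x$verdicts[[v]])) "pass" else "FAIL", v))
  }
  invisible(x)
}

#' @export
#' @rdname run_platform_bias_experiment
#' @param x An `experiment_report`.
#' @param ... Unused.
tidy.experiment_report <- function(x, ...) x$per_rep

#' Platform-bias experiment
#'
#' Per replicate: simulate a multi-platform sorted-cell compendium, build a
#' basis from a *single* platform's sorted cells (the best-represented one)
#' and a basis from *all* platforms, deconvolve platform-distorted mixtures
#' with every method against both, and compare their platform-heterogeneity
#' MAD statistics. A multi-platform basis absorbs platform distortion into
#' its mean profiles, so its goodness of fit should be more homogeneous
#' across platforms.
#'
#' @param cfg A [sim_config()]; needs >= 2 platforms with `platform_tau > 0`
#'   (default: [experiment_config()]).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param methods Deconvolution methods to pool.
#' @param n_mix_per_platform Mixtures per platform per replicate.
#' @param mad_n_perm Permutations for the MAD Z-test.
#' @return An `experiment_report`. `per_rep` carries per-replicate MAD, Z and
#'   p per basis plus per-platform median gof; `summary` the fraction of
#'   replicates with MAD(single) > MAD(multi).
#' @export
run_platform_bias_experiment <- function(cfg = experiment_config("platform"),
                                         n_reps = 20, seed = 1,
                                         methods = c("linear", "qp", "robust", "svr"),
                                         n_mix_per_platform = 5, mad_n_perm = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_platforms < 2) stop_bd("platform experiment needs >= 2 platforms")
  rows <- list(); platform_rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- child_seed(seed, r)
    sim <- simulate_sorted_compendium(cfg_r)
    ann <- sim$expr$annotations
    main_platform <- names(sort(table(ann$platform), decreasing = TRUE))[1]
    single <- subset_samples(sim$expr, which(ann$platform == main_platform))
    bases <- list(
      single_platform = suppressWarnings(build_basis(single, name = "single_platform")),
      multi_platform = suppressWarnings(build_basis(sim$expr, name = "multi_platform"))
    )
    mx <- platform_mixtures(sim, n_mix_per_platform, seed = child_seed(seed, 1000 + r))
    for (b in names(bases)) {
      res <- deconvolve_dataset(mx$expr, bases[[b]], methods = methods)
      res <- dplyr::left_join(res, mx$expr$annotations[c("sample_id", "platform")],
                              by = "sample_id")
      het <- suppressWarnings(
        mad_heterogeneity(res, n_perm = mad_n_perm, seed = child_seed(seed, 2000 + r)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, basis = b, mad = het$mad_observed, z = het$z, pvalue = het$pvalue)
      pp <- het$per_platform; pp$rep <- r; pp$basis <- b
      platform_rows[[length(platform_rows) + 1]] <- pp
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(per_rep[c("rep", "basis", "mad")],
                             names_from = "basis", values_from = "mad")
  frac <- mean(wide$single_platform > wide$multi_platform)
  summary <- tibble::tibble(
    frac_single_gt_multi = frac,
    median_mad_single = stats::median(wide$single_platform),
    median_mad_multi = stats::median(wide$multi_platform))
  rep <- new_experiment_report("platform_bias", cfg, n_reps, seed, per_rep, summary,
                               list(single_platform_more_heterogeneous = frac >= 0.9))
  rep$per_platform <- dplyr::bind_rows(platform_rows)
  rep
}

#' Disease-bias experiment
#'
#' Per replicate: build a basis from healthy sorted cells only (`H`) and one
#' from healthy + disease cells (`HD`). Test cohorts are blood-like mixtures
#' and out-of-basis tissue-like samples, generated separately in the healthy
#' and the disease state. Each sample's goodness-of-fit permutation p-value
#' scores the blood-versus-tissue AUROC per (basis, state). A healthy-only
#' basis should lose discrimination on disease-state samples, while both
#' bases should discriminate well on healthy-state samples.
#'
#' @param cfg A [sim_config()] with `disease_fraction > 0` and
#'   `n_out_of_basis >= 1` (default: [experiment_config("disease")]).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param method Deconvolution method. The simplex-constrained QP solver is
#'   the default: its few effective degrees of freedom keep the permutation
#'   null tight, so fit quality differences stay visible in the p-values.
#' @param n_mix,n_tissue Blood mixtures / tissue samples per state.
#' @param n_perm Permutations for each goodness-of-fit p-value.
#' @return An `experiment_report`; `per_rep` has one AUROC per
#'   (rep, basis, state), `summary` the fraction of replicates with
#'   AUROC(HD) > AUROC(H) on disease-state samples and the median AUROCs.
#' @export
run_disease_bias_experiment <- function(cfg = experiment_config("disease"),
                                        n_reps = 20, seed = 1, method = "qp",
                                        n_mix = 12, n_tissue = 16, n_perm = 120) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$disease_fraction <= 0) stop_bd("disease experiment needs disease_fraction > 0")
  if (cfg$n_out_of_basis < 1) stop_bd("disease experiment needs n_out_of_basis >= 1")
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- child_seed(seed, r)
    sim <- simulate_sorted_compendium(cfg_r)
    ann <- sim$expr$annotations
    healthy_only <- subset_samples(sim$expr, which(ann$disease_state == "healthy"))
    bases <- list(
      H = suppressWarnings(build_basis(healthy_only, name = "H")),
      HD = suppressWarnings(build_basis(sim$expr, name = "HD"))
    )
    for (state in c("healthy", "disease")) {
      blood <- simulate_mixtures(sim$truth, n_mix, seed = child_seed(seed, 3000 + r),
                                 disease_state = state)$expr
      tissue <- simulate_out_of_basis_samples(cfg_r, sim$truth, n_tissue,
                                              seed = child_seed(seed, 4000 + r),
                                              disease_state = state)
      test <- expression_matrix(cbind(blood$values, tissue$values),
                                dplyr::bind_rows(blood$annotations, tissue$annotations))
      for (b in names(bases)) {
        res <- deconvolve_dataset(test, bases[[b]], methods = method,
                                  with_pvalue = TRUE, n_perm = n_perm,
                                  seed = child_seed(seed, 5000 + r))
        res <- dplyr::left_join(res, test$annotations[c("sample_id", "tissue_source")],
                                by = "sample_id")
        au <- separation_auroc(res$pvalue, res$tissue_source, positive = "blood")
        rows[[length(rows) + 1]] <- tibble::tibble(
          rep = r, basis = b, state = state, auroc = au)
      }
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(per_rep, names_from = "basis", values_from = "auroc")
  dis <- wide[wide$state == "disease", ]
  hea <- wide[wide$state == "healthy", ]
  summary <- tibble::tibble(
    frac_HD_gt_H_on_disease = mean(dis$HD > dis$H),
    median_auroc_H_disease = stats::median(dis$H),
    median_auroc_HD_disease = stats::median(dis$HD),
    median_auroc_H_healthy = stats::median(hea$H),
    median_auroc_HD_healthy = stats::median(hea$HD))
  new_experiment_report("disease_bias", cfg, n_reps, seed, per_rep, summary, list(
    mixed_state_basis_wins_on_disease = summary$frac_HD_gt_H_on_disease >= 0.9,
    both_bases_strong_on_healthy = summary$median_auroc_H_healthy > 0.9 &&
      summary$median_auroc_HD_healthy > 0.9))
}

#' Matrix-versus-method concordance experiment
#'
#' Per replicate: construct two distinct bases from the same compendium (all
#' platforms versus the best-represented single platform, so gene selection
#' and expression values both differ), deconvolve noisy mixtures with every
#' method against both, and correlate the per-sample proportion estimates
#' pairwise. Pairs are grouped as same matrix / different methods, different
#' matrices / same method, and both different. The choice of basis matrix
#' should drive discordance more than the choice of method.
#'
#' @param cfg A [sim_config()] with >= 2 platforms (default:
#'   [experiment_config("concordance")]).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param methods Methods to cross.
#' @param n_mix Mixtures per replicate.
#' @return An `experiment_report`; `per_rep` holds group median correlations
#'   per replicate, `summary` the fraction of replicates in which the
#'   same-matrix median exceeds both different-matrix medians.
#' @export
run_concordance_experiment <- function(cfg = experiment_config("concordance"),
                                       n_reps = 20, seed = 1,
                                       methods = c("linear", "qp", "robust", "svr"),
                                       n_mix = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_platforms < 2) stop_bd("concordance experiment needs >= 2 platforms (two constructible bases)")
  if (length(methods) < 2) stop_bd("concordance experiment needs >= 2 methods")
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- child_seed(seed, r)
    sim <- simulate_sorted_compendium(cfg_r)
    ann <- sim$expr$annotations
    main_platform <- names(sort(table(ann$platform), decreasing = TRUE))[1]
    single <- subset_samples(sim$expr, which(ann$platform == main_platform))
    bases <- list(
      A = suppressWarnings(build_basis(sim$expr, name = "A")),
      B = suppressWarnings(build_basis(single, name = "B"))
    )
    mx <- simulate_mixtures(sim$truth, n_mix, seed = child_seed(seed, 6000 + r))
    res <- dplyr::bind_rows(lapply(bases, function(b)
      deconvolve_dataset(mx$expr, b, methods = methods)))
    long <- tidyr::pivot_longer(
      tibble::as_tibble(res)[c("sample_id", "method", "basis_id", proportion_cols(res))],
      -dplyr::all_of(c("sample_id", "method", "basis_id")),
      names_to = "cell_type", values_to = "proportion")
    cors <- list()
    for (sid in unique(long$sample_id)) {
      sub <- long[long$sample_id == sid, ]
      est <- tidyr::pivot_wider(sub, names_from = "cell_type", values_from = "proportion")
      V <- as.matrix(est[-(1:3)])
      n_est <- nrow(V)
      for (i in seq_len(n_est - 1)) for (j in seq((i + 1), n_est)) {
        grp <- if (est$basis_id[i] == est$basis_id[j]) "same_matrix"
               else if (est$method[i] == est$method[j]) "different_matrix_same_method"
               else "both_different"
        cors[[length(cors) + 1]] <- tibble::tibble(
          rep = r, sample_id = sid, group = grp, r_est = safe_cor(V[i, ], V[j, ]))
      }
    }
    cors <- dplyr::bind_rows(cors)
    med <- dplyr::summarise(dplyr::group_by(cors, .data$group),
                            median_r = stats::median(.data$r_est, na.rm = TRUE),
                            .groups = "drop")
    med$rep <- r
    rows[[length(rows) + 1]] <- med
  }
  per_rep <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(per_rep, names_from = "group", values_from = "median_r")
  frac <- mean(wide$same_matrix > wide$different_matrix_same_method &
                 wide$same_matrix > wide$both_different)
  summary <- tibble::tibble(
    frac_same_matrix_highest = frac,
    median_same_matrix = stats::median(wide$same_matrix),
    median_different_matrix_same_method = stats::median(wide$different_matrix_same_method),
    median_both_different = stats::median(wide$both_different))
  new_experiment_report("concordance", cfg, n_reps, seed, per_rep, summary,
                        list(matrix_dominates_method = frac >= 0.9))
}
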