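#' Permutation significance of a goodness of fit
#'
#' Builds a null distribution for the goodness of fit by repeatedly drawing a
#' uniform random gene subset (of the same size as the number of basis genes
#' actually used) from the sample's full expression profile, assigning those
#' values to the basis gene slots, re-solving, and recording the resulting
#' goodness of fit. The p-value uses the add-one permutation estimator
#' `p = (1 + (number of null gof >= observed gof)) / (n_perm + 1)`.
#'
#' @param sample Named numeric vector over the sample's full gene universe
#'   (must be strictly larger than the basis gene set).
#' @param basis A `basis_matrix`.
#' @param method Solver name, see [deconvolve_sample()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed (reproducible p-values under a fixed seed).
#' @param rescale Passed through to the solver contract.
#' @return A single p-value in (0, 1].
#' @export
gof_significance <- function(sample, basis, method = "qp", n_perm = 100,
                             seed = NULL, rescale = TRUE) {
  if (n_perm < 1) stop_bd("n_perm must be >= 1")
  al <- align_and_scale(sample, basis, rescale = rescale)
  solver <- solver_for(method)
  obs_p <- solver(al$s, al$M)
  obs <- safe_cor(al$s, as.numeric(al$M %*% obs_p))
  universe <- as.numeric(sample)
  k <- al$n_genes_used
  if (length(universe) <= k) {
    stop_bd("sample gene universe (%d) must exceed the basis gene count (%d)",
            length(universe), k)
  }
  M <- basis$values[intersect(rownames(basis$values), names(sample)), , drop = FALSE]
  Ms <- if (rescale) (M - mean(M)) / sd(as.numeric(M)) else M
  null_gof <- with_optional_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sv <- universe[sample.int(length(universe), k)]
      if (rescale) {
        if (sd(sv) == 0) return(NA_real_)
        sv <- (sv - mean(sv)) / sd(sv)
      }
      p <- tryCatch(solver(sv, Ms), error = function(e) NULL)
      if (is.null(p)) return(NA_real_)
      safe_cor(sv, as.numeric(Ms %*% p))
    }, 0.0)
  })
  null_gof <- null_gof[!is.na(null_gof)]
  (1 + sum(null_gof >= obs)) / (n_perm + 1)
}

#' Platform-heterogeneity MAD Z-test
#'
#' Quantifies how much deconvolution goodness of fit varies between
#' measurement platforms. The observed statistic (default variant) is the raw
#' median absolute deviation of the per-platform median goodness of fit
#' (methods pooled; no normal-consistency constant). A null distribution is
#' generated by permuting platform labels across samples (group sizes
#' preserved) and recomputing the statistic; significance is a one-sided
#' upper-tail Z-test against that background.
#'
#' The `"per_sample"` variant instead takes the median over samples of the
#' absolute deviation of each sample's goodness of fit from the pooled mean.
#'
#' @param results A `deconv_tbl` (needs a `platform` column, or supply
#'   `annotations` with `sample_id` + `platform` to join).
#' @param annotations Optional annotation table to supply platforms.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @param variant `"platform_median"` (default) or `"per_sample"`.
#' @return A `heterogeneity_report`: list with `per_platform` (tibble of
#'   per-platform median gof), `mad_observed`, `null_mean`, `null_sd`, `z`,
#'   `pvalue`, `n_permutations`, `seed`, `variant`.
#' @export
mad_heterogeneity <- function(results, annotations = NULL, n_perm = 1000,
                              seed = NULL, variant = c("platform_median", "per_sample")) {
  variant <- match.arg(variant)
  res <- tibble::as_tibble(results)
  if (!"platform" %in% names(res)) {
    if (is.null(annotations)) stop_bd("results need a `platform` column (or pass `annotations`)")
    res <- dplyr::left_join(res, tibble::as_tibble(annotations)[c("sample_id", "platform")],
                            by = "sample_id")
  }
  if (anyNA(res$platform)) stop_bd("missing platform annotation for some samples")
  samples <- unique(res$sample_id)
  platform_of <- res$platform[match(samples, res$sample_id)]
  if (length(unique(platform_of)) < 2) stop_bd("mad_heterogeneity needs >= 2 platforms")

  stat_fun <- if (variant == "platform_median") {
    function(plat) {
      med <- tapply(res$gof, plat[match(res$sample_id, samples)], stats::median)
      stats::median(abs(med - stats::median(med)))
    }
  } else {
    function(plat) {
      # deviation of each sample's gof from the mean of per-platform means
      grand <- mean(tapply(res$gof, plat[match(res$sample_id, samples)], mean))
      stats::median(abs(res$gof - grand))
    }
  }
  observed <- stat_fun(platform_of)
  null_stats <- with_optional_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(platform_of)), 0.0)
  })
  null_mean <- mean(null_stats); null_sd <- sd(null_stats)
  if (null_sd == 0) {
    warn("mad_heterogeneity: degenerate null (sd = 0); pvalue set to 1")
    z <- 0; pvalue <- 1
  } else {
    z <- (observed - null_mean) / null_sd
    pvalue <- stats::pnorm(z, lower.tail = FALSE)
  }
  per_platform <- dplyr::summarise(dplyr::group_by(res, .data$platform),
                                   n = dplyr::n(), median_gof = stats::median(.data$gof),
                                   .groups = "drop")
  structure(list(per_platform = per_platform, mad_observed = observed,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 pvalue = max(pvalue, .Machine$double.xmin),
                 n_permutations = n_perm, seed = seed, variant = variant),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("<heterogeneity_report> MAD = %.4f (null %.4f +/- %.4f), Z = %.2f, p = %.3g [%s]\n",
              x$mad_observed, x$null_mean, x$null_sd, x$z, x$pvalue, x$variant))
  invisible(x)
}

#' @export
#' @rdname mad_heterogeneity
#' @param x A `heterogeneity_report`.
#' @param ... Unused.
glance.heterogeneity_report <- function(x, ...) {
  tibble::tibble(mad_observed = x$mad_observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, z = x$z, pvalue = x$pvalue,
                 n_permutations = x$n_permutations, variant = x$variant)
}

#' Fisher's log-sum p-value combination
#'
#' Combines k independent p-values through `chi^2 = -2 * sum(log(p))` with
#' `2k` degrees of freedom.
#'
#' @param pvalues Non-empty vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05)) # ~0.0175
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0) stop_bd("fisher_combine needs a non-empty p-value list")
  if (any(pvalues <= 0 | pvalues > 1)) stop_bd("p-values must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(pvalues)), df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Blood-versus-tissue separation AUROC
#'
#' Scores each sample by `-log10(pvalue)` of its goodness of fit and measures
#' how well that score separates blood-derived samples (positive class) from
#' solid-tissue samples via the rank-based [auroc()].
#'
#' @param pvalues Per-sample goodness-of-fit p-values.
#' @param labels Tissue source per sample; values equal to `positive` are the
#'   positive class.
#' @param positive Positive-class label (default `"blood"`).
#' @return AUROC in \[0, 1\].
#' @export
separation_auroc <- function(pvalues, labels, positive = "blood") {
  if (any(pvalues <= 0 | pvalues > 1)) stop_bd("p-values must lie in (0, 1]")
  pos <- labels == positive
  if (all(pos) || !any(pos)) stop_bd("both classes must be present")
  auroc(-log10(pvalues), pos)
}

#' Agreement between estimated and measured proportions
#'
#' Pools all (cell type, sample) pairs shared by the two tables and reports
#' the Pearson correlation and the root-mean-square error. RMSE is always
#' reported in percentage points (values on the fraction scale are converted
#' by x100 first).
#'
#' @param estimated,measured Wide data frames: a `sample_id` column plus one
#'   numeric column per cell type (a `deconv_tbl` works directly; extra
#'   columns are ignored). An optional `dataset` column in `estimated` splits
#'   the report per dataset.
#' @param scale Scale both tables are on: `"percent"` (default) or
#'   `"fraction"`.
#' @return An `agreement_report` tibble: one row per dataset with
#'   `pearson_r`, `rmse` (percentage points), `n_pairs`, `r_defined`.
#' @export
proportion_agreement <- function(estimated, measured, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  est <- tibble::as_tibble(estimated)
  mea <- tibble::as_tibble(measured)
  if (!"sample_id" %in% names(est) || !"sample_id" %in% names(mea)) {
    stop_bd("both tables need a `sample_id` column")
  }
  meta <- c("sample_id", "dataset", "method", "basis_id", "gof", "pvalue", "n_genes_used")
  cts <- intersect(setdiff(names(est), meta), setdiff(names(mea), meta))
  cts <- cts[vapply(cts, function(ct) is.numeric(est[[ct]]) && is.numeric(mea[[ct]]), TRUE)]
  if (length(cts) == 0) stop_bd("no overlapping cell-type columns")
  samples <- intersect(est$sample_id, mea$sample_id)
  if (length(samples) == 0) stop_bd("no overlapping sample ids")
  est <- est[match(samples, est$sample_id), ]
  mea <- mea[match(samples, mea$sample_id), ]
  mult <- if (scale == "fraction") 100 else 1
  datasets <- if ("dataset" %in% names(est)) est$dataset else rep("all", length(samples))
  out <- lapply(unique(datasets), function(ds) {
    i <- datasets == ds
    e <- as.numeric(as.matrix(est[i, cts])) * mult
    m <- as.numeric(as.matrix(mea[i, cts])) * mult
    r <- safe_cor(e, m)
    if (is.na(r)) warn(sprintf("proportion_agreement: correlation undefined for '%s' (zero variance)", ds))
    tibble::tibble(dataset = ds, pearson_r = r,
                   rmse = sqrt(mean((m - e)^2)), n_pairs = sum(i) * length(cts),
                   r_defined = !is.na(r))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("agreement_report", class(out))
  out
}
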