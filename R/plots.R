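#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot estimated cell-type composition
#'
#' Stacked per-sample proportion bars, faceted by method (and basis when
#' several are present).
#'
#' @param object A `deconv_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconv_tbl <- function(object, ...) {
  long <- tidy.deconv_tbl(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                          fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
  if (length(unique(long$basis_id)) > 1) {
    p + ggplot2::facet_grid(basis_id ~ method)
  } else {
    p + ggplot2::facet_wrap(~method)
  }
}

#' Plot a basis matrix as a heatmap
#'
#' Gene-wise z-scores of the mean expression, genes ordered by selection
#' stage.
#'
#' @param object A `basis_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.basis_matrix <- function(object, ...) {
  long <- tidy.basis_matrix(object)
  long <- dplyr::mutate(dplyr::group_by(long, .data$gene),
                        z = (.data$mean_expression - mean(.data$mean_expression)) /
                          (sd(.data$mean_expression) + 1e-12))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$gene, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::facet_grid(stage ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot a stepwise-selection AUROC trajectory
#'
#' @param object A `signature_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- tidy.signature_set(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::labs(title = sprintf("%s '%s'", object$level, object$target),
                  x = "signature size (ranked prefix)", y = "AUROC") +
    ggplot2::theme_minimal()
}

#' Plot a platform-heterogeneity permutation test
#'
#' Null MAD distribution with the observed statistic marked.
#'
#' @param object A `heterogeneity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heterogeneity_report <- function(object, ...) {
  per <- object$per_platform
  ggplot2::ggplot(per, ggplot2::aes(x = .data$platform, y = .data$median_gof)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = stats::median(per$median_gof), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "median goodness of fit",
                  subtitle = sprintf("MAD = %.3f, Z = %.2f, p = %.3g",
                                     object$mad_observed, object$z, object$pvalue)) +
    ggplot2::theme_minimal()
}

#' Plot per-replicate experiment statistics
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- object$per_rep
  if (object$experiment == "platform_bias") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$basis, y = .data$mad)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "MAD of per-platform median gof", x = NULL) +
      ggplot2::theme_minimal()
  } else if (object$experiment == "disease_bias") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$basis, y = .data$auroc)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~state) +
      ggplot2::labs(y = "blood-vs-tissue AUROC", x = "basis") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median_r)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "median pairwise correlation", x = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
  }
}

#' Scatter plot of estimated versus measured proportions
#'
#' @param estimated,measured Wide tables as in [proportion_agreement()].
#' @param scale Input scale, `"percent"` or `"fraction"`.
#' @return A ggplot of pooled (cell type, sample) pairs with the identity
#'   line.
#' @export
plot_agreement <- function(estimated, measured, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  est <- tibble::as_tibble(estimated); mea <- tibble::as_tibble(measured)
  meta <- c("sample_id", "dataset", "method", "basis_id", "gof", "pvalue", "n_genes_used")
  cts <- intersect(setdiff(names(est), meta), setdiff(names(mea), meta))
  samples <- intersect(est$sample_id, mea$sample_id)
  mult <- if (scale == "fraction") 100 else 1
  df <- tibble::tibble(
    cell_type = rep(cts, each = length(samples)),
    measured = as.numeric(as.matrix(mea[match(samples, mea$sample_id), cts])) * mult,
    estimated = as.numeric(as.matrix(est[match(samples, est$sample_id), cts])) * mult)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$estimated,
                                   colour = .data$cell_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "measured proportion (%)", y = "estimated proportion (%)") +
    ggplot2::theme_minimal()
}
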