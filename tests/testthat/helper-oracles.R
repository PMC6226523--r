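# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

oracle_hedges_g <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  sp2 <- (sum((case - mean(case))^2) + sum((control - mean(control))^2)) / (n1 + n2 - 2)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp2 == 0) return(if (mean(case) == mean(control)) 0 else sign(mean(case) - mean(control)) * 1e6)
  J * (mean(case) - mean(control)) / sqrt(sp2)
}

# AUROC by exhaustive positive/negative pair enumeration.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Min-delta by explicit double loop over competitor groups.
oracle_delta <- function(effects_by_target, target) {
  others <- effects_by_target[setdiff(names(effects_by_target), target)]
  min(vapply(others, function(e) effects_by_target[[target]] - e, 0.0))
}

# chi^2_4 upper tail in closed form: (1 + x/2) exp(-x/2)
oracle_fisher2 <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  (1 + x / 2) * exp(-x / 2)
}

oracle_rmse <- function(a, b) sqrt(mean((a - b)^2))

# Tiny annotated expression matrix shared across tests.
toy_expr <- function(values, cell_type = NULL, lineage = NULL, platform = NULL,
                     disease_state = NULL, tissue_source = NULL) {
  ann <- tibble::tibble(sample_id = colnames(values))
  if (!is.null(cell_type)) ann$cell_type <- cell_type
  if (!is.null(lineage)) ann$lineage <- lineage
  if (!is.null(platform)) ann$platform <- platform
  if (!is.null(disease_state)) ann$disease_state <- disease_state
  if (!is.null(tissue_source)) ann$tissue_source <- tissue_source
  expression_matrix(values, ann)
}

named_matrix <- function(data, nrow, ncol, prefix_row = "g", prefix_col = "s") {
  matrix(data, nrow, ncol,
         dimnames = list(paste0(prefix_row, seq_len(nrow)), paste0(prefix_col, seq_len(ncol))))
}

# Small planted-marker scenario used by several suites.
small_scenario <- function(seed = 1, n_genes = 600, n_markers = 6,
                           n_samples_per_type = 10, fold_change = 4,
                           cell_types = NULL, ...) {
  if (is.null(cell_types)) {
    cell_types <- stats::setNames(
      rep(c("L1", "L2", "L3", "L4"), each = 3),
      paste0("ct", 1:12))
  }
  sim_config(n_genes = n_genes, cell_types = cell_types,
             n_samples_per_type = n_samples_per_type, n_markers = n_markers,
             fold_change = fold_change, n_platforms = 1, platform_tau = 0,
             seed = seed, ...)
}
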