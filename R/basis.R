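#' Hedges' g standardized mean difference
#'
#' Pooled-SD standardized difference in means with the Hedges-Olkin
#' small-sample bias correction `J = 1 - 3 / (4(n1 + n2) - 9)`, applied
#' always. When the pooled SD is exactly zero the value is 0 for equal means
#' and otherwise a signed sentinel `cap` (default 1e6), so that perfect
#' separators outrank every finite effect without producing non-finite
#' arithmetic.
#'
#' @param case,control Numeric vectors, each with >= 2 observations.
#' @param cap Magnitude assigned when the pooled SD is zero but means differ.
#' @return A single number.
#' @export
#' @examples
#' hedges_g(c(3, 4, 5), c(1, 2, 3)) # 1.6
hedges_g <- function(case, control, cap = 1e6) {
  n1 <- length(case); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop_bd("hedges_g needs >= 2 observations per group")
  d <- mean(case) - mean(control)
  sp <- sqrt(((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp == 0) {
    if (d == 0) return(0)
    return(sign(d) * cap)
  }
  J * d / sp
}

# Vectorized one-vs-rest Hedges' g over the rows of a matrix.
hedges_g_rows <- function(x, case_idx, control_idx, cap = 1e6) {
  n1 <- length(case_idx); n2 <- length(control_idx)
  xc <- x[, case_idx, drop = FALSE]; xr <- x[, control_idx, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xr)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xr - m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  d <- m1 - m2
  g <- J * d / sp
  zero <- sp == 0
  g[zero] <- sign(d[zero]) * cap
  g
}

#' One-vs-rest effect sizes per gene and group
#'
#' For `level = "cell_type"`, each cell type (cases) is compared against all
#' remaining cell types *within its lineage* (controls). For
#' `level = "lineage"`, each lineage is compared against all other lineages.
#' Effect size is [hedges_g()] per gene.
#'
#' @param m Annotated `expr_matrix` (needs `cell_type` and `lineage`
#'   annotations at cell-type level; `lineage` at lineage level).
#' @param level `"cell_type"` or `"lineage"`.
#' @param min_samples Minimum samples per group and per complement (default 3;
#'   the small-sample correction degenerates below this). Groups below the
#'   floor are excluded with a warning.
#' @param cap Zero-pooled-variance sentinel passed to the effect computation.
#' @return A tibble of class `effect_tbl` with columns `gene`, `target`
#'   (the case group), `family` (the lineage at cell-type level; `"(all)"` at
#'   lineage level), `effect`, `n_case`, `n_control`.
#' @export
one_vs_rest_effects <- function(m, level = c("cell_type", "lineage"),
                                min_samples = 3, cap = 1e6) {
  level <- match.arg(level)
  stopifnot(inherits(m, "expr_matrix"))
  ann <- m$annotations
  if (level == "cell_type") {
    ok <- !is.na(ann$cell_type) & !is.na(ann$lineage)
    pairs <- unique(tibble::tibble(family = ann$lineage[ok], target = ann$cell_type[ok]))
    groups <- lapply(seq_len(nrow(pairs)), function(i) {
      ann$sample_id[ok & ann$lineage == pairs$family[i] & ann$cell_type == pairs$target[i]]
    })
    fam_of <- pairs$family; tgt_of <- pairs$target
  } else {
    ok <- !is.na(ann$lineage)
    tgt_of <- unique(ann$lineage[ok])
    groups <- lapply(tgt_of, function(l) ann$sample_id[ok & ann$lineage == l])
    fam_of <- rep("(all)", length(groups))
  }
  if (length(groups) == 0) stop_bd("no annotated groups at level '%s'", level)
  res <- list()
  skipped <- character()
  for (i in seq_along(groups)) {
    fam <- fam_of[i]; tgt <- tgt_of[i]
    case_ids <- groups[[i]]
    if (level == "cell_type") {
      fam_ids <- ann$sample_id[ok & ann$lineage == fam]
    } else {
      fam_ids <- ann$sample_id[ok]
    }
    control_ids <- setdiff(fam_ids, case_ids)
    if (length(case_ids) < min_samples || length(control_ids) < min_samples) {
      skipped <- c(skipped, tgt)
      next
    }
    g <- hedges_g_rows(m$values,
                       match(case_ids, colnames(m$values)),
                       match(control_ids, colnames(m$values)), cap = cap)
    res[[length(res) + 1]] <- tibble::tibble(
      gene = rownames(m$values), target = tgt, family = fam,
      effect = unname(g), n_case = length(case_ids), n_control = length(control_ids)
    )
  }
  if (length(skipped) > 0) {
    warn(sprintf("one_vs_rest_effects: excluded group(s) below min_samples: %s",
                 paste(unique(skipped), collapse = ", ")))
  }
  if (length(res) == 0) stop_bd("no group meets the min_samples floor of %d", min_samples)
  out <- dplyr::bind_rows(res)
  class(out) <- c("effect_tbl", class(out))
  out
}

#' Min-delta separation statistic
#'
#' For every (gene, target, family) entry, adds
#' `delta = min over competitors j != i in the family of (effect_i - effect_j)`,
#' i.e. the target's effect minus the largest competing effect for the same
#' gene. High delta marks genes that separate the target from its closest
#' relative. Families with a single target carry no competitors and are
#' dropped with a warning.
#'
#' @param effects An `effect_tbl` from [one_vs_rest_effects()].
#' @return The table with a `delta` column, class `effect_tbl`.
#' @export
delta_effects <- function(effects) {
  stopifnot(is.data.frame(effects), all(c("gene", "target", "family", "effect") %in% names(effects)))
  n_targets <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(effects), .data$family),
                                n = dplyr::n_distinct(.data$target))
  lonely <- n_targets$family[n_targets$n < 2]
  if (length(lonely) > 0) {
    warn(sprintf("delta_effects: family with a single member skipped: %s",
                 paste(lonely, collapse = ", ")))
  }
  out <- dplyr::filter(tibble::as_tibble(effects), !.data$family %in% lonely)
  # delta_i = effect_i - max_{j != i} effect_j, vectorized per family via a
  # genes x targets matrix (row max and second max)
  parts <- lapply(split(out, out$family), function(sub) {
    w <- tidyr::pivot_wider(sub[c("gene", "target", "effect")],
                            names_from = "target", values_from = "effect")
    W <- as.matrix(w[-1])
    rmax <- do.call(pmax, as.data.frame(W))
    arg <- max.col(W, ties.method = "first")
    W2 <- W
    W2[cbind(seq_len(nrow(W)), arg)] <- -Inf
    rsec <- do.call(pmax, as.data.frame(W2))
    n_at_max <- rowSums(W == rmax)
    D <- W - rmax
    fix <- which(W == rmax & n_at_max == 1, arr.ind = TRUE)
    D[fix] <- W[fix] - rsec[fix[, 1]]
    key <- tibble::tibble(
      gene = rep(w$gene, times = ncol(W)),
      target = rep(colnames(W), each = nrow(W)),
      delta = as.numeric(D)
    )
    dplyr::inner_join(sub, key, by = c("gene", "target"))
  })
  out <- dplyr::bind_rows(parts)
  class(out) <- c("effect_tbl", class(out))
  out
}

#' Area under the ROC curve
#'
#' Rank-based AUROC, identical to the normalized Mann-Whitney U statistic;
#' tied scores contribute 1/2.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical, or coercible to logical/binary; `TRUE` (or 1) marks
#'   the positive class. Both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)) # 0.75
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  pos <- as.logical(labels)
  if (anyNA(pos)) pos <- labels == max(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_bd("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Multi-gene discrimination score: per-gene z-scores over the comparison
# population, averaged over the gene set. Zero-variance genes contribute 0.
prefix_score_matrix <- function(x) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  z <- (x - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Stepwise AUROC signature selection
#'
#' Walks down a ranked candidate list, scoring each sample by the mean of
#' per-gene z-scores over the current prefix, and records the AUROC of
#' classifying the target group against the rest of its comparison
#' population at every prefix length. The chosen signature is the smallest
#' prefix whose AUROC is within `epsilon` of the maximum over the searched
#' horizon, raised to at least `min_genes`.
#'
#' @param m Annotated `expr_matrix`.
#' @param target Cell-type or lineage label to separate.
#' @param ranked Ordered candidate gene list (best first).
#' @param level `"cell_type"` (comparison population = the target's lineage)
#'   or `"lineage"` (population = all annotated samples).
#' @param epsilon AUROC proximity tolerance (default 0.005).
#' @param min_genes Minimum signature size (default 5).
#' @param max_genes Search horizon over prefix lengths (default 50).
#' @return A `signature_set`: list with `target`, `level`, `ranked_genes`,
#'   `auroc_trajectory`, `chosen_k`, `genes`, and `flagged` (TRUE when fewer
#'   than `min_genes` candidates were available).
#' @export
stepwise_select <- function(m, target, ranked, level = c("cell_type", "lineage"),
                            epsilon = 0.005, min_genes = 5, max_genes = 50) {
  level <- match.arg(level)
  stopifnot(inherits(m, "expr_matrix"))
  assert_scalar_number(epsilon, "epsilon", 0, 1)
  if (length(ranked) == 0) stop_bd("`ranked` must be a non-empty gene list")
  missing <- setdiff(ranked, rownames(m$values))
  if (length(missing) > 0) stop_bd("ranked genes absent from matrix: %s",
                                   paste(head(missing, 5), collapse = ", "))
  ann <- m$annotations
  lab_col <- if (level == "cell_type") ann$cell_type else ann$lineage
  if (!target %in% lab_col) stop_bd("target '%s' absent from %s annotations", target, level)
  if (level == "cell_type") {
    lineage <- unique(ann$lineage[!is.na(ann$cell_type) & ann$cell_type == target])
    lineage <- lineage[!is.na(lineage)]
    pop <- !is.na(ann$cell_type) & !is.na(ann$lineage) & ann$lineage %in% lineage
  } else {
    pop <- !is.na(ann$lineage)
  }
  pos <- lab_col[pop] == target
  if (all(pos) || !any(pos)) stop_bd("target '%s' has no comparison population", target)

  horizon <- min(max_genes, length(ranked))
  sub <- m$values[ranked[seq_len(horizon)], pop, drop = FALSE]
  z <- prefix_score_matrix(sub)
  cum <- apply(z, 2, cumsum)                       # horizon x samples (or vector)
  if (horizon == 1) cum <- matrix(cum, nrow = 1)
  traj <- vapply(seq_len(horizon), function(k) auroc(cum[k, ] / k, pos), 0.0)

  chosen <- which(traj >= max(traj) - epsilon)[1]
  flagged <- length(ranked) < min_genes
  chosen <- min(max(chosen, min_genes), length(ranked), horizon)
  if (flagged) {
    warn(sprintf("stepwise_select('%s'): only %d candidate gene(s) (< %d), selecting all",
                 target, length(ranked), min_genes))
    chosen <- horizon
  }
  structure(list(
    target = target, level = level,
    ranked_genes = ranked[seq_len(horizon)],
    auroc_trajectory = traj,
    chosen_k = chosen,
    genes = ranked[seq_len(chosen)],
    flagged = flagged
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s '%s': %d genes (AUROC %.4f, max %.4f)\n",
              x$level, x$target, x$chosen_k,
              x$auroc_trajectory[x$chosen_k], max(x$auroc_trajectory)))
  invisible(x)
}

#' Tidy a signature set
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Tibble with one row per prefix length: `target`, `level`, `k`,
#'   `gene`, `auroc`, `selected`.
#' @export
tidy.signature_set <- function(x, ...) {
  tibble::tibble(
    target = x$target, level = x$level,
    k = seq_along(x$auroc_trajectory),
    gene = x$ranked_genes,
    auroc = x$auroc_trajectory,
    selected = seq_along(x$auroc_trajectory) <= x$chosen_k
  )
}

# Ranked candidate list for one target: delta descending, ties broken
# lexicographically by gene id.
ranked_candidates <- function(deltas, tgt) {
  d <- deltas[deltas$target == tgt, ]
  d <- d[order(-d$delta, d$gene), ]
  d$gene
}

#' Build a hierarchical basis matrix from a sorted-cell compendium
#'
#' Two-stage signature selection followed by mean-expression assembly:
#'
#' 1. *Cell-type stage*: within each lineage, genes are ranked per cell type
#'    by the min-delta separation of one-vs-rest Hedges' g effects, and a
#'    stepwise-AUROC signature is selected per cell type.
#' 2. *Lineage stage*: all stage-1 genes are removed from the candidate pool
#'    (their cell-type-specific signal would confound lineage separation),
#'    then the same ranking and selection distinguishes lineages from one
#'    another.
#'
#' Basis values are the per-cell-type mean expression of the union gene set,
#' computed from the quantile-normalized compendium.
#'
#' @param m Annotated `expr_matrix` with `cell_type` and `lineage` filled in.
#' @param hierarchy Optional named character vector mapping cell type ->
#'   lineage; defaults to the map implied by the annotations.
#' @param epsilon,min_genes,max_genes Stepwise-selection controls, see
#'   [stepwise_select()].
#' @param min_samples Per-group sample floor for effect computation.
#' @param qn Quantile-normalize the compendium first (default TRUE; a no-op on
#'   already-normalized data).
#' @param name Identifier stored with the basis.
#' @return A `basis_matrix`: list with `values` (signature genes x cell
#'   types), `lineage_of`, `stage_of` (`"cell_type_stage"` or
#'   `"lineage_stage"` per gene), `signatures` (the per-target
#'   `signature_set`s), and `name`.
#' @export
build_basis <- function(m, hierarchy = NULL, epsilon = 0.005, min_genes = 5,
                        max_genes = 50, min_samples = 3, qn = TRUE,
                        name = "basis") {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- m$annotations
  if (all(is.na(ann$cell_type))) stop_bd("build_basis needs cell_type annotations")
  if (!is.null(hierarchy)) {
    ann$lineage <- unname(hierarchy[ann$cell_type])
    missing <- setdiff(unique(stats::na.omit(ann$cell_type)), names(hierarchy))
    if (length(missing) > 0) stop_bd("hierarchy missing cell types: %s",
                                     paste(missing, collapse = ", "))
    m <- expression_matrix(m$values, ann)
  }
  if (all(is.na(m$annotations$lineage))) stop_bd("build_basis needs lineage annotations (or `hierarchy`)")
  if (qn && ncol(m$values) >= 2) m <- quantile_normalize(m)

  # stage 1: cell types within lineages
  ct_effects <- one_vs_rest_effects(m, "cell_type", min_samples = min_samples)
  ct_deltas <- delta_effects(ct_effects)
  stage1 <- list()
  for (tgt in unique(ct_deltas$target)) {
    ranked <- ranked_candidates(ct_deltas, tgt)
    stage1[[tgt]] <- stepwise_select(m, tgt, ranked, level = "cell_type",
                                     epsilon = epsilon, min_genes = min_genes,
                                     max_genes = max_genes)
  }
  stage1_genes <- unique(unlist(lapply(stage1, `[[`, "genes")))

  # stage 2: lineages against one another, stage-1 genes excluded
  lineages <- unique(stats::na.omit(m$annotations$lineage))
  stage2 <- list()
  if (length(lineages) < 2) {
    warn("build_basis: single lineage, lineage stage skipped")
  } else {
    lin_effects <- one_vs_rest_effects(m, "lineage", min_samples = min_samples)
    lin_deltas <- delta_effects(lin_effects)
    lin_deltas <- dplyr::filter(lin_deltas, !.data$gene %in% stage1_genes)
    for (tgt in unique(lin_deltas$target)) {
      ranked <- ranked_candidates(lin_deltas, tgt)
      if (length(ranked) == 0) next
      stage2[[tgt]] <- stepwise_select(m, tgt, ranked, level = "lineage",
                                       epsilon = epsilon, min_genes = min_genes,
                                       max_genes = max_genes)
    }
  }
  stage2_genes <- setdiff(unique(unlist(lapply(stage2, `[[`, "genes"))), stage1_genes)

  union_genes <- c(stage1_genes, stage2_genes)
  if (length(union_genes) == 0) stop_bd("empty signature union")
  stage_of <- stats::setNames(
    c(rep("cell_type_stage", length(stage1_genes)), rep("lineage_stage", length(stage2_genes))),
    union_genes
  )
  lineage_of <- lineage_map_from(m$annotations)
  values <- group_mean_matrix(m, union_genes, names(lineage_of))
  structure(list(values = values, lineage_of = lineage_of, stage_of = stage_of,
                 signatures = c(stage1, stage2), name = name,
                 params = list(epsilon = epsilon, min_genes = min_genes,
                               max_genes = max_genes, min_samples = min_samples)),
            class = "basis_matrix")
}

lineage_map_from <- function(ann) {
  ok <- !is.na(ann$cell_type)
  map <- unique(tibble::tibble(cell_type = ann$cell_type[ok], lineage = ann$lineage[ok]))
  stats::setNames(map$lineage, map$cell_type)
}

group_mean_matrix <- function(m, genes, cell_types) {
  vals <- vapply(cell_types, function(ct) {
    idx <- which(!is.na(m$annotations$cell_type) & m$annotations$cell_type == ct)
    rowMeans(m$values[genes, idx, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) vals <- matrix(vals, nrow = 1)
  dimnames(vals) <- list(genes, cell_types)
  vals
}

#' Basis matrix from a fixed gene list
#'
#' Computes per-cell-type mean expression for a user-supplied gene list -
#' e.g. to re-estimate an external signature matrix's expression values from
#' a different compendium while keeping its gene selection fixed.
#'
#' @param m Annotated `expr_matrix` with `cell_type` filled in.
#' @param genes Gene list; all must be present in `m`.
#' @param cell_types Cell types to include (default: all annotated).
#' @param name Identifier stored with the basis.
#' @return A `basis_matrix` with `stage_of = "unspecified"` for every gene.
#' @export
basis_from_gene_list <- function(m, genes, cell_types = NULL, name = "gene_list_basis") {
  stopifnot(inherits(m, "expr_matrix"))
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing) > 0) stop_bd("genes absent from matrix: %s", paste(missing, collapse = ", "))
  lineage_of <- lineage_map_from(m$annotations)
  if (!is.null(cell_types)) lineage_of <- lineage_of[intersect(names(lineage_of), cell_types)]
  if (length(lineage_of) == 0) stop_bd("no annotated cell types to average over")
  values <- group_mean_matrix(m, genes, names(lineage_of))
  structure(list(values = values, lineage_of = lineage_of,
                 stage_of = stats::setNames(rep("unspecified", length(genes)), genes),
                 signatures = list(), name = name, params = list()),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("<basis_matrix> '%s': %d signature genes x %d cell types (%d lineages)\n",
              x$name, nrow(x$values), ncol(x$values),
              length(unique(x$lineage_of))))
  st <- table(x$stage_of)
  cat(" stages:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a basis matrix
#'
#' @param x A `basis_matrix`.
#' @param ... Unused.
#' @return Long tibble: `gene`, `cell_type`, `lineage`, `stage`, `mean_expression`.
#' @export
tidy.basis_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    cell_type = rep(colnames(x$values), each = nrow(x$values)),
    lineage = rep(unname(x$lineage_of[colnames(x$values)]), each = nrow(x$values)),
    stage = rep(unname(x$stage_of[rownames(x$values)]), times = ncol(x$values)),
    mean_expression = as.numeric(x$values)
  )
}

#' One-row summary of a basis matrix
#'
#' @param x A `basis_matrix`.
#' @param ... Unused.
#' @return Tibble with gene/cell-type/lineage counts and per-stage gene counts.
#' @export
glance.basis_matrix <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_genes = nrow(x$values),
    n_cell_types = ncol(x$values),
    n_lineages = length(unique(x$lineage_of)),
    n_cell_type_stage = sum(x$stage_of == "cell_type_stage"),
    n_lineage_stage = sum(x$stage_of == "lineage_stage")
  )
}

#' Write a basis matrix to TSV
#'
#' Column 1 is the gene id, one column per cell type - the same dialect as
#' published signature-matrix files, so they load interchangeably. The
#' lineage map and stage provenance go to an optional sidecar TSV.
#'
#' @param x A `basis_matrix`.
#' @param path Output TSV path.
#' @param sidecar Optional path for the lineage/stage sidecar TSV.
#' @return `x`, invisibly.
#' @export
write_basis <- function(x, path, sidecar = NULL) {
  df <- tibble::as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(df, path)
  if (!is.null(sidecar)) {
    side <- tibble::tibble(
      kind = c(rep("lineage", length(x$lineage_of)), rep("stage", length(x$stage_of))),
      key = c(names(x$lineage_of), names(x$stage_of)),
      value = c(unname(x$lineage_of), unname(x$stage_of))
    )
    readr::write_tsv(side, sidecar)
  }
  invisible(x)
}

#' Read a basis matrix from TSV
#'
#' Accepts the common signature-matrix dialect: gene ids in column 1, one
#' column per cell type.
#'
#' @param path TSV path.
#' @param sidecar Optional lineage/stage sidecar written by [write_basis()].
#' @param name Identifier for the loaded basis (default: file name).
#' @return A `basis_matrix`. Without a sidecar each cell type is its own
#'   lineage and stage provenance is `"unspecified"`.
#' @export
read_basis <- function(path, sidecar = NULL, name = NULL) {
  if (!file.exists(path)) stop_bd("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  genes <- raw[[1]]
  if (anyDuplicated(genes)) stop_bd("duplicate gene ids in basis file")
  values <- apply(as.matrix(raw[-1]), 2, as.numeric)
  rownames(values) <- genes
  lineage_of <- stats::setNames(colnames(values), colnames(values))
  stage_of <- stats::setNames(rep("unspecified", length(genes)), genes)
  if (!is.null(sidecar)) {
    side <- readr::read_tsv(sidecar, col_types = "ccc", progress = FALSE)
    lin <- side[side$kind == "lineage", ]
    stg <- side[side$kind == "stage", ]
    if (nrow(lin) > 0) lineage_of[lin$key] <- lin$value
    if (nrow(stg) > 0) stage_of[stg$key] <- stg$value
  }
  structure(list(values = values, lineage_of = lineage_of, stage_of = stage_of,
                 signatures = list(), name = name %||% basename(path), params = list()),
            class = "basis_matrix")
}
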