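#' Construct a gene-by-sample expression matrix
#'
#' The central data container: a non-negative, linear-scale expression matrix
#' (genes in rows, samples in columns) together with an optional per-sample
#' annotation table. Expression is treated as linear-scale throughout the
#' package; no log transform is ever applied or detected automatically.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and unique colnames (sample ids). All values must be finite
#'   and non-negative.
#' @param annotations Optional data frame with a `sample_id` column and any of
#'   `cell_type`, `lineage`, `platform`, `disease_state` (`"healthy"` or
#'   `"disease"`), `tissue_source` (`"blood"`, `"tissue"` or `NA`). Every
#'   annotated sample must exist in `colnames(values)`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `annotations` (a tibble, one row per sample).
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' dim(m$values)
expression_matrix <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_bd("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_bd("`values` must have rownames (gene ids) and colnames (sample ids)")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    stop_bd("duplicate gene ids: %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop_bd("duplicate sample ids: %s", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(values))) stop_bd("expression values must all be finite")
  if (any(values < 0)) stop_bd("expression values must be non-negative (linear scale)")

  ann <- normalize_annotations(annotations, colnames(values))
  structure(list(values = values, annotations = ann), class = "expr_matrix")
}

annotation_fields <- c("cell_type", "lineage", "platform", "disease_state", "tissue_source")

normalize_annotations <- function(annotations, sample_ids) {
  base <- tibble::tibble(sample_id = sample_ids)
  for (f in annotation_fields) base[[f]] <- NA_character_
  if (is.null(annotations)) return(base)
  ann <- tibble::as_tibble(annotations)
  if (!"sample_id" %in% names(ann)) stop_bd("annotations must have a `sample_id` column")
  missing <- setdiff(ann$sample_id, sample_ids)
  if (length(missing) > 0) {
    stop_bd("annotated samples absent from the matrix: %s",
            paste(head(missing, 5), collapse = ", "))
  }
  if (anyDuplicated(ann$sample_id)) stop_bd("duplicate sample ids in annotations")
  keep <- intersect(names(ann), c("sample_id", annotation_fields))
  ann <- ann[keep]
  ds <- if ("disease_state" %in% names(ann)) ann$disease_state else NULL
  if (!is.null(ds) && !all(is.na(ds) | ds %in% c("healthy", "disease"))) {
    stop_bd("disease_state must be 'healthy', 'disease' or NA")
  }
  out <- dplyr::left_join(base["sample_id"], ann, by = "sample_id")
  for (f in setdiff(annotation_fields, names(out))) out[[f]] <- NA_character_
  out[c("sample_id", annotation_fields)]
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  filled <- vapply(annotation_fields, function(f) sum(!is.na(x$annotations[[f]])), 0L)
  filled <- filled[filled > 0]
  if (length(filled) > 0) {
    cat("annotations:", paste(sprintf("%s (%d)", names(filled), filled), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tidy an expression matrix to long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `expression`, joined to
#'   the per-sample annotations.
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.numeric(x$values)
  )
  dplyr::left_join(long, x$annotations, by = "sample_id")
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects column 1 to hold gene ids and the header row to hold sample ids.
#' An annotation sidecar (TSV with `sample_id`, `cell_type`, `lineage`,
#' `platform`, `disease_state`, `tissue_source`) may be supplied alongside.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"`, `"csv"`, or `"auto"` (from the file extension).
#' @param annotations Optional path to the annotation sidecar TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv"), annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bd("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  delim <- if (format == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) stop_bd("expression file needs a gene-id column plus >=1 sample column")
  genes <- raw[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) stop_bd("duplicate gene ids: %s", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_bd("non-numeric value '%s' at gene '%s', sample '%s'",
            vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  rownames(num) <- genes
  ann <- if (!is.null(annotations)) read_annotations(annotations) else NULL
  expression_matrix(num, ann)
}

#' Write an expression matrix to TSV/CSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the matrix.
#' @param format `"tsv"` or `"csv"`.
#' @param annotations Optional path for the annotation sidecar TSV.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv"), annotations = NULL) {
  format <- match.arg(format)
  df <- tibble::as_tibble(x$values, rownames = "gene_id")
  if (format == "csv") readr::write_csv(df, path) else readr::write_tsv(df, path)
  if (!is.null(annotations)) readr::write_tsv(x$annotations, annotations)
  invisible(x)
}

#' Read a per-sample annotation table
#'
#' @param path TSV with a `sample_id` column plus any of the standard
#'   annotation fields.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_bd("file not found: %s", path)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read a probe-to-gene map
#'
#' One row per (probe, gene) mapping. Probes mapping to more than one distinct
#' gene are flagged promiscuous and excluded by [collapse_probes()].
#'
#' @param path TSV with columns `probe_id` and `gene_id`.
#' @return A tibble of class `probe_map` with columns `probe_id`, `gene_id`,
#'   `promiscuous`.
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  probe_map(pm)
}

#' Construct a probe map from a data frame
#'
#' @param x Data frame with columns `probe_id` and `gene_id`.
#' @return A tibble of class `probe_map`.
#' @export
probe_map <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("probe_id", "gene_id") %in% names(x))) {
    stop_bd("probe map needs columns `probe_id` and `gene_id`")
  }
  x <- dplyr::distinct(x, .data$probe_id, .data$gene_id)
  x <- dplyr::mutate(
    dplyr::group_by(x, .data$probe_id),
    promiscuous = dplyr::n_distinct(.data$gene_id) > 1L
  )
  x <- dplyr::ungroup(x)
  class(x) <- c("probe_map", class(x))
  x
}

#' Collapse probe-level expression to gene level
#'
#' Each gene row is the arithmetic mean (linear scale) of its uniquely mapping
#' probe rows. Probes mapping to more than one gene (promiscuous) and probes
#' with no mapping are dropped.
#'
#' @param m Probe-level `expr_matrix` (rownames are probe ids).
#' @param pm A [probe_map()].
#' @return Gene-level `expr_matrix` with the same samples and annotations.
#' @export
collapse_probes <- function(m, pm) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!inherits(pm, "probe_map")) pm <- probe_map(pm)
  probes <- rownames(m$values)
  keep_map <- dplyr::filter(pm, !.data$promiscuous, .data$probe_id %in% probes)
  n_promiscuous <- sum(unique(pm$probe_id[pm$promiscuous]) %in% probes)
  n_unmapped <- sum(!probes %in% pm$probe_id)
  if (nrow(keep_map) == 0) {
    stop_bd("no probes left after dropping %d promiscuous and %d unmapped probes",
            n_promiscuous, n_unmapped)
  }
  inform(sprintf("collapse_probes: dropped %d promiscuous and %d unmapped probe(s)",
                 n_promiscuous, n_unmapped))
  sub <- m$values[keep_map$probe_id, , drop = FALSE]
  grp <- factor(keep_map$gene_id, levels = unique(keep_map$gene_id))
  collapsed <- rowsum(sub, grp) / as.numeric(table(grp))
  expression_matrix(as.matrix(collapsed), m$annotations)
}

# Quantile-normalize a bare numeric matrix. Reference distribution = per-rank
# mean of the sorted columns; tied values within a column receive the mean of
# the reference values spanned by their ranks (run-length trick keeps this
# O(n log n) per column).
qn_matrix <- function(x) {
  if (nrow(x) == 1) {
    x[] <- mean(x)
    return(x)
  }
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    o <- order(col)
    runs <- rle(col[o])$lengths
    v <- numeric(length(col))
    if (length(runs) == length(col)) {
      v[o] <- ref
    } else {
      grp <- rep.int(seq_along(runs), runs)
      means <- as.numeric(rowsum(ref, grp)) / runs
      v[o] <- rep.int(means, runs)
    }
    v
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical distribution - the
#' per-rank mean of the sorted input columns - while preserving within-sample
#' rank order. Tied values receive the mean of the reference values their rank
#' span covers. Idempotent up to numerical tolerance.
#'
#' @param m An `expr_matrix` (or bare numeric matrix) with at least one gene.
#' @return Object of the same type, quantile-normalized. A single-sample input
#'   is returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  bare <- !inherits(m, "expr_matrix")
  x <- if (bare) m else m$values
  if (nrow(x) < 1) stop_bd("quantile_normalize needs at least one gene")
  if (ncol(x) < 2) {
    warn("quantile_normalize: single sample, returned unchanged")
    return(m)
  }
  out <- qn_matrix(x)
  if (bare) out else expression_matrix(out, m$annotations)
}

#' Merge expression datasets into one compendium
#'
#' Restricts to the gene intersection, concatenates samples, and
#' quantile-normalizes the combined matrix (each dataset is also
#' quantile-normalized on its own first, by default, mirroring per-study
#' normalization before cross-study combination).
#'
#' @param ms List of >= 2 `expr_matrix` objects.
#' @param qn_each Quantile-normalize each dataset before combining?
#' @return A single `expr_matrix` over the common genes, with annotations
#'   concatenated.
#' @export
merge_datasets <- function(ms, qn_each = TRUE) {
  if (!is.list(ms) || length(ms) < 2) stop_bd("merge_datasets needs a list of >= 2 matrices")
  stopifnot(all(vapply(ms, inherits, TRUE, "expr_matrix")))
  genes <- Reduce(intersect, lapply(ms, function(m) rownames(m$values)))
  if (length(genes) == 0) stop_bd("empty gene intersection across datasets")
  all_samples <- unlist(lapply(ms, function(m) colnames(m$values)))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup) > 0) {
    stop_bd("duplicate sample ids across datasets: %s", paste(head(dup, 5), collapse = ", "))
  }
  mats <- lapply(ms, function(m) {
    v <- m$values[genes, , drop = FALSE]
    if (qn_each && ncol(v) >= 2) v <- qn_matrix(v)
    v
  })
  combined <- do.call(cbind, mats)
  ann <- dplyr::bind_rows(lapply(ms, function(m) m$annotations))
  expression_matrix(qn_matrix(combined), ann)
}
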