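default_cell_types <- function() {
  c("CD4 T" = "T cell", "CD8 T" = "T cell", "gamma-delta T" = "T cell",
    "CD14 monocyte" = "monocyte", "CD16 monocyte" = "monocyte",
    "macrophage M0" = "macrophage", "macrophage M1" = "macrophage",
    "macrophage M2" = "macrophage",
    "NK CD56 bright" = "NK cell", "NK CD56 dim" = "NK cell",
    "naive B" = "B cell", "memory B" = "B cell", "plasma cell" = "B cell",
    "myeloid DC" = "myeloid DC", "plasmacytoid DC" = "plasmacytoid DC",
    "progenitor" = "progenitor", "mast cell" = "mast cell",
    "neutrophil" = "granulocyte", "eosinophil" = "granulocyte",
    "basophil" = "granulocyte")
}

#' Configuration for the synthetic sorted-cell compendium
#'
#' Defines the study conditions the generator emulates: a multi-platform
#' compendium of purified (sorted) cell populations with planted marker
#' genes, platform-specific measurement distortions, optional disease-state
#' perturbations, and Dirichlet-weighted mixtures. The default hierarchy is a
#' 20-cell-type, 9-lineage immune panel; the default scale (5000 genes, 10
#' samples per cell type, 8 platforms) echoes a realistic multi-study
#' compendium at desk cost.
#'
#' @param n_genes Number of genes.
#' @param cell_types Named character vector: names are cell types, values
#'   their lineages.
#' @param n_samples_per_type Sorted samples per cell type.
#' @param n_markers Planted marker genes per cell type.
#' @param fold_change Linear-scale fold change of a marker in its own cell
#'   type (> 1).
#' @param base_meanlog,base_sdlog Log-normal location/scale of the shared
#'   baseline gene expression profile.
#' @param noise_sd Additive Gaussian noise SD on the linear scale, clamped at
#'   zero; `NULL` means 5 percent of the mean baseline signal.
#' @param bio_cv Per-gene biological coefficient of variation of sorted
#'   replicates (log-normal, applied multiplicatively before additive noise).
#'   Without it, quantile normalization maps rank-stable genes of a clean
#'   simulation to identical values in every replicate, creating
#'   zero-variance artifacts real replicates do not show.
#' @param n_platforms Number of platforms samples are spread across.
#' @param platform_tau Per-platform gene-factor dispersion (log scale SD of
#'   the multiplicative factor); 0 disables.
#' @param platform_gamma Per-platform dynamic-range exponent (scalar recycled
#'   or one per platform); 1 disables.
#' @param disease_fraction Fraction of sorted samples in the disease state.
#' @param disease_gene_fraction Fraction `f` of genes carrying the disease
#'   perturbation.
#' @param disease_scale Log-scale magnitude of the per-gene disease factor.
#' @param disease_factor_model `"lognormal"`: factors `exp(N(0, scale^2))`;
#'   `"fold"`: each perturbed gene is up- or down-regulated (equal
#'   probability) by the fixed fold `exp(scale)` -- same median magnitude,
#'   no heavy tail.
#' @param disease_program_mass Maximum fraction of a disease sample's
#'   transcriptome displaced by an aberrant disease expression program (an
#'   out-of-basis cell state, e.g. blasts in leukemia). 0 disables; the
#'   realized fraction per mixture is this mass times the sample's severity.
#' @param dirichlet_alpha Dirichlet concentration for mixture proportions
#'   (scalar or one per cell type).
#' @param n_out_of_basis Number of extra cell types *not* part of the basis
#'   truth (used for tissue-like out-of-basis samples).
#' @param seed RNG seed; every generator derived from this config is a pure
#'   function of (config, seed).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       cell_types = default_cell_types(),
                       n_samples_per_type = 10,
                       n_markers = 15,
                       fold_change = 4,
                       base_meanlog = 6,
                       base_sdlog = 1,
                       noise_sd = NULL,
                       bio_cv = 0.2,
                       n_platforms = 8,
                       platform_tau = 0.3,
                       platform_gamma = 1,
                       disease_fraction = 0,
                       disease_gene_fraction = 0.3,
                       disease_scale = 0.8,
                       disease_factor_model = c("lognormal", "fold"),
                       disease_program_mass = 0,
                       dirichlet_alpha = 1,
                       n_out_of_basis = 0,
                       seed = 1) {
  assert_scalar_number(n_genes, "n_genes", 1)
  assert_scalar_number(n_samples_per_type, "n_samples_per_type", 1)
  assert_scalar_number(n_markers, "n_markers", 1)
  assert_scalar_number(fold_change, "fold_change", lower = 1 + 1e-9)
  assert_scalar_number(n_platforms, "n_platforms", 1)
  assert_scalar_number(platform_tau, "platform_tau", 0)
  assert_scalar_number(disease_fraction, "disease_fraction", 0, 1)
  assert_scalar_number(disease_gene_fraction, "disease_gene_fraction", 0, 1)
  assert_scalar_number(disease_scale, "disease_scale", 0)
  assert_scalar_number(disease_program_mass, "disease_program_mass", 0, 1)
  assert_scalar_number(bio_cv, "bio_cv", 0)
  disease_factor_model <- match.arg(disease_factor_model)
  if (any(platform_gamma <= 0)) stop_bd("platform_gamma must be > 0")
  if (any(dirichlet_alpha <= 0)) stop_bd("dirichlet_alpha must be > 0")
  if (is.null(names(cell_types))) stop_bd("cell_types must be named (cell type -> lineage)")
  total_markers <- n_markers * (length(cell_types) + n_out_of_basis)
  if (total_markers > n_genes) {
    stop_bd("marker demand (%d) exceeds n_genes (%d)", total_markers, n_genes)
  }
  if (is.null(noise_sd)) noise_sd <- 0.05 * exp(base_meanlog + base_sdlog^2 / 2)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    n_samples_per_type = as.integer(n_samples_per_type),
    n_markers = as.integer(n_markers), fold_change = fold_change,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog, noise_sd = noise_sd,
    bio_cv = bio_cv,
    n_platforms = as.integer(n_platforms), platform_tau = platform_tau,
    platform_gamma = rep(platform_gamma, length.out = n_platforms),
    disease_fraction = disease_fraction,
    disease_gene_fraction = disease_gene_fraction, disease_scale = disease_scale,
    disease_factor_model = disease_factor_model,
    disease_program_mass = disease_program_mass,
    dirichlet_alpha = dirichlet_alpha,
    n_out_of_basis = as.integer(n_out_of_basis), seed = as.integer(seed)
  ), class = "sim_config")
}

# Additive Gaussian noise truncated at zero, by inverse-CDF sampling of the
# left-truncated normal (no probability atom at zero -- clamping would create
# exact ties that microarray intensities do not show).
add_noise <- function(x, noise_sd) {
  if (noise_sd == 0) return(x)
  lo <- stats::pnorm(-x / noise_sd)
  u <- stats::runif(length(x), lo, 1)
  x + noise_sd * stats::qnorm(u)
}

#' Simulate a sorted-cell compendium
#'
#' Draws one shared log-normal baseline profile, multiplies each cell type's
#' planted (disjoint) marker genes by the configured fold change, and emits
#' `n_samples_per_type` noisy replicates per cell type. Samples are assigned
#' round-robin to platforms and, when configured, to the disease state;
#' platform distortions (shared per-gene multiplicative factors plus a
#' dynamic-range exponent) and disease perturbations (a shared gene set
#' scaled in disease samples only) are then applied. Pure function of
#' (config, seed).
#'
#' @param cfg A [sim_config()].
#' @return List with `expr` (annotated `expr_matrix`) and `truth` (a
#'   `sim_truth`: mean profiles, marker map, platform factors and exponents,
#'   disease mask and factors, out-of-basis profiles, seed).
#' @export
simulate_sorted_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    cts <- names(cfg$cell_types)
    base <- stats::setNames(rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog), genes)

    n_extra <- cfg$n_out_of_basis
    marker_pool <- sample(genes, cfg$n_markers * (length(cts) + n_extra))
    markers <- split(marker_pool[seq_len(cfg$n_markers * length(cts))],
                     rep(cts, each = cfg$n_markers))[cts]

    profiles <- vapply(cts, function(ct) {
      p <- base
      p[markers[[ct]]] <- p[markers[[ct]]] * cfg$fold_change
      p
    }, numeric(cfg$n_genes))

    out_profiles <- NULL
    if (n_extra > 0) {
      extra_markers <- marker_pool[-seq_len(cfg$n_markers * length(cts))]
      out_cts <- sprintf("tissue type %d", seq_len(n_extra))
      out_profiles <- vapply(seq_len(n_extra), function(i) {
        # out-of-basis populations get their own independent baseline
        p <- rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog)
        mk <- extra_markers[seq((i - 1) * cfg$n_markers + 1, i * cfg$n_markers)]
        p[match(mk, genes)] <- p[match(mk, genes)] * cfg$fold_change
        p
      }, numeric(cfg$n_genes))
      dimnames(out_profiles) <- list(genes, out_cts)
    }

    n_samp <- length(cts) * cfg$n_samples_per_type
    sample_ids <- sprintf("s%04d", seq_len(n_samp))
    cell_type <- rep(cts, each = cfg$n_samples_per_type)
    # balanced within cell type so every platform sees every population
    platforms <- sprintf("platform_%d",
                         rep(rep_len(seq_len(cfg$n_platforms), cfg$n_samples_per_type),
                             times = length(cts)))
    disease <- rep("healthy", n_samp)
    n_dis_per_ct <- round(cfg$disease_fraction * cfg$n_samples_per_type)
    if (n_dis_per_ct > 0) {
      for (ct in cts) {
        idx <- which(cell_type == ct)
        disease[sample(idx, n_dis_per_ct)] <- "disease"
      }
    }
    n_dis <- sum(disease == "disease")

    vals <- profiles[, match(cell_type, cts), drop = FALSE]
    if (cfg$bio_cv > 0) {
      vals <- vals * exp(matrix(rnorm(length(vals), 0, cfg$bio_cv), nrow = cfg$n_genes))
    }
    vals <- matrix(add_noise(as.numeric(vals), cfg$noise_sd), nrow = cfg$n_genes,
                   dimnames = list(genes, sample_ids))

    # disease perturbation: shared gene set with per-gene log-normal factors,
    # modulated per cell type (disease reshapes each population's state to a
    # different degree) and applied to disease samples only
    n_pert <- round(cfg$disease_gene_fraction * cfg$n_genes)
    perturbed_genes <- sort(sample(genes, n_pert))
    disease_factors <- stats::setNames(
      if (cfg$disease_factor_model == "fold") {
        exp(sample(c(-1, 1), n_pert, replace = TRUE) * cfg$disease_scale)
      } else {
        exp(rnorm(n_pert, 0, cfg$disease_scale))
      }, perturbed_genes)
    # disease response is organized by lineage: half the lineages carry the
    # perturbation program (responders), the rest do not -- mixtures therefore
    # always combine responding and non-responding content
    lineages_all <- unique(unname(cfg$cell_types))
    responders <- sample(lineages_all, ceiling(length(lineages_all) / 2))
    disease_response <- stats::setNames(
      as.numeric(unname(cfg$cell_types) %in% responders), cts)
    # aberrant disease program: an out-of-basis expression state (e.g. blast
    # expansion) that displaces part of a diseased sample's transcriptome
    disease_program <- stats::setNames(
      rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog), genes)
    if (n_dis > 0) {
      m_sorted <- cfg$disease_program_mass / 2
      for (j in which(disease == "disease")) {
        if (n_pert > 0) {
          vals[perturbed_genes, j] <- vals[perturbed_genes, j] *
            disease_factors^disease_response[cell_type[j]]
        }
        if (m_sorted > 0) {
          vals[, j] <- (1 - m_sorted) * vals[, j] + m_sorted * disease_program
        }
      }
    }

    # platform distortion: per-platform per-gene factor + power exponent
    plats <- sprintf("platform_%d", seq_len(cfg$n_platforms))
    platform_factors <- matrix(
      exp(rnorm(cfg$n_genes * cfg$n_platforms, 0, cfg$platform_tau)),
      nrow = cfg$n_genes, dimnames = list(genes, plats))
    gamma <- stats::setNames(cfg$platform_gamma, plats)
    for (pl in plats) {
      idx <- platforms == pl
      if (!any(idx)) next
      vals[, idx] <- (vals[, idx] * platform_factors[, pl])^gamma[pl]
    }

    ann <- tibble::tibble(
      sample_id = sample_ids, cell_type = cell_type,
      lineage = unname(cfg$cell_types[cell_type]), platform = platforms,
      disease_state = disease, tissue_source = "blood")
    truth <- structure(list(
      mean_profiles = profiles, markers = markers,
      platform_factors = platform_factors, platform_gamma = gamma,
      perturbed_genes = perturbed_genes, disease_factors = disease_factors,
      disease_response = disease_response, disease_program = disease_program,
      out_profiles = out_profiles, lineage_of = cfg$cell_types,
      config = cfg, seed = cfg$seed, proportions = NULL
    ), class = "sim_truth")
    list(expr = expression_matrix(vals, ann), truth = truth)
  })
}

#' Apply a platform distortion to an expression matrix
#'
#' Per platform, every gene gets a shared multiplicative factor
#' `exp(N(0, tau^2))` (the same factor for all samples of that platform),
#' after which values are raised to the platform's exponent `gamma`.
#' `tau = 0, gamma = 1` is the identity. Pre-drawn factors (e.g. from a
#' `sim_truth`, so mixtures see the same distortion as the compendium) can be
#' supplied via `factors`/`gamma` directly.
#'
#' @param m An `expr_matrix`.
#' @param platforms Platform label per sample (default: the `platform`
#'   annotation).
#' @param tau Log-scale factor dispersion (ignored when `factors` given).
#' @param gamma Exponent, scalar or named per platform.
#' @param seed RNG seed for drawing factors.
#' @param factors Optional genes x platforms factor matrix.
#' @return The distorted `expr_matrix`.
#' @export
apply_platform_effect <- function(m, platforms = NULL, tau = 0, gamma = 1,
                                  seed = NULL, factors = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  platforms <- platforms %||% m$annotations$platform
  if (anyNA(platforms)) stop_bd("missing platform labels")
  plats <- unique(platforms)
  if (!is.null(factors)) {
    unknown <- setdiff(plats, colnames(factors))
    if (length(unknown) > 0) stop_bd("unknown platform label(s): %s",
                                     paste(unknown, collapse = ", "))
    factors <- factors[rownames(m$values), , drop = FALSE]
  } else {
    assert_scalar_number(tau, "tau", 0)
    factors <- with_optional_seed(seed, matrix(
      exp(rnorm(nrow(m$values) * length(plats), 0, tau)),
      nrow = nrow(m$values), dimnames = list(rownames(m$values), plats)))
  }
  if (is.null(names(gamma))) gamma <- stats::setNames(rep(gamma, length.out = length(plats)), plats)
  if (any(gamma <= 0)) stop_bd("gamma must be > 0")
  vals <- m$values
  for (pl in plats) {
    idx <- platforms == pl
    vals[, idx] <- (vals[, idx] * factors[, pl])^gamma[[pl]]
  }
  expression_matrix(vals, m$annotations)
}

#' Apply a disease perturbation to an expression matrix
#'
#' A random fraction `f` of genes is selected once (the shared perturbation
#' set); in disease samples only, those genes are scaled by a per-gene factor
#' `exp(N(0, scale^2))`. Healthy samples are untouched.
#'
#' @param m An `expr_matrix`.
#' @param disease Logical (or `"disease"`/`"healthy"`) per sample; default:
#'   the `disease_state` annotation.
#' @param f Fraction of genes perturbed.
#' @param scale Log-scale SD of the perturbation factor.
#' @param seed RNG seed.
#' @param perturbed_genes,factors Optional pre-drawn perturbation (gene set
#'   and named factor vector), e.g. from a `sim_truth`.
#' @return The perturbed `expr_matrix`.
#' @export
apply_disease_effect <- function(m, disease = NULL, f = 0.3, scale = 0.8,
                                 seed = NULL, perturbed_genes = NULL, factors = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  assert_scalar_number(f, "f", 0, 1)
  disease <- disease %||% (m$annotations$disease_state == "disease")
  if (is.character(disease)) disease <- disease == "disease"
  disease[is.na(disease)] <- FALSE
  if (is.null(perturbed_genes)) {
    drawn <- with_optional_seed(seed, {
      genes <- sample(rownames(m$values), round(f * nrow(m$values)))
      list(genes = genes, factors = stats::setNames(exp(rnorm(length(genes), 0, scale)), genes))
    })
    perturbed_genes <- drawn$genes; factors <- drawn$factors
  }
  perturbed_genes <- intersect(perturbed_genes, rownames(m$values))
  if (length(perturbed_genes) == 0 || !any(disease)) return(m)
  vals <- m$values
  vals[perturbed_genes, disease] <- vals[perturbed_genes, disease] * factors[perturbed_genes]
  expression_matrix(vals, m$annotations)
}

# Dirichlet draws, rows on the simplex.
rdirichlet_mat <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate bulk mixtures from a compendium truth
#'
#' Per mixture, proportions are drawn from a Dirichlet over the truth's cell
#' types and the expression profile is the proportion-weighted combination of
#' the cell-type mean profiles plus clamped additive Gaussian noise -- the
#' linear-mixing regime deconvolution assumes.
#'
#' @param truth A `sim_truth` from [simulate_sorted_compendium()].
#' @param n Number of mixtures.
#' @param alpha Dirichlet concentration (scalar or per cell type; default:
#'   the config's).
#' @param noise_sd Additive noise SD (default: the config's).
#' @param seed RNG seed.
#' @param disease_state `"healthy"` (default) mixes the clean profiles;
#'   `"disease"` applies the truth's disease perturbation to the profiles
#'   before mixing and annotates the samples accordingly. Patients differ in
#'   how strongly disease has reshaped their circulating cells, so each
#'   disease mixture draws a severity `w` uniform over `severity` and its
#'   perturbation factors are attenuated to `factor^w`.
#' @param severity Length-2 range of the per-sample disease severity.
#' @param prefix Sample-id prefix.
#' @return List with `expr` (annotated, `tissue_source = "blood"`) and
#'   `truth` with `$proportions` (mixtures x cell types) and, for disease
#'   cohorts, `$severity` filled in.
#' @export
simulate_mixtures <- function(truth, n, alpha = NULL, noise_sd = NULL, seed = 1,
                              disease_state = c("healthy", "disease"),
                              severity = c(0.4, 1), prefix = "mix") {
  stopifnot(inherits(truth, "sim_truth"))
  disease_state <- match.arg(disease_state)
  assert_scalar_number(n, "n", 1)
  if (length(severity) != 2 || any(severity < 0)) stop_bd("`severity` must be a range >= 0")
  cfg <- truth$config
  profiles <- truth$mean_profiles
  k <- ncol(profiles)
  alpha <- alpha %||% cfg$dirichlet_alpha
  alpha <- rep(alpha, length.out = k)
  noise_sd <- noise_sd %||% cfg$noise_sd
  pg <- intersect(truth$perturbed_genes, rownames(profiles))
  with_optional_seed(seed, {
    P <- rdirichlet_mat(n, alpha)
    colnames(P) <- colnames(profiles)
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    rownames(P) <- ids
    sev <- NULL
    if (disease_state == "disease") {
      # a designed cohort spanning mild to maximal severity
      sev <- stats::setNames(seq(severity[1], severity[2], length.out = n), ids)
      resp <- truth$disease_response[colnames(profiles)]
      m <- cfg$disease_program_mass
      vals <- vapply(seq_len(n), function(i) {
        pi <- profiles
        if (length(pg) > 0) {
          pi[pg, ] <- pi[pg, ] *
            outer(truth$disease_factors[pg], sev[i] * resp, function(f, e) f^e)
        }
        v <- as.numeric(pi %*% P[i, ])
        if (m > 0) {
          b <- m * sev[i]
          v <- (1 - b) * v + b * truth$disease_program
        }
        v
      }, numeric(nrow(profiles)))
      dimnames(vals) <- list(rownames(profiles), ids)
    } else {
      vals <- profiles %*% t(P)
    }
    vals <- matrix(add_noise(as.numeric(vals), noise_sd), nrow = nrow(profiles),
                   dimnames = list(rownames(profiles), ids))
    ann <- tibble::tibble(sample_id = ids, cell_type = NA_character_,
                          lineage = NA_character_, platform = NA_character_,
                          disease_state = disease_state, tissue_source = "blood")
    truth$proportions <- P
    truth$severity <- sev
    list(expr = expression_matrix(vals, ann), truth = truth)
  })
}

#' Simulate out-of-basis (tissue-like) samples
#'
#' Emits noisy samples dominated by cell populations that are *not* part of
#' the basis truth (requires `n_out_of_basis > 0` in the config), annotated
#' with `tissue_source = "tissue"`. Like real solid-tissue biopsies, each
#' sample carries an immune infiltrate: a per-sample fraction (uniform over
#' `infiltrate`) of Dirichlet-mixed in-basis cell content, which is what
#' makes separating biopsies from blood by fit quality a non-trivial task.
#' `disease_state` only annotates the cohort: the disease axis modeled by the
#' generator is the systemic derangement of *circulating* immune cells (see
#' [simulate_mixtures()]), while a biopsy's parenchyma and tissue-resident
#' infiltrate are held at their own baseline.
#'
#' @param cfg The [sim_config()] (for noise level and Dirichlet alpha).
#' @param truth A `sim_truth` carrying `out_profiles`.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param disease_state Cohort annotation, `"healthy"` or `"disease"`.
#' @param infiltrate Length-2 range of the immune-infiltrate fraction.
#' @param prefix Sample-id prefix.
#' @return An annotated `expr_matrix`.
#' @export
simulate_out_of_basis_samples <- function(cfg, truth, n, seed = 1,
                                          disease_state = c("healthy", "disease"),
                                          infiltrate = c(0.04, 0.15),
                                          prefix = "tis") {
  stopifnot(inherits(truth, "sim_truth"))
  disease_state <- match.arg(disease_state)
  if (is.null(truth$out_profiles)) {
    stop_bd("no out-of-basis cell types configured (set n_out_of_basis > 0)")
  }
  if (length(infiltrate) != 2 || any(infiltrate < 0) || any(infiltrate > 1)) {
    stop_bd("`infiltrate` must be a fraction range within [0, 1]")
  }
  profiles <- truth$out_profiles
  imm <- truth$mean_profiles
  alpha <- rep(cfg$dirichlet_alpha, length.out = ncol(imm))
  with_optional_seed(seed, {
    which_ct <- sample.int(ncol(profiles), n, replace = TRUE)
    # a designed cohort spanning the infiltration range
    frac <- seq(infiltrate[1], infiltrate[2], length.out = n)
    P_imm <- rdirichlet_mat(n, alpha)
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    vals <- profiles[, which_ct, drop = FALSE] %*% diag(1 - frac, n) +
      imm %*% t(P_imm * frac)
    vals <- matrix(add_noise(as.numeric(vals), cfg$noise_sd), nrow = nrow(profiles),
                   dimnames = list(rownames(profiles), ids))
    ann <- tibble::tibble(sample_id = ids,
                          cell_type = colnames(profiles)[which_ct],
                          lineage = NA_character_, platform = NA_character_,
                          disease_state = disease_state, tissue_source = "tissue")
    expression_matrix(vals, ann)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes x %d cell types; %d markers/type; seed %d\n",
              nrow(x$mean_profiles), ncol(x$mean_profiles),
              length(x$markers[[1]]), x$seed))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d genes, %d cell types (%d lineages), %d samples/type,\n",
                     "  fc %.1f x %d markers, noise_sd %.2f, %d platforms (tau %.2f),\n",
                     "  disease %.0f%% (f %.2f, scale %.2f), seed %d\n"),
              x$n_genes, length(x$cell_types), length(unique(x$cell_types)),
              x$n_samples_per_type, x$fold_change, x$n_markers, x$noise_sd,
              x$n_platforms, x$platform_tau, 100 * x$disease_fraction,
              x$disease_gene_fraction, x$disease_scale, x$seed))
  invisible(x)
}
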