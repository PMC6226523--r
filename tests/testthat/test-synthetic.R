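test_that("sim_config validates its invariants", {
  expect_s3_class(small_scenario(), "sim_config")
  expect_error(small_scenario(fold_change = 1), "fold_change")
  expect_error(small_scenario(n_genes = 10), "marker demand")
  expect_error(sim_config(platform_tau = -0.1), "platform_tau")
  expect_error(sim_config(platform_gamma = 0), "platform_gamma")
  expect_error(sim_config(disease_gene_fraction = 1.5), "disease_gene_fraction")
  expect_error(sim_config(cell_types = c("a", "b")), "named")
})

test_that("a deterministic configuration yields identical replicate columns", {
  cfg <- small_scenario(noise_sd = 0, bio_cv = 0, n_samples_per_type = 3)
  sim <- simulate_sorted_compendium(cfg)
  ann <- sim$expr$annotations
  for (ct in unique(ann$cell_type)) {
    cols <- sim$expr$values[, ann$cell_type == ct, drop = FALSE]
    expect_lt(max(abs(cols - cols[, 1])), 1e-12)
  }
})

test_that("compendium simulation is bit-reproducible and satisfies invariants", {
  cfg <- small_scenario(seed = 77)
  s1 <- simulate_sorted_compendium(cfg)
  s2 <- simulate_sorted_compendium(cfg)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$truth$markers, s2$truth$markers)
  expect_true(all(s1$expr$values >= 0))
  expect_false(anyDuplicated(colnames(s1$expr$values)) > 0)
  # marker sets are disjoint across cell types
  all_markers <- unlist(s1$truth$markers)
  expect_false(anyDuplicated(all_markers) > 0)
})

test_that("realized marker fold-change tracks the configured value", {
  ratios <- c()
  for (s in 1:20) {
    cfg <- small_scenario(seed = 200 + s, n_genes = 300, cell_types = stats::setNames(
      rep(c("L1", "L2"), each = 3), paste0("ct", 1:6)))
    sim <- simulate_sorted_compendium(cfg)
    ann <- sim$expr$annotations
    for (ct in c("ct1", "ct4")) {
      mk <- sim$truth$markers[[ct]]
      own <- rowMeans(sim$expr$values[mk, ann$cell_type == ct, drop = FALSE])
      other <- rowMeans(sim$expr$values[mk, ann$cell_type != ct, drop = FALSE])
      ratios <- c(ratios, own / other)
    }
  }
  expect_lt(abs(mean(ratios) - 4) / 4, 0.1)
})

test_that("apply_platform_effect is identity at tau 0, gamma 1 and shares factors", {
  cfg <- small_scenario(seed = 5, n_samples_per_type = 4)
  sim <- simulate_sorted_compendium(cfg)
  m <- sim$expr
  plats <- rep(c("A", "B"), length.out = ncol(m$values))
  out0 <- apply_platform_effect(m, plats, tau = 0, gamma = 1, seed = 3)
  expect_equal(out0$values, m$values)

  out <- apply_platform_effect(m, plats, tau = 0.4, gamma = 1, seed = 3)
  pos <- rowSums(m$values == 0) == 0 # zero-clamped entries have no ratio
  ratio <- out$values[pos, ] / m$values[pos, ]
  a_cols <- which(plats == "A")
  # same per-gene factor across all samples of a platform
  expect_lt(max(abs(ratio[, a_cols] - ratio[, a_cols[1]])), 1e-12)
  # factors differ between platforms
  expect_gt(max(abs(ratio[, a_cols[1]] - ratio[, which(plats == "B")[1]])), 0.01)
})

test_that("platform log-factors have the configured moments", {
  set.seed(6)
  v <- named_matrix(rep(1, 2000), 1000, 2)
  m <- toy_expr(v)
  out <- apply_platform_effect(m, c("P", "P"), tau = 0.35, seed = 11)
  lf <- log(out$values[, 1])
  expect_lt(abs(mean(lf)), 0.05)
  expect_lt(abs(sd(lf) - 0.35), 0.05)
})

test_that("apply_platform_effect validates labels against supplied factors", {
  v <- named_matrix(rep(1, 20), 10, 2)
  m <- toy_expr(v)
  factors <- matrix(1, 10, 1, dimnames = list(rownames(v), "known"))
  expect_error(apply_platform_effect(m, c("known", "mystery"), factors = factors),
               "mystery")
})

test_that("apply_disease_effect perturbs only disease samples on a shared gene set", {
  set.seed(8)
  v <- named_matrix(rlnorm(400, 3, 0.5), 100, 4)
  m <- toy_expr(v, disease_state = c("healthy", "disease", "healthy", "disease"))
  out0 <- apply_disease_effect(m, f = 0, seed = 2)
  expect_equal(out0$values, m$values)
  out <- apply_disease_effect(m, f = 0.4, scale = 1, seed = 2)
  # healthy columns bit-identical
  expect_identical(out$values[, c(1, 3)], m$values[, c(1, 3)])
  changed <- rowSums(out$values[, c(2, 4)] != m$values[, c(2, 4)]) > 0
  expect_equal(sum(changed), 40) # f * n_genes exactly, by construction
  # the same factor applies to both disease samples
  r2 <- out$values[changed, 2] / m$values[changed, 2]
  r4 <- out$values[changed, 4] / m$values[changed, 4]
  expect_equal(r2, r4)
})

test_that("mixtures live on the simplex and reduce to the exact product at zero noise", {
  cfg <- small_scenario(seed = 30)
  sim <- simulate_sorted_compendium(cfg)
  mx <- simulate_mixtures(sim$truth, 25, noise_sd = 0, seed = 4)
  expect_equal(unname(rowSums(mx$truth$proportions)), rep(1, 25))
  recon <- sim$truth$mean_profiles %*% t(mx$truth$proportions)
  expect_lt(max(abs(recon - mx$expr$values)), 1e-9)
  expect_true(all(mx$expr$annotations$tissue_source == "blood"))
  # reproducible under seed
  mx2 <- simulate_mixtures(sim$truth, 25, noise_sd = 0, seed = 4)
  expect_identical(mx$expr$values, mx2$expr$values)
  expect_error(simulate_mixtures(sim$truth, 5, alpha = c(1, 2), seed = 1), NA)
})

test_that("Dirichlet proportions have the configured mean", {
  cfg <- small_scenario(seed = 31, cell_types = stats::setNames(
    rep(c("L1", "L2"), each = 2), paste0("ct", 1:4)), n_genes = 200)
  sim <- simulate_sorted_compendium(cfg)
  alpha <- c(4, 2, 1, 1)
  mx <- simulate_mixtures(sim$truth, 5000, alpha = alpha, noise_sd = 0, seed = 9)
  expect_lt(max(abs(colMeans(mx$truth$proportions) - alpha / sum(alpha))), 0.01)
})

test_that("out-of-basis samples are tissue-annotated and fit worse than mixtures", {
  cfg <- small_scenario(seed = 32, n_out_of_basis = 2)
  sim <- simulate_sorted_compendium(cfg)
  tis <- simulate_out_of_basis_samples(cfg, sim$truth, 8, seed = 3)
  expect_true(all(tis$annotations$tissue_source == "tissue"))
  expect_false(any(tis$annotations$cell_type %in% colnames(sim$truth$mean_profiles)))
  tis2 <- simulate_out_of_basis_samples(cfg, sim$truth, 8, seed = 3)
  expect_identical(tis$values, tis2$values)

  b <- suppressWarnings(build_basis(sim$expr))
  mx <- simulate_mixtures(sim$truth, 8, seed = 5)
  res_mix <- deconvolve_dataset(mx$expr, b, methods = "qp")
  res_tis <- deconvolve_dataset(tis, b, methods = "qp")
  expect_lt(median(res_tis$gof), median(res_mix$gof))

  cfg0 <- small_scenario(seed = 33)
  sim0 <- simulate_sorted_compendium(cfg0)
  expect_error(simulate_out_of_basis_samples(cfg0, sim0$truth, 3, seed = 1),
               "n_out_of_basis")
})

test_that("disease mixtures lose fit against a healthy basis as severity grows", {
  cfg <- small_scenario(seed = 34, disease_fraction = 0.5, disease_program_mass = 1,
                        n_out_of_basis = 1)
  sim <- simulate_sorted_compendium(cfg)
  healthy_ids <- sim$expr$annotations$disease_state == "healthy"
  b <- suppressWarnings(build_basis(
    expression_matrix(sim$expr$values[, healthy_ids],
                      sim$expr$annotations[healthy_ids, ])))
  mx_h <- simulate_mixtures(sim$truth, 10, seed = 6, disease_state = "healthy")
  mx_d <- simulate_mixtures(sim$truth, 10, seed = 6, disease_state = "disease")
  gof_h <- deconvolve_dataset(mx_h$expr, b, methods = "qp")$gof
  res_d <- deconvolve_dataset(mx_d$expr, b, methods = "qp")
  expect_gt(median(gof_h), median(res_d$gof))
  # within the disease cohort, fit decreases with severity
  sev <- mx_d$truth$severity[res_d$sample_id]
  expect_lt(cor(sev, res_d$gof, method = "spearman"), -0.5)
})
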