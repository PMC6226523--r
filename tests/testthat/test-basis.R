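test_that("hedges_g matches hand computation and handles degeneracy", {
  expect_equal(hedges_g(c(5, 5, 5), c(5, 5, 5)), 0)
  # s_pooled = 1, J = 1 - 3/15 = 0.8, mean difference 2
  expect_equal(hedges_g(c(3, 4, 5), c(1, 2, 3)), 1.6)
  expect_equal(hedges_g(c(2, 2), c(0, 0)), 1e6)
  expect_equal(hedges_g(c(0, 0), c(2, 2)), -1e6)
  expect_error(hedges_g(c(1), c(1, 2)), ">= 2")
})

test_that("hedges_g is antisymmetric and affine-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2))
    g <- hedges_g(a, b)
    expect_equal(hedges_g(b, a), -g)
    shift <- runif(1, -10, 10); scale <- runif(1, 0.1, 5)
    expect_equal(hedges_g(a + shift, b + shift), g)
    expect_equal(hedges_g(a * scale, b * scale), g)
    expect_equal(g, oracle_hedges_g(a, b))
  }
})

test_that("one_vs_rest_effects equals per-gene scalar computation on a toy matrix", {
  v <- named_matrix(c(1, 9, 2, 8, 5, 5, 6, 4, 3, 7, 2, 8), 2, 6)
  m <- toy_expr(v, cell_type = rep(c("a", "b"), each = 3), lineage = "L")
  eff <- one_vs_rest_effects(m, "cell_type")
  for (g in rownames(v)) for (ct in c("a", "b")) {
    idx <- m$annotations$cell_type == ct
    expect_equal(
      eff$effect[eff$gene == g & eff$target == ct],
      oracle_hedges_g(v[g, idx], v[g, !idx]),
      info = paste(g, ct))
  }
  expect_true(all(eff$n_case == 3 & eff$n_control == 3))
})

test_that("one_vs_rest_effects excludes undersized groups and finds planted signal", {
  set.seed(11)
  v <- named_matrix(rlnorm(50 * 13, 3, 0.2), 50, 13)
  ct <- c(rep("big1", 5), rep("big2", 6), rep("tiny", 2))
  v["g1", ct == "big1"] <- v["g1", ct == "big1"] * 5
  m <- toy_expr(v, cell_type = ct, lineage = "L")
  expect_warning(eff <- one_vs_rest_effects(m, "cell_type"), "tiny")
  expect_false("tiny" %in% eff$target)
  expect_gt(eff$effect[eff$gene == "g1" & eff$target == "big1"], 2)
})

test_that("delta_effects equals brute-force competitor enumeration", {
  eff <- tibble::tibble(
    gene = "g", target = c("i", "j1", "j2"), family = "L",
    effect = c(2.0, 0.5, -1.0), n_case = 3, n_control = 6)
  d <- delta_effects(eff)
  expect_equal(d$delta[d$target == "i"], 1.5) # min(1.5, 3.0)
  expect_equal(d$delta[d$target == "j1"], -1.5)
  expect_equal(d$delta[d$target == "j2"], -3.0)

  # two-member family: delta is the pairwise difference
  eff2 <- tibble::tibble(gene = "g", target = c("a", "b"), family = "L",
                         effect = c(1.2, 0.2), n_case = 3, n_control = 3)
  d2 <- delta_effects(eff2)
  expect_equal(d2$delta[d2$target == "a"], 1.0)

  # all-equal effects give delta 0 everywhere
  eff3 <- tibble::tibble(gene = "g", target = c("a", "b", "c"), family = "L",
                         effect = c(0.7, 0.7, 0.7), n_case = 3, n_control = 6)
  expect_true(all(delta_effects(eff3)$delta == 0))

  # random instances against the double-loop oracle
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    eff4 <- tibble::tibble(
      gene = rep(c("g1", "g2"), each = k),
      target = rep(paste0("t", 1:k), 2), family = "F",
      effect = rnorm(2 * k), n_case = 3, n_control = 6)
    d4 <- delta_effects(eff4)
    for (g in c("g1", "g2")) {
      by_t <- stats::setNames(eff4$effect[eff4$gene == g], eff4$target[eff4$gene == g])
      for (t in names(by_t)) {
        expect_equal(d4$delta[d4$gene == g & d4$target == t], oracle_delta(by_t, t))
      }
    }
  }
})

test_that("delta_effects drops single-member families with a warning", {
  eff <- tibble::tibble(gene = "g", target = c("a", "b", "solo"),
                        family = c("L1", "L1", "L2"),
                        effect = c(1, 0, 2), n_case = 3, n_control = 3)
  expect_warning(d <- delta_effects(eff), "L2")
  expect_false("solo" %in% d$target)
})

test_that("auroc equals the normalized Mann-Whitney U with tie handling", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auroc(c(2, 2, 2, 2), c(0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(13)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    scores <- sample(rnorm(8), n, replace = TRUE) # deliberately tied
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (all(labels == labels[1])) labels[1] <- 1 - labels[1]
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auroc matches pROC on random untied data", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.4)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("stepwise_select honors the minimum signature size on perfect markers", {
  set.seed(19)
  cfg <- small_scenario(seed = 19, noise_sd = 5)
  sim <- simulate_sorted_compendium(cfg)
  tgt <- "ct1"
  ranked <- c(sim$truth$markers[[tgt]],
              setdiff(rownames(sim$expr$values), sim$truth$markers[[tgt]])[1:20])
  sig <- stepwise_select(sim$expr, tgt, ranked, level = "cell_type")
  expect_equal(sig$auroc_trajectory[1], 1) # a perfect marker alone separates
  expect_equal(sig$chosen_k, 5)            # minimum-size rule dominates
  expect_equal(sig$genes, ranked[1:5])
})

test_that("stepwise_select picks the smallest AUROC-proximal prefix", {
  # two groups separable only by combining genes: engineered trajectory
  set.seed(23)
  n <- 40
  lab <- rep(c("pos", "neg"), each = n / 2)
  v <- named_matrix(rnorm(12 * n, 10, 1), 12, n)
  # genes 1..8 each carry weak signal; AUROC grows with prefix length
  for (g in 1:8) v[g, lab == "pos"] <- v[g, lab == "pos"] + 0.55
  m <- toy_expr(v, cell_type = lab, lineage = "L")
  sig <- stepwise_select(m, "pos", rownames(v), level = "cell_type", epsilon = 0.005)
  traj <- sig$auroc_trajectory
  expected_k <- max(min(which(traj >= max(traj) - 0.005)), 5)
  expect_equal(sig$chosen_k, expected_k)
  # with a huge epsilon the floor of 5 genes is binding
  sig2 <- stepwise_select(m, "pos", rownames(v), level = "cell_type", epsilon = 0.49)
  expect_equal(sig2$chosen_k, 5)
})

test_that("stepwise_select flags degenerate candidate lists and bad targets", {
  v <- named_matrix(abs(rnorm(3 * 12, 10)), 3, 12)
  m <- toy_expr(v, cell_type = rep(c("a", "b"), 6), lineage = "L")
  expect_warning(sig <- stepwise_select(m, "a", rownames(v)[1:3], level = "cell_type"),
                 "selecting all")
  expect_equal(sig$chosen_k, 3)
  expect_true(sig$flagged)
  expect_error(stepwise_select(m, "zz", rownames(v), level = "cell_type"), "absent")
})

test_that("build_basis assembles per-cell-type means with disjoint stages", {
  cfg <- small_scenario(seed = 3, noise_sd = 10)
  sim <- simulate_sorted_compendium(cfg)
  b <- build_basis(sim$expr)
  expect_s3_class(b, "basis_matrix")
  expect_equal(sort(colnames(b$values)), sort(names(cfg$cell_types)))
  expect_true(all(b$values >= 0))
  # stage provenance is disjoint by construction
  s1 <- names(b$stage_of)[b$stage_of == "cell_type_stage"]
  s2 <- names(b$stage_of)[b$stage_of == "lineage_stage"]
  expect_length(intersect(s1, s2), 0)
  expect_true(all(vapply(b$signatures, function(s) s$chosen_k >= 5, TRUE) |
                    vapply(b$signatures, function(s) s$flagged, TRUE)))
  # assembly definition: basis values equal group means of the QN'd compendium
  qn <- quantile_normalize(sim$expr)
  ct1 <- qn$annotations$sample_id[qn$annotations$cell_type == "ct1"]
  expect_equal(b$values[, "ct1"],
               rowMeans(qn$values[rownames(b$values), ct1]))
})

test_that("build_basis is deterministic and warns on a single lineage", {
  cfg <- small_scenario(seed = 8)
  sim <- simulate_sorted_compendium(cfg)
  b1 <- build_basis(sim$expr)
  b2 <- build_basis(sim$expr)
  expect_identical(b1$values, b2$values)
  expect_identical(b1$stage_of, b2$stage_of)

  one_lineage <- stats::setNames(rep("only", 4), paste0("ct", 1:4))
  cfg2 <- small_scenario(seed = 9, cell_types = one_lineage, n_genes = 300)
  sim2 <- simulate_sorted_compendium(cfg2)
  expect_warning(b3 <- build_basis(sim2$expr), "single lineage")
  expect_true(all(b3$stage_of == "cell_type_stage"))
})

test_that("basis_from_gene_list computes group means and validates genes", {
  v <- named_matrix(c(2, 10, 4, 12, 6, 20, 8, 22), 2, 4)
  rownames(v) <- c("A", "B")
  m <- toy_expr(v, cell_type = c("x", "x", "y", "y"), lineage = "L")
  b <- basis_from_gene_list(m, c("A", "B"))
  expect_equal(b$values["A", "x"], 3)
  expect_equal(b$values["B", "y"], 21)
  expect_true(all(b$stage_of == "unspecified"))
  expect_error(basis_from_gene_list(m, c("A", "ZZ")), "ZZ")
})

test_that("basis_from_gene_list on build_basis genes reproduces its values", {
  cfg <- small_scenario(seed = 12)
  sim <- simulate_sorted_compendium(cfg)
  b <- build_basis(sim$expr)
  qn <- quantile_normalize(sim$expr)
  b2 <- basis_from_gene_list(qn, rownames(b$values))
  expect_equal(b2$values[rownames(b$values), colnames(b$values)], b$values)
})

test_that("basis matrices round-trip through TSV with sidecar", {
  cfg <- small_scenario(seed = 15, n_genes = 300)
  sim <- simulate_sorted_compendium(cfg)
  b <- build_basis(sim$expr)
  path <- withr::local_tempfile(fileext = ".tsv")
  side <- withr::local_tempfile(fileext = ".tsv")
  write_basis(b, path, sidecar = side)
  back <- read_basis(path, sidecar = side)
  expect_equal(back$values, b$values)
  expect_equal(back$lineage_of[names(b$lineage_of)], b$lineage_of)
  expect_equal(back$stage_of[names(b$stage_of)], b$stage_of)
})

test_that("planted markers dominate the delta ranking at low noise", {
  set.seed(31)
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- small_scenario(seed = 100 + s, noise_sd = 15)
    sim <- simulate_sorted_compendium(cfg)
    eff <- delta_effects(one_vs_rest_effects(sim$expr, "cell_type"))
    for (tgt in unique(eff$target)) {
      sub <- eff[eff$target == tgt, ]
      top <- sub$gene[order(-sub$delta)][seq_along(sim$truth$markers[[tgt]])]
      hits <- hits + sum(sim$truth$markers[[tgt]] %in% top)
      total <- total + length(sim$truth$markers[[tgt]])
    }
  }
  expect_gt(hits / total, 0.95)
})
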