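# A well-conditioned basis with planted markers, plus a mixture generator,
# shared by the solver tests.
solver_fixture <- function(seed = 1, n_genes = 200, k = 8) {
  set.seed(seed)
  base <- rlnorm(n_genes, 4, 1)
  M <- matrix(rep(base, k), n_genes, k,
              dimnames = list(sprintf("g%03d", 1:n_genes), paste0("ct", 1:k)))
  idx <- split(sample(n_genes, 8 * k), rep(1:k, each = 8))
  for (j in 1:k) M[idx[[j]], j] <- M[idx[[j]], j] * 4
  lineage_of <- stats::setNames(rep(c("A", "B"), length.out = k), colnames(M))
  basis <- structure(list(values = M, lineage_of = lineage_of,
                          stage_of = stats::setNames(rep("unspecified", n_genes), rownames(M)),
                          signatures = list(), name = "fixture", params = list()),
                     class = "basis_matrix")
  simplex <- function() { p <- rgamma(k, 1); p / sum(p) }
  list(basis = basis, M = M, simplex = simplex)
}

test_that("align_and_scale restricts to shared genes and z-scores both objects", {
  fx <- solver_fixture()
  sample_vec <- stats::setNames(rexp(300, 1 / 50), sprintf("g%03d", 300:1))
  al <- align_and_scale(sample_vec, fx$basis)
  expect_equal(al$n_genes_used, 200)
  expect_equal(mean(al$s), 0, tolerance = 1e-12)
  expect_equal(sd(al$s), 1, tolerance = 1e-12)
  expect_equal(mean(al$M), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(al$M)), 1, tolerance = 1e-12)
  # hand-computed z-score on a 4-gene vector
  v <- stats::setNames(c(2, 4, 6, 8), sprintf("g%03d", 1:4))
  al2 <- align_and_scale(v, fx$basis)
  expect_equal(al2$s, (c(2, 4, 6, 8) - 5) / sd(c(2, 4, 6, 8)))
  # scaling is idempotent
  al3_s <- (al2$s - mean(al2$s)) / sd(al2$s)
  expect_equal(al3_s, al2$s, tolerance = 1e-12)
})

test_that("align_and_scale rejects degenerate samples", {
  fx <- solver_fixture()
  expect_error(align_and_scale(stats::setNames(c(1, 2), c("zz1", "zz2")), fx$basis),
               "fewer than 2")
  flat <- stats::setNames(rep(3, 200), rownames(fx$M))
  expect_error(align_and_scale(flat, fx$basis), "zero-variance")
  expect_equal(align_and_scale(flat, fx$basis, rescale = FALSE)$n_genes_used, 200)
})

test_that("solve_linear matches hand-derived OLS, clipping, and rank checks", {
  M <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(solve_linear(c(1, 2, 3), M)), c(1, 2) / 3)
  I2 <- diag(2); colnames(I2) <- c("a", "b")
  expect_equal(unname(solve_linear(c(1, -1, 0), rbind(I2, 0))), c(1, 0))
  Mc <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(1, 1, 3))
  expect_error(solve_linear(c(1, 2, 3), Mc), "collinear")
  expect_error(solve_linear(c(-1, -2, -3), cbind(a = c(1, 2, 3))), "non-positive")
})

test_that("solve_qp solves the simplex-constrained problem", {
  I2 <- rbind(diag(2), 0); colnames(I2) <- c("a", "b")
  expect_equal(unname(solve_qp(c(0.3, 0.7, 0), I2)), c(0.3, 0.7), tolerance = 1e-8)
  # unconstrained optimum 1.5 projects to the simplex boundary
  expect_equal(unname(solve_qp(c(2, 0, 0), I2)), c(1, 0), tolerance = 1e-8)
  fx <- solver_fixture(2)
  for (i in 1:5) {
    p <- fx$simplex()
    expect_lt(max(abs(solve_qp(as.numeric(fx$M %*% p), fx$M) - p)), 1e-6)
  }
})

test_that("solve_qp agrees with independent QP solvers on random instances", {
  skip_if_not_installed("kernlab")
  set.seed(3)
  for (i in 1:8) {
    n <- 60; k <- 6
    M <- matrix(rexp(n * k), n, k, dimnames = list(NULL, paste0("c", 1:k)))
    s <- rnorm(n)
    p1 <- unname(solve_qp(s, M))
    # oracle 1: augmented-row NNLS via pracma's Lawson-Hanson
    lam <- 1e3 * max(1, mean(abs(M)))
    p2 <- pracma::lsqnonneg(rbind(M, lam), c(s, lam))$x
    p2 <- pmax(p2, 0); p2 <- p2 / sum(p2)
    # the augmented-row oracle carries O(1/lambda^2) constraint slack
    expect_equal(p1, p2, tolerance = 1e-4)
    # oracle 2: interior-point QP with explicit equality constraint
    ip <- kernlab::ipop(c = -crossprod(M, s), H = crossprod(M) + diag(1e-10, k),
                        A = matrix(1, 1, k), b = 1, l = rep(0, k), u = rep(1, k),
                        r = 0, sigf = 9, maxiter = 200)
    expect_equal(p1, kernlab::primal(ip), tolerance = 1e-4)
  }
})

test_that("solve_robust recovers noiseless mixtures and resists outliers", {
  fx <- solver_fixture(4)
  p <- fx$simplex()
  s <- as.numeric(fx$M %*% p)
  expect_lt(max(abs(solve_robust(s, fx$M) - p)), 1e-4)
  # a gross outlier hurts OLS more than the Huber fit
  s_out <- s
  s_out[5] <- s_out[5] + 10 * sd(s)
  err_rob <- sum(abs(solve_robust(s_out, fx$M) - p))
  err_ols <- sum(abs(solve_linear(s_out, fx$M) - p))
  expect_lt(err_rob, err_ols)
  out <- solve_robust(s_out, fx$M)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1)
})

test_that("the Huber IRLS agrees with MASS::rlm on noisy instances", {
  fx <- solver_fixture(11)
  set.seed(11)
  for (i in 1:5) {
    p <- fx$simplex()
    s <- as.numeric(fx$M %*% p) + rnorm(nrow(fx$M), 0, 0.1 * mean(fx$M))
    sz <- (s - mean(s)) / sd(s)
    Mz <- (fx$M - mean(fx$M)) / sd(as.numeric(fx$M))
    ref <- suppressWarnings(MASS::rlm(x = Mz, y = sz, psi = MASS::psi.huber,
                                      k = 1.345, maxit = 200))
    expected <- pmax(unname(coef(ref)), 0)
    expected <- expected / sum(expected)
    expect_equal(unname(solve_robust(sz, Mz)), expected, tolerance = 1e-3)
  }
})

test_that("solve_svr recovers noiseless mixtures and selects nu by RMSE", {
  fx <- solver_fixture(5)
  p <- fx$simplex()
  s <- as.numeric(fx$M %*% p)
  est <- solve_svr(s, fx$M)
  expect_gt(cor(est, p), 0.99)
  expect_true(all(est >= 0))
  expect_equal(sum(est), 1)
  # the returned nu is the grid member with the smallest reconstruction RMSE
  sz <- (s - mean(s)) / sd(s); Mz <- (fx$M - mean(fx$M)) / sd(as.numeric(fx$M))
  rmse <- vapply(c(0.25, 0.5, 0.75), function(nu) {
    fit <- e1071::svm(x = Mz, y = sz, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = 1, tolerance = 1e-4, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    sqrt(mean((sz - Mz %*% w)^2))
  }, 0.0)
  expect_equal(attr(est, "nu"), c(0.25, 0.5, 0.75)[which.min(rmse)])
})

test_that("deconvolve_sample dispatches solvers and reports goodness of fit", {
  fx <- solver_fixture(6)
  p <- fx$simplex()
  s <- stats::setNames(as.numeric(fx$M %*% p), rownames(fx$M))
  res <- deconvolve_sample(s, fx$basis, method = "qp", sample_id = "m1")
  al <- align_and_scale(s, fx$basis)
  expect_equal(unlist(res[proportion_cols(res)], use.names = FALSE),
               unname(solve_qp(al$s, al$M)))
  expect_gte(res$gof, 0.999)
  expect_equal(res$n_genes_used, nrow(fx$M))
  expect_error(deconvolve_sample(s, fx$basis, method = "pert"), "unknown method")
})

test_that("goodness of fit is invariant to affine rescaling of the mixture", {
  fx <- solver_fixture(7)
  p <- fx$simplex()
  s <- stats::setNames(as.numeric(fx$M %*% p) + rnorm(nrow(fx$M), 0, 20), rownames(fx$M))
  s <- pmax(s, 0)
  g1 <- deconvolve_sample(s, fx$basis, method = "linear")$gof
  g2 <- deconvolve_sample(s * 3.7, fx$basis, method = "linear")$gof
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("deconvolve_dataset runs every sample-method pair and isolates failures", {
  fx <- solver_fixture(8)
  vals <- vapply(1:3, function(i) as.numeric(fx$M %*% fx$simplex()), numeric(nrow(fx$M)))
  dimnames(vals) <- list(rownames(fx$M), paste0("m", 1:3))
  m <- toy_expr(vals)
  res <- deconvolve_dataset(m, fx$basis, methods = c("linear", "qp"))
  expect_equal(nrow(res), 6)
  expect_equal(nrow(attr(res, "failures")), 0)
  # per-sample consistency: identical to deconvolve_sample on the QN'd columns
  qn <- quantile_normalize(m)
  direct <- deconvolve_sample(qn$values[, "m2"], fx$basis, method = "qp", sample_id = "m2")
  row <- tibble::as_tibble(res)[res$sample_id == "m2" & res$method == "qp", ]
  expect_equal(as.numeric(row[proportion_cols(res)]),
               as.numeric(direct[proportion_cols(direct)]))
  # a constant column fails alone, the rest still succeed
  vals_bad <- cbind(vals, m4 = rep(5, nrow(vals)))
  res2 <- deconvolve_dataset(toy_expr(vals_bad), fx$basis, methods = c("linear", "qp"),
                             qn = FALSE)
  expect_equal(nrow(res2), 6)
  expect_equal(nrow(attr(res2, "failures")), 2)
  expect_error(deconvolve_dataset(m, fx$basis, methods = character(0)), "empty method")
})

test_that("estimates with and without rescaling agree for the renormalizing solvers", {
  fx <- solver_fixture(9)
  cors <- c()
  for (i in 1:6) {
    p <- fx$simplex()
    s <- stats::setNames(pmax(as.numeric(fx$M %*% p) + rnorm(nrow(fx$M), 0, 15), 0),
                         rownames(fx$M))
    for (meth in c("linear", "robust")) {
      e1 <- deconvolve_sample(s, fx$basis, method = meth, rescale = TRUE)
      e2 <- deconvolve_sample(s, fx$basis, method = meth, rescale = FALSE)
      cors <- c(cors, cor(as.numeric(e1[proportion_cols(e1)]),
                          as.numeric(e2[proportion_cols(e2)])))
    }
  }
  expect_gt(min(cors), 0.95)
})

test_that("methods agree with each other on noisy mixtures from a fixed basis", {
  fx <- solver_fixture(10)
  noise_sd <- 0.05 * mean(fx$M)
  vals <- vapply(1:10, function(i) {
    pmax(as.numeric(fx$M %*% fx$simplex()) + rnorm(nrow(fx$M), 0, noise_sd), 0)
  }, numeric(nrow(fx$M)))
  dimnames(vals) <- list(rownames(fx$M), paste0("m", 1:10))
  res <- deconvolve_dataset(toy_expr(vals), fx$basis,
                            methods = c("linear", "qp", "robust", "svr"),
                            qn = FALSE, rescale = FALSE)
  long <- tidy(res)
  wide <- tidyr::pivot_wider(long[c("sample_id", "method", "cell_type", "proportion")],
                             names_from = "method", values_from = "proportion")
  pairs <- utils::combn(c("linear", "qp", "robust", "svr"), 2)
  cors <- apply(pairs, 2, function(pr) cor(wide[[pr[1]]], wide[[pr[2]]]))
  expect_gt(median(cors), 0.9)
})
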