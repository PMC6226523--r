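#' Align a mixture profile with a basis matrix and rescale
#'
#' Restricts the mixture vector and basis to their shared genes and, when
#' `rescale = TRUE`, z-scores the mixture vector by its own mean/SD and the
#' basis matrix by its matrix-wide mean/SD (global, not per column, so
#' between-cell-type contrasts are preserved). Dataset-level quantile
#' normalization is a separate, earlier step ([deconvolve_dataset()] applies
#' it once before the per-sample loop).
#'
#' @param sample Named numeric vector of linear-scale expression (names =
#'   gene ids).
#' @param basis A `basis_matrix`.
#' @param rescale Apply the z-scoring contract (default TRUE).
#' @return List with `s` (aligned, optionally scaled vector), `M` (aligned,
#'   optionally scaled matrix) and `n_genes_used`.
#' @export
align_and_scale <- function(sample, basis, rescale = TRUE) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (is.null(names(sample))) stop_bd("`sample` must be a named vector (gene ids)")
  shared <- intersect(rownames(basis$values), names(sample))
  if (length(shared) < 2) stop_bd("fewer than 2 basis genes found in the sample")
  s <- as.numeric(sample[shared])
  M <- basis$values[shared, , drop = FALSE]
  if (rescale) {
    if (sd(s) == 0) stop_bd("zero-variance sample vector over the basis genes")
    s <- (s - mean(s)) / sd(s)
    M <- (M - mean(M)) / sd(as.numeric(M))
  }
  list(s = s, M = M, n_genes_used = length(shared))
}

# Shared post-processing: clip negative coefficients, renormalize to the
# simplex.
clip_renormalize <- function(p) {
  p <- pmax(p, 0)
  if (sum(p) <= 0) stop_bd("all coefficients non-positive after clipping")
  p / sum(p)
}

#' Ordinary least-squares deconvolution
#'
#' Unconstrained OLS fit of `s ~ M` (no intercept), then negative
#' coefficients clipped to zero and the rest renormalized to sum to one.
#'
#' @param s,M Aligned inputs from [align_and_scale()].
#' @return Named proportion vector on the simplex.
#' @export
solve_linear <- function(s, M) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop_bd("basis matrix is rank deficient; collinear cell type(s): %s",
            paste(bad, collapse = ", "))
  }
  stats::setNames(clip_renormalize(qr.coef(qrM, s)), colnames(M))
}

# Fast active-set non-negative least squares on the normal equations
# (Bro & de Jong 1997): argmin ||b - A x||^2 s.t. x >= 0, taking C = A'A and
# d = A'b. Cost per iteration depends only on ncol(A).
fnnls <- function(C, d, tol = NULL) {
  n <- length(d)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * norm(C, "1") * n
  P <- logical(n)
  x <- numeric(n)
  w <- d - C %*% x
  outer_iter <- 0L
  while (any(!P) && any(w[!P] > tol)) {
    outer_iter <- outer_iter + 1L
    if (outer_iter > 30L * n) stop_bd("NNLS active-set iteration limit reached")
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s_try <- numeric(n)
      s_try[P] <- solve(C[P, P, drop = FALSE], d[P])
      if (all(s_try[P] > tol)) break
      idx <- P & s_try <= tol
      alpha <- min(x[idx] / (x[idx] - s_try[idx]))
      x <- x + alpha * (s_try - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s_try
    w <- d - C %*% x
  }
  pmax(x, 0)
}

#' Simplex-constrained quadratic-programming deconvolution
#'
#' Minimizes `||s - M p||^2` subject to `p >= 0` and `sum(p) = 1`. Solved as
#' fully-constrained non-negative least squares: the sum-to-one constraint
#' enters as a heavily weighted augmentation row, the non-negativity through
#' a fast active-set solver on the normal equations, and the (numerically
#' exact) solution is renormalized onto the simplex.
#'
#' @param s,M Aligned inputs from [align_and_scale()].
#' @param sum_weight Weight of the sum-to-one augmentation row, relative to
#'   the data scale.
#' @return Named proportion vector on the simplex.
#' @export
solve_qp <- function(s, M, sum_weight = 1e3) {
  # p is invariant to a common rescaling of (s, M); work on O(1) data so the
  # squared augmentation weight does not swamp the normal equations
  sc <- sqrt(mean(M^2))
  if (sc == 0) stop_bd("QP solver got an all-zero basis")
  Ms <- M / sc
  ss <- s / sc
  C <- crossprod(Ms) + sum_weight^2
  d <- as.numeric(crossprod(Ms, ss)) + sum_weight^2
  p <- tryCatch(fnnls(C, d), error = function(e) {
    # slower Lawson-Hanson on the augmented system as a safety net
    tryCatch(pracma::lsqnonneg(rbind(Ms, sum_weight), c(ss, sum_weight))$x,
             error = function(e2) stop_bd("QP solver failed: %s", conditionMessage(e2)))
  })
  if (!all(is.finite(p))) stop_bd("QP solver returned non-finite coefficients")
  # the penalty solve identifies the active set; refine to the exact
  # equality-constrained KKT solution on that support
  sup <- which(p > 1e-10)
  if (length(sup) > 0) {
    Msup <- Ms[, sup, drop = FALSE]
    k <- length(sup)
    kkt <- rbind(cbind(2 * crossprod(Msup), 1), c(rep(1, k), 0))
    rhs <- c(2 * as.numeric(crossprod(Msup, ss)), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (!is.null(sol) && all(sol[seq_len(k)] > -1e-10)) {
      p <- numeric(ncol(M))
      p[sup] <- sol[seq_len(k)]
    }
  }
  stats::setNames(clip_renormalize(p), colnames(M))
}

#' Robust (Huber M-estimator) deconvolution
#'
#' Iteratively reweighted least squares with the Huber psi function (tuning
#' constant 1.345): residuals beyond `k` scale estimates (MAD) are
#' downweighted, the weighted least-squares fit is re-solved, and iteration
#' stops when no coefficient moves by more than 1e-6 (relative to the
#' coefficient scale). Convergence is linear and slow on strongly collinear
#' bases, so the default iteration cap is a generous 500 (each iteration is a small weighted solve). Negative
#' coefficients are
#' clipped and the vector renormalized. [MASS::rlm()] with the same psi is
#' the independent cross-check in the test suite.
#'
#' @param s,M Aligned inputs from [align_and_scale()].
#' @param k Huber tuning constant.
#' @param maxit Iteration cap.
#' @param tol Coefficient-change tolerance.
#' @return Named proportion vector on the simplex.
#' @export
solve_robust <- function(s, M, k = 1.345, maxit = 500, tol = 1e-6) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) stop_bd("basis matrix is rank deficient")
  beta <- qr.coef(qrM, s)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- s - as.numeric(M %*% beta)
    sigma <- stats::median(abs(r)) / 0.6745
    if (sigma < 1e-10 * (sd(s) + 1e-300)) { converged <- TRUE; break } # exact fit
    w <- pmin(1, k / (abs(r) / sigma))
    wM <- M * w
    beta_new <- tryCatch(solve(crossprod(wM, M), crossprod(wM, s))[, 1],
                         error = function(e) stop_bd("robust regression failed: %s",
                                                     conditionMessage(e)))
    step <- max(abs(beta_new - beta)) / max(max(abs(beta_new)), 1e-10)
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) stop_bd("robust regression (IRLS) did not converge in %d iterations", maxit)
  stats::setNames(clip_renormalize(unname(beta)), colnames(M))
}

#' Linear-kernel nu-SVR deconvolution
#'
#' Fits a linear-kernel nu-support-vector regression of the mixture on the
#' basis for `nu` in \{0.25, 0.5, 0.75\} (C = 1, tolerance 1e-4) and keeps the
#' fit whose raw coefficient vector minimizes the root-mean-square error
#' between `s` and `M %*% p_hat`; negatives are then clipped and the vector
#' renormalized. SVR requires standardized inputs, so this solver always
#' applies the z-scoring contract internally (a no-op on already-scaled
#' inputs).
#'
#' @param s,M Aligned inputs from [align_and_scale()].
#' @param nu_grid Candidate nu values.
#' @return Named proportion vector on the simplex, with the selected `nu`
#'   attached as attribute `"nu"`.
#' @export
solve_svr <- function(s, M, nu_grid = c(0.25, 0.5, 0.75)) {
  # idempotent standardization: SVR is scale-sensitive
  if (sd(s) == 0) stop_bd("zero-variance sample vector")
  s <- (s - mean(s)) / sd(s)
  M <- (M - mean(M)) / sd(as.numeric(M))
  fits <- lapply(nu_grid, function(nu) {
    tryCatch(
      e1071::svm(x = M, y = s, type = "nu-regression", kernel = "linear",
                 nu = nu, cost = 1, tolerance = 1e-4, scale = FALSE),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop_bd("all nu-SVR fits failed")
  coefs <- lapply(fits[ok], function(f) as.numeric(t(f$coefs) %*% f$SV))
  rmse <- vapply(coefs, function(w) sqrt(mean((s - M %*% w)^2)), 0.0)
  best <- which.min(rmse)
  p <- stats::setNames(clip_renormalize(coefs[[best]]), colnames(M))
  attr(p, "nu") <- nu_grid[ok][best]
  p
}

deconv_methods <- c("linear", "qp", "robust", "svr")

solver_for <- function(method) {
  switch(method,
         linear = solve_linear, qp = solve_qp, robust = solve_robust, svr = solve_svr,
         stop_bd("unknown method '%s' (available: %s)", method,
                 paste(deconv_methods, collapse = ", ")))
}

#' Deconvolve one mixture sample
#'
#' Aligns the sample with the basis, dispatches the requested solver, and
#' reports the estimated proportions with their goodness of fit: the Pearson
#' correlation between the (scaled) mixture vector `s` and its reconstitution
#' `M %*% p`. Optionally attaches a permutation p-value for the goodness of
#' fit (see [gof_significance()]); this requires the sample's full gene
#' universe, so pass `full_profile` when the named vector `sample` has
#' already been restricted.
#'
#' @param sample Named numeric expression vector.
#' @param basis A `basis_matrix`.
#' @param method One of `"linear"`, `"qp"`, `"robust"`, `"svr"`.
#' @param rescale Apply the z-scoring contract (default TRUE).
#' @param with_pvalue Attach a permutation p-value?
#' @param n_perm Number of permutations for the p-value.
#' @param seed Seed for the permutation p-value.
#' @param sample_id Identifier recorded in the result.
#' @param full_profile Full gene universe for the permutation null (default:
#'   `sample` itself).
#' @return One-row tibble of class `deconv_tbl`: `sample_id`, `method`,
#'   `basis_id`, one proportion column per basis cell type, `gof`, `pvalue`,
#'   `n_genes_used`.
#' @export
deconvolve_sample <- function(sample, basis, method = "qp", rescale = TRUE,
                              with_pvalue = FALSE, n_perm = 100, seed = NULL,
                              sample_id = "sample", full_profile = NULL) {
  if (!method %in% deconv_methods) {
    stop_bd("unknown method '%s' (available: %s)", method,
            paste(deconv_methods, collapse = ", "))
  }
  al <- align_and_scale(sample, basis, rescale = rescale)
  p <- withCallingHandlers(
    solver_for(method)(al$s, al$M),
    error = function(e) stop_bd("sample '%s': %s", sample_id, conditionMessage(e))
  )
  gof <- safe_cor(al$s, as.numeric(al$M %*% p))
  pval <- NA_real_
  if (with_pvalue) {
    pval <- gof_significance(sample = full_profile %||% sample, basis = basis,
                             method = method, n_perm = n_perm, seed = seed,
                             rescale = rescale)
  }
  row <- tibble::tibble(sample_id = sample_id, method = method, basis_id = basis$name)
  for (ct in names(p)) row[[ct]] <- unname(p[ct])
  row$gof <- gof
  row$pvalue <- pval
  row$n_genes_used <- al$n_genes_used
  class(row) <- c("deconv_tbl", class(row))
  row
}

#' Deconvolve every sample of a dataset with one or more methods
#'
#' Applies dataset-level quantile normalization once (when `qn = TRUE`), then
#' runs [deconvolve_sample()] for every (sample, method) pair. Per-sample
#' failures are recorded, not fatal: they are collected in the `"failures"`
#' attribute of the result.
#'
#' @param m An `expr_matrix` of mixture samples.
#' @param basis A `basis_matrix`.
#' @param methods Character vector of solver names.
#' @param qn Quantile-normalize the mixture dataset first (default TRUE).
#' @param rescale Apply the z-scoring contract per sample (default TRUE).
#' @param with_pvalue,n_perm,seed Permutation p-value controls.
#' @return A `deconv_tbl` tibble, one row per successful (sample, method)
#'   pair, with a `failures` tibble (sample_id, method, message) attached as
#'   an attribute.
#' @export
deconvolve_dataset <- function(m, basis, methods = c("linear", "qp", "robust", "svr"),
                               qn = TRUE, rescale = TRUE, with_pvalue = FALSE,
                               n_perm = 100, seed = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(methods) == 0) stop_bd("empty method list")
  bad <- setdiff(methods, deconv_methods)
  if (length(bad) > 0) stop_bd("unknown method '%s' (available: %s)",
                               bad[1], paste(deconv_methods, collapse = ", "))
  if (qn && ncol(m$values) >= 2) m <- quantile_normalize(m)
  rows <- list()
  fails <- list()
  for (j in seq_len(ncol(m$values))) {
    sid <- colnames(m$values)[j]
    prof <- m$values[, j]
    for (meth in methods) {
      res <- tryCatch(
        deconvolve_sample(prof, basis, method = meth, rescale = rescale,
                          with_pvalue = with_pvalue, n_perm = n_perm,
                          seed = child_seed(seed, j * 131 + match(meth, deconv_methods)),
                          sample_id = sid),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- tibble::tibble(
          sample_id = sid, method = meth, message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("deconv_tbl", class(out))
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}

#' Proportion columns of a deconvolution table
#'
#' @param x A `deconv_tbl`.
#' @return Character vector of cell-type column names.
#' @export
proportion_cols <- function(x) {
  setdiff(names(x), c("sample_id", "method", "basis_id", "gof", "pvalue", "n_genes_used"))
}

#' Tidy a deconvolution result table to long format
#'
#' @param x A `deconv_tbl`.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `method`, `basis_id`, `cell_type`,
#'   `proportion`, `gof`, `pvalue`, `n_genes_used`.
#' @export
tidy.deconv_tbl <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::all_of(proportion_cols(x)),
                      names_to = "cell_type", values_to = "proportion")
}

#' One-row-per-method summary of a deconvolution table
#'
#' @param x A `deconv_tbl`.
#' @param ... Unused.
#' @return Tibble per (method, basis_id): sample count, median and IQR of the
#'   goodness of fit.
#' @export
glance.deconv_tbl <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method, .data$basis_id),
    n_samples = dplyr::n(),
    median_gof = stats::median(.data$gof),
    iqr_gof = stats::IQR(.data$gof),
    .groups = "drop"
  )
}
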