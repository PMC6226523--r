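#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats cor sd median quantile rnorm rlnorm rgamma pchisq pnorm
#' @importFrom utils head
NULL

# Run `code` under a fixed RNG seed when one is given, otherwise use the
# ambient RNG state.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483587L)
}

stop_bd <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "basisdeconv_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_bd("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

# Pearson correlation that tolerates zero-variance input by returning NA
# (with no warning noise) instead of erroring.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
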