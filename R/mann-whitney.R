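# One-sided Mann-Whitney U machinery.
#
# Exact enumeration (all choose(n1+n2, n1) group assignments of the pooled
# midranks) is used for pooled samples of at most `exact_limit`
# observations; the mid-p convention [P(U < u) + 0.5 P(U = u)] makes the
# test well defined under heavy ties (a single tied pair gives p = 0.5).
# Larger samples use the normal approximation with the tie-corrected
# variance, without continuity correction (which matches mid-p asymptotics).

mw_u_statistic <- function(x, y) {
  r <- rank(c(x, y))            # midranks
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_exact_p_less <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_along(x)]) - n1 * (n1 + 1) / 2
  sel <- combn(N, n1)
  u_all <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(u_all < u_obs - 1e-9) + 0.5 * mean(abs(u_all - u_obs) < 1e-9)
}

mw_normal_p_less <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(0.5)  # fully tied pool
  pnorm((u - n1 * n2 / 2) / sqrt(sigma2))
}

#' One-sided Mann-Whitney U test of observed vs null variability
#'
#' Tests whether the observed per-community variabilities are
#' stochastically smaller than a null distribution (e.g. the Dirichlet
#' random-community null): alternative "observed < null". Uses exact
#' enumeration with the mid-p midrank convention for pooled samples of at
#' most `exact_limit` values, and the tie-corrected normal approximation
#' otherwise.
#'
#' @param observed Numeric vector of observed values (non-empty).
#' @param null Numeric vector of null values (non-empty).
#' @param exact_limit Maximum pooled sample size for exact enumeration.
#' @return An object of class `evo_mw_test` with elements `statistic` (the
#'   U statistic of the observed sample), `p_value`, `method`,
#'   `n_observed`, `n_null`; supports [tidy()] and [glance()].
#' @examples
#' variability_vs_null_test(c(0.01, 0.02), c(0.2, 0.3, 0.4))
#' @export
variability_vs_null_test <- function(observed, null, exact_limit = 20) {
  if (length(observed) == 0 || length(null) == 0) {
    abort("`observed` and `null` must be non-empty")
  }
  exact <- length(observed) + length(null) <= exact_limit
  p <- if (exact) mw_exact_p_less(observed, null)
       else mw_normal_p_less(observed, null)
  structure(
    list(
      statistic = mw_u_statistic(observed, null),
      p_value = p,
      method = if (exact) "exact (mid-p)" else "normal approximation",
      alternative = "observed < null",
      n_observed = length(observed),
      n_null = length(null)
    ),
    class = "evo_mw_test"
  )
}

#' @export
print.evo_mw_test <- function(x, ...) {
  cat("One-sided Mann-Whitney U test (", x$alternative, ")\n", sep = "")
  cat(sprintf("  U = %g, p = %.4g  [%s; n = %d vs %d]\n", x$statistic,
              x$p_value, x$method, x$n_observed, x$n_null))
  invisible(x)
}

#' @rdname variability_vs_null_test
#' @param x An `evo_mw_test` object.
#' @param ... Unused.
#' @method tidy evo_mw_test
#' @export
tidy.evo_mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method, alternative = x$alternative)
}

#' @rdname variability_vs_null_test
#' @method glance evo_mw_test
#' @export
glance.evo_mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n.observed = x$n_observed, n.null = x$n_null)
}
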