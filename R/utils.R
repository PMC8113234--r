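# Internal helpers shared across modules.

# Draw n vectors from a uniform Dirichlet(1, ..., 1) over the k-simplex,
# via normalized Exponential(1) (= Gamma(1, 1)) variates. Rows sum to 1.
rdirichlet_unif <- function(n, k) {
  g <- matrix(rexp(n * k), nrow = n, ncol = k)
  g / rowSums(g)
}

# Fraction vectors must live on the simplex within tolerance.
check_simplex <- function(x, tol = 1e-6, arg = "x") {
  if (any(x < -tol) || abs(sum(x) - 1) > tol) {
    abort(sprintf("`%s` must be a fraction vector summing to 1 (got sum %.6g)",
                  arg, sum(x)))
  }
  invisible(x)
}

# Euclidean distance between two fraction vectors.
euclid <- function(x, y) sqrt(sum((x - y)^2))

# Canonical pair/trio key from species labels (sorted, "|"-separated).
species_key <- function(...) {
  paste(sort(c(...)), collapse = "|")
}

# Deterministic per-iteration seeds derived from one master seed, so that
# iteration k of a resampling scheme is reproducible in isolation.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Spread a composition table to one row per (community, replicate, transfer)
# with a list-column of fractions in fixed species order.
composition_wide <- function(data) {
  data |>
    dplyr::arrange(.data$community, .data$replicate, .data$transfer,
                   .data$species) |>
    dplyr::summarise(
      species = list(.data$species),
      fraction = list(.data$fraction),
      .by = c("community", "replicate", "transfer")
    )
}

# Number of species per community (asserting a fixed roster across samples).
community_sizes <- function(data) {
  data |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     .by = "community")
}
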