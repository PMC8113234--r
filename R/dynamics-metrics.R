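#' Normalized Euclidean distance between two community compositions
#'
#' Euclidean distance between two fraction vectors divided by `sqrt(n)`,
#' where `n` is the number of species — the convention used throughout the
#' figures of serial-dilution coevolution studies, where `sqrt(n)` is taken
#' as the maximal distance between two n-species communities. Note the true
#' maximal distance between two points of the simplex is `sqrt(2)` for any
#' `n >= 2`; set `normalization = "true_max"` for that alternative.
#'
#' @param x,y Fraction vectors of equal length, each summing to 1.
#' @param normalization `"sqrt_n"` (default) or `"true_max"` (`sqrt(2)`).
#' @return A distance in `[0, 1]`.
#' @examples
#' normalized_distance(c(0.8, 0.2), c(0.5, 0.5))  # 0.3
#' @export
normalized_distance <- function(x, y,
                                normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length")
  }
  check_simplex(x, arg = "x")
  check_simplex(y, arg = "y")
  denom <- if (normalization == "sqrt_n") sqrt(length(x)) else sqrt(2)
  euclid(x, y) / denom
}

# delta between consecutive rows of a wide composition block (one replicate)
.block_deltas <- function(frac_list, normalization) {
  n_t <- length(frac_list)
  if (n_t < 2) return(numeric(0))
  vapply(seq_len(n_t - 1), function(i) {
    normalized_distance(frac_list[[i + 1]], frac_list[[i]],
                        normalization = normalization)
  }, numeric(1))
}

#' Step-to-step compositional change of every replicate
#'
#' For each replicate, the normalized Euclidean distance between its
#' composition at consecutive sampled transfers, `Delta(t, t-1)`. Rapidly
#' assembling communities show large early steps that decay once the
#' ecological equilibrium is reached; later, slower steps reflect
#' evolutionary change.
#'
#' @param data A composition tibble.
#' @param map A [generation_map()] used to annotate generations.
#' @param normalization Passed to [normalized_distance()].
#' @return A tibble with columns `community`, `replicate`, `transfer`,
#'   `generation` and `delta`, one row per consecutive transfer pair
#'   (labelled by the later transfer). Replicates observed at a single
#'   transfer contribute no rows and are listed in attribute `skipped`.
#' @export
stepwise_change <- function(data, map = generation_map(),
                            normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  wide <- composition_wide(data)
  skipped <- wide |>
    dplyr::count(.data$community, .data$replicate) |>
    dplyr::filter(.data$n < 2)
  if (nrow(skipped) > 0) {
    warn(sprintf("%d replicate(s) with a single timepoint give an empty change profile",
                 nrow(skipped)))
  }
  out <- wide |>
    dplyr::group_by(.data$community, .data$replicate) |>
    dplyr::arrange(.data$transfer, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) {
        return(tibble::tibble(transfer = integer(), delta = numeric()))
      }
      tibble::tibble(
        transfer = g$transfer[-1],
        delta = .block_deltas(g$fraction, normalization)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(generation = transfer_generation(.data$transfer, map),
                  .before = "delta")
  attr(out, "skipped") <- skipped
  out
}

#' Compositional change relative to a reference generation
#'
#' For each replicate, the normalized distance between its composition at
#' every sampled transfer at or after a reference generation and its own
#' composition at that reference — e.g. the drift away from the ecological
#' equilibrium reached by generation ~70.
#'
#' @inheritParams stepwise_change
#' @param g_ref Reference generation (resolved by [nearest_transfer()]).
#' @return A tibble `community`, `replicate`, `transfer`, `generation`,
#'   `delta`, for all sampled transfers at generations >= the reference.
#'   Replicates missing the reference sample are skipped (attribute
#'   `skipped`).
#' @export
change_from_reference <- function(data, g_ref = 70, map = generation_map(),
                                  normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  ref_transfer <- nearest_transfer(g_ref, map)
  wide <- composition_wide(data)
  has_ref <- wide |>
    dplyr::filter(.data$transfer == ref_transfer) |>
    dplyr::select("community", "replicate", ref_fraction = "fraction")
  skipped <- wide |>
    dplyr::distinct(.data$community, .data$replicate) |>
    dplyr::anti_join(has_ref, by = c("community", "replicate"))
  if (nrow(skipped) > 0) {
    warn(sprintf("%d replicate(s) missing the reference transfer were skipped",
                 nrow(skipped)))
  }
  out <- wide |>
    dplyr::filter(.data$transfer >= ref_transfer) |>
    dplyr::inner_join(has_ref, by = c("community", "replicate")) |>
    dplyr::mutate(
      delta = purrr::map2_dbl(.data$fraction, .data$ref_fraction,
                              normalized_distance,
                              normalization = normalization),
      generation = transfer_generation(.data$transfer, map)
    ) |>
    dplyr::select("community", "replicate", "transfer", "generation",
                  "delta") |>
    dplyr::arrange(.data$community, .data$replicate, .data$transfer)
  attr(out, "skipped") <- skipped
  attr(out, "reference_transfer") <- ref_transfer
  out
}

# medoid index of a matrix of compositions (rows = replicates); ties by
# the caller-supplied order (rows should be sorted by replicate id).
medoid_index <- function(m) {
  d <- as.matrix(stats::dist(m))
  which.min(rowSums(d))
}

#' Medoid replicate of a set of replicate compositions
#'
#' The replicate whose summed Euclidean distance to all other replicates is
#' minimal; ties resolve to the lexicographically first replicate id.
#'
#' @param data A tibble with columns `replicate`, `species`, `fraction` —
#'   the compositions of the replicates of one community at one transfer.
#' @return The medoid replicate id (character scalar).
#' @export
medoid_replicate <- function(data) {
  m <- data |>
    tidyr::pivot_wider(id_cols = "replicate", names_from = "species",
                       values_from = "fraction") |>
    dplyr::arrange(.data$replicate)
  ids <- m$replicate
  ids[medoid_index(as.matrix(m[-1]))]
}

# variability from a plain matrix of compositions (rows = replicates),
# shared by the tidy front-end and the Dirichlet null.
.variability_matrix <- function(m, include_medoid = TRUE,
                                normalization = "sqrt_n") {
  k <- nrow(m)
  if (k < 2) abort("replicate variability needs >= 2 replicates")
  denom <- if (normalization == "sqrt_n") sqrt(ncol(m)) else sqrt(2)
  med <- medoid_index(m)
  d <- sqrt(colSums((t(m) - m[med, ])^2)) / denom
  if (include_medoid) mean(d) else mean(d[-med])
}

#' Replicate-to-replicate variability of one community
#'
#' The mean normalized Euclidean distance of each replicate from the medoid
#' replicate. Zero iff all replicates have identical composition. By default
#' the medoid's own zero distance is included in the mean (a mean over all
#' replicates); set `include_medoid = FALSE` to average only over the
#' non-medoid replicates.
#'
#' @inheritParams medoid_replicate
#' @param include_medoid Include the medoid's zero term in the mean?
#' @param normalization Passed to [normalized_distance()].
#' @return A one-row tibble with columns `medoid`, `n_replicates` and
#'   `variability`.
#' @export
replicate_variability <- function(data, include_medoid = TRUE,
                                  normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  m <- data |>
    tidyr::pivot_wider(id_cols = "replicate", names_from = "species",
                       values_from = "fraction") |>
    dplyr::arrange(.data$replicate)
  mat <- as.matrix(m[-1])
  tibble::tibble(
    medoid = m$replicate[medoid_index(mat)],
    n_replicates = nrow(mat),
    variability = .variability_matrix(mat, include_medoid, normalization)
  )
}

#' Variability of every community at the sampled transfers
#'
#' Applies [replicate_variability()] to each (community, transfer) group
#' with at least two replicates.
#'
#' @param data A composition tibble.
#' @param map A [generation_map()].
#' @inheritParams replicate_variability
#' @return A tibble `community`, `n_species`, `transfer`, `generation`,
#'   `medoid`, `n_replicates`, `variability`.
#' @export
variability_profile <- function(data, map = generation_map(),
                                include_medoid = TRUE,
                                normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  sizes <- community_sizes(data)
  data |>
    dplyr::group_by(.data$community, .data$transfer) |>
    dplyr::group_modify(function(g, key) {
      if (dplyr::n_distinct(g$replicate) < 2) {
        return(tibble::tibble(medoid = character(),
                              n_replicates = integer(),
                              variability = numeric()))
      }
      replicate_variability(g, include_medoid = include_medoid,
                            normalization = normalization)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(generation = transfer_generation(.data$transfer, map),
                  .after = "transfer") |>
    dplyr::left_join(sizes, by = "community") |>
    dplyr::relocate("n_species", .after = "community")
}

#' Replicate variability expected of random communities
#'
#' Monte-Carlo distribution of [replicate_variability()] when every
#' replicate composition is drawn independently from the uniform Dirichlet
#' distribution (`alpha = 1`) on the n-species simplex — the null model of a
#' community whose species are equally likely to take any relative
#' abundance.
#'
#' @param n_species Number of species (>= 2).
#' @param n_replicates Replicates per simulated community (>= 2).
#' @param n_draws Number of simulated communities.
#' @param seed Integer seed; fixed seed gives a bit-identical distribution.
#' @inheritParams replicate_variability
#' @return A numeric vector of `n_draws` variability values.
#' @export
dirichlet_null_variability <- function(n_species, n_replicates,
                                       n_draws = 1000, seed = 1,
                                       include_medoid = TRUE,
                                       normalization = c("sqrt_n",
                                                         "true_max")) {
  normalization <- match.arg(normalization)
  if (n_replicates < 2) {
    abort("`n_replicates` must be >= 2 (variability is undefined otherwise)")
  }
  if (n_draws < 1) abort("`n_draws` must be >= 1")
  set.seed(seed)
  draws <- rdirichlet_unif(n_draws * n_replicates, n_species)
  vapply(seq_len(n_draws), function(i) {
    rows <- ((i - 1) * n_replicates + 1):(i * n_replicates)
    .variability_matrix(draws[rows, , drop = FALSE], include_medoid,
                        normalization)
  }, numeric(1))
}
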