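#' Fold change in relative abundance between two generation anchors
#'
#' For every (community, replicate, species) present at both anchors, the
#' ratio of its relative abundance at the later anchor to the earlier one —
#' the "factor of change" used to identify each replicate's maximally
#' increasing member. Zero fractions are floored before division: by the
#' plating pseudo-fraction `1 / (total colonies + 1)` when colony counts are
#' available, and by `floor` otherwise, so all fold changes are finite and
#' positive.
#'
#' @param data A composition tibble.
#' @param g1,g2 Generation anchors (defaults 70 and 400), resolved by
#'   [nearest_transfer()].
#' @param floor Pseudo-fraction used for zero fractions when no counts are
#'   available.
#' @param map A [generation_map()].
#' @return A tibble `community`, `replicate`, `species`, `fraction_g1`,
#'   `fraction_g2`, `fold`. Replicates missing either anchor are excluded
#'   and listed in attribute `excluded`.
#' @export
fold_changes <- function(data, g1 = 70, g2 = 400, floor = 1e-3,
                         map = generation_map()) {
  if (g1 >= g2) abort("`g1` must be earlier than `g2`")
  floor_sample <- function(anchor) {
    anchor |>
      dplyr::mutate(
        total = sum(.data$count),
        fraction = dplyr::case_when(
          .data$fraction > 0 ~ .data$fraction,
          !is.na(.data$total) ~ 1 / (.data$total + 1),
          TRUE ~ .env$floor
        ),
        .by = c("community", "replicate", "transfer")
      ) |>
      dplyr::select("community", "replicate", "species", "fraction")
  }
  a1 <- floor_sample(composition_at_generation(data, g1, map))
  a2 <- floor_sample(composition_at_generation(data, g2, map))
  out <- dplyr::inner_join(a1, a2,
                           by = c("community", "replicate", "species"),
                           suffix = c("_g1", "_g2")) |>
    dplyr::mutate(fold = .data$fraction_g2 / .data$fraction_g1) |>
    dplyr::arrange(.data$community, .data$replicate, .data$species)

  all_reps <- dplyr::distinct(data, .data$community, .data$replicate)
  excluded <- dplyr::anti_join(
    all_reps, dplyr::distinct(out, .data$community, .data$replicate),
    by = c("community", "replicate"))
  if (nrow(excluded) > 0) {
    warn(sprintf("%d replicate(s) missing generation ~%g or ~%g excluded from fold changes",
                 nrow(excluded), g1, g2))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Maximally increasing member of one replicate
#'
#' @param folds Named numeric vector of per-species fold changes (>= 2
#'   species, finite values).
#' @return A one-row tibble with `species` (the argmax; exact ties resolve
#'   to the first species in label order) and `tie` (logical flag).
#' @export
max_increaser <- function(folds) {
  if (length(folds) < 2 || is.null(names(folds))) {
    abort("`folds` must be a named vector of >= 2 fold changes")
  }
  if (any(!is.finite(folds))) abort("fold changes must be finite")
  o <- order(names(folds))
  folds <- folds[o]
  top <- max(folds)
  hits <- which(folds >= top - 1e-12)
  tibble::tibble(species = names(folds)[hits[1]], tie = length(hits) > 1)
}

#' Maximally increasing member of every replicate
#'
#' @param fold_data A fold-change tibble from [fold_changes()].
#' @return A tibble `community`, `replicate`, `species` (the winner), `tie`.
#' @export
max_increasers <- function(fold_data) {
  fold_data |>
    dplyr::group_by(.data$community, .data$replicate) |>
    dplyr::group_modify(function(g, key) {
      max_increaser(setNames(g$fold, g$species))
    }) |>
    dplyr::ungroup()
}

#' Repeatability score of each community
#'
#' The frequency of replicates sharing the community's modal maximally
#' increasing member — between `1/n` (every species wins equally often) and
#' 1 (the same species wins in every replicate). Communities with fewer
#' than `min_replicates` replicates present at both anchors are excluded
#' (attribute `excluded`).
#'
#' @inheritParams max_increasers
#' @param min_replicates Minimum replicates required per community
#'   (default 3).
#' @return A tibble `community`, `n_species`, `n_replicates`, `winner` (the
#'   modal max-increaser), `score`.
#' @export
repeatability_score <- function(fold_data, min_replicates = 3) {
  winners <- max_increasers(fold_data)
  sizes <- fold_data |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     .by = "community")
  scores <- winners |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      winner = names(sort(table(.data$species), decreasing = TRUE))[1],
      score = max(table(.data$species)) / dplyr::n(),
      .by = "community"
    ) |>
    dplyr::left_join(sizes, by = "community") |>
    dplyr::relocate("n_species", .after = "community")
  excluded <- scores |>
    dplyr::filter(.data$n_replicates < min_replicates) |>
    dplyr::transmute(.data$community,
                     reason = sprintf("only %d replicate(s) at both anchors",
                                      .data$n_replicates))
  out <- scores |>
    dplyr::filter(.data$n_replicates >= min_replicates)
  attr(out, "excluded") <- excluded
  out
}

# fold table -> matrix (rows = replicates across communities, cols =
# species in label order per community) + community index per row
.fold_matrix <- function(fold_data) {
  n <- dplyr::n_distinct(fold_data$species[fold_data$community ==
                                             fold_data$community[1]])
  sizes <- fold_data |>
    dplyr::summarise(k = dplyr::n_distinct(.data$species),
                     .by = "community")
  if (any(sizes$k != n)) {
    abort("all communities must have the same number of species (one size class)")
  }
  fd <- fold_data |>
    dplyr::arrange(.data$community, .data$replicate, .data$species)
  m <- matrix(fd$fold, ncol = n, byrow = TRUE)
  rows <- fd |>
    dplyr::distinct(.data$community, .data$replicate)
  list(values = m, community = match(rows$community,
                                     unique(rows$community)),
       communities = unique(rows$community), n_species = n)
}

# mean repeatability score given a fold matrix and community index
.mean_score <- function(values, comm, n_species, n_comm, reps_per_comm) {
  w <- max.col(values, ties.method = "first")
  counts <- tabulate((comm - 1L) * n_species + w, nbins = n_comm * n_species)
  top <- do.call(pmax, lapply(seq_len(n_species), function(s) {
    counts[seq(s, n_comm * n_species, by = n_species)]
  }))
  mean(top / reps_per_comm)
}

#' Permutation (shuffle) null for the mean repeatability score
#'
#' Tests the mean repeatability score of one size class (all pairs, or all
#' trios) against the null hypothesis that the factor by which a species'
#' abundance changes is independent of species and community. Each
#' iteration pools every (community, replicate, species) fold change of the
#' size class, permutes the pooled values uniformly at random without
#' replacement, reassigns them to the original slots, and recomputes the
#' across-community mean score. The p-value is the raw frequency of
#' iterations whose null mean is at least the observed mean (set
#' `plus_one = TRUE` for the (b+1)/(m+1) estimator, which cannot return 0).
#'
#' @inheritParams repeatability_score
#' @param iterations Number of shuffle iterations (default 2000).
#' @param seed Master seed; per-iteration streams are derived
#'   deterministically so iteration k is reproducible in isolation.
#' @param plus_one Use the (b+1)/(m+1) p-value estimator?
#' @param shuffle `"values"` (default) permutes individual fold-change
#'   values across all samples; `"vectors"` permutes whole per-replicate
#'   fold-change vectors intact across replicates.
#' @return An object of class `shuffle_null`: a list with `scores` (the
#'   observed per-community tibble), `observed_mean`, `null_means`,
#'   `p_value`, `iterations`, `seed`, `n_species`, `n_communities`.
#'   Supports [tidy()] and [glance()].
#' @export
shuffle_null <- function(fold_data, iterations = 2000, seed = 1,
                         min_replicates = 3, plus_one = FALSE,
                         shuffle = c("values", "vectors")) {
  shuffle <- match.arg(shuffle)
  scores <- repeatability_score(fold_data, min_replicates = min_replicates)
  if (nrow(scores) < 2) {
    abort("shuffle_null needs >= 2 communities after replicate filtering")
  }
  fold_data <- dplyr::semi_join(fold_data, scores, by = "community")
  fm <- .fold_matrix(fold_data)
  n_comm <- length(fm$communities)
  reps_per_comm <- tabulate(fm$community, nbins = n_comm)
  observed_mean <- mean(scores$score)

  pool <- as.vector(fm$values)
  n_rows <- nrow(fm$values)
  n_sp <- fm$n_species
  slot <- (fm$community - 1L) * n_sp
  species_idx <- lapply(seq_len(n_sp), function(s) {
    seq(s, n_comm * n_sp, by = n_sp)
  })
  iter_seeds <- derive_seeds(seed, iterations)
  null_means <- vapply(seq_len(iterations), function(k) {
    set.seed(iter_seeds[k])
    vals <- if (shuffle == "values") {
      matrix(pool[sample.int(length(pool))], ncol = n_sp)
    } else {
      fm$values[sample.int(n_rows), , drop = FALSE]
    }
    w <- max.col(vals, ties.method = "first")
    counts <- tabulate(slot + w, nbins = n_comm * n_sp)
    top <- do.call(pmax, lapply(species_idx, function(ix) counts[ix]))
    mean(top / reps_per_comm)
  }, numeric(1))

  b <- sum(null_means >= observed_mean - 1e-12)
  p <- if (plus_one) (b + 1) / (iterations + 1) else b / iterations
  structure(
    list(
      scores = scores,
      observed_mean = observed_mean,
      null_means = null_means,
      p_value = p,
      iterations = iterations,
      seed = seed,
      shuffle = shuffle,
      n_species = fm$n_species,
      n_communities = n_comm
    ),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "<shuffle_null> %d-species class: %d communities, observed mean score %.3f\n",
    x$n_species, x$n_communities, x$observed_mean))
  cat(sprintf("  null mean %.3f (%d iterations), p = %.4g\n",
              mean(x$null_means), x$iterations, x$p_value))
  invisible(x)
}

#' @rdname shuffle_null
#' @param x A `shuffle_null` object.
#' @param ... Unused.
#' @method tidy shuffle_null
#' @export
tidy.shuffle_null <- function(x, ...) x$scores

#' @rdname shuffle_null
#' @method glance shuffle_null
#' @export
glance.shuffle_null <- function(x, ...) {
  tibble::tibble(
    n_species = x$n_species,
    n_communities = x$n_communities,
    observed_mean = x$observed_mean,
    null_mean = mean(x$null_means),
    p.value = x$p_value,
    iterations = x$iterations,
    seed = x$seed
  )
}

#' Observed-vs-null summary across size classes
#'
#' Combines the shuffle-null results for pairs and trios into one summary
#' table with the significance tier convention used in the figures:
#' `"**"` for p < 0.005, `"*"` for p <= 0.05, empty otherwise.
#'
#' @param ... One or more `shuffle_null` objects (e.g. pairs and trios).
#' @return A tibble with one row per size class: `size_class`,
#'   `n_communities`, `observed_mean`, `null_mean`, `null_q25`, `null_q75`,
#'   `p_value`, `tier`.
#' @export
observed_vs_null_report <- function(...) {
  results <- list(...)
  purrr::map_dfr(results, function(x) {
    stopifnot(inherits(x, "shuffle_null"))
    q <- quantile(x$null_means, c(0.25, 0.75), names = FALSE)
    tibble::tibble(
      size_class = sprintf("%d-species", x$n_species),
      n_communities = x$n_communities,
      observed_mean = x$observed_mean,
      null_mean = mean(x$null_means),
      null_q25 = q[1],
      null_q75 = q[2],
      p_value = x$p_value,
      tier = dplyr::case_when(x$p_value < 0.005 ~ "**",
                              x$p_value <= 0.05 ~ "*",
                              TRUE ~ "")
    )
  })
}
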