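#' Replicate-averaged pairwise outcomes at a generation
#'
#' Summarizes every two-species community at the transfer nearest a target
#' generation: the mean fraction of each species across replicates, keyed
#' by the species and its competition partner.
#'
#' @param data A composition tibble; only two-species communities are used.
#' @param generation Target generation.
#' @param map A [generation_map()].
#' @return A tibble `pair` (canonical "A|B" key), `species`, `partner`,
#'   `generation` (actual), `fraction` (mean across replicates),
#'   `n_replicates`.
#' @export
pair_outcomes <- function(data, generation, map = generation_map()) {
  sizes <- community_sizes(data)
  pairs <- data |>
    dplyr::semi_join(dplyr::filter(sizes, .data$n_species == 2),
                     by = "community")
  if (nrow(pairs) == 0) abort("no two-species communities in `data`")
  at_g <- composition_at_generation(pairs, generation, map)
  at_g |>
    dplyr::summarise(
      fraction = mean(.data$fraction),
      n_replicates = dplyr::n(),
      .by = c("community", "species", "generation")
    ) |>
    dplyr::mutate(
      pair = purrr::map_chr(.data$community, function(co) {
        species_key(unique(at_g$species[at_g$community == co]))
      }),
      partner = purrr::map2_chr(.data$pair, .data$species, function(p, s) {
        setdiff(strsplit(p, "|", fixed = TRUE)[[1]], s)
      })
    ) |>
    dplyr::select("pair", "species", "partner", "generation", "fraction",
                  "n_replicates") |>
    dplyr::arrange(.data$pair, .data$species)
}

#' Predict a trio composition from its three pairwise outcomes
#'
#' The assembly rule: the fraction of each species in a three-species
#' community is predicted to be proportional to the weighted geometric mean
#' of its fractions in the two pairwise cocultures it takes part in,
#' normalized so the prediction sums to 1. With the default equal weights
#' this is `g_i = (f_i|ij * f_i|ik)^(1/2)`, `f_i = g_i / sum(g)`. Zero
#' pairwise fractions are floored by `floor` before the product so a species
#' excluded in pairs gets a small but positive predicted fraction.
#'
#' @param pair_data A tibble with columns `species`, `partner`, `fraction`
#'   (six rows: each of the three species against each of its two
#'   partners), e.g. a filtered [pair_outcomes()] result. If a `generation`
#'   column is present it must be constant.
#' @param weights Optional tibble `species`, `partner`, `weight` giving the
#'   geometric-mean weights; they are normalized to sum to 1 within each
#'   species. Default: equal weights (exponent 1/2 each).
#' @param floor Pseudo-fraction replacing zero pairwise fractions.
#' @return A tibble `species`, `predicted` (sorted by species label,
#'   summing to 1).
#' @examples
#' pairs <- tibble::tibble(
#'   species = c("A", "A", "B", "B", "C", "C"),
#'   partner = c("B", "C", "A", "C", "A", "B"),
#'   fraction = c(0.8, 0.2, 0.2, 0.6, 0.8, 0.4))
#' predict_trio_from_pairs(pairs)
#' @export
predict_trio_from_pairs <- function(pair_data, weights = NULL,
                                    floor = 1e-3) {
  species <- sort(unique(pair_data$species))
  if (length(species) != 3) {
    abort("`pair_data` must cover exactly 3 species")
  }
  needed <- tidyr::expand_grid(species = species, partner = species) |>
    dplyr::filter(.data$species != .data$partner)
  got <- dplyr::distinct(pair_data, .data$species, .data$partner)
  if (nrow(dplyr::anti_join(needed, got,
                            by = c("species", "partner"))) > 0) {
    abort("`pair_data` must contain every species against both partners (a missing pair?)")
  }
  if ("generation" %in% names(pair_data) &&
      dplyr::n_distinct(round(pair_data$generation, 6)) > 1) {
    abort("all pairwise outcomes must come from the same generation")
  }
  pd <- pair_data |>
    dplyr::mutate(fraction = pmax(.data$fraction, .env$floor))
  if (is.null(weights)) {
    pd$weight <- 0.5
  } else {
    pd <- dplyr::left_join(pd, weights, by = c("species", "partner"))
    if (any(is.na(pd$weight))) abort("`weights` must cover every (species, partner)")
    pd <- pd |>
      dplyr::mutate(weight = .data$weight / sum(.data$weight),
                    .by = "species")
  }
  g <- pd |>
    dplyr::summarise(g = prod(.data$fraction^.data$weight),
                     .by = "species") |>
    dplyr::arrange(.data$species)
  tibble::tibble(species = g$species, predicted = g$g / sum(g$g))
}

#' Best-uninformed composition guess
#'
#' The barycentric guess assigning every species the fraction `1/n`.
#'
#' @param n Number of species (>= 2).
#' @return A fraction vector of length `n`.
#' @export
uninformed_guess <- function(n) {
  if (n < 2) abort("`n` must be >= 2")
  rep(1 / n, n)
}

#' Accuracy of a composition prediction
#'
#' `1 - ||prediction - observation|| / sqrt(n)`: 1 for a perfect prediction,
#' decreasing with the normalized Euclidean distance between the predicted
#' and observed (replicate-mean) compositions.
#'
#' @param prediction,observation Fraction vectors of equal length.
#' @param normalization Passed to [normalized_distance()].
#' @return A scalar accuracy (<= 1).
#' @export
prediction_accuracy <- function(prediction, observation,
                                normalization = c("sqrt_n", "true_max")) {
  1 - normalized_distance(prediction, observation,
                          normalization = match.arg(normalization))
}

# mean observed composition of a trio at a transfer, as a named vector
.trio_observed <- function(trio_rows) {
  obs <- trio_rows |>
    dplyr::summarise(fraction = mean(.data$fraction), .by = "species") |>
    dplyr::arrange(.data$species)
  setNames(obs$fraction / sum(obs$fraction), obs$species)
}

#' Trio prediction accuracy across generations and methods
#'
#' Evaluates, for every three-species community whose three constituent
#' pairs are present in the data, the accuracy of four predictions of its
#' (replicate-mean) composition: pairwise outcomes at the same generation,
#' pairwise outcomes frozen at the end of the ecological phase
#' (`g_eco`), monoculture carrying capacities normalized to fractions, and
#' the uninformed `1/3` guess.
#'
#' @param data A composition tibble containing both the pair and the trio
#'   communities.
#' @param map A [generation_map()].
#' @param methods Subset of `c("pairs_same_generation", "pairs_ecological",
#'   "carrying_capacity", "uninformed")`.
#' @param generations Generations to evaluate; default, every sampled
#'   transfer of `map`.
#' @param g_eco Generation anchoring the `pairs_ecological` method.
#' @param carrying_capacities Optional tibble `species`, `K` used by the
#'   `carrying_capacity` method (that method is skipped when absent).
#' @param floor Passed to [predict_trio_from_pairs()].
#' @return A tibble `trio`, `generation`, `method`, `accuracy`. Trios with
#'   a missing constituent pair are excluded and listed in attribute
#'   `excluded`.
#' @seealso [summarize_accuracy()]
#' @export
accuracy_sweep <- function(data, map = generation_map(),
                           methods = c("pairs_same_generation",
                                       "pairs_ecological",
                                       "carrying_capacity", "uninformed"),
                           generations = NULL, g_eco = 70,
                           carrying_capacities = NULL, floor = 1e-3) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(carrying_capacities)) {
    methods <- setdiff(methods, "carrying_capacity")
  }
  if (is.null(generations)) {
    generations <- transfer_generation(map$sampled_transfers, map)
  }
  sizes <- community_sizes(data)
  trio_ids <- dplyr::filter(sizes, .data$n_species == 3)$community
  rosters <- data |>
    dplyr::distinct(.data$community, .data$species)
  pair_keys <- rosters |>
    dplyr::semi_join(dplyr::filter(sizes, .data$n_species == 2),
                     by = "community") |>
    dplyr::summarise(pair = species_key(.data$species), .by = "community")

  trio_species <- split(rosters$species[rosters$community %in% trio_ids],
                        rosters$community[rosters$community %in% trio_ids])
  complete <- purrr::keep(names(trio_species), function(tr) {
    sp <- trio_species[[tr]]
    need <- combn(sort(sp), 2, FUN = function(z) species_key(z))
    all(need %in% pair_keys$pair)
  })
  excluded <- tibble::tibble(
    trio = setdiff(names(trio_species), complete),
    reason = "constituent pair not measured")
  if (nrow(excluded) > 0) {
    warn(sprintf("%d trio(s) excluded: constituent pair not measured",
                 nrow(excluded)))
  }

  if (length(complete) == 0) {
    out <- tibble::tibble(trio = character(), generation = numeric(),
                          method = character(), accuracy = numeric())
    attr(out, "excluded") <- excluded
    return(out)
  }

  eco_pairs <- if ("pairs_ecological" %in% methods) {
    pair_outcomes(data, g_eco, map)
  }
  rows <- purrr::map_dfr(generations, function(g) {
    trio_at_g <- composition_at_generation(
      dplyr::filter(data, .data$community %in% complete), g, map)
    same_pairs <- if ("pairs_same_generation" %in% methods) {
      pair_outcomes(data, g, map)
    }
    purrr::map_dfr(complete, function(tr) {
      trio_rows <- dplyr::filter(trio_at_g, .data$community == tr)
      if (nrow(trio_rows) == 0) return(NULL)
      obs <- .trio_observed(trio_rows)
      sp <- names(obs)
      purrr::map_dfr(methods, function(method) {
        pred <- switch(
          method,
          pairs_same_generation = {
            pp <- dplyr::filter(same_pairs, .data$species %in% sp,
                                .data$partner %in% sp)
            if (dplyr::n_distinct(pp$pair) < 3) return(NULL)
            p <- predict_trio_from_pairs(
              dplyr::select(pp, "species", "partner", "fraction"),
              floor = floor)
            setNames(p$predicted, p$species)[sp]
          },
          pairs_ecological = {
            pp <- dplyr::filter(eco_pairs, .data$species %in% sp,
                                .data$partner %in% sp)
            if (dplyr::n_distinct(pp$pair) < 3) return(NULL)
            p <- predict_trio_from_pairs(
              dplyr::select(pp, "species", "partner", "fraction"),
              floor = floor)
            setNames(p$predicted, p$species)[sp]
          },
          carrying_capacity = {
            k <- carrying_capacities$K[match(sp, carrying_capacities$species)]
            if (any(is.na(k))) return(NULL)
            setNames(k / sum(k), sp)
          },
          uninformed = setNames(uninformed_guess(length(sp)), sp)
        )
        if (is.null(pred)) return(NULL)
        tibble::tibble(trio = tr, generation = g, method = method,
                       accuracy = prediction_accuracy(pred, obs))
      })
    })
  })
  attr(rows, "excluded") <- excluded
  rows
}

#' Mean accuracy and standard error across trios
#'
#' @param accuracy A tibble from [accuracy_sweep()].
#' @return A tibble `generation`, `method`, `n_trios`, `mean_accuracy`,
#'   `se` (standard error across trios).
#' @export
summarize_accuracy <- function(accuracy) {
  accuracy |>
    dplyr::summarise(
      n_trios = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      se = sd(.data$accuracy) / sqrt(dplyr::n()),
      .by = c("generation", "method")
    ) |>
    dplyr::arrange(.data$generation, .data$method)
}

#' Predict a trio's maximally increasing member from its pairs
#'
#' If the same species is the maximally increasing member of both pairs it
#' belongs to, it is predicted to be the trio's maximally increasing
#' member. If every pair has a different winner (a "transient topology",
#' the rock-paper-scissors-like case), the species with the highest mean
#' fold-change increase across its pairs is predicted instead.
#'
#' @param pair_winners A three-row tibble `species_a`, `species_b`,
#'   `winner` (one row per constituent pair; `tie` column optional).
#' @param mean_increases Named numeric vector: each species' mean
#'   fold-change increase across the replicates of both its pairs (only
#'   needed in the transient case).
#' @return A one-row tibble `species`, `rule` (`"double_winner"` or
#'   `"transient"`), `tie` (TRUE when a pair-level winner was itself
#'   tie-flagged or the double-winner is ambiguous).
#' @export
predict_trio_max_increaser <- function(pair_winners,
                                       mean_increases = NULL) {
  if (nrow(pair_winners) != 3) {
    abort("`pair_winners` must have one row per constituent pair (3 rows)")
  }
  tie_in <- if ("tie" %in% names(pair_winners)) any(pair_winners$tie) else FALSE
  wins <- table(pair_winners$winner)
  if (max(wins) >= 2) {
    winners2 <- sort(names(wins)[wins >= 2])
    tibble::tibble(species = winners2[1], rule = "double_winner",
                   tie = tie_in || length(winners2) > 1)
  } else {
    if (is.null(mean_increases)) {
      abort("transient topology: `mean_increases` is required")
    }
    pick <- max_increaser(mean_increases)
    tibble::tibble(species = pick$species, rule = "transient",
                   tie = tie_in || pick$tie)
  }
}

#' End-to-end max-increaser prediction for every trio
#'
#' Computes pair-level winners (the species that is the maximally
#' increasing member in the most replicates of that pair), predicts each
#' trio's maximally increasing member with
#' [predict_trio_max_increaser()], and compares it to the trio's observed
#' modal max-increaser.
#'
#' @inheritParams fold_changes
#' @return A tibble `trio`, `predicted`, `observed`, `rule`, `tie`,
#'   `correct`. Trios whose three pairs are not all present are skipped.
#' @export
trio_max_increaser_analysis <- function(data, g1 = 70, g2 = 400,
                                        floor = 1e-3,
                                        map = generation_map()) {
  sizes <- community_sizes(data)
  folds <- suppressWarnings(
    fold_changes(data, g1 = g1, g2 = g2, floor = floor, map = map))
  folds <- dplyr::left_join(folds, sizes, by = "community")
  pair_folds <- dplyr::filter(folds, .data$n_species == 2)
  trio_folds <- dplyr::filter(folds, .data$n_species == 3)
  if (nrow(pair_folds) == 0 || nrow(trio_folds) == 0) {
    abort("need both pair and trio communities with data at both anchors")
  }

  # modal winner of each pair community
  pair_winner_tbl <- max_increasers(pair_folds) |>
    dplyr::summarise(
      winner = names(sort(table(.data$species), decreasing = TRUE))[1],
      tie = max(table(.data$species)) * 2 == dplyr::n(),
      .by = "community"
    )
  pair_roster <- pair_folds |>
    dplyr::summarise(pair = species_key(unique(.data$species)),
                     species_a = sort(unique(.data$species))[1],
                     species_b = sort(unique(.data$species))[2],
                     .by = "community")
  pair_winner_tbl <- dplyr::left_join(pair_winner_tbl, pair_roster,
                                      by = "community")

  trio_rosters <- trio_folds |>
    dplyr::summarise(species = list(sort(unique(.data$species))),
                     .by = "community")
  observed <- max_increasers(trio_folds) |>
    dplyr::summarise(
      observed = names(sort(table(.data$species), decreasing = TRUE))[1],
      .by = "community")

  purrr::map_dfr(seq_len(nrow(trio_rosters)), function(i) {
    tr <- trio_rosters$community[i]
    sp <- trio_rosters$species[[i]]
    keys <- combn(sp, 2, FUN = function(z) species_key(z))
    pw <- dplyr::filter(pair_winner_tbl, .data$pair %in% keys)
    if (nrow(pw) < 3) return(NULL)
    mean_inc <- pair_folds |>
      dplyr::semi_join(dplyr::select(pw, "community"), by = "community") |>
      dplyr::filter(.data$species %in% sp) |>
      dplyr::summarise(fold = mean(.data$fold), .by = "species")
    pred <- predict_trio_max_increaser(
      dplyr::select(pw, "species_a", "species_b", "winner", "tie"),
      setNames(mean_inc$fold, mean_inc$species))
    obs <- observed$observed[observed$community == tr]
    tibble::tibble(trio = tr, predicted = pred$species, observed = obs,
                   rule = pred$rule, tie = pred$tie,
                   correct = pred$species == obs)
  })
}

#' Accuracy of max-increaser predictions with an exact binomial test
#'
#' Fraction of trios whose predicted maximally increasing member matches
#' the observed one, with the exact one-sided binomial tail probability of
#' doing at least that well by chance (success probability 1/3: guessing
#' one species of three).
#'
#' @param predictions A tibble with logical column `correct` (e.g. from
#'   [trio_max_increaser_analysis()]), or a logical vector.
#' @param chance Chance success probability (default 1/3).
#' @return A one-row tibble `n`, `n_correct`, `accuracy`, `p_value`.
#' @export
max_increaser_prediction_accuracy <- function(predictions, chance = 1/3) {
  correct <- if (is.data.frame(predictions)) predictions$correct
             else predictions
  n <- length(correct)
  if (n == 0) abort("no evaluable trios")
  k <- sum(correct)
  tibble::tibble(
    n = n, n_correct = k, accuracy = k / n,
    p_value = pbinom(k - 1, n, chance, lower.tail = FALSE)
  )
}
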