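#' Compositional-dynamics stage: step changes and drift from equilibrium
#'
#' Runs [stepwise_change()] and [change_from_reference()] on a composition
#' table and summarizes both as medians and interquartile ranges per size
#' class (pairs vs trios) and generation.
#'
#' @param data A composition tibble.
#' @param map A [generation_map()].
#' @param g_ref Reference generation for the drift metric (default 70).
#' @param normalization Passed to the distance metrics.
#' @return An object of class `evo_dynamics`: list with tibbles `stepwise`,
#'   `from_reference` and `summary` (columns `metric`, `n_species`,
#'   `generation`, `median`, `q25`, `q75`, `n`).
#' @export
run_dynamics <- function(data, map = generation_map(), g_ref = 70,
                         normalization = c("sqrt_n", "true_max")) {
  normalization <- match.arg(normalization)
  if (nrow(data) == 0) abort("empty composition table")
  sizes <- community_sizes(data)
  stepwise <- suppressWarnings(
    stepwise_change(data, map, normalization = normalization))
  from_ref <- suppressWarnings(
    change_from_reference(data, g_ref = g_ref, map = map,
                          normalization = normalization))
  summarize_delta <- function(x, metric) {
    x |>
      dplyr::left_join(sizes, by = "community") |>
      dplyr::summarise(
        median = median(.data$delta),
        q25 = quantile(.data$delta, 0.25, names = FALSE),
        q75 = quantile(.data$delta, 0.75, names = FALSE),
        n = dplyr::n(),
        .by = c("n_species", "generation")
      ) |>
      dplyr::mutate(metric = metric, .before = 1) |>
      dplyr::arrange(.data$n_species, .data$generation)
  }
  structure(
    list(
      stepwise = stepwise,
      from_reference = from_ref,
      summary = dplyr::bind_rows(
        summarize_delta(stepwise, "stepwise"),
        summarize_delta(from_ref, "from_reference"))
    ),
    class = "evo_dynamics"
  )
}

#' Repeatability stage: variability, scores, shuffle and Dirichlet nulls
#'
#' For each size class (pairs, trios): fold changes between the two
#' generation anchors, per-community repeatability scores, and the
#' 2000-iteration shuffle null of the mean score. Replicate variability is
#' computed at both anchors and, at the later anchor, compared with the
#' Dirichlet random-community null (matched per community in species count
#' and replicate number) by a one-sided Mann-Whitney U test.
#'
#' @inheritParams run_dynamics
#' @param g1,g2 Generation anchors (defaults 70 and 400).
#' @param iterations Shuffle iterations per size class.
#' @param seed Master seed for all resampling.
#' @param floor Zero-fraction pseudo-fraction (see [fold_changes()]).
#' @param dirichlet_draws Null draws per community for the Dirichlet null.
#' @param include_medoid Passed to the variability functions.
#' @return An object of class `evo_repeatability`: list with `variability`
#'   (per community at both anchors), `shuffle` (named list of
#'   [shuffle_null()] results per size class), `report` (the
#'   [observed_vs_null_report()] table), `dirichlet_test` (an
#'   `evo_mw_test`), `dirichlet_null` (the pooled null draws) and the
#'   anchors used.
#' @export
run_repeatability <- function(data, map = generation_map(), g1 = 70,
                              g2 = 400, iterations = 2000, seed = 1,
                              floor = 1e-3, dirichlet_draws = 200,
                              include_medoid = TRUE) {
  sizes <- community_sizes(data)
  seeds <- derive_seeds(seed, 3 + nrow(sizes))

  folds <- suppressWarnings(
    fold_changes(data, g1 = g1, g2 = g2, floor = floor, map = map))
  folds <- dplyr::left_join(folds, sizes, by = "community")
  shuffle <- list()
  for (n_sp in sort(unique(folds$n_species))) {
    fd <- folds |>
      dplyr::filter(.data$n_species == n_sp) |>
      dplyr::select(-"n_species")
    n_comm <- dplyr::n_distinct(fd$community)
    if (n_comm >= 2) {
      shuffle[[sprintf("n%d", n_sp)]] <- shuffle_null(
        fd, iterations = iterations,
        seed = seeds[if (n_sp == 2) 1 else 2])
    }
  }
  if (length(shuffle) == 0) {
    abort("no size class has >= 2 communities with enough replicates")
  }
  report <- do.call(observed_vs_null_report, unname(shuffle))

  profile <- variability_profile(data, map,
                                 include_medoid = include_medoid)
  t1 <- nearest_transfer(g1, map)
  t2 <- nearest_transfer(g2, map)
  variability <- profile |>
    dplyr::filter(.data$transfer %in% c(t1, t2)) |>
    dplyr::mutate(anchor = dplyr::if_else(.data$transfer == t1,
                                          "ecological", "evolutionary"))

  # matched Dirichlet null at the later anchor
  obs <- dplyr::filter(variability, .data$transfer == t2)
  null_draws <- purrr::map(seq_len(nrow(obs)), function(i) {
    dirichlet_null_variability(
      n_species = obs$n_species[i], n_replicates = obs$n_replicates[i],
      n_draws = dirichlet_draws, seed = seeds[3 + i],
      include_medoid = include_medoid)
  })
  dirichlet_null <- unlist(null_draws)
  dirichlet_test <- if (nrow(obs) > 0) {
    variability_vs_null_test(obs$variability, dirichlet_null)
  }

  structure(
    list(
      variability = variability,
      shuffle = shuffle,
      report = report,
      dirichlet_test = dirichlet_test,
      dirichlet_null = dirichlet_null,
      anchors = c(g1 = g1, g2 = g2),
      seed = seed
    ),
    class = "evo_repeatability"
  )
}

#' Prediction stage: assembly rule, max-increaser and growth dominance
#'
#' Evaluates the pairwise-to-trio assembly rule across generations
#' ([accuracy_sweep()]), the trio max-increaser prediction from pairs
#' ([trio_max_increaser_analysis()]), and — when growth parameters are
#' supplied — the growth-based dominance predictions for pairs at both
#' generation anchors.
#'
#' @inheritParams run_repeatability
#' @param growth_params Optional tibble `species`, `r`, `K` (either column
#'   may be missing).
#' @param g_eco,g_evo Generation anchors (defaults 70 and 400).
#' @return An object of class `evo_predictions`: list with `accuracy`,
#'   `accuracy_summary`, `max_increaser` (per-trio predictions),
#'   `max_increaser_accuracy`, and `dominance` (tibble with one row per
#'   criterion x anchor, or NULL).
#' @export
run_predictions <- function(data, map = generation_map(),
                            growth_params = NULL, g_eco = 70, g_evo = 400,
                            floor = 1e-3) {
  ks <- if (!is.null(growth_params) && "K" %in% names(growth_params)) {
    dplyr::filter(growth_params, !is.na(.data$K))
  }
  accuracy <- suppressWarnings(
    accuracy_sweep(data, map, g_eco = g_eco, carrying_capacities = ks,
                   floor = floor))
  sizes0 <- community_sizes(data)
  max_inc <- if (all(c(2, 3) %in% sizes0$n_species)) {
    trio_max_increaser_analysis(data, g1 = g_eco, g2 = g_evo,
                                floor = floor, map = map)
  } else {
    tibble::tibble(trio = character(), predicted = character(),
                   observed = character(), rule = character(),
                   tie = logical(), correct = logical())
  }
  dominance <- NULL
  if (!is.null(growth_params)) {
    sizes <- community_sizes(data)
    pair_data <- data |>
      dplyr::semi_join(dplyr::filter(sizes, .data$n_species == 2),
                       by = "community")
    criteria <- intersect(c("r", "K"), names(growth_params))
    dominance <- purrr::map_dfr(c(g_eco, g_evo), function(g) {
      obs <- observed_dominant(pair_data, g, map)
      purrr::map_dfr(criteria, function(cr) {
        pred <- predict_dominant_from_growth(
          dplyr::select(obs, "species_a", "species_b"), growth_params,
          criterion = cr)
        acc <- dominance_prediction_accuracy(obs, pred)
        dplyr::mutate(acc, criterion = cr, generation = g, .before = 1)
      })
    })
  }
  structure(
    list(
      accuracy = accuracy,
      accuracy_summary = summarize_accuracy(accuracy),
      max_increaser = max_inc,
      max_increaser_accuracy =
        if (nrow(max_inc) > 0) max_increaser_prediction_accuracy(max_inc),
      dominance = dominance
    ),
    class = "evo_predictions"
  )
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Simulates a serial-dilution coevolution experiment, applies the
#' coexistence filter, runs the dynamics, repeatability and prediction
#' stages, and writes every artifact (delimited tables, JSON summaries and
#' a manifest) to `out_dir` with deterministic content and row order:
#' rerunning with the same configuration reproduces the outputs
#' byte-for-byte.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param iterations Shuffle-null iterations.
#' @param dirichlet_draws Dirichlet-null draws per community.
#' @return Invisibly, a list with the simulation, the filtered
#'   composition, the three stage results, the estimated growth
#'   parameters, and the manifest of files written.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         iterations = 2000, dirichlet_draws = 200) {
  sim <- simulate_serial_dilution(config)
  map <- sim$map
  seeds <- derive_seeds(config$seed + 1L, 4)

  filtered <- filter_coexisting(sim$composition, g_threshold = 70,
                                map = map)
  exclusions <- attr(filtered, "exclusions")

  dynamics <- run_dynamics(filtered, map)
  repeatability <- run_repeatability(filtered, map,
                                     iterations = iterations,
                                     seed = seeds[1],
                                     dirichlet_draws = dirichlet_draws)

  # monoculture growth assays from the simulator's ground truth:
  # r is the gLV exponential rate (per hour), so doubling = ln 2 / r
  truth <- sim$ground_truth
  set.seed(seeds[2])
  gp_true <- tibble::tibble(
    species = names(truth$r),
    lag = runif(length(truth$r), 0.5, 2),
    doubling = log(2) / unname(truth$r),
    K = unname(truth$K)
  )
  curves <- simulate_growth_curves(gp_true, seed = seeds[3])
  endpoints <- simulate_cycle_endpoints(gp_true, cycles = config$cycles,
                                        seed = seeds[4])
  growth_params <- aggregate_growth_params(curves) |>
    dplyr::left_join(
      endpoints |>
        dplyr::group_by(.data$species) |>
        dplyr::group_modify(function(g, key) {
          tibble::tibble(K = carrying_capacity(g))
        }) |>
        dplyr::ungroup(),
      by = "species")

  predictions <- run_predictions(filtered, map,
                                 growth_params = growth_params)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
      name
    }
    files <- c(
      wr(sim$composition, "composition.csv"),
      wr(exclusions, "coexistence_exclusions.csv"),
      wr(dynamics$stepwise, "dynamics_stepwise.csv"),
      wr(dynamics$from_reference, "dynamics_from_reference.csv"),
      wr(dynamics$summary, "dynamics_summary.csv"),
      wr(repeatability$variability, "variability.csv"),
      wr(dplyr::bind_rows(purrr::map(repeatability$shuffle, tidy)),
         "repeatability_scores.csv"),
      wr(repeatability$report, "repeatability_report.csv"),
      wr(growth_params, "growth_params.csv"),
      wr(predictions$accuracy, "prediction_accuracy.csv"),
      wr(predictions$accuracy_summary, "prediction_accuracy_summary.csv"),
      wr(predictions$max_increaser, "max_increaser_predictions.csv"),
      wr(predictions$dominance, "dominance_accuracy.csv")
    )
    summary <- list(
      package_version = as.character(utils::packageVersion("evoassembly")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      n_communities_simulated = length(truth$communities),
      n_communities_retained =
        dplyr::n_distinct(filtered$community),
      repeatability = repeatability$report,
      dirichlet_mw_p = repeatability$dirichlet_test$p_value,
      max_increaser = predictions$max_increaser_accuracy
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "summary.json")
    manifest <- list(files = files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(
    simulation = sim,
    composition = filtered,
    exclusions = exclusions,
    dynamics = dynamics,
    repeatability = repeatability,
    predictions = predictions,
    growth_params = growth_params,
    manifest = manifest
  ))
}
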