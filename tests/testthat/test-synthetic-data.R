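test_that("simulation config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(replicate_range = c(2, 6)), ">= 3")
  expect_error(simulation_config(sampling_depth = c(10, 50)), "> 15")
  expect_error(simulation_config(dilution_factor = 1), "> 1")
  expect_error(simulation_config(sampled_transfers = c(0, 40)),
               "cannot exceed")
})

small_cfg <- function(...) {
  simulation_config(n_species_pool = 5, n_pairs = 4, n_trios = 2,
                    replicate_range = c(3, 4), cycles = 10,
                    sampled_transfers = c(0, 2, 5, 7, 10), ...)
}

test_that("neutral symmetric communities keep their initial fractions", {
  cfg <- small_cfg(
    growth = list(r_range = c(0.5, 0.5), K_range = c(0.5, 0.5),
                  interaction_range = c(0, 0)),
    drift = list(onset_transfer = 99, pull = 0, step_sd = 0, kappa = 20,
                 attractor_sd = 0, community_sd = 0),
    seed = 13)
  sim <- simulate_serial_dilution(cfg)
  # with no interactions, equal rates and K, latent fractions never move
  by_sample <- sim$latent |>
    dplyr::summarise(spread = max(fraction) - min(fraction),
                     .by = c(community, replicate, transfer))
  expect_lt(max(by_sample$spread), 1e-6)
})

test_that("latent fractions are exact compositions; observations multinomial", {
  sim <- simulate_serial_dilution(small_cfg(seed = 17))
  sums <- sim$latent |>
    dplyr::summarise(s = sum(fraction), .by = c(community, replicate,
                                                transfer))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)

  # observed fractions are counts over the sample depth
  obs <- sim$composition |>
    dplyr::mutate(depth = sum(count),
                  .by = c(community, replicate, transfer))
  expect_true(all(obs$depth >= 20 & obs$depth <= 100))
  expect_equal(obs$fraction, obs$count / obs$depth)

  # without drift, replicate latent trajectories are identical
  cfg0 <- small_cfg(
    drift = list(onset_transfer = 99, pull = 0, step_sd = 0, kappa = 20,
                 attractor_sd = 0, community_sd = 0),
    seed = 19)
  sim0 <- simulate_serial_dilution(cfg0)
  spread <- sim0$latent |>
    dplyr::summarise(spread = max(fraction) - min(fraction),
                     .by = c(community, transfer, species))
  expect_lt(max(spread$spread), 1e-7)

  # and with no drift the latent series converges toward a cycle-to-cycle
  # fixed point: late-transfer movement is small and much smaller than the
  # early assembly steps (weakly competing pairs converge geometrically,
  # so 10 cycles leave a sub-percent residual rather than exactly zero)
  movement <- function(trs) {
    sim0$latent |>
      dplyr::filter(transfer %in% trs) |>
      dplyr::summarise(spread = max(fraction) - min(fraction),
                       .by = c(community, replicate, species)) |>
      dplyr::pull(spread) |>
      max()
  }
  expect_lt(movement(c(7, 10)), 0.01)
  expect_lt(movement(c(7, 10)), movement(c(0, 2)) / 10)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_serial_dilution(small_cfg(seed = 23))
  b <- simulate_serial_dilution(small_cfg(seed = 23))
  expect_identical(a$composition, b$composition)
  expect_identical(a$latent, b$latent)
})

test_that("strong attractor concentration makes evolution repeatable", {
  cfg <- simulation_config(
    n_species_pool = 4, n_pairs = 4, n_trios = 0,
    replicate_range = c(6, 6), cycles = 10,
    sampled_transfers = c(0, 2, 5, 7, 10),
    drift = list(onset_transfer = 2, pull = 0.2, step_sd = 0.002,
                 kappa = 1e5, attractor_sd = 0.6, community_sd = 0.1),
    seed = 29)
  sim <- simulate_serial_dilution(cfg)
  folds <- suppressWarnings(
    fold_changes(sim$latent |>
                   dplyr::mutate(count = NA_integer_),
                 g1 = 20, g2 = 100, map = sim$map))
  scores <- repeatability_score(folds)
  expect_gt(mean(scores$score), 0.9)
})

test_that("planted repeatability has exactly the requested structure", {
  expect_error(plant_repeatability(q = 0.2, n_species = 2), "must be in")
  q1 <- plant_repeatability(n_communities = 8, n_species = 3,
                            n_replicates = 5, q = 1, seed = 37)
  gt <- attr(q1, "ground_truth")
  scores <- repeatability_score(fold_changes(q1))
  expect_equal(scores$score, rep(1, 8))
  expect_equal(scores$winner, gt$planted_winner)

  # q = 0.9 trios with 18 replicates: observed mean within Monte-Carlo
  # error of the exact enumeration of the modal frequency
  modal_expectation_trio <- function(k, q) {
    probs <- c(q, (1 - q) / 2, (1 - q) / 2)
    total <- 0
    for (k1 in 0:k) for (k2 in 0:(k - k1)) {
      cc <- c(k1, k2, k - k1 - k2)
      total <- total + dmultinom(cc, k, probs) * max(cc) / k
    }
    total
  }
  planted <- plant_repeatability(n_communities = 60, n_species = 3,
                                 n_replicates = 18, q = 0.9, seed = 41)
  sc <- repeatability_score(fold_changes(planted))$score
  expected <- modal_expectation_trio(18, 0.9)
  expect_lt(abs(mean(sc) - expected), 3 * sd(sc) / sqrt(length(sc)))
})

test_that("consistent trios are fixed points of the assembly rule", {
  tab <- trio_pair_table(0.8, 0.2, 0.6)
  obs <- make_consistent_trio(tab)
  pred <- predict_trio_from_pairs(tab)
  expect_equal(prediction_accuracy(pred$predicted, obs$fraction), 1)
  expect_equal(make_consistent_trio(trio_pair_table(0.5, 0.5, 0.5))$fraction,
               rep(1/3, 3))

  # noisy observations: accuracy approaches 1 as the noise shrinks
  set.seed(43)
  mean_acc <- sapply(c(0.2, 0.05, 0.01), function(scale) {
    mean(replicate(200, {
      noisy <- obs$fraction + scale * (as.vector(rsimplex(1, 3)) - 1/3)
      noisy <- pmax(noisy, 0); noisy <- noisy / sum(noisy)
      prediction_accuracy(pred$predicted, noisy)
    }))
  })
  expect_true(all(diff(mean_acc) > 0))
})

test_that("simulated growth curves recover their parameters", {
  # noiseless logistic: r matches the closed-form threshold crossing
  params <- tibble::tibble(species = "X", lag = 0, doubling = 1, K = 0.5)
  clean <- simulate_growth_curves(params, noise_sd = 0, seed = 47,
                                  n_tech = 1)
  r <- growth_rate_time_to_threshold(clean$time_h, clean$od)
  r_closed <- log2(800) / log2((0.5 / 1e-4 - 1) / (0.5 / 0.08 - 1))
  expect_equal(r, r_closed, tolerance = 1e-3)
  # with K far above the threshold the logistic bias vanishes: r -> 1
  tall <- simulate_growth_curves(
    tibble::tibble(species = "X", lag = 0, doubling = 1, K = 5),
    noise_sd = 0, seed = 47, n_tech = 1)
  expect_equal(growth_rate_time_to_threshold(tall$time_h, tall$od), 1,
               tolerance = 0.01)

  low_K <- tibble::tibble(species = "X", lag = 0, doubling = 1, K = 0.05)
  lk <- simulate_growth_curves(low_K, noise_sd = 0, seed = 47, n_tech = 1)
  expect_true(is.na(growth_rate_time_to_threshold(lk$time_h, lk$od)))

  expect_error(simulate_growth_curves(
    tibble::tibble(species = "X", lag = 0, doubling = 1, K = 5e-5)),
    "exceed the inoculation")

  # noise SD 0.003, 4 technical replicates: r within 5%
  params2 <- tibble::tibble(species = "Y", lag = 1.5, doubling = 1.2,
                            K = 0.6)
  noisy <- simulate_growth_curves(params2, noise_sd = 0.003, seed = 53,
                                  n_tech = 4)
  est <- aggregate_growth_params(noisy)
  t_star <- 1.5 + 1.2 * log2((0.6 / 1e-4 - 1) / (0.6 / 0.08 - 1))
  r_true <- log2(0.08 / 1e-4) / t_star
  expect_lt(abs(est$r - r_true) / r_true, 0.05)
})
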