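#' Configuration of the serial-dilution community simulator
#'
#' Describes a coevolution experiment: a pool of species from which pair
#' and trio communities are drawn, a serial growth-dilution schedule, a
#' generalized Lotka-Volterra (gLV) latent model with slow parameter drift
#' emulating evolution, and a multinomial colony-count observation model.
#'
#' Defaults mirror a typical bench design: 16-species pool, 44 pairs and 43
#' trios (trios preferentially composed of measured pairs), 3-18 replicates
#' per community, 38 cycles of 48 h growth followed by 1500-fold dilution,
#' composition sampled at transfers 0, 2, 5, 7, 10, 14, 19, 30 and 38 by
#' counting 20-100 colonies per sample.
#'
#' The drift model: after `drift$onset_transfer`, each replicate's gLV
#' parameters take per-cycle Gaussian steps on the log scale, pulled toward
#' an attractor representing the evolved phenotype. Attractors are
#' hierarchical: a pool-level evolved target per species parameter and
#' interaction (log-scale SD `attractor_sd` around the ancestral value) is
#' shared by every community — so a species' evolution in pairs is
#' mechanistically coupled to its evolution in trios — with a
#' community-level deviation (`community_sd`) and a replicate-level
#' deviation (`attractor_sd / kappa`); large `kappa` makes evolution
#' repeatable across replicates.
#'
#' @param n_species_pool Size of the species pool.
#' @param n_pairs,n_trios Numbers of two- and three-species communities.
#' @param replicate_range Integer range of replicates per community
#'   (minimum >= 3).
#' @param cycles Number of growth-dilution cycles.
#' @param hours_per_cycle Growth time per cycle (h).
#' @param dilution_factor Fold-dilution between cycles (> 1).
#' @param sampled_transfers Transfers at which composition is observed.
#' @param growth List with `r_range` (per-hour exponential growth rates),
#'   `K_range` (carrying capacities, OD units) and `interaction_range`
#'   (off-diagonal gLV competition coefficients; diagonal is 1).
#' @param drift List with `onset_transfer`, `pull` (per-cycle pull toward
#'   the attractor), `step_sd` (per-cycle log-scale step SD), `kappa`
#'   (replicate-attractor concentration), `attractor_sd` (log-scale SD of
#'   the pool-level evolved attractor around the ancestral parameters) and
#'   `community_sd` (log-scale SD of community-level attractor
#'   deviations).
#' @param sampling_depth Range of colony counts per sample (minimum > 15).
#' @param initial_od Total inoculation OD, split equally among species.
#' @param seed Integer seed driving every random choice.
#' @return A `simulation_config` object (a validated list).
#' @export
simulation_config <- function(n_species_pool = 16,
                              n_pairs = 44,
                              n_trios = 43,
                              replicate_range = c(3L, 18L),
                              cycles = 38,
                              hours_per_cycle = 48,
                              dilution_factor = 1500,
                              sampled_transfers = c(0L, 2L, 5L, 7L, 10L,
                                                    14L, 19L, 30L, 38L),
                              growth = list(r_range = c(0.3, 0.7),
                                            K_range = c(0.3, 0.9),
                                            interaction_range = c(0.2, 0.9)),
                              drift = list(onset_transfer = 7,
                                           pull = 0.08,
                                           step_sd = 0.01,
                                           kappa = 20,
                                           attractor_sd = 0.35,
                                           community_sd = 0.1),
                              sampling_depth = c(20L, 100L),
                              initial_od = 1e-4,
                              seed = 1) {
  if (replicate_range[1] < 3) abort("replicate counts must be >= 3")
  if (sampling_depth[1] <= 15) abort("minimum sampling depth must be > 15")
  if (dilution_factor <= 1) abort("`dilution_factor` must be > 1")
  if (any(unlist(growth[c("r_range", "K_range")]) <= 0)) {
    abort("growth rates and carrying capacities must be positive")
  }
  if (max(sampled_transfers) > cycles) {
    abort("`sampled_transfers` cannot exceed `cycles`")
  }
  structure(
    list(n_species_pool = n_species_pool, n_pairs = n_pairs,
         n_trios = n_trios,
         replicate_range = as.integer(replicate_range),
         cycles = as.integer(cycles), hours_per_cycle = hours_per_cycle,
         dilution_factor = dilution_factor,
         sampled_transfers = sort(unique(as.integer(sampled_transfers))),
         growth = growth, drift = drift,
         sampling_depth = as.integer(sampling_depth),
         initial_od = initial_od, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d-species pool, %d pairs + %d trios, %d cycles (%g h, 1:%g), seed %d\n",
    x$n_species_pool, x$n_pairs, x$n_trios, x$cycles, x$hours_per_cycle,
    x$dilution_factor, x$seed))
  invisible(x)
}

# gLV right-hand side for nrep stacked replicates:
# dx_i/dt = x_i r_i (1 - sum_j a_ij x_j / K_i), per replicate.
# parms: list(R, K: nrep x n matrices; Aflat: (n*n) x nrep matrix, n)
.glv_deriv <- function(t, y, parms) {
  n <- parms$n
  nrep <- nrow(parms$R)
  X <- matrix(pmax(y, 0), nrow = nrep, ncol = n)
  M <- matrix(0, nrep, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[, i] <- M[, i] + parms$Aflat[(j - 1L) * n + i, ] * X[, j]
    }
  }
  list(as.vector(X * parms$R * (1 - M / parms$K)))
}

# integrate one 48-h growth cycle for all replicates of one community
.grow_cycle <- function(X, parms, hours) {
  sol <- deSolve::ode(y = as.vector(X), times = c(0, hours),
                      func = .glv_deriv, parms = parms,
                      method = "lsoda", rtol = 1e-8, atol = 1e-14)
  Xe <- matrix(sol[nrow(sol), -1], nrow = nrow(X))
  Xe[Xe < 1e-12] <- 0   # extinction below the numerical floor
  Xe
}

# Community roster sampling, emulating a bench design pre-screened for
# coexistence: pairs are drawn preferentially from species pairs whose
# ancestral gLV parameters satisfy the two-species coexistence criterion
# (a_ij < K_i/K_j and a_ji < K_j/K_i), and trios preferentially from
# triangles of the measured-pair graph.
.sample_communities <- function(species, r0, K0, A0, n_pairs, n_trios) {
  all_pairs <- t(combn(species, 2))
  coex <- apply(all_pairs, 1, function(z) {
    A0[z[1], z[2]] < K0[z[1]] / K0[z[2]] &&
      A0[z[2], z[1]] < K0[z[2]] / K0[z[1]]
  })
  cand <- which(coex)
  pick <- cand[sample.int(length(cand), min(length(cand), n_pairs))]
  if (length(pick) < n_pairs) {
    rest <- setdiff(seq_len(nrow(all_pairs)), pick)
    pick <- c(pick, rest[sample.int(length(rest), n_pairs - length(pick))])
  }
  pairs <- all_pairs[pick, , drop = FALSE]
  pair_keys <- apply(pairs, 1, function(z) species_key(z))

  all_trios <- t(combn(species, 3))
  trio_cov <- apply(all_trios, 1, function(sp) {
    sum(combn(sp, 2, FUN = function(z) species_key(z)) %in% pair_keys)
  })
  triangles <- which(trio_cov == 3)
  take <- triangles[sample.int(length(triangles),
                               min(length(triangles), n_trios))]
  if (length(take) < n_trios) {
    rest <- setdiff(order(trio_cov, decreasing = TRUE), take)
    take <- c(take, rest[seq_len(n_trios - length(take))])
  }
  trios <- all_trios[take, , drop = FALSE]
  list(pairs = lapply(seq_len(nrow(pairs)), function(i) pairs[i, ]),
       trios = lapply(seq_len(nrow(trios)), function(i) trios[i, ]))
}

#' Simulate a serial-dilution coevolution experiment
#'
#' Generates composition time series for every community in the
#' configuration by integrating generalized Lotka-Volterra dynamics within
#' each growth cycle (adaptive ODE solver, relative tolerance 1e-8;
#' abundances below 1e-12 clamped to zero), diluting all abundances by the
#' dilution factor between cycles, and — after the drift onset — letting
#' each replicate's parameters random-walk toward its attractor (see
#' [simulation_config()]). Observed compositions at the sampled transfers
#' are multinomial colony counts of the configured depth drawn from the
#' latent fractions.
#'
#' @param config A [simulation_config()].
#' @return A list of class `evo_simulation`:
#' * `composition`: observed tibble (`community`, `replicate`, `transfer`,
#'   `species`, `count`, `fraction`) ready for the analysis functions;
#' * `latent`: the noise-free latent fractions, same shape minus `count`;
#' * `ground_truth`: list with per-species ancestral parameters (`r`, `K`),
#'   the interaction matrix, and the community rosters;
#' * `map`: the matching [generation_map()].
#' @export
simulate_serial_dilution <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- config$growth
  species <- sprintf("S%02d", seq_len(config$n_species_pool))
  np <- length(species)
  r0 <- setNames(runif(np, g$r_range[1], g$r_range[2]), species)
  K0 <- setNames(runif(np, g$K_range[1], g$K_range[2]), species)
  A0 <- matrix(runif(np * np, g$interaction_range[1],
                     g$interaction_range[2]), np, np,
               dimnames = list(species, species))
  diag(A0) <- 1
  roster <- .sample_communities(species, r0, K0, A0, config$n_pairs,
                                config$n_trios)

  # pool-level evolved attractors, shared across all communities
  drift <- config$drift
  r_evo <- log(r0) + rnorm(np, 0, drift$attractor_sd)
  K_evo <- log(K0) + rnorm(np, 0, drift$attractor_sd)
  A_evo <- log(A0) + matrix(rnorm(np * np, 0, drift$attractor_sd), np, np)
  diag(A_evo) <- 0  # self-limitation stays at 1
  dimnames(A_evo) <- dimnames(A0)

  communities <- c(roster$pairs, roster$trios)
  comm_ids <- sprintf("C%02d_%s", seq_along(communities),
                      vapply(communities, paste, "", collapse = "-"))
  n_reps <- sample(seq(config$replicate_range[1],
                       config$replicate_range[2]),
                   length(communities), replace = TRUE)
  depth_lo <- config$sampling_depth[1]
  depth_hi <- config$sampling_depth[2]

  latent_rows <- vector("list", length(communities))
  obs_rows <- vector("list", length(communities))

  for (ci in seq_along(communities)) {
    sp <- communities[[ci]]
    n <- length(sp)
    nrep <- n_reps[ci]
    rep_ids <- sprintf("R%02d", seq_len(nrep))

    # ancestral parameters restricted to this community
    base_log <- c(log(r0[sp]), log(K0[sp]), log(as.vector(A0[sp, sp])))
    # attractor hierarchy: pool-level evolved target, community deviation,
    # then replicate deviations concentrated as 1/kappa
    attr_pool <- c(r_evo[sp], K_evo[sp], as.vector(A_evo[sp, sp]))
    attr_comm <- attr_pool + rnorm(length(base_log), 0, drift$community_sd)
    attr_rep <- matrix(rep(attr_comm, each = nrep), nrow = nrep) +
      matrix(rnorm(nrep * length(base_log), 0,
                   drift$attractor_sd / drift$kappa), nrow = nrep)
    theta <- matrix(rep(base_log, each = nrep), nrow = nrep)

    unpack <- function(theta) {
      list(R = exp(theta[, seq_len(n), drop = FALSE]),
           K = exp(theta[, n + seq_len(n), drop = FALSE]),
           Aflat = t(exp(theta[, 2 * n + seq_len(n * n),
                               drop = FALSE])),
           n = n)
    }

    X <- matrix(config$initial_od / n, nrow = nrep, ncol = n)
    sampled <- config$sampled_transfers
    lat <- matrix(NA_real_, length(sampled), nrep * n)
    if (0L %in% sampled) {
      lat[match(0L, sampled), ] <- as.vector(X / rowSums(X))
    }
    for (cycle in seq_len(config$cycles)) {
      if (cycle > drift$onset_transfer) {
        theta <- theta + drift$pull * (attr_rep - theta) +
          matrix(rnorm(length(theta), 0, drift$step_sd), nrow = nrep)
      }
      X <- .grow_cycle(X, unpack(theta), config$hours_per_cycle)
      if (cycle %in% sampled) {
        tot <- rowSums(X)
        frac <- X / ifelse(tot > 0, tot, 1)
        lat[match(cycle, sampled), ] <- as.vector(frac)
      }
      X <- X / config$dilution_factor
    }

    grid <- expand.grid(replicate = rep_ids, species = sp,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    lat_tbl <- tibble::tibble(
      community = comm_ids[ci],
      replicate = rep(grid$replicate, times = length(sampled)),
      transfer = rep(sampled, each = nrow(grid)),
      species = rep(grid$species, times = length(sampled)),
      fraction = as.vector(t(lat))
    )
    latent_rows[[ci]] <- lat_tbl

    # multinomial plating observation, one depth per (replicate, transfer)
    obs <- lat_tbl |>
      dplyr::group_by(.data$replicate, .data$transfer) |>
      dplyr::group_modify(function(gdf, key) {
        depth <- sample(depth_lo:depth_hi, 1)
        counts <- as.vector(rmultinom(1, depth, gdf$fraction))
        gdf$count <- counts
        gdf$fraction <- counts / depth
        gdf
      }) |>
      dplyr::ungroup() |>
      dplyr::select("community", "replicate", "transfer", "species",
                    "count", "fraction")
    obs_rows[[ci]] <- obs
  }

  latent <- dplyr::bind_rows(latent_rows) |>
    dplyr::arrange(.data$community, .data$replicate, .data$transfer,
                   .data$species)
  composition <- dplyr::bind_rows(obs_rows) |>
    dplyr::arrange(.data$community, .data$replicate, .data$transfer,
                   .data$species)

  structure(
    list(
      composition = composition,
      latent = latent,
      ground_truth = list(
        r = r0, K = K0, interactions = A0,
        r_evolved = exp(r_evo), K_evolved = exp(K_evo),
        interactions_evolved = exp(A_evo),
        communities = setNames(communities, comm_ids),
        n_replicates = setNames(n_reps, comm_ids)
      ),
      map = generation_map(config$dilution_factor,
                           config$sampled_transfers),
      config = config
    ),
    class = "evo_simulation"
  )
}

#' @export
print.evo_simulation <- function(x, ...) {
  sizes <- lengths(x$ground_truth$communities)
  cat(sprintf(
    "<evo_simulation> %d pairs + %d trios, %d composition rows (seed %d)\n",
    sum(sizes == 2), sum(sizes == 3), nrow(x$composition),
    x$config$seed))
  invisible(x)
}

#' Plant a known repeatability structure
#'
#' Directly synthesizes composition samples at the two generation anchors
#' such that, in every replicate, a planted species is the maximally
#' increasing member with probability exactly `q` (the remaining
#' probability split evenly among the other species). The anchor
#' compositions are random Dirichlet draws rescaled by per-species
#' multipliers whose argmax is the chosen winner, so the fold-change
#' machinery recovers the structure exactly. Bypasses the ODE model for
#' fast statistical tests of the repeatability score and its shuffle null.
#'
#' @param n_communities Number of communities.
#' @param n_species Species per community (2 or 3).
#' @param n_replicates Replicates per community.
#' @param q Probability that the planted species wins in a replicate, in
#'   `[1/n_species, 1]`.
#' @param seed Integer seed.
#' @param g1,g2 Generation anchors; resolved by [nearest_transfer()].
#' @param map A [generation_map()].
#' @return A composition tibble restricted to the two anchor transfers
#'   (fractions only), with attribute `ground_truth`: a tibble
#'   `community`, `planted_winner`, `q`.
#' @export
plant_repeatability <- function(n_communities = 20, n_species = 2,
                                n_replicates = 6, q = 1, seed = 1,
                                g1 = 70, g2 = 400,
                                map = generation_map()) {
  if (q < 1 / n_species - 1e-12 || q > 1 + 1e-12) {
    abort(sprintf("`q` must be in [1/%d, 1]", n_species))
  }
  set.seed(seed)
  t1 <- nearest_transfer(g1, map)
  t2 <- nearest_transfer(g2, map)
  species <- LETTERS[seq_len(n_species)]
  comm_ids <- sprintf("P%03d", seq_len(n_communities))
  planted <- sample.int(n_species, n_communities, replace = TRUE)

  # one row block per (community x replicate), fully vectorized
  n_tot <- n_communities * n_replicates
  planted_row <- rep(planted, each = n_replicates)
  is_planted <- runif(n_tot) < q
  offset <- sample.int(max(n_species - 1, 1), n_tot, replace = TRUE)
  widx <- ifelse(is_planted, planted_row,
                 (planted_row - 1L + offset) %% n_species + 1L)
  f1 <- rdirichlet_unif(n_tot, n_species)
  mult <- matrix(runif(n_tot * n_species, 0.3, 0.9), n_tot, n_species)
  mult[cbind(seq_len(n_tot), widx)] <- runif(n_tot, 1.5, 3)
  f2 <- f1 * mult
  f2 <- f2 / rowSums(f2)

  rows <- tibble::tibble(
    community = rep(rep(comm_ids, each = n_replicates), each = 2 * n_species),
    replicate = rep(rep(sprintf("R%02d", seq_len(n_replicates)),
                        times = n_communities), each = 2 * n_species),
    transfer = rep(rep(c(t1, t2), each = n_species), times = n_tot),
    species = rep(rep(species, 2), times = n_tot),
    count = NA_integer_,
    fraction = as.vector(rbind(t(f1), t(f2)))
  )
  attr(rows, "ground_truth") <- tibble::tibble(
    community = comm_ids, planted_winner = species[planted], q = q)
  rows
}

#' Construct a trio observation satisfying the assembly rule exactly
#'
#' Returns the [predict_trio_from_pairs()] prediction verbatim as an
#' "observed" trio composition — a fixed point of the rule, useful for
#' validating that the accuracy machinery scores a self-consistent trio
#' as 1.
#'
#' @inheritParams predict_trio_from_pairs
#' @return A tibble `species`, `fraction`.
#' @export
make_consistent_trio <- function(pair_data, weights = NULL, floor = 1e-3) {
  p <- predict_trio_from_pairs(pair_data, weights = weights, floor = floor)
  tibble::tibble(species = p$species, fraction = p$predicted)
}

#' Simulate plate-reader growth curves from known parameters
#'
#' Lagged logistic growth,
#' `od(t) = K / (1 + (K/od0 - 1) * 2^(-max(0, t - lag) / doubling))`, with
#' iid Gaussian OD noise truncated at zero, sampled on a regular grid
#' (default every 10 minutes).
#'
#' @param params A tibble with columns `species`, `lag` (h), `doubling`
#'   (h), `K` (OD units).
#' @param od0 Inoculation OD (must be < every `K`).
#' @param noise_sd OD noise standard deviation.
#' @param dt_min Sampling interval in minutes.
#' @param t_max_h Assay duration in hours.
#' @param n_evo,n_tech Evolutionary and technical replicates per species.
#' @param seed Integer seed.
#' @return A growth-curve tibble: `well`, `species`, `evo_replicate`,
#'   `tech_replicate`, `time_min`, `time_h`, `od`.
#' @export
simulate_growth_curves <- function(params, od0 = 1e-4, noise_sd = 0.003,
                                   dt_min = 10, t_max_h = 48,
                                   n_evo = 1, n_tech = 4, seed = 1) {
  if (any(params$K <= od0)) {
    abort("every carrying capacity must exceed the inoculation OD")
  }
  if (any(params$doubling <= 0) || any(params$lag < 0)) {
    abort("doubling times must be positive and lags non-negative")
  }
  set.seed(seed)
  time_h <- seq(0, t_max_h, by = dt_min / 60)
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    purrr::map_dfr(seq_len(n_evo), function(e) {
      purrr::map_dfr(seq_len(n_tech), function(tech) {
        od <- p$K / (1 + (p$K / od0 - 1) *
                       2^(-pmax(0, time_h - p$lag) / p$doubling))
        od <- pmax(od + rnorm(length(od), 0, noise_sd), 0)
        tibble::tibble(
          well = sprintf("%s_e%d_t%d", p$species, e, tech),
          species = p$species,
          evo_replicate = sprintf("e%d", e),
          tech_replicate = sprintf("t%d", tech),
          time_min = time_h * 60,
          time_h = time_h,
          od = od
        )
      })
    })
  })
}

#' Simulate end-of-cycle monoculture optical densities
#'
#' One OD value per (replicate, cycle), fluctuating around the true
#' carrying capacity with multiplicative Gaussian noise — the raw material
#' of [carrying_capacity()].
#'
#' @param params A tibble with columns `species`, `K`.
#' @param cycles Number of cycles.
#' @param n_replicates Replicates per species.
#' @param noise_sd Relative noise SD.
#' @param seed Integer seed.
#' @return A tibble `species`, `replicate`, `cycle`, `od`.
#' @export
simulate_cycle_endpoints <- function(params, cycles = 38, n_replicates = 3,
                                     noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(
    species = params$species,
    replicate = sprintf("r%d", seq_len(n_replicates)),
    cycle = seq_len(cycles)
  ) |>
    dplyr::left_join(params[c("species", "K")], by = "species") |>
    dplyr::mutate(od = .data$K * pmax(1 + rnorm(dplyr::n(), 0,
                                                .env$noise_sd), 0)) |>
    dplyr::select("species", "replicate", "cycle", "od")
}
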