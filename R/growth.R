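#' Read a long-format plate-reader growth-curve table
#'
#' Columns: `well`, `species`, `evo_replicate`, `tech_replicate`,
#' `time_min`, `od`. Times must be strictly increasing within a well and
#' OD values non-negative.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; default from the extension.
#' @return A tibble sorted by well and time, with `time_h = time_min / 60`.
#' @export
read_growth_curves <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("well", "species", "evo_replicate", "tech_replicate",
                "time_min", "od")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("growth table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- raw |>
    dplyr::mutate(time_h = .data$time_min / 60) |>
    dplyr::arrange(.data$well, .data$time_min)
  bad <- out |>
    dplyr::summarise(ok = all(diff(.data$time_min) > 0) & all(.data$od >= 0),
                     .by = "well")
  if (any(!bad$ok)) {
    abort("each well needs strictly increasing times and non-negative OD")
  }
  tibble::as_tibble(out)
}

#' Growth rate as divisions per hour to an OD threshold
#'
#' The number of doublings needed to grow from the inoculation density
#' `od0` to `threshold` (`log2(threshold / od0)`), divided by the time the
#' curve first reaches the threshold. The crossing time is found by linear
#' interpolation between the bracketing samples. Because the clock starts
#' at inoculation, the measure includes the strain's lag time.
#'
#' @param time Time points in hours (strictly increasing).
#' @param od Optical densities (same length as `time`).
#' @param od0 Inoculation OD (default 1e-4).
#' @param threshold OD threshold (default 0.08).
#' @return Divisions per hour, or `NA` with attribute
#'   `reason = "threshold not reached"` when the curve never attains the
#'   threshold.
#' @examples
#' t <- seq(0, 15, by = 1/6)
#' growth_rate_time_to_threshold(t, 1e-4 * 2^t)  # 1 division/hour
#' @export
growth_rate_time_to_threshold <- function(time, od, od0 = 1e-4,
                                          threshold = 0.08) {
  if (length(time) != length(od)) abort("`time` and `od` lengths differ")
  if (od[1] > threshold) abort("curve must start at or below the threshold")
  hit <- which(od >= threshold)
  if (length(hit) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "threshold not reached"
    return(out)
  }
  i <- hit[1]
  t_star <- if (i == 1) time[1] else {
    time[i - 1] + (threshold - od[i - 1]) / (od[i] - od[i - 1]) *
      (time[i] - time[i - 1])
  }
  log2(threshold / od0) / t_star
}

#' Centered moving mean with truncated endpoints
#'
#' @param x Numeric series.
#' @param window Odd positive integer window (default 3). Endpoints use
#'   the part of the window that fits.
#' @return Smoothed series of the same length.
#' @examples
#' smooth_moving_mean(c(0, 1, 0))  # 0.5, 1/3, 0.5
#' @export
smooth_moving_mean <- function(x, window = 3) {
  if (length(x) == 0) abort("`x` must be non-empty")
  if (window < 1 || window %% 2 == 0) {
    abort("`window` must be an odd positive integer")
  }
  as.numeric(zoo::rollapply(x, window, mean, partial = TRUE))
}

#' Carrying capacity from end-of-cycle optical densities
#'
#' The OD a monoculture reaches by the end of a growth cycle, averaged
#' across replicates: each replicate's end-of-cycle trajectory is smoothed
#' with a centered moving mean, then the smoothed values at the requested
#' cycles are averaged across replicates and cycles.
#'
#' @param data A tibble with columns `replicate`, `cycle`, `od` (one
#'   end-of-cycle OD per replicate per cycle).
#' @param cycles Cycles to average over; default, all available.
#' @param window Smoothing window (default 3).
#' @return The carrying capacity estimate (scalar), or `NA` if no values
#'   remain.
#' @export
carrying_capacity <- function(data, cycles = NULL, window = 3) {
  if (nrow(data) == 0) return(NA_real_)
  smoothed <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::arrange(.data$cycle, .by_group = TRUE) |>
    dplyr::mutate(od_smooth = smooth_moving_mean(.data$od,
                                                 window = window)) |>
    dplyr::ungroup()
  if (!is.null(cycles)) {
    smoothed <- dplyr::filter(smoothed, .data$cycle %in% cycles)
  }
  if (nrow(smoothed) == 0) return(NA_real_)
  mean(smoothed$od_smooth)
}

#' Per-species growth parameters from replicated curves
#'
#' Computes the time-to-threshold growth rate of every well, then averages
#' in two levels: technical replicates are averaged into one value per
#' evolutionary replicate, and evolutionary replicates are averaged into
#' the species value (so unbalanced technical replication does not bias
#' the species mean). Wells that never reach the threshold are dropped
#' from the averages; a species with no well reaching the threshold gets
#' `NA`.
#'
#' @param data A growth-curve tibble (see [read_growth_curves()]); must
#'   contain `species`, `evo_replicate`, `tech_replicate`, `time_h`, `od`.
#' @inheritParams growth_rate_time_to_threshold
#' @return A tibble `species`, `r` (divisions/hour), `n_evo_replicates`,
#'   `n_wells`.
#' @export
aggregate_growth_params <- function(data, od0 = 1e-4, threshold = 0.08) {
  per_well <- data |>
    dplyr::group_by(.data$species, .data$evo_replicate,
                    .data$tech_replicate) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      r = as.numeric(growth_rate_time_to_threshold(
        .data$time_h, .data$od, od0 = od0, threshold = threshold)),
      .groups = "drop"
    )
  per_evo <- per_well |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE),
                     n_wells = sum(!is.na(.data$r)),
                     .by = c("species", "evo_replicate"))
  per_evo |>
    dplyr::summarise(
      n_evo_replicates = sum(is.finite(.data$r)),
      n_wells = sum(.data$n_wells),
      r = ifelse(any(is.finite(.data$r)),
                 mean(.data$r[is.finite(.data$r)]), NA_real_),
      .by = "species"
    ) |>
    dplyr::select("species", "r", "n_evo_replicates", "n_wells") |>
    dplyr::arrange(.data$species)
}

#' Predict the dominant species of each pair from growth parameters
#'
#' Predicts that the species with the strictly larger growth criterion
#' (rate `r` or carrying capacity `K`) dominates the pairwise coculture.
#' Pairs in which the criterion is undefined for either species are
#' excluded and reported; exact ties are flagged and resolved by label
#' order.
#'
#' @param pairs A tibble `species_a`, `species_b` (one row per pair).
#' @param params A tibble with column `species` and the criterion column.
#' @param criterion `"r"` or `"K"` — which column of `params` to compare.
#' @return A tibble `species_a`, `species_b`, `predicted`, `tie`. Excluded
#'   pairs are in attribute `excluded` (with reasons).
#' @export
predict_dominant_from_growth <- function(pairs, params,
                                         criterion = c("r", "K")) {
  criterion <- match.arg(criterion)
  if (!criterion %in% names(params)) {
    abort(sprintf("`params` has no column `%s`", criterion))
  }
  val <- setNames(params[[criterion]], params$species)
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$species_a[i]; b <- pairs$species_b[i]
    va <- val[a]; vb <- val[b]
    if (is.na(va) || is.na(vb)) {
      return(tibble::tibble(species_a = a, species_b = b,
                            predicted = NA_character_, tie = NA,
                            reason = sprintf(
                              "%s undefined for %s", criterion,
                              paste(c(a, b)[is.na(c(va, vb))],
                                    collapse = ", "))))
    }
    tie <- isTRUE(all.equal(unname(va), unname(vb)))
    winner <- if (tie) sort(c(a, b))[1] else c(a, b)[which.max(c(va, vb))]
    tibble::tibble(species_a = a, species_b = b, predicted = winner,
                   tie = tie, reason = NA_character_)
  })
  out <- rows |>
    dplyr::filter(!is.na(.data$predicted)) |>
    dplyr::select(-"reason")
  attr(out, "excluded") <- rows |>
    dplyr::filter(is.na(.data$predicted)) |>
    dplyr::select("species_a", "species_b", "reason")
  out
}

#' Observed dominant species of each pair at a generation
#'
#' The species whose mean fraction across replicates exceeds 0.5 at the
#' transfer nearest `generation`. With `mode = "majority"`, the species
#' dominating (fraction > 0.5) in the majority of replicates instead.
#'
#' @param data A composition tibble of two-species communities.
#' @param generation Target generation.
#' @param map A [generation_map()].
#' @param mode `"mean"` (default) or `"majority"`.
#' @return A tibble `community`, `species_a`, `species_b`, `dominant`.
#' @export
observed_dominant <- function(data, generation, map = generation_map(),
                              mode = c("mean", "majority")) {
  mode <- match.arg(mode)
  at_g <- composition_at_generation(data, generation, map)
  if (mode == "mean") {
    at_g |>
      dplyr::summarise(fraction = mean(.data$fraction),
                       .by = c("community", "species")) |>
      dplyr::arrange(.data$community, .data$species) |>
      dplyr::summarise(
        species_a = .data$species[1], species_b = .data$species[2],
        dominant = .data$species[which.max(.data$fraction)],
        .by = "community")
  } else {
    at_g |>
      dplyr::summarise(
        wins = sum(.data$fraction > 0.5),
        .by = c("community", "species")) |>
      dplyr::arrange(.data$community, .data$species) |>
      dplyr::summarise(
        species_a = .data$species[1], species_b = .data$species[2],
        dominant = .data$species[which.max(.data$wins)],
        .by = "community")
  }
}

#' Accuracy of growth-based dominance predictions
#'
#' Fraction of evaluable pairs whose predicted dominant species matches
#' the observed one, with the exact one-sided binomial tail probability of
#' doing at least that well by chance (success probability 1/2).
#'
#' @param observed A tibble with columns `species_a`, `species_b`,
#'   `dominant` (see [observed_dominant()]).
#' @param predicted A tibble with columns `species_a`, `species_b`,
#'   `predicted` (see [predict_dominant_from_growth()]).
#' @return A one-row tibble `n`, `n_correct`, `accuracy`, `p_value`.
#' @export
dominance_prediction_accuracy <- function(observed, predicted) {
  joined <- dplyr::inner_join(observed, predicted,
                              by = c("species_a", "species_b"))
  if (nrow(joined) == 0) abort("no evaluable pairs")
  k <- sum(joined$dominant == joined$predicted)
  n <- nrow(joined)
  tibble::tibble(
    n = n, n_correct = k, accuracy = k / n,
    p_value = pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  )
}
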