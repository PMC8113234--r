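#' Read a long-format community composition table
#'
#' Reads a delimited file with one row per (community, replicate, transfer,
#' species) holding a colony `count` and/or a relative `fraction`, as
#' produced by plating replicate communities at sampled transfers. Fractions
#' are computed from counts where only counts are present; where both are
#' present and disagree, counts win and a validation warning is recorded.
#'
#' Validation rules:
#' * required columns: `community`, `replicate`, `transfer`, `species`, and
#'   at least one of `count`, `fraction` (missing -> error);
#' * fractions within a (community, replicate, transfer) sample must sum to
#'   1 within `tol` when no counts are available to renormalize (-> error);
#' * total colony counts of 15 or fewer per sample are flagged with a
#'   warning (small plating samples give noisy fractions);
#' * a fraction inconsistent with `count/total` is overridden by the counts,
#'   with a warning.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected from the
#'   extension, or set `delim`).
#' @param delim Field delimiter; default `","`, or `"\t"` for `.tsv` files.
#' @param tol Tolerance on the sum of fractions per sample.
#' @return A tibble with columns `community`, `replicate`, `transfer`,
#'   `species`, `count` (integer, possibly `NA`) and `fraction`, carrying a
#'   validation report retrievable with [composition_validation()].
#' @seealso [validate_composition()], [write_composition_table()]
#' @export
read_composition_table <- function(path, delim = NULL, tol = 1e-6) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_composition(raw, tol = tol)
}

#' Validate and normalize an in-memory composition table
#'
#' @param data A data frame with the columns described in
#'   [read_composition_table()].
#' @inheritParams read_composition_table
#' @return The normalized tibble with a `validation` attribute.
#' @export
validate_composition <- function(data, tol = 1e-6) {
  required <- c("community", "replicate", "transfer", "species")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("composition table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("count", "fraction") %in% names(data))) {
    abort("composition table needs a `count` or `fraction` column")
  }
  if (!"count" %in% names(data)) data$count <- NA_integer_
  if (!"fraction" %in% names(data)) data$fraction <- NA_real_

  data <- tibble::as_tibble(data) |>
    dplyr::mutate(
      community = as.character(.data$community),
      replicate = as.character(.data$replicate),
      transfer = as.integer(.data$transfer),
      species = as.character(.data$species),
      count = as.integer(.data$count),
      fraction = as.numeric(.data$fraction)
    )
  if (any(data$transfer < 0, na.rm = TRUE)) {
    abort("`transfer` must be >= 0")
  }
  if (any(!is.na(data$count) & data$count < 0)) {
    abort("`count` must be non-negative")
  }

  warnings <- character()
  out <- data |>
    dplyr::group_by(.data$community, .data$replicate, .data$transfer) |>
    dplyr::group_modify(function(g, key) {
      lab <- sprintf("community %s, replicate %s, transfer %d",
                     key$community, key$replicate, key$transfer)
      has_counts <- all(!is.na(g$count))
      if (has_counts) {
        total <- sum(g$count)
        if (total == 0) {
          abort(sprintf("all colony counts are zero in %s", lab))
        }
        frac <- g$count / total
        if (total <= 15) {
          warnings <<- c(warnings, sprintf(
            "low colony count (n = %d <= 15) in %s", total, lab))
        }
        if (any(!is.na(g$fraction) & abs(g$fraction - frac) > tol)) {
          warnings <<- c(warnings, sprintf(
            "fraction column inconsistent with counts in %s; counts win",
            lab))
        }
        g$fraction <- frac
      } else {
        if (any(is.na(g$fraction))) {
          abort(sprintf("neither complete counts nor fractions in %s", lab))
        }
        if (abs(sum(g$fraction) - 1) > tol) {
          abort(sprintf("fractions sum to %.6g (not 1) in %s",
                        sum(g$fraction), lab))
        }
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$community, .data$replicate, .data$transfer,
                   .data$species)

  # fixed species roster per community
  roster <- out |>
    dplyr::distinct(.data$community, .data$replicate, .data$transfer,
                    .data$species) |>
    dplyr::count(.data$community, .data$replicate, .data$transfer)
  sizes <- community_sizes(out)
  bad <- roster |>
    dplyr::left_join(sizes, by = "community") |>
    dplyr::filter(.data$n != .data$n_species)
  if (nrow(bad) > 0) {
    warnings <- c(warnings, sprintf(
      "incomplete species roster in community %s, replicate %s, transfer %d",
      bad$community, bad$replicate, bad$transfer))
  }

  attr(out, "validation") <- list(
    n_warnings = length(warnings),
    warnings = warnings
  )
  if (length(warnings) > 0) {
    warn(sprintf("composition table: %d validation warning(s); see composition_validation()",
                 length(warnings)))
  }
  out
}

#' Retrieve the validation report attached to a composition table
#'
#' @param data A table returned by [read_composition_table()] or
#'   [validate_composition()].
#' @return A list with `n_warnings` and the warning messages.
#' @export
composition_validation <- function(data) {
  attr(data, "validation") %||% list(n_warnings = 0L, warnings = character())
}

#' Write a composition table back to delimited text
#'
#' Inverse of [read_composition_table()]; fractions survive a round trip to
#' better than 1e-9.
#'
#' @param data A composition tibble.
#' @param path Output file path (`.tsv` extension selects tab delimiting).
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  cols <- intersect(c("community", "replicate", "transfer", "species",
                      "count", "fraction"), names(data))
  readr::write_delim(data[cols], path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Posterior uncertainty of a plated species fraction
#'
#' Standard deviation of the posterior Beta distribution of a species
#' fraction estimated from colony counts: `sqrt(p * (1 - p)) / (n + 1)`,
#' where `p` is the observed fraction and `n` the total number of colonies
#' counted in the sample.
#'
#' @param p Observed species fraction in `[0, 1]` (vectorized).
#' @param n Total colony count (>= 1; vectorized).
#' @return The posterior standard deviation(s).
#' @examples
#' fraction_posterior_sd(0.5, 15)  # 0.03125
#' @export
fraction_posterior_sd <- function(p, n) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1]")
  if (any(n < 1)) abort("`n` must be >= 1")
  sqrt(p * (1 - p)) / (n + 1)
}

#' Composition of every replicate at the transfer nearest a target generation
#'
#' @param data A composition tibble (see [read_composition_table()]).
#' @param generation Target generation.
#' @param map A [generation_map()].
#' @return A tibble of the rows at the resolved transfer, with an added
#'   `generation` column giving the actual generation used. Replicates with
#'   no sample at that transfer are simply absent. The resolved transfer is
#'   attached as attribute `transfer`.
#' @export
composition_at_generation <- function(data, generation,
                                      map = generation_map()) {
  tr <- nearest_transfer(generation, map)
  out <- data |>
    dplyr::filter(.data$transfer == tr) |>
    dplyr::mutate(generation = transfer_generation(tr, map))
  attr(out, "transfer") <- tr
  out
}

#' Drop communities that did not coexist through the ecological phase
#'
#' A community is excluded when at least one of its species is extinct in
#' every replicate at the transfer nearest `g_threshold`. A species is
#' considered extinct in a replicate when its colony count is zero (or, when
#' only fractions are available, its fraction falls below `min_fraction`,
#' reflecting the plating detection limit).
#'
#' @inheritParams composition_at_generation
#' @param g_threshold Generation by which all species must still be present
#'   in at least one replicate (default 70, the end of the ecological
#'   phase).
#' @param min_fraction Detection floor applied when counts are unavailable.
#' @return The filtered tibble. Exclusions (community, species lost) are
#'   recorded in attribute `exclusions`, a tibble with columns `community`
#'   and `reason`.
#' @export
filter_coexisting <- function(data, g_threshold = 70, min_fraction = 1e-9,
                              map = generation_map()) {
  anchor <- composition_at_generation(data, g_threshold, map)
  extinct <- anchor |>
    dplyr::mutate(
      gone = dplyr::if_else(!is.na(.data$count), .data$count == 0L,
                            .data$fraction < min_fraction)
    ) |>
    dplyr::summarise(all_gone = all(.data$gone),
                     .by = c("community", "species")) |>
    dplyr::filter(.data$all_gone)

  exclusions <- extinct |>
    dplyr::summarise(
      reason = sprintf("species %s extinct in all replicates at generation ~%g",
                       paste(.data$species, collapse = ", "), g_threshold),
      .by = "community")

  out <- data |>
    dplyr::filter(!.data$community %in% exclusions$community)
  attr(out, "exclusions") <-
    exclusions %||% tibble::tibble(community = character(),
                                   reason = character())
  out
}
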