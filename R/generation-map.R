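#' Map between transfer (dilution cycle) index and generations
#'
#' In a serial-dilution experiment each growth-dilution cycle corresponds to
#' `log2(dilution_factor)` generations, because the culture must double that
#' many times to regrow to its pre-dilution density. With the default
#' 1500-fold dilution a cycle is ~10.55 generations, and 38 cycles span
#' ~400 generations.
#'
#' @param dilution_factor Fold-dilution applied between cycles (> 1).
#' @param sampled_transfers Integer vector of the transfers at which
#'   composition was measured, in increasing order.
#'
#' @return An object of class `generation_map`: a list with elements
#'   `dilution_factor`, `generations_per_cycle` and `sampled_transfers`.
#'
#' @examples
#' gm <- generation_map()
#' gm$generations_per_cycle   # log2(1500) = 10.55
#' transfer_generation(38, gm)  # ~ 400 generations
#' @export
generation_map <- function(dilution_factor = 1500,
                           sampled_transfers = c(0L, 2L, 5L, 7L, 10L, 14L,
                                                 19L, 30L, 38L)) {
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 ||
      dilution_factor <= 1) {
    abort("`dilution_factor` must be a single number > 1")
  }
  sampled_transfers <- sort(unique(as.integer(sampled_transfers)))
  if (any(sampled_transfers < 0)) {
    abort("`sampled_transfers` must be non-negative integers")
  }
  structure(
    list(
      dilution_factor = dilution_factor,
      generations_per_cycle = log2(dilution_factor),
      sampled_transfers = sampled_transfers
    ),
    class = "generation_map"
  )
}

#' @export
print.generation_map <- function(x, ...) {
  cat(sprintf(
    "<generation_map> %g-fold dilution, %.3f generations/cycle\n",
    x$dilution_factor, x$generations_per_cycle))
  cat("  sampled transfers:", paste(x$sampled_transfers, collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname generation_map
#' @param transfer Integer transfer index (vectorized).
#' @param map A `generation_map`.
#' @export
transfer_generation <- function(transfer, map = generation_map()) {
  transfer * map$generations_per_cycle
}

#' Resolve a target generation to the nearest sampled transfer
#'
#' Composition is only measured at discrete transfers, so generation anchors
#' such as "generation ~70" are resolved to the sampled transfer whose
#' generation is closest to the target; exact ties resolve to the earlier
#' transfer. No interpolation is performed.
#'
#' @param generation Target generation (scalar, >= 0).
#' @inheritParams transfer_generation
#' @return The nearest sampled transfer (integer). The generation it actually
#'   corresponds to is `transfer_generation(result, map)`.
#' @examples
#' nearest_transfer(70)   # transfer 7 (generation 73.9)
#' nearest_transfer(400)  # transfer 38 (generation 400.9)
#' @export
nearest_transfer <- function(generation, map = generation_map()) {
  if (!is.numeric(generation) || length(generation) != 1 || generation < 0) {
    abort("`generation` must be a single non-negative number")
  }
  gens <- transfer_generation(map$sampled_transfers, map)
  map$sampled_transfers[which.min(abs(gens - generation))]
}
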