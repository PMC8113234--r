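# Fixture builders used across the test files. Everything is generated in
# code; no data files.

# one composition row set for a single sample from named fractions
sample_rows <- function(community, replicate, transfer, fractions,
                        counts = NULL) {
  tibble::tibble(
    community = community, replicate = replicate,
    transfer = as.integer(transfer), species = names(fractions),
    count = if (is.null(counts)) NA_integer_ else as.integer(counts),
    fraction = as.numeric(fractions)
  )
}

# a pair community whose per-transfer fractions are given as a matrix
# (rows = transfers) replicated identically across replicates
pair_series <- function(community, transfers, frac_a,
                        replicates = c("R1", "R2"),
                        species = c("A", "B")) {
  purrr::map_dfr(replicates, function(rep) {
    purrr::map_dfr(seq_along(transfers), function(i) {
      sample_rows(community, rep, transfers[i],
                  setNames(c(frac_a[i], 1 - frac_a[i]), species))
    })
  })
}

# random simplex point(s)
rsimplex <- function(n, k) {
  g <- matrix(rexp(n * k), n, k)
  g / rowSums(g)
}

# six-row pair-outcome table for a trio from the three "focal" fractions
# f_ab = fraction of A against B, etc.
trio_pair_table <- function(f_ab, f_ac, f_bc) {
  tibble::tibble(
    species = c("A", "A", "B", "B", "C", "C"),
    partner = c("B", "C", "A", "C", "A", "B"),
    fraction = c(f_ab, f_ac, 1 - f_ab, f_bc, 1 - f_ac, 1 - f_bc)
  )
}

# composition table containing three constant pairs and one trio whose
# observed composition equals the assembly-rule prediction at every
# sampled transfer (a fixed point of the rule)
consistent_trio_dataset <- function(f_ab = 0.8, f_ac = 0.2, f_bc = 0.6,
                                    transfers = c(0, 2, 5, 7, 10, 14, 19,
                                                  30, 38)) {
  pairs <- dplyr::bind_rows(
    pair_series("pAB", transfers, rep(f_ab, length(transfers)),
                species = c("A", "B")),
    pair_series("pAC", transfers, rep(f_ac, length(transfers)),
                species = c("A", "C")),
    pair_series("pBC", transfers, rep(f_bc, length(transfers)),
                species = c("B", "C"))
  )
  pred <- make_consistent_trio(trio_pair_table(f_ab, f_ac, f_bc))
  trio <- purrr::map_dfr(c("R1", "R2"), function(rep) {
    purrr::map_dfr(transfers, function(t) {
      sample_rows("tABC", rep, t, setNames(pred$fraction, pred$species))
    })
  })
  dplyr::bind_rows(pairs, trio)
}
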