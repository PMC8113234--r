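# evoassembly

Quantitative analysis of how two- and three-species bacterial community
compositions change, diverge, and remain predictable over hundreds of
generations of coevolution in serial-dilution (batch) culture — together
with a generalized Lotka–Volterra simulator that generates community data
with the same statistical structure, so the whole pipeline is testable
without external data.

The package is aimed at microbial ecologists analyzing replicated
coevolution experiments in which community composition is measured by
plating and colony counting at a series of growth–dilution transfers,
and monoculture growth is assayed in plate readers.

## What it computes

Communities are composition vectors (species fractions summing to 1)
tracked across transfers; with a 1500-fold dilution each 48-h cycle
corresponds to log2(1500) ≈ 10.5 generations, so 38 cycles span ~400
generations.

* **Compositional change** between samples x and y is the normalized
  Euclidean distance ‖x − y‖₂/√n (n = number of species): step-to-step
  change Δ(t, t−1) and drift from the ecological equilibrium Δ(g, g₇₀).
  Sampling noise on a plated fraction p with n colonies is
  σ = √(p(1−p))/(n+1), the SD of the posterior Beta distribution.
* **Replicate variability**: the mean distance of replicates from their
  medoid replicate, compared against random communities drawn from a
  uniform Dirichlet distribution (one-sided Mann–Whitney U test).
* **Repeatability**: each replicate's *maximally increasing member* (the
  species whose relative abundance grew by the largest factor between
  generations ~70 and ~400); the repeatability score of a community is
  the frequency of replicates sharing the modal winner (between 1/n
  and 1), tested against a permutation null that pools and reshuffles
  all fold changes (2000 iterations).
* **Assembly rule**: a trio composition is predicted from its three
  pairs — each species' fraction is proportional to the geometric mean of
  its fractions in its two pairwise cocultures. Prediction accuracy is
  1 − Δ(prediction, observation)/√n. The trio's maximally increasing
  member is predicted from the pair winners, with an exact binomial test
  at chance 1/3.
* **Growth-based predictions**: growth rate r = log2(0.08/10⁻⁴)/t*
  (divisions per hour to an OD threshold, lag included), carrying
  capacity K from smoothed end-of-cycle ODs; the species with higher r
  or K is predicted to dominate its pair (exact binomial test at
  chance 1/2).

## Worked example

Simulate the default experiment (16-species pool, 44 pairs + 43 trios,
3–18 replicates each, 38 cycles, multinomial colony counts of 20–100
per sample), drop communities that lost a species during the ecological
phase, and run the repeatability and prediction stages:

```r
library(evoassembly)

cfg  <- simulation_config(seed = 1)
sim  <- simulate_serial_dilution(cfg)
comp <- filter_coexisting(sim$composition, map = sim$map)
dplyr::n_distinct(comp$community)
#> [1] 63

rp <- run_repeatability(comp, sim$map, seed = 1)
rp$report
#> # A tibble: 2 × 8
#>   size_class n_communities observed_mean null_mean null_q25 null_q75 p_value
#>   <chr>              <int>         <dbl>     <dbl>    <dbl>    <dbl>   <dbl>
#> 1 2-species             40         0.948     0.622    0.612    0.632       0
#> 2 3-species             23         0.853     0.499    0.485    0.513       0

pr <- run_predictions(comp, sim$map)
dplyr::filter(pr$accuracy_summary, generation > 395)
#> # A tibble: 3 × 5
#>   generation method                n_trios mean_accuracy     se
#>        <dbl> <chr>                   <int>         <dbl>  <dbl>
#> 1       401. pairs_ecological           12         0.726 0.0427
#> 2       401. pairs_same_generation      12         0.839 0.0445
#> 3       401. uninformed                 12         0.683 0.0303

pr$max_increaser_accuracy
#> # A tibble: 1 × 4
#>       n n_correct accuracy p_value
#>   <int>     <int>    <dbl>   <dbl>
#> 1    12         9     0.75 0.00386
```

Reading the output: in every simulated size class the same species
increases the most in nearly every replicate (observed mean scores 0.95
and 0.85 against shuffle-null means of ~0.62 and ~0.50; permutation
p = 0 at 2000 iterations). Trio compositions at generation ~400 are
predicted well by the pair outcomes *at the same generation* (mean
accuracy 0.84) but barely better than the uninformed 1/3 guess by pair
outcomes frozen at generation ~70 (0.73 vs 0.68) — pair and trio
compositions keep tracking each other while both change. The trio's
maximally increasing member is predicted from pair winners in 9/12
trios (exact binomial p = 0.004 at chance 1/3).

`run_pipeline(cfg, out_dir = "out")` runs everything (dynamics,
repeatability, predictions, growth-parameter estimation) and writes
deterministic CSV/JSON artifacts plus a manifest; a second run with the
same configuration reproduces every file byte-for-byte.

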