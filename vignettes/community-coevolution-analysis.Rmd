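---
title: "Assembly rules and repeatability in coevolving bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly rules and repeatability in coevolving bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, estimators and design choices behind
`evoassembly`. The package analyzes replicated serial-dilution coevolution
experiments on two- and three-species bacterial communities: composition
trajectories measured by plating at a subset of growth–dilution transfers,
and plate-reader growth assays of the member strains.

```{r setup, eval = FALSE}
library(evoassembly)
```

## The measurement model

A sample is a composition vector $x$ on the $n$-simplex, estimated from
colony counts $c_i$ of total $N$: $\hat x_i = c_i / N$. The uncertainty of a
plated fraction $p$ is the standard deviation of its posterior Beta
distribution, $\sigma = \sqrt{p(1-p)}/(N+1)$ (`fraction_posterior_sd()`).
Validation flags samples with $N \le 15$, where this SD exceeds ~3 points.

Time is indexed by transfers. One cycle of growth followed by a $D$-fold
dilution forces $\log_2 D$ doublings, so generations per cycle is
$\log_2 D$ — 10.55 for the default $D = 1500$, giving ~400 generations over
38 cycles. Generation anchors such as "generation ~70" are resolved to the
*nearest sampled transfer* (transfer 7, generation 73.9, under the default
schedule), ties to the earlier transfer. We deliberately do not interpolate
compositions between transfers: plating is the measurement unit, and the
sampling grid is coarse enough that interpolation would manufacture
precision.

## Distances, variability, and their nulls

All compositional change is measured with the normalized Euclidean
distance $\Delta(x, y) = \lVert x - y\rVert_2 / \sqrt{n}$. The $\sqrt{n}$
normalization is the convention of the experimental literature this
package serves; the true maximal distance between two points of the
simplex is $\sqrt 2$ for every $n \ge 2$, so $\Delta$ for trios never
reaches 1 (its maximum is $\sqrt{2/3} \approx 0.816$). Every distance-based
function accepts `normalization = "true_max"` for the $\sqrt 2$
alternative; the default stays $\sqrt n$ for comparability.

Replicate variability of a community at a transfer is the mean distance of
its replicates from the **medoid** replicate (the minimizer of summed
distances; ties broken by replicate label). Two conventions exist for the
mean: including the medoid's own zero term or not. The package defaults to
*including* it (a mean over all $k$ replicates); `include_medoid = FALSE`
gives the other. The choice shifts values by a factor $k/(k-1)$ but not
the ordering of communities, and the same convention is applied to the
null, so tests are unaffected.

The random-community null replaces every replicate with an independent
draw from the uniform Dirichlet ($\alpha = 1$) distribution — the maximum
entropy model in which any composition is equally likely. The null is
*matched per community* in species number and replicate count, since the
variability statistic depends on both. Observed-versus-null comparison
uses a one-sided Mann–Whitney U test (alternative: observed smaller).
The U test is implemented with midranks and the mid-p convention
($P(U < u) + \tfrac12 P(U = u)$), exact by enumeration when the pooled
sample has at most 20 values and by the tie-corrected normal
approximation otherwise. Mid-p makes the test well defined under heavy
ties (a single tied pair gives exactly 0.5) and is the convention the
exactness tests assert.

## Repeatability of the maximally increasing member

For each replicate present at both generation anchors (~70 and ~400), the
fold change of each species' relative abundance is computed; the species
with the largest factor is the replicate's maximally increasing member.
Zero fractions are floored before division: with colony counts, by the
plating pseudo-fraction $1/(N+1)$; without counts, by a configurable
pseudo-fraction (default $10^{-3}$). A community's repeatability score is
the frequency of replicates sharing the modal winner, between $1/n$ and 1;
communities with fewer than 3 replicates at either anchor are excluded.

The permutation null pools every (community, replicate, species) fold
change of one size class, reshuffles the pool uniformly without
replacement, reassigns values to slots and recomputes the mean score;
2000 iterations by default. The p-value is the raw frequency of null
means at least as large as the observed mean — exactly the frequency
definition, so 0 is a possible value; `plus_one = TRUE` switches to the
$(b+1)/(m+1)$ estimator. The verbal description "shuffled across all
samples" admits a second reading — permuting whole per-replicate fold
vectors intact — which is available as `shuffle = "vectors"`; the default
is the more literal value-level pool. One master seed derives
per-iteration streams, so any iteration is reproducible in isolation.

Calibration is checked empirically: on data planted at the null
(winner probability $1/n$) the rejection rate at $\alpha = 0.05$ across
500 datasets of 20 pair-communities × 6 replicates stays within
[0.03, 0.07], and the expected null score matches exact enumeration of
modal frequencies of fair labels.

## The pairwise-to-trio assembly rule

The fraction of species $i$ in a trio is predicted to be proportional to
the weighted geometric mean of its fractions in its two pairwise
cocultures:
$$g_i = \prod_{j \ne i} f_{i|ij}^{\,w_{ij}}, \qquad
  \hat f_i = g_i \Big/ \sum_k g_k .$$
The literature does not pin down the weights; the package defaults to
equal weights $w_{ij} = 1/2$ (the plain geometric mean), which preserves
the rule's fixed-point and permutation symmetry and requires no
information beyond the pair outcomes themselves. A `weights` argument
accepts any per-(species, partner) weighting, normalized within species.
Zero pairwise fractions are floored (shared configuration with the
repeatability module) so an excluded species receives a small positive
predicted fraction rather than breaking the product.

Accuracy is $1 - \Delta(\text{prediction}, \text{observation})$ with the
$\sqrt n$ normalization, the observation being the *mean* composition of
the trio replicates at the resolved transfer (a per-replicate diagnostic
mode is available in the sweep's raw table). Four prediction methods are
swept across generations: pairs at the same generation, pairs frozen at
the ecological anchor (~70), species carrying capacities normalized to
fractions (the minimal proportional reading, used because no explicit
transformation is established), and the uninformed $1/n$ guess.

The trio's maximally increasing member is predicted from the pair-level
winners (each pair's winner being the species winning the most
replicates): a species winning both its pairs is the prediction; if every
pair has a different winner ("transient topology"), the species with the
highest mean fold increase across the replicates of both its pairs is
used, and the prediction is flagged. Accuracy is tested with the exact
one-sided binomial tail at chance $1/3$.

## Growth parameters

The growth rate is time-to-threshold based by design, not a model fit:
$r = \log_2(0.08/10^{-4}) / t^\*$ divisions per hour, where $t^\*$ is the
first time the OD reaches 0.08 from inoculation at $10^{-4}$ — lag time is
inside $t^\*$ by construction. The crossing is linearly interpolated
between the bracketing samples, reducing the 10-minute quantization error
to first order; curves never reaching the threshold yield `NA` with a
reason code. Replicates are averaged in two levels — technical replicates
into an evolutionary-replicate value, those into the species value — so
unbalanced technical replication cannot bias the species mean.

Carrying capacity is the end-of-cycle OD of a monoculture, smoothed per
replicate with a centered moving mean (window 3, truncated at the ends)
and averaged across replicates; by default all available cycles enter the
average (a `cycles` argument restricts the window). Dominance prediction
takes the species with the strictly larger criterion ($r$ or $K$); exact
ties are flagged and broken by label, pairs with an undefined criterion
are excluded and reported, and accuracy is tested with the exact
one-sided binomial tail at chance $1/2$. The observed dominant is the
species with mean fraction above $1/2$ across replicates
(`mode = "majority"` offers replicate-majority voting instead).

## The synthetic-data generator

`simulate_serial_dilution()` provides the latent truth the analysis
assumes. Within each 48-h cycle, abundances follow generalized
Lotka–Volterra competition
$$\frac{dx_i}{dt} = x_i r_i \Big(1 - \sum_j a_{ij} x_j / K_i\Big),$$
integrated with an adaptive solver (relative tolerance $10^{-8}$;
abundances below $10^{-12}$ are clamped to zero as extinct), then all
abundances are divided by the dilution factor. This latent model is a
modelling convenience chosen because batch-culture gLV naturally produces
the two-timescale structure the analysis targets — fast convergence to an
ecological equilibrium within a few transfers, then nothing (without
drift) or slow movement (with drift). No analysis function depends on the
choice.

Default generator conditions mirror the bench design the package
emulates: a 16-species pool; 44 pairs and 43 trios with 3–18 replicates
each; 38 cycles of 48 h and 1500-fold dilution; composition observed at
transfers 0, 2, 5, 7, 10, 14, 19, 30, 38 as multinomial colony counts
with per-sample depth uniform on 20–100 (respecting the > 15 colony
floor). Ancestral rates are uniform on 0.3–0.7 h⁻¹, carrying capacities
on 0.3–0.9 OD, off-diagonal competition coefficients on 0.2–0.9 (the
diagonal is 1). The interaction range was chosen so that a random species
pair satisfies the two-species gLV coexistence criterion about 74% of the
time, and — as on the bench, where communities were pre-screened in a
preliminary experiment — pairs are drawn preferentially from coexisting
combinations and trios preferentially from triangles of measured pairs.
Some communities still collapse during the run; the coexistence filter
removes them exactly as it would in real data (63 of 87 communities
survive the default seed-1 run).

Evolution is phenomenological: after the drift onset (transfer 7), each
replicate's parameters random-walk on the log scale toward an attractor,
with per-cycle pull 0.08 and step SD 0.01. Attractors are hierarchical —
a pool-level evolved target per parameter (log-SD 0.35 around the
ancestral value) shared by all communities, a community-level deviation
(log-SD 0.1), and a replicate-level deviation with SD scaled by $1/\kappa$
(default $\kappa = 20$). The shared pool-level target is what couples
evolution in pairs to evolution in trios, so the assembly rule keeps
working under coevolution and pair fold changes carry information about
trio fold changes; $\kappa$ tunes how repeatable replicate evolution is.
These simulated data reproduce the qualitative structure of real
experiments — decelerating compositional change, variability growing
after the ecological phase yet staying far below the Dirichlet null, high
repeatability scores, and same-generation pair predictions outperforming
frozen ecological-generation predictions — but they are not a quantitative
stand-in: real communities have non-logistic dynamics, cross-feeding,
mutational cohorts and measurement artifacts the generator does not
attempt. Passing tests demonstrate correctness of the statistical
machinery under a model with the assumed structure, not field validity of
the assembly rule.

Two shortcut generators support fast statistical tests without the ODE:
`plant_repeatability()` synthesizes anchor compositions whose maximally
increasing member is a planted species with exactly probability $q$
(anchor compositions are Dirichlet draws rescaled by per-species
multipliers whose argmax is the chosen winner), and
`make_consistent_trio()` returns the assembly-rule prediction verbatim as
an observation — a fixed point whose accuracy must be exactly 1.
`simulate_growth_curves()` produces lagged-logistic OD traces
($\mathrm{od}(t) = K / (1 + (K/od_0 - 1)\, 2^{-\max(0, t - \mathrm{lag})/d})$)
with truncated Gaussian noise at 10-minute sampling.

## Numerical and degenerate-input conventions

* Argmax ties (max increaser, dominance): broken by species label order
  and flagged, never silently.
* Exact-tie detection uses a $10^{-12}$ relative band; fraction-sum
  validation uses $10^{-6}$; round-tripping composition tables preserves
  fractions to $10^{-9}$.
* Counts win over an inconsistent fraction column (plating counts are the
  primary record); a warning is recorded.
* Replicates with missing transfers are retained; each operation drops
  only the replicates missing the specific transfer it needs, with a
  warning attribute.
* All resampling takes explicit integer seeds; outputs record them, and
  pipeline artifacts are byte-identical across reruns of the same
  configuration.

## Problem sizes used in the shipped checks

The package's own test battery runs the calibration study at 500 null
datasets of 20 pair-communities × 6 replicates with 2000-iteration
shuffles; planted-recovery at 100 trio-communities × 18 replicates;
Monte-Carlo oracles at $10^6$ draws (brute force) vs $10^4$ draws
(implementation); and the end-to-end determinism check on the full
default simulation. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping the battery
runnable on a laptop in a few minutes.

## Known limitations

* The gLV drift model evolves interaction parameters, not genotypes;
  clonal interference, sweeps and historical contingency are out of
  scope.
* The carrying-capacity prediction method assumes fractions proportional
  to K — a deliberately minimal reading, flagged as such.
* The $\sqrt n$ accuracy normalization bounds trio accuracies below by
  $1 - \sqrt{2}/\sqrt{3} \approx 0.18$, compressing the low end of the
  scale; comparisons across community sizes should use
  `normalization = "true_max"`.
* No multiple-testing correction is applied across communities: the
  design reports one pooled test per size class.
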