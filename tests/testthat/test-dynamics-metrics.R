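test_that("normalized distance matches hand computations and is a metric", {
  expect_equal(normalized_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(normalized_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(normalized_distance(c(0.8, 0.2), c(0.5, 0.5)), 0.3)
  expect_error(normalized_distance(c(1, 0), c(1, 0, 0)), "same length")
  # true-max alternative normalizes by sqrt(2) for any n
  expect_equal(normalized_distance(c(1, 0, 0), c(0, 1, 0),
                                   normalization = "true_max"), 1)

  set.seed(1)
  for (n in 2:4) {
    x <- as.vector(rsimplex(1, n)); y <- as.vector(rsimplex(1, n))
    z <- as.vector(rsimplex(1, n))
    expect_equal(normalized_distance(x, y), normalized_distance(y, x))
    expect_gte(normalized_distance(x, z) + 1e-12,
               normalized_distance(x, y) - normalized_distance(y, z))
    expect_gte(normalized_distance(x, y), 0)
    expect_lte(normalized_distance(x, y), 1)
  }
  # for pairs the normalized distance reduces to |x1 - y1|
  set.seed(2)
  for (i in 1:20) {
    x <- as.vector(rsimplex(1, 2)); y <- as.vector(rsimplex(1, 2))
    expect_equal(normalized_distance(x, y), abs(x[1] - y[1]))
  }
})

test_that("stepwise change profiles track consecutive sampled transfers", {
  transfers <- c(0, 2, 5, 7, 10, 14, 19, 30, 38)
  const <- pair_series("c", transfers, rep(0.4, 9))
  out <- stepwise_change(const)
  expect_equal(nrow(out), 2 * 8)  # 9 transfers -> 8 steps per replicate
  expect_true(all(out$delta == 0))

  jump <- pair_series("j", c(0, 2), c(0.5, 0.8), replicates = "R1")
  expect_equal(stepwise_change(jump)$delta, 0.3)

  single <- pair_series("s", 0, 0.5, replicates = "R1")
  expect_warning(out2 <- stepwise_change(single), "single timepoint")
  expect_equal(nrow(out2), 0)
})

test_that("change from reference uses each replicate's own anchor", {
  transfers <- c(5, 7, 10, 38)
  x <- pair_series("c", transfers, c(0.3, 0.6, 0.6, 0.1),
                   replicates = "R1")
  out <- change_from_reference(x, g_ref = 70)
  expect_equal(attr(out, "reference_transfer"), 7L)
  expect_equal(out$transfer, c(7L, 10L, 38L))
  expect_equal(out$delta, c(0, 0, 0.5))
  # a replicate returning to its reference composition scores 0
  back <- pair_series("b", transfers, c(0.3, 0.6, 0.2, 0.6),
                      replicates = "R1")
  expect_equal(tail(change_from_reference(back, g_ref = 70)$delta, 1), 0)
  # missing reference -> replicate skipped with warning
  x2 <- dplyr::bind_rows(x, pair_series("c", c(10, 38), c(0.5, 0.5),
                                        replicates = "R9"))
  expect_warning(out2 <- change_from_reference(x2, g_ref = 70), "skipped")
  expect_false("R9" %in% out2$replicate)
})

test_that("medoid replicate agrees with an exhaustive oracle", {
  one <- tibble::tibble(replicate = "R1", species = c("A", "B"),
                        fraction = c(0.5, 0.5))
  expect_equal(medoid_replicate(one), "R1")

  collinear <- tibble::tibble(
    replicate = rep(c("R1", "R2", "R3"), each = 2),
    species = rep(c("A", "B"), 3),
    fraction = c(0.1, 0.9, 0.5, 0.5, 0.9, 0.1))
  expect_equal(medoid_replicate(collinear), "R2")

  # exhaustive O(k^2) oracle over random replicate sets
  oracle_medoid <- function(m) {
    sums <- sapply(seq_len(nrow(m)), function(i) {
      sum(sapply(seq_len(nrow(m)), function(j) sqrt(sum((m[i, ] - m[j, ])^2))))
    })
    which.min(sums)
  }
  set.seed(3)
  for (i in 1:100) {
    m <- rsimplex(5, 3)
    df <- tibble::tibble(
      replicate = rep(sprintf("R%d", 1:5), each = 3),
      species = rep(c("A", "B", "C"), 5),
      fraction = as.vector(t(m)))
    expect_equal(medoid_replicate(df), sprintf("R%d", oracle_medoid(m)))
  }
})

test_that("replicate variability behaves as mean distance from medoid", {
  same <- tibble::tibble(replicate = rep(c("R1", "R2", "R3"), each = 2),
                         species = rep(c("A", "B"), 3),
                         fraction = rep(c(0.3, 0.7), 3))
  expect_equal(replicate_variability(same)$variability, 0)

  two <- tibble::tibble(replicate = rep(c("R1", "R2"), each = 2),
                        species = rep(c("A", "B"), 2),
                        fraction = c(1, 0, 0, 1))
  # include-medoid convention: mean of {0, 1}
  expect_equal(replicate_variability(two)$variability, 0.5)
  expect_equal(replicate_variability(two, include_medoid = FALSE)$variability,
               1)

  outlier <- tibble::tibble(
    replicate = rep(sprintf("R%d", 1:5), each = 2),
    species = rep(c("A", "B"), 5),
    fraction = c(rep(c(0.5, 0.5), 4), 0.9, 0.1))
  v <- replicate_variability(outlier)$variability
  expect_gt(v, 0)
  expect_lt(v, 0.4)  # below the outlier's own distance

  # invariance under relabeling of replicates
  relabeled <- outlier |>
    dplyr::mutate(replicate = c(R1 = "Z9", R2 = "Z8", R3 = "Z7",
                                R4 = "Z6", R5 = "Z5")[replicate])
  expect_equal(replicate_variability(relabeled)$variability, v)
  expect_error(replicate_variability(dplyr::filter(outlier,
                                                   replicate == "R1")),
               ">= 2 replicates")
})

test_that("Dirichlet null variability is reproducible and unbiased", {
  expect_error(dirichlet_null_variability(2, 1, 10), ">= 2")
  a <- dirichlet_null_variability(2, 3, 500, seed = 11)
  b <- dirichlet_null_variability(2, 3, 500, seed = 11)
  expect_identical(a, b)

  # independent Monte-Carlo oracle: for 3 replicates of a 2-species
  # community the variability is (max - min)/3 of three iid U(0,1) draws
  set.seed(99)
  m <- matrix(runif(3 * 2e5), ncol = 3)
  oracle <- (apply(m, 1, max) - apply(m, 1, min)) / 3
  x <- dirichlet_null_variability(2, 3, 10000, seed = 12)
  se <- sqrt(var(x) / length(x) + var(oracle) / length(oracle))
  expect_lt(abs(mean(x) - mean(oracle)), 3 * se)
})

test_that("one-sided Mann-Whitney test has the stated tie conventions", {
  # clearly separated samples: exact enumeration gives a tiny p
  r <- variability_vs_null_test(rep(0, 8), seq(0.1, 0.8, by = 0.1))
  expect_lt(r$p_value, 0.01)
  expect_equal(r$statistic, 0)

  # identical samples are symmetric
  expect_equal(variability_vs_null_test(1:9 / 10, 1:9 / 10)$p_value, 0.5,
               tolerance = 1e-12)
  # single tied pair: midrank mid-p convention gives exactly 0.5
  expect_equal(variability_vs_null_test(0.3, 0.3)$p_value, 0.5)

  # tie-free exact case: mid-p lies between P(U < u) and P(U <= u),
  # bracketed by wilcox.test run both ways as an independent oracle
  set.seed(4)
  x <- runif(6); y <- runif(7) + 0.2
  mine <- variability_vs_null_test(x, y)$p_value
  p_le <- wilcox.test(x, y, alternative = "less", exact = TRUE)$p.value
  p_lt <- 1 - wilcox.test(x, y, alternative = "greater",
                          exact = TRUE)$p.value
  expect_gte(mine, p_lt - 1e-12)
  expect_lte(mine, p_le + 1e-12)
  expect_equal(mine, (p_lt + p_le) / 2, tolerance = 1e-9)

  # large samples use the normal approximation and stay close to wilcox
  set.seed(5)
  x2 <- runif(30); y2 <- runif(40) + 0.1
  mine2 <- variability_vs_null_test(x2, y2)$p_value
  ref <- wilcox.test(x2, y2, alternative = "less", exact = FALSE,
                     correct = FALSE)$p.value
  expect_equal(mine2, ref, tolerance = 1e-6)
  expect_error(variability_vs_null_test(numeric(0), 1), "non-empty")

  # broom-style accessors
  expect_named(tidy(r), c("statistic", "p.value", "method", "alternative"))
  expect_equal(glance(r)$n.observed, 8)
})

test_that("variability profile summarizes communities across transfers", {
  set.seed(6)
  transfers <- c(0, 7, 38)
  x <- purrr::map_dfr(sprintf("R%d", 1:4), function(rep) {
    purrr::map_dfr(transfers, function(t) {
      sample_rows("c1", rep, t,
                  setNames(as.vector(rsimplex(1, 2)), c("A", "B")))
    })
  })
  prof <- variability_profile(x)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$n_replicates, rep(4L, 3))
  expect_equal(prof$generation, transfers * log2(1500))
  expect_true(all(prof$variability >= 0 & prof$variability <= 1))
})
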