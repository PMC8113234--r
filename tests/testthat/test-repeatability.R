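test_that("fold changes are ratios of floored fractions at the anchors", {
  x <- pair_series("p", c(7, 38), c(0.5, 0.8), replicates = "R1")
  fc <- fold_changes(x)
  expect_equal(fc$fold, c(1.6, 0.4))

  same <- pair_series("p", c(7, 38), c(0.4, 0.4), replicates = "R1")
  expect_equal(fold_changes(same)$fold, c(1, 1))

  # zero fraction floored by 1/(total colonies + 1) when counts exist
  counts <- dplyr::bind_rows(
    sample_rows("p", "R1", 7, c(A = 0.5, B = 0.5), counts = c(25, 25)),
    sample_rows("p", "R1", 38, c(A = 1, B = 0), counts = c(49, 0)))
  fcc <- fold_changes(counts)
  expect_true(all(is.finite(fcc$fold) & fcc$fold > 0))
  expect_equal(fcc$fold[fcc$species == "B"], (1 / 50) / 0.5)

  # no counts: configurable pseudo-fraction
  frac0 <- dplyr::bind_rows(
    sample_rows("p", "R1", 7, c(A = 0.5, B = 0.5)),
    sample_rows("p", "R1", 38, c(A = 1, B = 0)))
  expect_equal(fold_changes(frac0, floor = 1e-3)$fold[2], 1e-3 / 0.5)

  # replicates missing an anchor are excluded and reported
  x2 <- dplyr::bind_rows(x, pair_series("p", 7, 0.5, replicates = "R9"))
  expect_warning(fc2 <- fold_changes(x2), "excluded")
  expect_equal(attr(fc2, "excluded")$replicate, "R9")
  expect_error(fold_changes(x, g1 = 400, g2 = 70), "earlier")
})

test_that("max increaser takes the argmax with label-order tie-break", {
  expect_equal(max_increaser(c(A = 1.6, B = 0.4))$species, "A")
  tie <- max_increaser(c(B = 1, A = 1))
  expect_equal(tie$species, "A")
  expect_true(tie$tie)
  expect_equal(max_increaser(c(A = 0.9, B = 1.1, C = 3.0))$species, "C")
  expect_error(max_increaser(c(A = 1)), ">= 2")
  expect_error(max_increaser(c(A = Inf, B = 1)), "finite")
})

test_that("repeatability score is the modal winner frequency in [1/n, 1]", {
  mk <- function(winners, n_species = 2) {
    species <- LETTERS[seq_len(n_species)]
    purrr::map_dfr(seq_along(winners), function(i) {
      fold <- setNames(rep(0.5, n_species), species)
      fold[winners[i]] <- 2
      tibble::tibble(community = "c", replicate = sprintf("R%02d", i),
                     species = species, fold = fold)
    })
  }
  expect_equal(repeatability_score(mk(rep("A", 6)))$score, 1)
  expect_equal(repeatability_score(mk(c("A", "A", "B", "B")))$score, 0.5)
  expect_equal(
    repeatability_score(mk(c("A", "A", "A", "B", "C", "A"), 3))$score,
    4 / 6)

  few <- repeatability_score(mk(c("A", "B")))
  expect_equal(nrow(few), 0)
  expect_match(attr(few, "excluded")$reason, "2 replicate")

  # property: score always within [1/n, 1]
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:3, 1)
    winners <- sample(LETTERS[1:n], sample(3:12, 1), replace = TRUE)
    s <- repeatability_score(mk(winners, n))$score
    expect_gte(s, 1 / n)
    expect_lte(s, 1)
  }
})

test_that("planted winner probability is recovered via modal-frequency enumeration", {
  # exact expectation of the modal frequency of k iid winners where the
  # planted species wins with probability q and the rest split evenly
  modal_expectation <- function(k, n, q) {
    probs <- c(q, rep((1 - q) / (n - 1), n - 1))
    counts <- expand.grid(rep(list(0:k), n))
    counts <- counts[rowSums(counts) == k, , drop = FALSE]
    sum(apply(counts, 1, function(cc) {
      dmultinom(cc, k, probs) * max(cc) / k
    }))
  }
  # null pairs (q = 1/2): observed mean score matches the fair-label
  # enumeration for k = 6 replicates
  planted <- plant_repeatability(n_communities = 150, n_species = 2,
                                 n_replicates = 6, q = 0.5, seed = 21)
  folds <- fold_changes(planted)
  scores <- repeatability_score(folds)$score
  expected <- modal_expectation(6, 2, 0.5)
  expect_lt(abs(mean(scores) - expected),
            3 * sd(scores) / sqrt(length(scores)))
})

test_that("shuffle null conserves structure and flags planted repeatability", {
  planted <- plant_repeatability(n_communities = 20, n_species = 2,
                                 n_replicates = 6, q = 1, seed = 31)
  folds <- fold_changes(planted)
  sn <- shuffle_null(folds, iterations = 200, seed = 5)
  expect_equal(sn$observed_mean, 1)
  expect_equal(sn$p_value, 0)
  expect_length(sn$null_means, 200)
  # null means stay within the score range
  expect_true(all(sn$null_means >= 0.5 & sn$null_means <= 1))

  # reproducible under the same master seed
  sn2 <- shuffle_null(folds, iterations = 200, seed = 5)
  expect_identical(sn$null_means, sn2$null_means)

  # one iteration gives a frequency p-value in {0, 1}
  sn1 <- shuffle_null(folds, iterations = 1, seed = 6)
  expect_true(sn1$p_value %in% c(0, 1))

  # plus-one estimator never returns zero
  snp <- shuffle_null(folds, iterations = 50, seed = 7, plus_one = TRUE)
  expect_equal(snp$p_value, 1 / 51)

  # mixing size classes is an error
  trio <- plant_repeatability(n_communities = 4, n_species = 3,
                              n_replicates = 6, q = 1, seed = 8)
  mixed <- dplyr::bind_rows(folds,
                            fold_changes(trio) |>
                              dplyr::mutate(community = paste0("t", community)))
  expect_error(shuffle_null(mixed), "same number of species")

  # broom-style accessors
  expect_equal(nrow(tidy(sn)), 20)
  expect_equal(glance(sn)$observed_mean, 1)
})

test_that("expected null score for pairs matches fair-label enumeration", {
  # Under the shuffle null each replicate's winner is essentially a fair
  # coin; compare the null-mean distribution against exact enumeration of
  # modal frequencies of k iid fair labels, k = 6.
  exact <- sum(sapply(0:6, function(x) {
    dbinom(x, 6, 0.5) * max(x, 6 - x) / 6
  }))
  planted <- plant_repeatability(n_communities = 40, n_species = 2,
                                 n_replicates = 6, q = 0.5, seed = 41)
  sn <- shuffle_null(fold_changes(planted), iterations = 500, seed = 9)
  # mean of null means estimates the expectation across 40 communities
  se <- sd(sn$null_means) / sqrt(length(sn$null_means))
  expect_lt(abs(mean(sn$null_means) - exact), 4 * se + 0.005)
})

test_that("observed-vs-null report applies the significance tier convention", {
  fake <- function(p, n_sp = 2) {
    structure(list(scores = tibble::tibble(), observed_mean = 0.9,
                   null_means = rep(0.65, 100), p_value = p,
                   iterations = 100, seed = 1, shuffle = "values",
                   n_species = n_sp, n_communities = 10),
              class = "shuffle_null")
  }
  rep <- observed_vs_null_report(fake(0.2), fake(0.004, 3))
  expect_equal(rep$tier, c("", "**"))
  expect_equal(observed_vs_null_report(fake(0.05))$tier, "*")
  expect_equal(rep$size_class, c("2-species", "3-species"))
})
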