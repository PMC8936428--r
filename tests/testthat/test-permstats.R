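# Permutation inference, effect sizes, FDR, correlation screening and the
# predictor-selection rule.

test_that("exact permutation test enumerates and counts correctly", {
  res <- exact_permutation_ttest(c(1, 2), c(3, 4))
  expect_equal(res$n_assignments, 6)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$t, -2 * sqrt(2), tolerance = 1e-12)
  # identical multisets: every assignment ties or exceeds
  res2 <- exact_permutation_ttest(c(1, 5, 9), c(9, 1, 5))
  expect_equal(res2$p_value, 1)
  # the published design size
  res3 <- exact_permutation_ttest(rnorm(7), rnorm(5))
  expect_equal(res3$n_assignments, choose(12, 7))
  # deterministic: no RNG involved
  a <- runif(6); b <- runif(5)
  expect_identical(exact_permutation_ttest(a, b),
                   exact_permutation_ttest(a, b))
  expect_error(exact_permutation_ttest(1, c(2, 3)), "at least 2")
  expect_error(exact_permutation_ttest(rnorm(15), rnorm(15),
                                       max_assignments = 1000),
               "Monte-Carlo")
})

test_that("degenerate permutations follow the infinite-t convention", {
  # constant groups with different means: only the observed split and its
  # mirror reach |t| = Inf
  res <- exact_permutation_ttest(c(1, 1, 1), c(2, 2, 2))
  expect_equal(res$p_value, 2 / choose(6, 3))
})

test_that("Hedges' g matches its closed form and is antisymmetric", {
  expect_equal(hedges_g(c(1, 2, 3), c(4, 5, 6)), -2.4)
  a <- rnorm(6); b <- rnorm(8)
  expect_equal(hedges_g(a, b), -hedges_g(b, a))
  expect_equal(hedges_g(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "undefined")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(2)
  p <- runif(25)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  # the smallest raw p attains the smallest adjusted value
  expect_equal(adj[which.min(p)], min(adj))
  # monotone: adjusted order never contradicts raw order
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("Spearman rho is rank-based", {
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
  expect_equal(spearman_rho(x, -y), -spearman_rho(x, y))
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
})

test_that("the permutation correlation test is seeded and calibrated", {
  x <- rnorm(12); y <- rnorm(12)
  r1 <- permutation_corr_test(x, y, n_perm = 500, seed = 11)
  r2 <- permutation_corr_test(x, y, n_perm = 500, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$seed, 11L)
  # strictly monotone pair of length 12: only exact re-orderings tie rho = 1
  mono <- permutation_corr_test(1:12, (1:12)^2, n_perm = 5000, seed = 3)
  expect_lte(mono$p_value, 0.001)
  expect_warning(permutation_corr_test(x, y, n_perm = 50, seed = 1),
                 "small")
})

test_that("predictor selection intersects the two screens in fixed order", {
  sel <- select_pls_inputs(reported_discriminative_networks(),
                           reported_significant_pairs())
  expect_equal(nrow(sel), 20)
  expect_equal(as.integer(table(sel$band)), c(9L, 5L, 3L, 3L))
  # deterministic ordering: band then pair label
  expect_equal(sel, dplyr::arrange(sel, band, pair))
  # pairs outside discriminative networks are dropped
  expect_false("C4-Cz" %in% sel$pair)

  expect_warning(
    empty <- select_pls_inputs(
      reported_discriminative_networks()[0, ],
      reported_significant_pairs()
    ),
    "No predictors"
  )
  expect_equal(nrow(empty), 0)

  one <- select_pls_inputs(
    tibble::tibble(band = "beta", network = "ContraLHemi"),
    tibble::tibble(band = "beta", electrode_a = "C3", electrode_b = "FC3")
  )
  expect_equal(one$pair, "C3-FC3")
})

test_that("group comparisons report every band-network cell with FDR", {
  set.seed(4)
  nets <- tidyr::crossing(
    subject_id = sprintf("s%02d", 1:12),
    band = coh_bands()$band,
    network = unique(network_pairs()$network)
  )
  nets$value <- runif(nrow(nets))
  labels <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    recovery = factor(rep(c("good", "poor"), c(7, 5)),
                      levels = c("good", "poor"))
  )
  rep <- group_comparison_report(nets, labels)
  expect_equal(nrow(rep), 20)
  expect_true(all(rep$n_assignments == choose(12, 7)))
  expect_true(all(rep$p_fdr >= rep$p_perm))
  # degenerate class sizes degrade to NA rows with a warning
  labels2 <- labels
  labels2$recovery[2:12] <- "poor"
  expect_warning(rep2 <- group_comparison_report(nets, labels2),
                 "Fewer than 2")
  expect_true(all(is.na(rep2$p_perm)))
})
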