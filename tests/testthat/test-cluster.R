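test_that("a strong uniform effect forms one map-wide cluster with minimal p", {
  set.seed(41)
  maps <- matrix(2 + 0.05 * rnorm(15 * 30), 15, 30)
  ct <- cluster_permutation_test(maps, chance = 0, n_perm = 200, seed = 1)
  expect_equal(nrow(ct$clusters), 1)
  expect_equal(sum(ct$clusters$mask[[1]]), 30)  # covers the whole map
  expect_lte(ct$clusters$p_value[1], 2 / 201)
  expect_true(ct$clusters$significant[1])
})

test_that("cluster masks recover a planted effect block (2-D, 4-connectivity)", {
  set.seed(42)
  arr <- array(rnorm(12 * 30 * 25), c(12, 30, 25))
  arr[, 8:16, 5:14] <- arr[, 8:16, 5:14] + 1.3
  ct <- cluster_permutation_test(arr, chance = 0, n_perm = 300, seed = 2)
  truth <- array(FALSE, c(30, 25)); truth[8:16, 5:14] <- TRUE
  best <- ct$clusters$mask[[1]]
  expect_gt(sum(best & truth) / sum(best | truth), 0.5)
  expect_lt(ct$clusters$p_value[1], 0.05)
  # negative effects form separate clusters
  arr2 <- arr; arr2[, 25:30, 20:25] <- arr2[, 25:30, 20:25] - 2.5
  ct2 <- cluster_permutation_test(arr2, chance = 0, n_perm = 300, seed = 2)
  expect_true(any(ct2$clusters$sign < 0 & ct2$clusters$significant))
})

test_that("masks depend on the data, not on the permutations", {
  set.seed(43)
  maps <- matrix(rnorm(8 * 40) + rep(c(0, 1.2, 0), c(10, 12, 18))[col(matrix(0, 8, 40))],
                 8, 40)
  ct1 <- cluster_permutation_test(maps, 0, n_perm = 50, seed = 9)
  ct2 <- cluster_permutation_test(maps, 0, n_perm = 400, seed = 10)
  expect_identical(ct1$clusters$mask, ct2$clusters$mask)
  expect_identical(ct1$clusters$mass, ct2$clusters$mass)
  # p resolution changes with n_perm
  expect_gte(min(ct1$clusters$p_value), 1 / 51)
  # determinism under a fixed seed
  ct3 <- cluster_permutation_test(maps, 0, n_perm = 400, seed = 10)
  expect_identical(ct2$null_positive, ct3$null_positive)
  expect_identical(tidy(ct2), tidy(ct3))
})

test_that("input contracts are enforced", {
  expect_error(cluster_permutation_test(matrix(1, 1, 10), 0), "2 subjects")
  expect_error(cluster_permutation_test(array(1, c(2, 2, 2, 2)), 0), "2-D")
  expect_error(cluster_permutation_test(data.frame(a = 1), 0), "matrix")
})

test_that("cross-section test averages the training window then tests 1-D", {
  # constant surfaces: result equals the scalar t test broadcast over time
  tt <- seq(0, 1, by = 0.25)
  subj_val <- c(0.5, 0.45, 0.55, 0.5, 0.52, 0.48)
  tg <- tidyr::expand_grid(subject = 1:6, train_time = tt, test_time = tt)
  tg$posterior <- subj_val[tg$subject]
  tg$n_trials <- 10
  tg <- structure(tg, chance = NULL, measure = "posterior",
                  class = c("tg_tbl", class(tg)))
  ct <- test_crosssection(tg, c(0, 1), chance = 1 / 3, n_perm = 100,
                          seed = 4)
  tref <- unname(t.test(subj_val, mu = 1 / 3)$statistic)
  expect_equal(as.vector(ct$t_observed), rep(tref, length(tt)),
               tolerance = 1e-12)
  expect_equal(sum(ct$clusters$mask[[1]]), length(tt))
  expect_error(test_crosssection(tg, c(5, 6), chance = 1 / 3), "no training")
  expect_error(test_crosssection(tg, c(0, 1), chance = 1 / 3,
                                 rotation = 60), "rotation_deg")
})

test_that("type-I error and power behave sensibly at small scale", {
  # null maps: false-positive rate near the nominal level (light version of
  # the full calibration in the acceptance suite)
  set.seed(44)
  fp <- replicate(60, {
    maps <- matrix(rnorm(10 * 25), 10, 25)
    ct <- cluster_permutation_test(maps, 0, n_perm = 150,
                                   seed = sample.int(1e6, 1))
    any(ct$clusters$significant)
  })
  expect_lt(mean(fp), 0.2)
  # p decreases with effect size (paired: same noise, growing shift)
  noise <- matrix(rnorm(10 * 25), 10, 25)
  ps <- sapply(c(0.3, 0.8, 1.6), function(eff) {
    ct <- cluster_permutation_test(noise + eff, 0, n_perm = 300, seed = 5)
    min(c(ct$clusters$p_value, 1))
  })
  expect_true(all(diff(ps) <= 0))
})
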