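test_that("pooled positive-test probability matches direct arithmetic", {
  expect_equal(pool_positive_prob(0, 3), 0)
  expect_equal(pool_positive_prob(0.5, 2), 0.75)
  expect_equal(pool_positive_prob(0.2, 2, assay_model(0.9, 0.95)),
               0.9 * 0.36 + 0.05 * 0.64)
  expect_equal(pool_positive_prob(1, 4), 1)
  expect_error(pool_positive_prob(1.2, 2), "\\[0, 1\\]")
})

test_that("closed-form MLE matches hand results and flags boundaries", {
  # all-negative batch: boundary at zero, no Wald variance
  est0 <- estimate_prevalence(make_batch(10, 0, 3))
  expect_equal(est0$q_hat, 0)
  expect_true(est0$boundary)
  expect_true(is.na(est0$variance))

  # 4/10 positive pools of size 2: q = 1 - sqrt(0.6)
  est <- estimate_prevalence(make_batch(10, 4, 2))
  expect_equal(est$q_hat, 1 - sqrt(0.6), tolerance = 1e-12)
  expect_false(est$boundary)
  expect_gt(est$variance, 0)
  expect_equal(est$assay_count, 10L)

  # grid-search oracle agreement on the same single-size batch
  expect_equal(est$q_hat, grid_search_mle(make_batch(10, 4, 2)),
               tolerance = 1e-4)

  expect_error(estimate_prevalence(make_batch(0, 0, 2)), "empty")
})

test_that("mixed-pool-size MLE agrees with dense grid search", {
  batch <- rbind(make_batch(5, 2, 2), make_batch(5, 3, 3))
  est <- estimate_prevalence(batch)
  expect_equal(est$q_hat, grid_search_mle(batch), tolerance = 1e-4)

  # explicit Se = Sp = 1 takes the identical code path as the default
  est_explicit <- estimate_prevalence(batch, assay_model(1, 1))
  expect_identical(est$q_hat, est_explicit$q_hat)
  expect_identical(est$variance, est_explicit$variance)
})

test_that("MLE matches the grid-search oracle over random batches", {
  set.seed(4021)
  for (i in 1:200) {
    n_sizes <- sample(1:3, 1)
    sizes <- sample(1:4, n_sizes)
    se <- stats::runif(1, 0.8, 1)
    sp <- stats::runif(1, 0.85, 1)
    q <- stats::runif(1, 0.02, 0.9)
    batch <- do.call(rbind, lapply(sizes, function(k) {
      m <- sample(5:30, 1)
      pi_ <- pool_positive_prob(q, k, assay_model(se, sp))
      make_batch(m, stats::rbinom(1, m, pi_), k)
    }))
    est <- estimate_prevalence(batch, assay_model(se, sp))
    oracle <- grid_search_mle(batch, se, sp)
    expect_lt(abs(est$q_hat - oracle), 1e-3)
  }
})

test_that("observed p-hat outside the assay range clips with a flag", {
  # 9/10 positive with Se = 0.8: p-hat = 0.9 > Se, so q-hat clips to 1
  est <- estimate_prevalence(make_batch(10, 9, 2), assay_model(0.8, 0.95))
  expect_equal(est$q_hat, 1)
  expect_true(est$boundary)
})

test_that("per-assay Fisher information matches analytic and numeric oracles", {
  expect_equal(per_assay_fisher_info(0.5, 1), 4)
  expect_equal(per_assay_fisher_info(0.5, 2), 16 / 3)
  # numeric-differentiation oracle of the expected log-likelihood
  for (case in list(c(0.24, 4), c(0.1, 3), c(0.6, 2))) {
    expect_equal(per_assay_fisher_info(case[1], case[2]),
                 numeric_fisher_info(case[1], case[2]), tolerance = 1e-5)
  }
  expect_equal(per_assay_fisher_info(0.3, 2, assay_model(0.9, 0.95)),
               numeric_fisher_info(0.3, 2, 0.9, 0.95), tolerance = 1e-5)
  expect_error(per_assay_fisher_info(0, 2), "strictly inside")
  expect_error(per_assay_fisher_info(1, 2), "strictly inside")
})

test_that("expected and observed information variances agree at the MLE", {
  batch <- rbind(make_batch(40, 11, 2), make_batch(40, 16, 3))
  v_e <- estimate_prevalence(batch, variance = "expected")$variance
  v_o <- estimate_prevalence(batch, variance = "observed")$variance
  expect_equal(v_e, v_o, tolerance = 0.2)
  expect_gt(v_o, 0)
})

test_that("empirical variance of the MLE tracks inverse Fisher information", {
  q <- 0.24; k <- 2; m <- 2000; nrep <- 1000
  pi_ <- pool_positive_prob(q, k)
  set.seed(515)
  s <- stats::rbinom(nrep, m, pi_)
  q_hat <- 1 - (1 - s / m)^(1 / k)
  pred <- 1 / (m * per_assay_fisher_info(q, k))
  expect_lt(abs(stats::var(q_hat) / pred - 1), 0.10)
})

test_that("the pooled MLE recovers the true prevalence on average", {
  q <- 0.24; k <- 3; m <- 1000; nrep <- 1000
  pi_ <- pool_positive_prob(q, k)
  set.seed(661)
  q_hat <- vapply(stats::rbinom(nrep, m, pi_), function(s)
    estimate_prevalence(make_batch(m, s, k))$q_hat, numeric(1))
  mc_se <- stats::sd(q_hat) / sqrt(nrep)
  expect_lt(abs(mean(q_hat) - q), 3 * mc_se)
})

test_that("optimal pool size follows the information crossovers", {
  expect_equal(optimal_pool_size(0.70, 4), 1L)
  expect_equal(optimal_pool_size(0.50, 4), 2L)
  expect_equal(optimal_pool_size(0.40, 4), 3L)
  expect_equal(optimal_pool_size(0.30, 4), 4L)

  ic <- info_crossovers(6)
  # crossover prevalences strictly decrease with pool size
  expect_true(all(diff(ic$crossovers$crossover) < 0))
  expect_true(all(ic$info >= 0))
  # analytic roots: I1 = I2 at 2/3; I2 = I3 at the root of 5u^2 + 5u - 4;
  # I3 = I4 at the root of 7u^3 + 7u^2 + 7u - 9 (u = 1 - q)
  expect_equal(ic$crossovers$crossover[1], 2 / 3, tolerance = 1e-9)
  expect_equal(ic$crossovers$crossover[2], 1 - (-5 + sqrt(105)) / 10,
               tolerance = 1e-9)
  u3 <- Re(polyroot(c(-9, 7, 7, 7)))[abs(Im(polyroot(c(-9, 7, 7, 7)))) < 1e-9]
  expect_equal(ic$crossovers$crossover[3], 1 - u3, tolerance = 1e-9)
})
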