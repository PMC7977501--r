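test_that("Bayes conversion recovers response rates and conserves margins", {
  # marker independent of outcome: both response rates equal r
  cp <- bayes_convert_prognostic(0.3, 0.3, 40, 60)
  expect_equal(cp$p1, 0.4)
  expect_equal(cp$p0, 0.4)

  cp2 <- bayes_convert_prognostic(0.3, 0.2, 50, 50)
  expect_equal(cp2$p1, 0.6)
  expect_equal(cp2$p0, 7 / 15)
  expect_equal(cp2$p1 * cp2$w + cp2$p0 * (1 - cp2$w), cp2$r,
               tolerance = 1e-12)

  # perfect separation
  cp3 <- bayes_convert_prognostic(1, 0, 40, 60)
  expect_equal(cp3$p1, 1)
  expect_equal(cp3$p0, 0)

  expect_error(bayes_convert_prognostic(0, 0, 50, 50), "degenerate")
  expect_error(bayes_convert_prognostic(1, 1, 50, 50), "degenerate")
})

test_that("Bayes conversion round-trips the algebraic inverse", {
  # forward map from cell probabilities p_tx to stratum prevalences q_ty
  set.seed(88)
  for (i in 1:20) {
    p <- stats::runif(4, 0.1, 0.9)  # p11, p10, p01, p00
    w <- stats::runif(2, 0.1, 0.9)  # marker prevalence per arm
    n_arm <- c(400, 300)
    q_of <- function(p_x1, p_x0, w) {
      r <- p_x1 * w + p_x0 * (1 - w)
      c(q1 = p_x1 * w / r, q0 = (1 - p_x1) * w / (1 - r), r = r)
    }
    a1 <- q_of(p[1], p[2], w[1]); a0 <- q_of(p[3], p[4], w[2])
    cells <- bayes_convert_predictive(
      a1[["q1"]], a1[["q0"]], a0[["q1"]], a0[["q0"]],
      n11 = a1[["r"]] * n_arm[1], n10 = (1 - a1[["r"]]) * n_arm[1],
      n01 = a0[["r"]] * n_arm[2], n00 = (1 - a0[["r"]]) * n_arm[2])
    expect_equal(c(cells$p11, cells$p10, cells$p01, cells$p00), p,
                 tolerance = 1e-12)
  }
})

test_that("association and interaction measures follow their definitions", {
  for (lk in c("logit", "log", "identity"))
    expect_equal(association_measure(list(p1 = 0.37, p0 = 0.37), lk), 0)
  expect_equal(association_measure(list(p1 = 0.6, p0 = 0.4), "logit"),
               2 * log(1.5), tolerance = 1e-12)
  expect_equal(association_measure(list(p1 = 0.6, p0 = 0.4), "log"),
               log(1.5), tolerance = 1e-12)
  expect_equal(association_measure(list(p1 = 0.6, p0 = 0.4), "identity"),
               0.2)
  # logit-link measure is the log cross-product odds ratio
  expect_equal(association_measure(list(p1 = 0.6, p0 = 0.4), "logit"),
               log((0.6 * 0.6) / (0.4 * 0.4)), tolerance = 1e-12)

  cells <- list(p11 = 0.7, p10 = 0.5, p01 = 0.6, p00 = 0.5)
  expect_equal(interaction_coefficient(cells, "identity"), 0.1,
               tolerance = 1e-12)
  for (lk in c("logit", "log", "identity")) {
    expect_equal(interaction_coefficient(cells, lk),
                 association_measure(list(p1 = cells$p11, p0 = cells$p10), lk) -
                   association_measure(list(p1 = cells$p01, p0 = cells$p00), lk))
    same <- list(p11 = 0.4, p10 = 0.4, p01 = 0.4, p00 = 0.4)
    expect_equal(interaction_coefficient(same, lk), 0)
  }
  expect_error(association_measure(list(p1 = 0, p0 = 0.4), "logit"),
               "boundary")
})

test_that("standard estimator matches the textbook 2x2 closed form", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  x <- c(rep(1, 100), rep(0, 100))
  td <- trial_data(outcome = y, marker = x)
  est <- estimate_standard(td, "logit")
  expect_equal(est$estimate, log(30 * 80 / (70 * 20)), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)

  # equal rates give zero under every link
  y2 <- c(rep(1, 30), rep(0, 70), rep(1, 30), rep(0, 70))
  td2 <- trial_data(outcome = y2, marker = x)
  for (lk in c("logit", "log", "identity"))
    expect_equal(estimate_standard(td2, lk)$estimate, 0)

  # empty marker group errors unless the continuity correction is on
  td3 <- trial_data(outcome = c(1, 0, 1), marker = c(1, 1, 1))
  expect_error(estimate_standard(td3, "identity"), "empty")
  expect_no_error(estimate_standard(td3, "identity", correction = TRUE))
})

test_that("standard estimator equals the saturated regression fit", {
  td <- make_predictive_trial(400, 0.3,
                              c(p11 = 0.65, p10 = 0.45, p01 = 0.5, p00 = 0.5),
                              seed = 301)
  rec <- td$records
  fit_logit <- stats::glm(outcome ~ treatment * marker, data = rec,
                          family = stats::binomial("logit"))
  expect_equal(estimate_standard(td, "logit")$estimate,
               unname(stats::coef(fit_logit)["treatment:marker"]),
               tolerance = 1e-6)
  # saturated OLS fits the cell means, so its interaction term is the
  # identity-link difference in differences
  fit_lm <- stats::lm(outcome ~ treatment * marker, data = rec)
  expect_equal(estimate_standard(td, "identity")$estimate,
               unname(stats::coef(fit_lm)["treatment:marker"]),
               tolerance = 1e-10)
})

test_that("swapping marker labels negates every association measure", {
  td <- make_prognostic_trial(300, 0.3, 0.6, 0.45, seed = 17)
  flipped <- trial_data(outcome = td$records$outcome,
                        marker = 1L - td$records$marker)
  for (lk in c("logit", "log", "identity")) {
    expect_equal(estimate_standard(td, lk)$estimate,
                 -estimate_standard(flipped, lk)$estimate, tolerance = 1e-12)
  }
})

test_that("pooled estimator with pool size 1 and full budget is the standard estimator", {
  td <- make_prognostic_trial(300, 0.3, 0.6, 0.4, seed = 42)
  plan <- allocate_pools(td, budget = 300, pool_size = 1, seed = 1)
  batch <- assay_pools(plan, td)
  for (lk in c("logit", "log", "identity")) {
    from_pools <- estimate_from_pools(td, batch, lk)
    standard <- estimate_standard(td, lk)
    expect_equal(from_pools$estimate, standard$estimate, tolerance = 1e-12)
    expect_equal(from_pools$se, standard$se, tolerance = 1e-8)
  }
})

test_that("logit-link pooled estimate depends on the data only through the q's", {
  # the odds ratio identity OR = q1 (1 - q0) / {q0 (1 - q1)} makes the
  # point estimate invariant to the outcome split r
  batch <- rbind(
    cbind(make_batch(30, 12, 2), stratum_outcome = 1L, pool_id = 1:30),
    cbind(make_batch(30, 6, 2), stratum_outcome = 0L, pool_id = 1:30))
  td_a <- trial_data(outcome = rep(c(1L, 0L), c(100, 200)))
  td_b <- trial_data(outcome = rep(c(1L, 0L), c(250, 50)))
  est_a <- estimate_from_pools(td_a, batch, "logit", se_method = "none")
  est_b <- estimate_from_pools(td_b, batch, "logit", se_method = "none")
  expect_equal(est_a$estimate, est_b$estimate, tolerance = 1e-12)
  q1 <- 1 - sqrt(1 - 12 / 30); q0 <- 1 - sqrt(1 - 6 / 30)
  expect_equal(est_a$estimate, log(q1 * (1 - q0) / (q0 * (1 - q1))),
               tolerance = 1e-12)
  # identity-link estimates do depend on r
  expect_false(isTRUE(all.equal(
    estimate_from_pools(td_a, batch, "identity", se_method = "none")$estimate,
    estimate_from_pools(td_b, batch, "identity", se_method = "none")$estimate)))
})

test_that("boundary strata error with the offending stratum named", {
  batch <- rbind(
    cbind(make_batch(10, 0, 2), stratum_outcome = 1L, pool_id = 1:10),
    cbind(make_batch(10, 4, 2), stratum_outcome = 0L, pool_id = 1:10))
  td <- trial_data(outcome = rep(c(1L, 0L), c(50, 50)))
  expect_error(estimate_from_pools(td, batch, "logit"), "y=1")
  est <- estimate_from_pools(td, batch, "logit", correction = TRUE,
                             se_method = "none")
  expect_gt(est$prevalences[["y=1"]]$q_hat, 0)
})

test_that("delta-method and bootstrap standard errors agree", {
  td <- make_prognostic_trial(600, 0.24, 0.55, 0.45, seed = 5150)
  plan <- allocate_pools(td, budget = 150, pool_size = 2, seed = 6)
  batch <- assay_pools(plan, td)
  for (lk in c("logit", "identity")) {
    delta <- estimate_from_pools(td, batch, lk, se_method = "delta")
    boot <- estimate_from_pools(td, batch, lk, se_method = "bootstrap",
                                B = 2000, seed = 7)
    expect_equal(delta$estimate, boot$estimate)
    expect_lt(abs(boot$se / delta$se - 1), 0.10)
  }
  # dropping the response-rate variance shrinks (or keeps) the SE
  d_known <- estimate_from_pools(td, batch, "identity", r_known = TRUE)
  d_full <- estimate_from_pools(td, batch, "identity")
  expect_lte(d_known$se, d_full$se)
})
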