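prog_spec <- function(reps = 50, seed = 13,
                      designs = c("RS-2", "GT-2"), n = 120) {
  scenario_spec("prognostic", n = n, prevalence = 0.3,
                response_probs = c(p1 = 0.6, p0 = 0.45),
                designs = designs, reps = reps, seed = seed)
}

test_that("design labels parse into budget fraction and pool size", {
  expect_equal(design_spec("standard")$type, "standard")
  rs3 <- design_spec("RS-3")
  expect_equal(rs3$fraction, 3L)
  expect_equal(rs3$pool_size, 1L)
  gt2 <- design_spec("GT-2")
  expect_equal(gt2$fraction, 2L)
  expect_equal(gt2$pool_size, 2L)
  gt24 <- design_spec("GT-2-4")
  expect_equal(gt24$fraction, 2L)
  expect_equal(gt24$pool_size, 4L)
  expect_error(design_spec("DORFMAN"), "unrecognized")
})

test_that("simulated trials follow the scenario's generative model", {
  spec <- scenario_spec("predictive", n = 657, prevalence = 0.24,
                        response_probs = c(p11 = 0.65, p10 = 0.45,
                                           p01 = 0.5, p00 = 0.5),
                        reps = 1, seed = 1)
  counts <- vapply(1:30, function(s)
    sum(simulate_trial(spec, seed = s)$records$marker), numeric(1))
  expect_true(all(abs(counts - 657 * 0.24) < 3 * sqrt(657 * 0.24 * 0.76)))

  # zero prevalence: all marker-negative, outcomes at the x = 0 rates
  spec0 <- scenario_spec("prognostic", n = 500, prevalence = 0,
                         response_probs = c(p1 = 0.9, p0 = 0.4),
                         reps = 1, seed = 1)
  td0 <- simulate_trial(spec0, seed = 2)
  expect_true(all(td0$records$marker == 0))
  expect_lt(abs(mean(td0$records$outcome) - 0.4), 3 * sqrt(0.24 / 500))

  # degenerate response probabilities are deterministic per cell
  spec1 <- scenario_spec("prognostic", n = 200, prevalence = 0.5,
                         response_probs = c(p1 = 1, p0 = 0),
                         reps = 1, seed = 1)
  td1 <- simulate_trial(spec1, seed = 3)
  expect_identical(td1$records$outcome, td1$records$marker)
})

test_that("a duplicated standard design has unit relative (cost-)efficiency", {
  spec <- scenario_spec("prognostic", n = 80, prevalence = 0.3,
                        response_probs = c(p1 = 0.6, p0 = 0.45),
                        designs = c("standard", "standard"),
                        reps = 40, seed = 2)
  # named duplicate: second copy keeps the label, both are standard type
  spec$designs[[2]]$label <- "standard-dup"
  comp <- run_designs(spec)
  dup <- comp$table[comp$table$design == "standard-dup", ]
  expect_true(all(abs(dup$RE - 1) < 1e-12))
  expect_true(all(abs(dup$RCE - 1) < 1e-12))
})

test_that("simulation runs are deterministic under the master seed", {
  t1 <- replicate_table(run_designs(prog_spec()))
  t2 <- replicate_table(run_designs(prog_spec()))
  expect_identical(t1, t2)
  t3 <- replicate_table(run_designs(prog_spec(seed = 14)))
  expect_false(identical(t1, t3))
})

test_that("the standard-design stream is unchanged by the non-standard design list", {
  c1 <- run_designs(prog_spec(designs = c("RS-2", "GT-2")))
  c2 <- run_designs(prog_spec(designs = c("GT-3")))
  expect_identical(c1$estimates_all[, "standard", ],
                   c2$estimates_all[, "standard", ])
  # and each design's own stream does not depend on its position
  c3 <- run_designs(prog_spec(designs = "GT-2"))
  expect_identical(c1$estimates_all[, "GT-2", ], c3$estimates_all[, "GT-2", ])
})

test_that("simulated prevalence-estimator variance matches inverse information", {
  # single-stratum sub-problem: m pools of size k at fixed q
  q <- 0.3; k <- 2; m <- 500; nrep <- 1000
  set.seed(99)
  s <- stats::rbinom(nrep, m, pool_positive_prob(q, k))
  q_hat <- vapply(s, function(si)
    estimate_prevalence(make_batch(m, si, k))$q_hat, numeric(1))
  pred <- 1 / (m * per_assay_fisher_info(q, k))
  expect_lt(abs(stats::var(q_hat) / pred - 1), 0.10)
})

test_that("replicate_table reports one row per scenario and measure", {
  comp <- run_designs(prog_spec(reps = 40))
  tab <- replicate_table(list(A = comp, B = comp))
  expect_equal(nrow(tab), 6L)  # 2 scenarios x 3 links
  expect_true(all(c("RE RS-2", "RE_se RS-2", "RCE GT-2", "RCE_se GT-2")
                  %in% names(tab)))
  single <- replicate_table(run_designs(prog_spec(reps = 40,
                                                  designs = "GT-2")))
  expect_equal(nrow(single), 3L)
  expect_equal(sum(grepl("^RE ", names(single))), 1L)
})

test_that("relative cost-efficiency is the assay-ratio-scaled efficiency", {
  expect_equal(relative_cost_efficiency(0.85, 600, 300), 1.7)
  expect_equal(relative_cost_efficiency(1, 100, 100), 1)
  comp <- run_designs(prog_spec(reps = 40))
  tab <- comp$table
  expect_equal(tab$RCE,
               tab$RE * tab$mean_assays[tab$design == "standard"][1] /
                 tab$mean_assays,
               tolerance = 1e-12)
})
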