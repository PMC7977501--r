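# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the MLE oracle is a dense grid search over the
# likelihood, the information oracle differentiates the expected
# log-likelihood numerically.

# pooled-batch log-likelihood on a prevalence grid; returns the maximizing q
grid_search_mle <- function(batch, sensitivity = 1, specificity = 1,
                            step = 1e-4) {
  qs <- seq(0, 1, by = step)
  sizes <- sort(unique(batch$pool_size))
  ll <- numeric(length(qs))
  for (k in sizes) {
    m <- sum(batch$pool_size == k)
    s <- sum(batch$result[batch$pool_size == k])
    pi_ <- sensitivity * (1 - (1 - qs)^k) + (1 - specificity) * (1 - qs)^k
    term <- numeric(length(qs))
    if (s > 0) term <- term + s * log(pi_)
    if (m - s > 0) term <- term + (m - s) * log(1 - pi_)
    ll <- ll + term
  }
  qs[which.max(ll)]
}

# per-assay Fisher information as minus the curvature of the expected
# log-likelihood of one pooled test, by central second differences
numeric_fisher_info <- function(q, k, sensitivity = 1, specificity = 1,
                                h = 1e-5) {
  pp <- function(qq) sensitivity * (1 - (1 - qq)^k) +
    (1 - specificity) * (1 - qq)^k
  pi0 <- pp(q)
  ell <- function(qq) pi0 * log(pp(qq)) + (1 - pi0) * log(1 - pp(qq))
  -(ell(q + h) - 2 * ell(q) + ell(q - h)) / h^2
}

# single-size pooled batch as a data frame: s positives out of m pools of k
make_batch <- function(m, s, k) {
  data.frame(pool_size = rep.int(k, m),
             result = rep(c(1L, 0L), c(s, m - s)))
}

# a quick prognostic trial with known markers
make_prognostic_trial <- function(n, prevalence, p1, p0, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, prevalence)
  y <- rbinom(n, 1, ifelse(x == 1, p1, p0))
  trial_data(outcome = y, marker = x)
}

make_predictive_trial <- function(n, prevalence, p_tx, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, prevalence)
  tr <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, unname(p_tx[paste0("p", tr, x)]))
  trial_data(outcome = y, treatment = tr, marker = x)
}
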