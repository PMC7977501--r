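#' Probability that a pooled assay tests positive
#'
#' For a pool of `k` specimens drawn from a stratum with marker prevalence
#' `q`, the pool is truly positive (contains at least one marker-positive
#' specimen) with probability `1 - (1 - q)^k`. With assay sensitivity Se and
#' specificity Sp the probability of a positive *test result* is
#' \deqn{\pi(q, k) = Se\,\{1 - (1-q)^k\} + (1 - Sp)\,(1-q)^k,}
#' which reduces to \eqn{1 - (1-q)^k} for the perfect assay.
#'
#' @param q Marker prevalence in \[0, 1\] (vectorized).
#' @param k Pool size, integer >= 1 (vectorized).
#' @param assay An [assay_model].
#' @return Probability of a positive pooled test result.
#' @examples
#' pool_positive_prob(0.5, 2)                        # 0.75
#' pool_positive_prob(0.2, 2, assay_model(0.9, 0.95)) # 0.356
#' @export
pool_positive_prob <- function(q, k, assay = assay_model()) {
  assay <- as_assay_model(assay)
  if (any(q < 0 | q > 1, na.rm = TRUE))
    stop("`q` must lie in [0, 1]", call. = FALSE)
  if (any(k < 1 | k != floor(k)))
    stop("`k` must be an integer >= 1", call. = FALSE)
  pool_prob_terms(q, k, assay$sensitivity, assay$specificity)$pi
}

# pi and 1 - pi computed in complementary forms that avoid cancellation for
# q near 0 or 1: with u = 1 - q,
#   pi     = Se (1 - u^k) + (1 - Sp) u^k
#   1 - pi = (1 - Se)(1 - u^k) + Sp u^k
pool_prob_terms <- function(q, k, se, sp) {
  lu <- log1p(-q)                       # log(1 - q); -Inf at q = 1 is fine
  uk <- exp(k * lu)
  cuk <- -expm1(k * lu)                 # 1 - (1 - q)^k, stable near q = 0
  list(pi = se * cuk + (1 - sp) * uk,
       one_minus_pi = (1 - se) * cuk + sp * uk)
}

#' Per-assay Fisher information about marker prevalence
#'
#' Expected Fisher information about the prevalence `q` carried by a single
#' pooled binary test of size `k`:
#' \deqn{I_k(q) = \frac{\{\pi'(q,k)\}^2}{\pi(q,k)\,\{1 - \pi(q,k)\}},}
#' with \eqn{\pi} as in [pool_positive_prob] and
#' \eqn{\pi'(q,k) = (Se + Sp - 1)\, k (1-q)^{k-1}}. For the perfect assay and
#' `k = 1` this is the familiar binomial information `1 / {q (1 - q)}`.
#'
#' @inheritParams pool_positive_prob
#' @param q Prevalence strictly inside (0, 1); the information is degenerate
#'   at the boundary.
#' @return Per-assay Fisher information (vectorized over `q` and `k`).
#' @examples
#' per_assay_fisher_info(0.5, 1)  # 4
#' per_assay_fisher_info(0.5, 2)  # 16/3
#' @export
per_assay_fisher_info <- function(q, k, assay = assay_model()) {
  assay <- as_assay_model(assay)
  if (any(q <= 0 | q >= 1, na.rm = TRUE))
    stop("`q` must lie strictly inside (0, 1)", call. = FALSE)
  if (any(k < 1 | k != floor(k)))
    stop("`k` must be an integer >= 1", call. = FALSE)
  se <- assay$sensitivity; sp <- assay$specificity
  terms <- pool_prob_terms(q, k, se, sp)
  dpi <- (se + sp - 1) * k * (1 - q)^(k - 1)
  dpi^2 / (terms$pi * terms$one_minus_pi)
}

# aggregate a stratum batch into per-size (pools, positives) counts
batch_counts <- function(batch) {
  if (nrow(batch) < 1L) stop("empty pooled batch", call. = FALSE)
  sizes <- sort(unique(batch$pool_size))
  m <- vapply(sizes, function(k) sum(batch$pool_size == k), numeric(1))
  s <- vapply(sizes, function(k) sum(batch$result[batch$pool_size == k]),
              numeric(1))
  list(k = sizes, m = m, s = s)
}

pooled_loglik <- function(q, counts, se, sp) {
  terms <- pool_prob_terms(q, counts$k, se, sp)
  sum(counts$s * log(terms$pi) +
        (counts$m - counts$s) * log(terms$one_minus_pi))
}

# MLE from per-size counts; closed form for a single pool size, bounded
# scalar optimization otherwise. Returns list(q_hat, boundary).
prev_mle_counts <- function(counts, se, sp, eps = 1e-10) {
  if (length(counts$k) == 1L) {
    k <- counts$k; phat <- counts$s / counts$m
    val <- (se - phat) / (se + sp - 1)
    if (val <= 0) return(list(q_hat = 1, boundary = TRUE))
    if (val >= 1) return(list(q_hat = 0, boundary = TRUE))
    return(list(q_hat = 1 - val^(1 / k), boundary = FALSE))
  }
  opt <- stats::optimize(pooled_loglik, c(eps, 1 - eps), maximum = TRUE,
                         counts = counts, se = se, sp = sp, tol = 1e-10)
  ll0 <- pooled_loglik(eps, counts, se, sp)
  ll1 <- pooled_loglik(1 - eps, counts, se, sp)
  if (ll0 >= opt$objective && ll0 >= ll1)
    return(list(q_hat = 0, boundary = TRUE))
  if (ll1 >= opt$objective)
    return(list(q_hat = 1, boundary = TRUE))
  list(q_hat = opt$maximum, boundary = FALSE)
}

#' Maximum-likelihood prevalence estimate from pooled assay results
#'
#' Estimates the marker prevalence `q` of one stratum from its binary pooled
#' assay results by maximizing the binomial likelihood
#' \deqn{\prod_j \pi(q, k_j)^{z_j} \{1 - \pi(q, k_j)\}^{1 - z_j}}
#' over `q` in \[0, 1\]. When all pools share one size `k` the maximizer has
#' the closed form \eqn{\hat q = 1 - \{(Se - \hat p)/(Se + Sp - 1)\}^{1/k}}
#' (clipped to \[0, 1\]), where \eqn{\hat p} is the observed positive
#' fraction; mixed pool sizes are handled by bounded scalar optimization of
#' the log-likelihood. Estimates on the boundary (e.g. all pools negative)
#' are flagged and carry no Wald variance.
#'
#' @param batch Pooled results for a single stratum: a data frame with
#'   columns `pool_size` and `result` (a one-stratum slice of an
#'   [assay_pools] batch works directly).
#' @param assay An [assay_model].
#' @param variance `"expected"` (default) inverts the expected Fisher
#'   information \eqn{\sum_j I_{k_j}(\hat q)}; `"observed"` inverts the
#'   observed information (numeric second derivative of the log-likelihood).
#' @return An object of class `"prevalence_estimate"`: `q_hat`, `variance`
#'   (`NA` when `boundary` is set), `assay_count`, `pool_sizes` (table), and
#'   `boundary` flag.
#' @examples
#' b <- data.frame(pool_size = 2, result = c(rep(1, 4), rep(0, 6)))
#' estimate_prevalence(b)  # q_hat = 1 - sqrt(0.6)
#' @export
estimate_prevalence <- function(batch, assay = assay_model(),
                                variance = c("expected", "observed")) {
  assay <- as_assay_model(assay)
  variance <- match.arg(variance)
  if (is.null(batch$pool_size) || is.null(batch$result))
    stop("`batch` needs `pool_size` and `result` columns", call. = FALSE)
  if (!is.null(batch$stratum_treatment) || !is.null(batch$stratum_outcome)) {
    key <- unique(stratum_label(batch$stratum_treatment %||% NA_integer_,
                                batch$stratum_outcome %||% 0L))
    if (length(key) > 1L)
      stop("`batch` spans several strata; estimate each stratum separately",
           call. = FALSE)
  }
  check_binary(batch$result, "result")
  counts <- batch_counts(batch)
  se <- assay$sensitivity; sp <- assay$specificity
  fit <- prev_mle_counts(counts, se, sp)
  v <- NA_real_
  if (!fit$boundary) {
    v <- switch(variance,
      expected = 1 / sum(counts$m *
                           per_assay_fisher_info(fit$q_hat, counts$k, assay)),
      observed = {
        h <- 1e-5
        d2 <- (pooled_loglik(fit$q_hat + h, counts, se, sp) -
                 2 * pooled_loglik(fit$q_hat, counts, se, sp) +
                 pooled_loglik(fit$q_hat - h, counts, se, sp)) / h^2
        -1 / d2
      })
  }
  structure(list(q_hat = fit$q_hat, variance = v,
                 assay_count = sum(counts$m),
                 pool_sizes = stats::setNames(counts$m, counts$k),
                 boundary = fit$boundary, variance_method = variance,
                 assay = assay),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Pooled-assay prevalence MLE: q_hat = %.4f", x$q_hat))
  if (x$boundary) {
    cat(" (boundary estimate; Wald variance undefined)\n")
  } else {
    cat(sprintf(" (SE %.4f)\n", sqrt(x$variance)))
  }
  cat(sprintf("Assays: %d; pool sizes: %s\n", x$assay_count,
              paste(sprintf("%d x size %s", x$pool_sizes,
                            names(x$pool_sizes)), collapse = ", ")))
  invisible(x)
}

#' Cost-efficiency-optimal pool size for a given prevalence
#'
#' With a fixed per-stratum assay budget, the pool size maximizing the
#' information per assay — hence the cost-efficiency of prevalence estimation
#' — is the `k` maximizing [per_assay_fisher_info]. Ties break toward the
#' smaller pool size.
#'
#' @param q True (or preliminary estimate of) marker prevalence in (0, 1).
#' @param k_max Largest pool size considered.
#' @param assay An [assay_model].
#' @return The optimal pool size, an integer in `1:k_max`.
#' @examples
#' optimal_pool_size(0.70, 4)  # 1: no pooling at high prevalence
#' optimal_pool_size(0.24, 4)  # 4: large pools pay off when rare
#' @export
optimal_pool_size <- function(q, k_max = 4L, assay = assay_model()) {
  stopifnot(length(q) == 1L, k_max >= 1L, k_max == floor(k_max))
  info <- vapply(seq_len(k_max), function(k)
    per_assay_fisher_info(q, k, assay), numeric(1))
  which.max(info)  # first maximum = smallest k on ties
}

#' Per-assay information curves and pool-size crossover prevalences
#'
#' Evaluates the per-assay Fisher information \eqn{I_k(q)} for pool sizes
#' `1:k_max` on a prevalence grid, reports the grid interval on which each
#' pool size is optimal, and locates the continuous crossover prevalences
#' where \eqn{I_k(q) = I_{k+1}(q)} by bracketed root finding. Above the
#' (k, k+1) crossover the smaller pool is preferable; the crossovers decrease
#' with `k`, so rarer markers favor larger pools.
#'
#' @param k_max Largest pool size considered (>= 2).
#' @param assay An [assay_model].
#' @param grid_step Grid resolution, default 0.01.
#' @param grid_range Grid endpoints, default `c(0.01, 0.99)`.
#' @return An object of class `"info_curve"`: the `grid`, the `info` matrix
#'   (grid x pool size), `optimal` pool size per grid point, the optimality
#'   `bands` data frame, and the `crossovers` data frame.
#' @examples
#' ic <- info_crossovers(4)
#' ic$bands
#' ic$crossovers
#' @export
info_crossovers <- function(k_max = 4L, assay = assay_model(),
                            grid_step = 0.01, grid_range = c(0.01, 0.99)) {
  stopifnot(k_max >= 2L, k_max == floor(k_max), grid_step > 0)
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  # round to grid resolution so e.g. 0.67 is hit exactly
  grid <- round(grid, ceiling(-log10(grid_step)) + 2L)
  info <- vapply(seq_len(k_max), function(k)
    per_assay_fisher_info(grid, k, assay), numeric(length(grid)))
  colnames(info) <- seq_len(k_max)
  optimal <- apply(info, 1L, which.max)  # ties -> smaller k
  bands <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    at <- grid[optimal == k]
    if (!length(at)) return(NULL)
    data.frame(pool_size = k, q_lower = min(at), q_upper = max(at))
  }))
  crossovers <- do.call(rbind, lapply(seq_len(k_max - 1L), function(k) {
    f <- function(q) per_assay_fisher_info(q, k, assay) -
      per_assay_fisher_info(q, k + 1L, assay)
    lo <- 1e-9; hi <- 1 - 1e-9
    root <- if (f(lo) * f(hi) < 0)
      stats::uniroot(f, c(lo, hi), tol = 1e-12)$root else NA_real_
    data.frame(smaller = k, larger = k + 1L, crossover = root)
  }))
  structure(list(grid = grid, info = info, optimal = optimal,
                 bands = bands, crossovers = crossovers, assay = assay),
            class = "info_curve")
}

#' @export
print.info_curve <- function(x, ...) {
  cat("Per-assay Fisher information about prevalence\n")
  cat("Optimality bands on the prevalence grid:\n")
  print(x$bands, row.names = FALSE)
  cat("Continuous crossover prevalences:\n")
  print(x$crossovers, row.names = FALSE)
  invisible(x)
}
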