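#' Link functions for association and interaction measures
#'
#' The three links under which biomarker effects are measured: `logit` turns
#' `g(p1) - g(p0)` into the log odds ratio, `log` into the log risk ratio,
#' and `identity` into the risk difference. The same links define the
#' treatment-by-marker interaction coefficient of the saturated binary
#' regression model as a difference in differences.
#'
#' @param name `"logit"`, `"log"`, or `"identity"`.
#' @return An object of class `"link_function"` with the forward map `g`,
#'   its derivative `gprime`, a domain predicate, and the conventional name
#'   of the association measure it induces.
#' @examples
#' link_function("logit")$g(0.5)  # 0
#' @export
link_function <- function(name = c("logit", "log", "identity")) {
  name <- match.arg(name)
  out <- switch(name,
    logit = list(name = "logit", g = stats::qlogis,
                 gprime = function(p) 1 / (p * (1 - p)),
                 in_domain = function(p) p > 0 & p < 1,
                 measure = "log-OR"),
    log = list(name = "log", g = log,
               gprime = function(p) 1 / p,
               in_domain = function(p) p > 0,
               measure = "log-ratio"),
    identity = list(name = "identity", g = identity,
                    gprime = function(p) rep(1, length(p)),
                    in_domain = function(p) rep(TRUE, length(p)),
                    measure = "difference"))
  structure(out, class = "link_function")
}

as_link <- function(link) {
  if (inherits(link, "link_function")) link else link_function(link)
}

check_link_domain <- function(p, link, cells) {
  bad <- !link$in_domain(p)
  if (any(bad))
    stop(sprintf(
      "cell probability %s = %g is on the boundary of the %s link's domain",
      cells[which(bad)[1]], p[which(bad)[1]], link$name), call. = FALSE)
  invisible(TRUE)
}

#' Convert outcome-stratified prevalences to marker-specific response rates
#'
#' In a retrospective sampling or pooling design one estimates the marker
#' prevalence among responders (`q1 = P(X=1 | Y=1)`) and non-responders
#' (`q0 = P(X=1 | Y=0)`), while the overall response rate
#' `r = n1 / (n1 + n0)` is known from the full phase-one outcome data. Bayes'
#' theorem then recovers the marker-specific response probabilities
#' \deqn{p_1 = P(Y=1 \mid X=1) = q_1 r / w, \qquad
#'       p_0 = P(Y=1 \mid X=0) = (1-q_1) r / (1-w),}
#' where \eqn{w = q_1 r + q_0 (1-r)} is the overall marker prevalence.
#'
#' @param q1,q0 Marker prevalence among responders / non-responders.
#' @param n1,n0 Responder / non-responder counts in the trial.
#' @return An object of class `"cell_probs"` (prognostic mode) with `p1`,
#'   `p0`, the implied marker prevalence `w`, and the response rate `r`.
#' @examples
#' bayes_convert_prognostic(0.3, 0.2, 50, 50)  # p1 = 0.6, p0 = 7/15
#' @export
bayes_convert_prognostic <- function(q1, q0, n1, n0) {
  stopifnot(q1 >= 0, q1 <= 1, q0 >= 0, q0 <= 1, n1 >= 0, n0 >= 0)
  if (n1 + n0 <= 0) stop("n1 + n0 must be positive", call. = FALSE)
  r <- n1 / (n1 + n0)
  w <- q1 * r + q0 * (1 - r)
  if (w <= 0 || w >= 1)
    stop(sprintf(
      "implied marker prevalence w = %g is degenerate; the marker is constant and measures are undefined",
      w), call. = FALSE)
  structure(list(p1 = q1 * r / w, p0 = (1 - q1) * r / (1 - w),
                 w = w, r = r, mode = "prognostic"),
            class = "cell_probs")
}

#' Convert (treatment, outcome)-stratified prevalences to response rates
#'
#' Applies the prognostic Bayes conversion within each randomized treatment
#' arm: from the four stratum prevalences `q_ty = P(X=1 | T=t, Y=y)` and the
#' observed stratum counts `n_ty`, recover the four response probabilities
#' `p_tx = P(Y=1 | T=t, X=x)` entering the interaction coefficient.
#'
#' @param q11,q10,q01,q00 Marker prevalences `q_ty` indexed treatment first,
#'   outcome second (`q10` is arm T=1, non-responders).
#' @param n11,n10,n01,n00 Corresponding stratum counts.
#' @return An object of class `"cell_probs"` (predictive mode) with `p11`,
#'   `p10`, `p01`, `p00` indexed treatment first, *marker* second, plus the
#'   per-arm marker prevalences `w` and response rates `r`.
#' @export
bayes_convert_predictive <- function(q11, q10, q01, q00,
                                     n11, n10, n01, n00) {
  arm1 <- bayes_convert_prognostic(q11, q10, n11, n10)
  arm0 <- bayes_convert_prognostic(q01, q00, n01, n00)
  structure(list(p11 = arm1$p1, p10 = arm1$p0,
                 p01 = arm0$p1, p00 = arm0$p0,
                 w = c(t1 = arm1$w, t0 = arm0$w),
                 r = c(t1 = arm1$r, t0 = arm0$r),
                 mode = "predictive"),
            class = "cell_probs")
}

#' @export
print.cell_probs <- function(x, ...) {
  if (x$mode == "prognostic") {
    cat(sprintf("Response rates: p1 = %.4f (marker+), p0 = %.4f (marker-)\n",
                x$p1, x$p0))
  } else {
    cat(sprintf("Response rates p_tx: p11 = %.4f p10 = %.4f p01 = %.4f p00 = %.4f\n",
                x$p11, x$p10, x$p01, x$p00))
  }
  invisible(x)
}

#' Prognostic association measure g(p1) - g(p0)
#'
#' The log odds ratio (logit link), log risk ratio (log link), or risk
#' difference (identity link) comparing marker-positive with marker-negative
#' subjects.
#'
#' @param cells A prognostic [bayes_convert_prognostic] `"cell_probs"` object,
#'   or a list with elements `p1` and `p0`.
#' @param link A [link_function] or its name.
#' @return The association measure, a single number.
#' @examples
#' association_measure(list(p1 = 0.6, p0 = 0.4), "logit")  # 2 log 1.5
#' @export
association_measure <- function(cells, link) {
  link <- as_link(link)
  p <- c(cells$p1, cells$p0)
  check_link_domain(p, link, c("p1", "p0"))
  link$g(p[1]) - link$g(p[2])
}

#' Treatment-by-marker interaction coefficient
#'
#' The interaction coefficient of the saturated binary regression of outcome
#' on treatment, marker, and their product, under the chosen link. For any
#' link it is the difference in differences
#' \deqn{\beta_{TX} = \{g(p_{11}) - g(p_{10})\} - \{g(p_{01}) - g(p_{00})\},}
#' i.e. the marker's association with outcome in the experimental arm minus
#' its association in the control arm.
#'
#' @param cells A predictive [bayes_convert_predictive] `"cell_probs"` object,
#'   or a list with elements `p11`, `p10`, `p01`, `p00` (treatment, marker).
#' @param link A [link_function] or its name.
#' @return The interaction coefficient, a single number.
#' @export
interaction_coefficient <- function(cells, link) {
  link <- as_link(link)
  p <- c(cells$p11, cells$p10, cells$p01, cells$p00)
  check_link_domain(p, link, c("p11", "p10", "p01", "p00"))
  (link$g(p[1]) - link$g(p[2])) - (link$g(p[3]) - link$g(p[4]))
}

measure_name <- function(mode, link) {
  if (mode == "prognostic") link$measure
  else paste0("interaction (", link$name, ")")
}

new_measure_estimate <- function(measure, estimate, se, se_method,
                                 assay_count, cells, extra = list()) {
  structure(c(list(measure = measure, estimate = estimate, se = se,
                   se_method = se_method, assay_count = assay_count,
                   cells = cells), extra),
            class = "measure_estimate")
}

#' @export
print.measure_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f, %s method; %d assays)\n",
              x$measure, x$estimate, x$se, x$se_method, x$assay_count))
  invisible(x)
}

#' Standard-design estimate of an association or interaction measure
#'
#' The standard prospective-retrospective design assays every subject, so the
#' cell probabilities are estimated by the observed proportions: `p_x` (or
#' `p_tx`) is the responder fraction among subjects with marker status `x`
#' (in arm `t`). The point estimate equals the corresponding coefficient of
#' the saturated regression model fit by maximum likelihood. The standard
#' error is first-order (delta-method) propagation of the binomial variance
#' of each cell proportion; under the logit link this is the classical
#' `sqrt(1/a + 1/b + 1/c + 1/d)` for the 2x2 table.
#'
#' @param trial A [trial_data] object with marker observed for every subject.
#' @param link A [link_function] or its name.
#' @param mode `"prognostic"` or `"predictive"`; defaults to the trial's mode.
#' @param correction Add 0.5 to every cell of each 2x2 table
#'   (Haldane-Anscombe) instead of erroring when a cell is empty or a
#'   proportion sits on the link's domain boundary. Off by default.
#' @return A `"measure_estimate"` object.
#' @examples
#' set.seed(1)
#' td <- trial_data(outcome = rbinom(200, 1, 0.4), marker = rbinom(200, 1, 0.3))
#' estimate_standard(td, "logit")
#' @export
estimate_standard <- function(trial, link, mode = trial$mode,
                              correction = FALSE) {
  stopifnot(inherits(trial, "trial_data"))
  link <- as_link(link)
  rec <- trial$records
  if (anyNA(rec$marker))
    stop("standard-design estimation requires marker status for every subject",
         call. = FALSE)
  if (mode == "predictive" && trial$mode != "predictive")
    stop("predictive mode requires treatment data", call. = FALSE)
  if (mode == "prognostic" && trial$mode == "predictive")
    stop("trial has two treatment arms; subset to one arm for a prognostic ",
         "analysis", call. = FALSE)

  arm_fit <- function(y, x) {
    a <- sum(y == 1 & x == 1); b <- sum(y == 0 & x == 1)
    cc <- sum(y == 1 & x == 0); d <- sum(y == 0 & x == 0)
    if (correction) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    if (a + b == 0 || cc + d == 0)
      stop("a marker group is empty; the measure is undefined", call. = FALSE)
    p1 <- a / (a + b); p0 <- cc / (cc + d)
    check_link_domain(c(p1, p0), link, c("p1", "p0"))
    var_ <- link$gprime(p1)^2 * p1 * (1 - p1) / (a + b) +
      link$gprime(p0)^2 * p0 * (1 - p0) / (cc + d)
    list(est = link$g(p1) - link$g(p0), var = var_, p1 = p1, p0 = p0,
         counts = c(a = a, b = b, c = cc, d = d))
  }

  if (mode == "prognostic") {
    fit <- arm_fit(rec$outcome, rec$marker)
    cells <- structure(list(p1 = fit$p1, p0 = fit$p0, mode = "prognostic"),
                       class = "cell_probs")
    return(new_measure_estimate(measure_name(mode, link), fit$est,
                                sqrt(fit$var), "delta", nrow(rec), cells,
                                list(counts = fit$counts, link = link$name)))
  }
  a1 <- rec$treatment == 1
  f1 <- arm_fit(rec$outcome[a1], rec$marker[a1])
  f0 <- arm_fit(rec$outcome[!a1], rec$marker[!a1])
  cells <- structure(list(p11 = f1$p1, p10 = f1$p0, p01 = f0$p1, p00 = f0$p0,
                          mode = "predictive"),
                     class = "cell_probs")
  new_measure_estimate(measure_name(mode, link), f1$est - f0$est,
                       sqrt(f1$var + f0$var), "delta", nrow(rec), cells,
                       list(counts = list(t1 = f1$counts, t0 = f0$counts),
                            link = link$name))
}

# per-stratum prevalence fits for the strata a mode requires; errors (or
# applies a half-positive-pool continuity correction) at boundary estimates
stratum_prevalences <- function(batch, strata, assay, correction) {
  fits <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    b <- batch_stratum(batch, strata$treatment[i], strata$outcome[i])
    if (nrow(b) == 0L)
      stop(sprintf("no pooled assays for stratum %s", strata$label[i]),
           call. = FALSE)
    fit <- estimate_prevalence(b, assay)
    if (fit$boundary) {
      if (!correction)
        stop(sprintf(
          "boundary prevalence estimate (q_hat = %g) in stratum %s; rerun with correction = TRUE to apply a half-pool continuity correction",
          fit$q_hat, strata$label[i]), call. = FALSE)
      fit <- corrected_prevalence(b, assay)
    }
    fits[[i]] <- fit
  }
  names(fits) <- strata$label
  fits
}

# continuity correction for boundary batches: move the positive-pool count
# half a pool off the boundary (applied within the most numerous pool size)
corrected_prevalence <- function(b, assay) {
  counts <- batch_counts(b)
  j <- which.max(counts$m)
  if (sum(counts$s) <= 0) counts$s[j] <- counts$s[j] + 0.5
  else counts$s[j] <- counts$s[j] - 0.5
  se <- assay$sensitivity; sp <- assay$specificity
  fit <- prev_mle_counts(counts, se, sp)
  v <- if (fit$boundary) NA_real_ else
    1 / sum(counts$m * per_assay_fisher_info(fit$q_hat, counts$k, assay))
  structure(list(q_hat = fit$q_hat, variance = v,
                 assay_count = sum(counts$m),
                 pool_sizes = stats::setNames(counts$m, counts$k),
                 boundary = fit$boundary, variance_method = "expected",
                 assay = assay, corrected = TRUE),
            class = "prevalence_estimate")
}

#' Association/interaction estimate from a pooled (group-testing) design
#'
#' Combines per-stratum pooled-assay prevalence MLEs with the fully observed
#' outcome (and treatment) data: each required stratum's prevalence is
#' estimated by [estimate_prevalence], converted to cell response
#' probabilities via Bayes' theorem ([bayes_convert_prognostic] /
#' [bayes_convert_predictive]), and plugged into the chosen measure. With
#' pool size 1 this is the random-sampling estimator; with pool size 1 and
#' every subject assayed it reproduces the standard-design estimator.
#'
#' Standard errors are either first-order delta-method propagation through
#' the stratum prevalence estimates (variance from inverse Fisher
#' information) and, unless `r_known = TRUE`, the arm response rates
#' (binomial variance), all treated as independent; or a nonparametric
#' bootstrap that resamples pools within stratum and subjects within arm.
#'
#' @param trial A [trial_data] object (markers may be unknown; only outcomes
#'   and treatments are used).
#' @param batch A [assay_pools] pooled result batch covering every required
#'   stratum.
#' @param link A [link_function] or its name.
#' @param assay The [assay_model] that produced the results.
#' @param mode `"prognostic"` or `"predictive"`; defaults to the trial's mode.
#' @param se_method `"delta"` (default), `"bootstrap"`, or `"none"` (point
#'   estimate only, used by the simulator).
#' @param B Bootstrap replicate count (default 2000).
#' @param r_known Treat the arm response rates as known constants, dropping
#'   their variance contribution from the delta-method SE.
#' @param correction Apply a half-pool continuity correction to boundary
#'   prevalence estimates instead of erroring. Off by default.
#' @param seed Optional seed for the bootstrap.
#' @return A `"measure_estimate"` object; its `prevalences` element holds the
#'   per-stratum `"prevalence_estimate"` fits.
#' @export
estimate_from_pools <- function(trial, batch, link, assay = assay_model(),
                                mode = trial$mode,
                                se_method = c("delta", "bootstrap", "none"),
                                B = 2000L, r_known = FALSE,
                                correction = FALSE, seed = NULL) {
  stopifnot(inherits(trial, "trial_data"))
  link <- as_link(link)
  assay <- as_assay_model(assay)
  se_method <- match.arg(se_method)
  batch <- as_pooled_batch(as.data.frame(batch))
  if (mode == "predictive" && trial$mode != "predictive")
    stop("predictive mode requires treatment data", call. = FALSE)
  strata <- if (mode == "prognostic" && trial$mode == "predictive")
    stop("trial has two treatment arms; subset to one arm for a prognostic ",
         "analysis", call. = FALSE)
  else trial_strata(trial)
  fits <- stratum_prevalences(batch, strata, assay, correction)
  n_s <- stats::setNames(strata$n, strata$label)

  point_fun <- if (mode == "prognostic") {
    function(q, nn) association_measure(
      bayes_convert_prognostic(q[["y=1"]], q[["y=0"]],
                               nn[["y=1"]], nn[["y=0"]]), link)
  } else {
    function(q, nn) interaction_coefficient(
      bayes_convert_predictive(q[["t=1,y=1"]], q[["t=1,y=0"]],
                               q[["t=0,y=1"]], q[["t=0,y=0"]],
                               nn[["t=1,y=1"]], nn[["t=1,y=0"]],
                               nn[["t=0,y=1"]], nn[["t=0,y=0"]]), link)
  }
  q_hat <- vapply(fits, `[[`, numeric(1), "q_hat")
  est <- point_fun(q_hat, n_s)
  cells <- if (mode == "prognostic")
    bayes_convert_prognostic(q_hat[["y=1"]], q_hat[["y=0"]],
                             n_s[["y=1"]], n_s[["y=0"]])
  else bayes_convert_predictive(q_hat[["t=1,y=1"]], q_hat[["t=1,y=0"]],
                                q_hat[["t=0,y=1"]], q_hat[["t=0,y=0"]],
                                n_s[["t=1,y=1"]], n_s[["t=1,y=0"]],
                                n_s[["t=0,y=1"]], n_s[["t=0,y=0"]])

  se <- NA_real_; boot_failed <- NULL
  if (se_method == "delta") {
    se <- delta_se_pools(point_fun, q_hat, n_s, fits, mode, r_known)
  } else if (se_method == "bootstrap") {
    bs <- bootstrap_se_pools(point_fun, batch, strata, n_s, assay, B,
                             correction, seed)
    se <- bs$se; boot_failed <- bs$failed
  }
  new_measure_estimate(measure_name(mode, link), est, se, se_method,
                       sum(vapply(fits, `[[`, numeric(1), "assay_count")),
                       cells,
                       list(prevalences = fits, link = link$name,
                            bootstrap_failed = boot_failed))
}

# first-order propagation through (stratum prevalences, arm response rates),
# treated as independent; gradient by central differences
delta_se_pools <- function(point_fun, q_hat, n_s, fits, mode, r_known) {
  labs <- names(q_hat)
  v_q <- vapply(fits, `[[`, numeric(1), "variance")
  f_of <- function(q, nn) point_fun(stats::setNames(q, labs),
                                    stats::setNames(nn, labs))
  h <- 1e-6
  grad_q <- vapply(seq_along(q_hat), function(i) {
    up <- q_hat; dn <- q_hat
    up[i] <- min(q_hat[i] + h, 1 - 1e-12)
    dn[i] <- max(q_hat[i] - h, 1e-12)
    (f_of(up, n_s) - f_of(dn, n_s)) / (up[i] - dn[i])
  }, numeric(1))
  var_total <- sum(grad_q^2 * v_q)
  if (!r_known) {
    # perturb the responder count within each arm, holding the arm size
    # fixed: r_t = n_t1 / n_t, Var(r_hat_t) = r_t (1 - r_t) / n_t
    arms <- if (mode == "prognostic") list(c("y=1", "y=0"))
    else list(c("t=1,y=1", "t=1,y=0"), c("t=0,y=1", "t=0,y=0"))
    for (arm in arms) {
      n_t <- sum(n_s[arm]); r_t <- n_s[arm[1]] / n_t
      hr <- 1e-6
      shift <- function(d) {
        nn <- n_s
        nn[arm[1]] <- (r_t + d) * n_t
        nn[arm[2]] <- (1 - r_t - d) * n_t
        f_of(q_hat, nn)
      }
      grad_r <- (shift(hr) - shift(-hr)) / (2 * hr)
      var_total <- var_total + grad_r^2 * r_t * (1 - r_t) / n_t
    }
  }
  sqrt(unname(var_total))
}

bootstrap_se_pools <- function(point_fun, batch, strata, n_s, assay, B,
                               correction, seed) {
  if (!is.null(seed)) set.seed(seed)
  labs <- strata$label
  stratum_rows <- lapply(seq_len(nrow(strata)), function(i)
    which(if (is.na(strata$treatment[i])) is.na(batch$stratum_treatment) &
            batch$stratum_outcome == strata$outcome[i]
          else !is.na(batch$stratum_treatment) &
            batch$stratum_treatment == strata$treatment[i] &
            batch$stratum_outcome == strata$outcome[i]))
  arms <- if (all(is.na(strata$treatment))) list(c("y=1", "y=0"))
  else list(c("t=1,y=1", "t=1,y=0"), c("t=0,y=1", "t=0,y=0"))
  se_ <- assay$sensitivity; sp_ <- assay$specificity
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    res <- try({
      q_b <- numeric(nrow(strata))
      for (i in seq_len(nrow(strata))) {
        rows <- sample(stratum_rows[[i]], replace = TRUE)
        counts <- batch_counts(batch[rows, , drop = FALSE])
        fit <- prev_mle_counts(counts, se_, sp_)
        if (fit$boundary) {
          if (!correction) stop("boundary")
          fit <- prev_mle_counts(local({
            j <- which.max(counts$m)
            if (sum(counts$s) <= 0) counts$s[j] <- counts$s[j] + 0.5
            else counts$s[j] <- counts$s[j] - 0.5
            counts
          }), se_, sp_)
        }
        q_b[i] <- fit$q_hat
      }
      names(q_b) <- labs
      nn <- n_s
      for (arm in arms) {
        n_t <- sum(n_s[arm])
        n1_b <- stats::rbinom(1L, n_t, n_s[arm[1]] / n_t)
        nn[arm[1]] <- n1_b; nn[arm[2]] <- n_t - n1_b
      }
      point_fun(q_b, nn)
    }, silent = TRUE)
    if (!inherits(res, "try-error")) reps[b] <- res
  }
  ok <- !is.na(reps)
  list(se = stats::sd(reps[ok]), failed = sum(!ok))
}
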