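#' Parse a design label into a design specification
#'
#' Recognized labels: `"standard"` (every subject assayed individually),
#' `"RS-f"` (random sampling: individual assays for about `1/f` of the
#' subjects, split equally over strata), and `"GT-f"` or `"GT-f-k"` (group
#' testing with the same assay budget as `RS-f` and pool size `k`, defaulting
#' to `k = f` so `GT-2`/`GT-3` match the convention that the pool size equals
#' the budget divisor).
#'
#' @param label Design label string.
#' @return An object of class `"design_spec"` with `label`, `type`,
#'   `fraction`, and `pool_size`.
#' @examples
#' design_spec("GT-3")
#' @export
design_spec <- function(label) {
  if (inherits(label, "design_spec")) return(label)
  lab <- toupper(trimws(label))
  if (lab == "STANDARD")
    return(structure(list(label = "standard", type = "standard",
                          fraction = 1, pool_size = 1L),
                     class = "design_spec"))
  m <- regmatches(lab, regexec("^(RS|GT)-([0-9]+)(-([0-9]+))?$", lab))[[1]]
  if (length(m) == 0L)
    stop(sprintf("unrecognized design label '%s' (expected 'standard', 'RS-f', 'GT-f' or 'GT-f-k')",
                 label), call. = FALSE)
  type <- tolower(m[2]); f <- as.integer(m[3])
  if (f < 1L) stop("assay fraction divisor must be >= 1", call. = FALSE)
  k <- if (type == "rs") 1L else if (m[5] != "") as.integer(m[5]) else f
  structure(list(label = toupper(label), type = type, fraction = f,
                 pool_size = k),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design %s: 1/%d of subjects assayed, pool size %d\n",
              x$label, x$fraction, x$pool_size))
  invisible(x)
}

# round-half-up (documented budget rule; R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Simulation scenario for design comparison
#'
#' Defines one Monte-Carlo experiment: the trial to simulate and the designs
#' to compare on it. In prognostic mode the marker `X ~ Bernoulli(prevalence)`
#' and the outcome `Y | X ~ Bernoulli(p_x)`; in predictive mode treatment
#' `T ~ Bernoulli(treatment_prob)` independently of `X`, and
#' `Y | (T, X) ~ Bernoulli(p_tx)`.
#'
#' @param mode `"prognostic"` or `"predictive"`.
#' @param n Trial sample size (>= 4).
#' @param prevalence Marker prevalence `P(X = 1)`.
#' @param response_probs Named vector of response probabilities: prognostic
#'   mode `c(p1 = , p0 = )` indexed by marker; predictive mode
#'   `c(p11 = , p10 = , p01 = , p00 = )` indexed treatment then marker.
#' @param designs Character vector or list of [design_spec] labels; the
#'   standard design is always included (it is the efficiency reference).
#' @param reps Number of Monte-Carlo replicates (default 10000).
#' @param seed Master seed; every replicate's randomness derives from it.
#' @param links Links to evaluate, default all three.
#' @param assay An [assay_model].
#' @param treatment_prob Randomization probability `P(T = 1)` (predictive
#'   mode), default 0.5.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("prognostic", n = 330, prevalence = 0.24,
#'               response_probs = c(p1 = 0.55, p0 = 0.45),
#'               designs = c("RS-2", "GT-2"), reps = 100, seed = 1)
#' @export
scenario_spec <- function(mode = c("prognostic", "predictive"), n, prevalence,
                          response_probs, designs = c("RS-2", "RS-3",
                                                      "GT-2", "GT-3"),
                          reps = 10000L, seed = 1L,
                          links = c("logit", "log", "identity"),
                          assay = assay_model(), treatment_prob = 0.5) {
  mode <- match.arg(mode)
  stopifnot(n >= 4, reps >= 1, prevalence >= 0, prevalence <= 1,
            treatment_prob > 0, treatment_prob < 1)
  need <- if (mode == "prognostic") c("p1", "p0")
  else c("p11", "p10", "p01", "p00")
  miss <- setdiff(need, names(response_probs))
  if (length(miss))
    stop("`response_probs` must be named ", paste(need, collapse = ", "),
         call. = FALSE)
  rp <- response_probs[need]
  if (any(rp < 0 | rp > 1))
    stop("response probabilities must lie in [0, 1]", call. = FALSE)
  designs <- lapply(designs, design_spec)
  labels <- vapply(designs, `[[`, character(1), "label")
  if (!"standard" %in% labels)
    designs <- c(list(design_spec("standard")), designs)
  links <- vapply(links, function(l) as_link(l)$name, character(1))
  structure(list(mode = mode, n = as.integer(n), prevalence = prevalence,
                 response_probs = rp, designs = designs,
                 reps = as.integer(reps), seed = as.integer(seed),
                 links = unname(links), assay = as_assay_model(assay),
                 treatment_prob = treatment_prob),
            class = "scenario_spec")
}

#' True value of each measure implied by a scenario
#'
#' @param spec A [scenario_spec].
#' @return Named vector of true measure values, one per link.
#' @export
true_measures <- function(spec) {
  rp <- spec$response_probs
  vapply(spec$links, function(l) {
    link <- link_function(l)
    if (spec$mode == "prognostic")
      association_measure(list(p1 = rp[["p1"]], p0 = rp[["p0"]]), link)
    else
      interaction_coefficient(list(p11 = rp[["p11"]], p10 = rp[["p10"]],
                                   p01 = rp[["p01"]], p00 = rp[["p00"]]),
                              link)
  }, numeric(1))
}

#' Simulate one phase-one trial from a scenario
#'
#' @param spec A [scenario_spec].
#' @param seed Integer seed for this replicate.
#' @return A [trial_data] object with fully known markers.
#' @export
simulate_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  x <- stats::rbinom(n, 1L, spec$prevalence)
  rp <- spec$response_probs
  if (spec$mode == "prognostic") {
    p <- ifelse(x == 1L, rp[["p1"]], rp[["p0"]])
    y <- stats::rbinom(n, 1L, p)
    trial_data(outcome = y, marker = x)
  } else {
    tr <- stats::rbinom(n, 1L, spec$treatment_prob)
    p <- unname(rp[paste0("p", tr, x)])
    y <- stats::rbinom(n, 1L, p)
    trial_data(outcome = y, treatment = tr, marker = x)
  }
}

# per-stratum assay budget for a non-standard design: total budget
# round(n / f) divided equally (round half up) over the strata, capped at
# stratum size by allocate_pools
design_budget <- function(design, n, n_strata) {
  total <- round_half_up(n / design$fraction)
  round_half_up(total / n_strata)
}

# stable per-design seed offset so a design's random stream does not depend
# on which other designs are in the list
design_offset <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100000L
}

#' Run a design-comparison Monte-Carlo experiment
#'
#' For each replicate, simulates a trial and estimates every requested
#' measure under every design: the standard design via [estimate_standard],
#' and each RS/GT design by allocating its per-stratum assay budget
#' ([allocate_pools]), assaying the pools ([assay_pools]), and applying the
#' pooled estimator ([estimate_from_pools], point estimates only). Replicates
#' on which *any* design fails (boundary prevalence estimate, empty cell, or
#' degenerate marker margin) are excluded pairwise from every design's
#' summary and counted.
#'
#' Across the retained replicates, the relative efficiency of a design for a
#' measure is `RE = Var(standard) / Var(design)` and its relative
#' cost-efficiency is `RCE = RE * (assays_standard / assays_design)` using
#' mean realized assay counts. Monte-Carlo uncertainty of RE and RCE is
#' quantified by a delete-1 jackknife over the paired replicate estimates.
#'
#' @param spec A [scenario_spec].
#' @return An object of class `"design_comparison"`: a summary `table` (one
#'   row per link x design), the retained estimate array (`estimates`) and
#'   the pre-exclusion array (`estimates_all`, `NA` where a design failed),
#'   per-design failure counts, mean assay counts, jackknife leave-one-out
#'   RE/RCE arrays, the truth per link, and the scenario.
#' @export
run_designs <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  designs <- spec$designs
  labels <- vapply(designs, `[[`, character(1), "label")
  links <- spec$links
  R <- spec$reps
  n_strata <- if (spec$mode == "prognostic") 2L else 4L

  set.seed(spec$seed)
  rep_seeds <- sample.int(2147483646L, R)

  est <- array(NA_real_, dim = c(R, length(designs), length(links)),
               dimnames = list(NULL, labels, links))
  assays <- matrix(NA_real_, R, length(designs),
                   dimnames = list(NULL, labels))
  failed <- stats::setNames(integer(length(designs)), labels)

  for (r in seq_len(R)) {
    trial <- simulate_trial(spec, seed = rep_seeds[r])
    for (d in seq_along(designs)) {
      des <- designs[[d]]
      res <- try({
        if (des$type == "standard") {
          assays[r, d] <- spec$n
          vapply(links, function(l)
            estimate_standard(trial, l)$estimate, numeric(1))
        } else {
          dseed <- (rep_seeds[r] + design_offset(des$label)) %% 2147483647L
          plan <- allocate_pools(trial,
                                 budget = design_budget(des, spec$n, n_strata),
                                 pool_size = des$pool_size, seed = dseed)
          batch <- assay_pools(plan, trial, spec$assay,
                               seed = (dseed + 1L) %% 2147483647L)
          assays[r, d] <- nrow(batch)
          strata <- trial_strata(trial)
          fits <- stratum_prevalences(batch, strata, spec$assay,
                                      correction = FALSE)
          q_hat <- vapply(fits, `[[`, numeric(1), "q_hat")
          n_s <- stats::setNames(strata$n, strata$label)
          cells <- if (spec$mode == "prognostic")
            bayes_convert_prognostic(q_hat[["y=1"]], q_hat[["y=0"]],
                                     n_s[["y=1"]], n_s[["y=0"]])
          else bayes_convert_predictive(q_hat[["t=1,y=1"]], q_hat[["t=1,y=0"]],
                                        q_hat[["t=0,y=1"]], q_hat[["t=0,y=0"]],
                                        n_s[["t=1,y=1"]], n_s[["t=1,y=0"]],
                                        n_s[["t=0,y=1"]], n_s[["t=0,y=0"]])
          vapply(links, function(l) {
            if (spec$mode == "prognostic") association_measure(cells, l)
            else interaction_coefficient(cells, l)
          }, numeric(1))
        }
      }, silent = TRUE)
      if (inherits(res, "try-error")) failed[d] <- failed[d] + 1L
      else est[r, d, ] <- res
    }
  }

  keep <- stats::complete.cases(matrix(est, nrow = R)) & !is.na(rowSums(assays))
  n_kept <- sum(keep)
  if (n_kept < 2L)
    stop("fewer than 2 replicates succeeded in every design", call. = FALSE)
  frac_failed <- 1 - n_kept / R
  if (frac_failed > 0.2)
    warning(sprintf(
      "%.1f%% of replicates failed in at least one design and were excluded pairwise",
      100 * frac_failed), call. = FALSE)
  est_k <- est[keep, , , drop = FALSE]
  assays_k <- assays[keep, , drop = FALSE]

  comp <- summarize_comparison(est_k, assays_k, labels, links)
  comp$estimates_all <- est   # pre-exclusion streams, NA where a design failed
  comp$keep <- keep
  comp$truth <- true_measures(spec)
  comp$n_total <- R
  comp$n_kept <- n_kept
  comp$failed <- failed
  comp$spec <- spec
  class(comp) <- "design_comparison"
  comp
}

# empirical variances, RE, RCE and delete-1 jackknife from retained
# replicate estimates (reps x designs x links) and realized assay counts
summarize_comparison <- function(est, assays, labels, links) {
  n <- dim(est)[1]; D <- dim(est)[2]; L <- dim(est)[3]
  std <- match("standard", labels)
  mean_assays <- colMeans(assays)

  # leave-one-out variance of each design x link estimate stream
  loo_var <- function(x) {
    s1 <- sum(x); s2 <- sum(x^2)
    mi <- (s1 - x) / (n - 1)
    (s2 - x^2 - (n - 1) * mi^2) / (n - 2)
  }
  loo_mean <- function(x) (sum(x) - x) / (n - 1)

  var_full <- apply(est, c(2, 3), stats::var)
  loo_v <- array(NA_real_, c(n, D, L))
  for (d in seq_len(D)) for (l in seq_len(L))
    loo_v[, d, l] <- loo_var(est[, d, l])
  loo_assay <- apply(assays, 2, loo_mean)

  re <- matrix(var_full[std, ], nrow = D, ncol = L, byrow = TRUE,
               dimnames = dimnames(var_full)) / var_full
  rce <- re * (mean_assays[std] / mean_assays)
  loo_re <- array(NA_real_, c(n, D, L))
  loo_rce <- array(NA_real_, c(n, D, L))
  for (d in seq_len(D)) for (l in seq_len(L)) {
    loo_re[, d, l] <- loo_v[, std, l] / loo_v[, d, l]
    loo_rce[, d, l] <- loo_re[, d, l] * loo_assay[, std] / loo_assay[, d]
  }
  jack_se <- function(theta) {
    m <- colMeans(theta)
    sqrt((n - 1) / n * colSums(sweep(theta, 2, m)^2))
  }
  re_se <- rce_se <- matrix(NA_real_, D, L, dimnames = list(labels, links))
  for (l in seq_len(L)) {
    re_se[, l] <- jack_se(loo_re[, , l, drop = TRUE])
    rce_se[, l] <- jack_se(loo_rce[, , l, drop = TRUE])
  }

  tab <- expand.grid(design = labels, link = links,
                     stringsAsFactors = FALSE)
  tab$mean_estimate <- mapply(function(d, l)
    mean(est[, match(d, labels), match(l, links)]), tab$design, tab$link)
  tab$variance <- mapply(function(d, l)
    var_full[match(d, labels), match(l, links)], tab$design, tab$link)
  tab$mean_assays <- mean_assays[tab$design]
  tab$RE <- mapply(function(d, l) re[match(d, labels), match(l, links)],
                   tab$design, tab$link)
  tab$RE_se <- mapply(function(d, l) re_se[match(d, labels), match(l, links)],
                      tab$design, tab$link)
  tab$RCE <- mapply(function(d, l) rce[match(d, labels), match(l, links)],
                    tab$design, tab$link)
  tab$RCE_se <- mapply(function(d, l)
    rce_se[match(d, labels), match(l, links)], tab$design, tab$link)
  rownames(tab) <- NULL

  list(table = tab, estimates = est, assays = assays,
       mean_assays = mean_assays,
       variances = var_full, RE = re, RCE = rce,
       RE_se = re_se, RCE_se = rce_se,
       loo_RE = loo_re, loo_RCE = loo_rce,
       designs = labels, links = links)
}

#' Relative cost-efficiency from relative efficiency and assay counts
#'
#' `RCE = RE * assays_standard / assays_design`: the information retained per
#' assay, relative to the standard design. A design with RE 0.85 using half
#' the assays of the standard design has RCE 1.7; RCE 2 means twice as much
#' information per assay as the standard design.
#'
#' @param re Relative efficiency (variance ratio standard / design).
#' @param assays_standard,assays_design Assay counts (or their means).
#' @return The relative cost-efficiency.
#' @examples
#' relative_cost_efficiency(0.85, 600, 300)  # 1.7
#' @export
relative_cost_efficiency <- function(re, assays_standard, assays_design) {
  stopifnot(re >= 0, assays_standard > 0, assays_design > 0)
  re * assays_standard / assays_design
}

#' Jackknife comparison of two designs' RE or RCE
#'
#' Difference in relative (cost-)efficiency between two designs for one link,
#' with a delete-1 jackknife standard error over the paired replicates.
#'
#' @param comparison A [run_designs] result.
#' @param design1,design2 Design labels; the difference is design1 - design2.
#' @param link Link name.
#' @param quantity `"RE"` or `"RCE"`.
#' @return List with `diff` and jackknife `se`.
#' @export
design_difference <- function(comparison, design1, design2, link,
                              quantity = c("RE", "RCE")) {
  quantity <- match.arg(quantity)
  d1 <- match(design_spec(design1)$label, comparison$designs)
  d2 <- match(design_spec(design2)$label, comparison$designs)
  l <- match(link, comparison$links)
  if (anyNA(c(d1, d2, l))) stop("design or link not in comparison",
                                call. = FALSE)
  full <- comparison[[quantity]]
  loo <- comparison[[paste0("loo_", quantity)]]
  diff_loo <- loo[, d1, l] - loo[, d2, l]
  n <- length(diff_loo)
  se <- sqrt((n - 1) / n * sum((diff_loo - mean(diff_loo))^2))
  list(diff = full[d1, l] - full[d2, l], se = se)
}

#' @export
print.design_comparison <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Design comparison (%s mode, n = %d, prevalence %.3g): %d/%d replicates retained\n",
    x$spec$mode, x$spec$n, x$spec$prevalence, x$n_kept, x$n_total))
  if (any(x$failed > 0))
    cat("Failed replicates per design:",
        paste(sprintf("%s: %d", names(x$failed), x$failed), collapse = ", "),
        "\n")
  print(format_comparison_table(x$table, digits), row.names = FALSE)
  invisible(x)
}

format_comparison_table <- function(tab, digits = 3) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  tab
}

#' Tabulate one or more design-comparison experiments
#'
#' Builds a wide report table with one row per scenario x measure and RE/RCE
#' (with jackknife Monte-Carlo SEs) in columns per design, mirroring the
#' usual layout of simulation summaries for design comparisons.
#'
#' @param comparisons A [run_designs] result or a (optionally named) list of
#'   them.
#' @return A data frame with columns `scenario`, `mode`, `n`, `measure`, then
#'   `RE <design>`, `RE_se <design>`, `RCE <design>`, `RCE_se <design>` per
#'   non-standard design.
#' @export
replicate_table <- function(comparisons) {
  if (inherits(comparisons, "design_comparison"))
    comparisons <- list(comparisons)
  if (is.null(names(comparisons)))
    names(comparisons) <- paste0("scenario", seq_along(comparisons))
  rows <- lapply(names(comparisons), function(nm) {
    comp <- comparisons[[nm]]
    nonstd <- setdiff(comp$designs, "standard")
    do.call(rbind, lapply(comp$links, function(l) {
      li <- match(l, comp$links)
      row <- data.frame(scenario = nm, mode = comp$spec$mode,
                        n = comp$spec$n,
                        measure = measure_name(comp$spec$mode,
                                               link_function(l)),
                        stringsAsFactors = FALSE)
      for (d in nonstd) {
        di <- match(d, comp$designs)
        row[[paste0("RE ", d)]] <- comp$RE[di, li]
        row[[paste0("RE_se ", d)]] <- comp$RE_se[di, li]
      }
      for (d in nonstd) {
        di <- match(d, comp$designs)
        row[[paste0("RCE ", d)]] <- comp$RCE[di, li]
        row[[paste0("RCE_se ", d)]] <- comp$RCE_se[di, li]
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
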