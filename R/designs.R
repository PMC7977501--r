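#' Assay error model for pooled binary tests
#'
#' Describes the accuracy of the binary assay applied to a (possibly pooled)
#' specimen. `sensitivity` is the probability that a pool containing at least
#' one marker-positive specimen tests positive; `specificity` is the
#' probability that a pool of only marker-negative specimens tests negative.
#' The default `assay_model()` is the perfect assay (Se = Sp = 1), under which
#' a pooled result is exactly the logical OR of its members' marker values.
#' Sensitivity and specificity are treated as known constants, not estimated.
#'
#' @param sensitivity Probability in (0, 1] that a truly positive pool tests
#'   positive.
#' @param specificity Probability in (0, 1] that a truly negative pool tests
#'   negative. `sensitivity + specificity` must exceed 1 (informative assay).
#' @return An object of class `"assay_model"`.
#' @examples
#' assay_model()            # perfect assay
#' assay_model(0.9, 0.95)   # imperfect assay
#' @export
assay_model <- function(sensitivity = 1, specificity = 1) {
  stopifnot(is.numeric(sensitivity), length(sensitivity) == 1L,
            is.numeric(specificity), length(specificity) == 1L)
  if (is.na(sensitivity) || sensitivity <= 0 || sensitivity > 1)
    stop("`sensitivity` must lie in (0, 1]", call. = FALSE)
  if (is.na(specificity) || specificity <= 0 || specificity > 1)
    stop("`specificity` must lie in (0, 1]", call. = FALSE)
  if (sensitivity + specificity <= 1)
    stop("uninformative assay: sensitivity + specificity must exceed 1",
         call. = FALSE)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "assay_model")
}

#' @export
print.assay_model <- function(x, ...) {
  if (x$sensitivity == 1 && x$specificity == 1) {
    cat("Perfect binary assay (Se = Sp = 1)\n")
  } else {
    cat(sprintf("Binary assay: sensitivity %.4g, specificity %.4g\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

is_perfect_assay <- function(assay) {
  assay$sensitivity == 1 && assay$specificity == 1
}

as_assay_model <- function(assay) {
  if (inherits(assay, "assay_model")) return(assay)
  if (is.list(assay))
    return(assay_model(assay$sensitivity %||% 1, assay$specificity %||% 1))
  stop("`assay` must be an assay_model object", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_binary <- function(x, what, allow_na = FALSE) {
  bad <- if (allow_na) !(is.na(x) | x %in% c(0, 1)) else !(x %in% c(0, 1))
  if (!allow_na && anyNA(x))
    stop(sprintf("`%s` contains missing values", what), call. = FALSE)
  if (any(bad))
    stop(sprintf("`%s` must be coded 0/1 (offending positions: %s)",
                 what, paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Phase-one trial data for a biomarker study
#'
#' Container for subject-level data from the completed clinical trial: the
#' binary outcome for everyone, the randomized treatment arm when the study is
#' in predictive mode, and the true marker status where known (fully known for
#' the standard design and for simulated subjects; unknown, i.e. `NA`, for real
#' subjects whose specimens have not been assayed individually).
#'
#' When `treatment` is supplied the study is in *predictive* mode and subjects
#' are stratified by (treatment, outcome); otherwise the study is in
#' *prognostic* mode and stratified by outcome only.
#'
#' @param outcome Integer vector of 0/1 outcomes (1 = responder).
#' @param treatment Optional integer vector of 0/1 treatment arms
#'   (1 = experimental).
#' @param marker Optional integer vector of 0/1 true marker values; `NA` for
#'   unknown. Defaults to all-`NA`.
#' @param subject_id Optional vector of unique subject identifiers.
#' @return An object of class `"trial_data"`: a list with the subject
#'   `records` data frame, the study `mode`, and per-stratum counts `n`.
#' @examples
#' td <- trial_data(outcome = c(1, 1, 0, 0), marker = c(1, 0, 0, 1))
#' td$n
#' @export
trial_data <- function(outcome, treatment = NULL, marker = NULL,
                       subject_id = NULL) {
  n <- length(outcome)
  if (n < 1L) stop("trial must contain at least one subject", call. = FALSE)
  check_binary(outcome, "outcome")
  if (!is.null(treatment)) {
    if (length(treatment) != n)
      stop("`treatment` length must match `outcome`", call. = FALSE)
    check_binary(treatment, "treatment")
  }
  if (is.null(marker)) marker <- rep(NA_integer_, n)
  if (length(marker) != n)
    stop("`marker` length must match `outcome`", call. = FALSE)
  check_binary(marker, "marker", allow_na = TRUE)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  if (anyDuplicated(subject_id))
    stop("`subject_id` values must be unique", call. = FALSE)
  mode <- if (is.null(treatment)) "prognostic" else "predictive"
  records <- data.frame(subject_id = subject_id,
                        treatment = if (mode == "predictive")
                          as.integer(treatment) else NA_integer_,
                        outcome = as.integer(outcome),
                        marker = as.integer(marker),
                        stringsAsFactors = FALSE)
  out <- structure(list(records = records, mode = mode), class = "trial_data")
  out$n <- stratum_counts(out)
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial data: %d subjects, %s mode\n", nrow(x$records), x$mode))
  print(x$n)
  invisible(x)
}

#' Strata of a trial
#'
#' Strata are defined by outcome in prognostic mode and by
#' (treatment, outcome) in predictive mode, ordered with responders first
#' within the experimental arm first.
#'
#' @param trial A [trial_data] object.
#' @return A data frame with columns `treatment` (`NA` in prognostic mode),
#'   `outcome`, `label`, and stratum size `n`.
#' @export
trial_strata <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  rec <- trial$records
  if (trial$mode == "prognostic") {
    df <- data.frame(treatment = NA_integer_, outcome = c(1L, 0L))
  } else {
    df <- data.frame(treatment = c(1L, 1L, 0L, 0L),
                     outcome = c(1L, 0L, 1L, 0L))
  }
  df$label <- stratum_label(df$treatment, df$outcome)
  df$n <- vapply(seq_len(nrow(df)), function(i) {
    sum(stratum_member(rec, df$treatment[i], df$outcome[i]))
  }, integer(1))
  df
}

stratum_label <- function(treatment, outcome) {
  ifelse(is.na(treatment),
         paste0("y=", outcome),
         paste0("t=", treatment, ",y=", outcome))
}

stratum_member <- function(records, treatment, outcome) {
  if (is.na(treatment)) records$outcome == outcome
  else records$treatment == treatment & records$outcome == outcome
}

stratum_counts <- function(trial) {
  s <- trial_strata(trial)
  stats::setNames(s$n, s$label)
}

resolve_per_stratum <- function(x, strata, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, nrow(strata)), strata$label))
  if (!is.null(names(x))) {
    miss <- setdiff(strata$label, names(x))
    if (length(miss))
      stop(sprintf("`%s` missing strata: %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    return(x[strata$label])
  }
  if (length(x) == nrow(strata))
    return(stats::setNames(x, strata$label))
  stop(sprintf("`%s` must be a scalar or one value per stratum", what),
       call. = FALSE)
}

#' Allocate subjects to assay pools within outcome (and treatment) strata
#'
#' Builds a pooling plan for a random-sampling or group-testing design. In
#' each stratum, `budget` pools of `pool_size` subjects are formed from
#' subjects drawn uniformly at random without replacement. When a stratum has
#' fewer than `budget * pool_size` subjects, pools are filled greedily at the
#' target size and the final pool shrinks (down to size 1) until subjects are
#' exhausted, so the target size is used "to the extent possible"; when it has
#' fewer than `budget` subjects, the number of pools is capped at the stratum
#' size. Shortfalls are recorded as warnings on the returned plan.
#'
#' `pool_size = 1` in every stratum yields a random-sampling (RS) design;
#' `pool_size = 1` with `budget` at least each stratum size reproduces the
#' standard design in which every subject is assayed individually.
#'
#' @param trial A [trial_data] object.
#' @param budget Number of assays per stratum: a scalar, or a vector named by
#'   stratum label (see [trial_strata]).
#' @param pool_size Target pool size(s) (integer >= 1), scalar or per-stratum
#'   as for `budget`.
#' @param seed Optional integer seed for reproducible subject selection.
#' @return An object of class `"pooling_plan"`: pool metadata (`pools` data
#'   frame with stratum, pool id, realized size), the member row indices per
#'   pool, and any shortfall `warnings`.
#' @examples
#' td <- trial_data(outcome = rep(c(1, 0), each = 50),
#'                  marker = rbinom(100, 1, 0.3))
#' plan <- allocate_pools(td, budget = 10, pool_size = 2, seed = 1)
#' plan$pools[1:3, ]
#' @export
allocate_pools <- function(trial, budget, pool_size, seed = NULL) {
  stopifnot(inherits(trial, "trial_data"))
  strata <- trial_strata(trial)
  budget <- resolve_per_stratum(budget, strata, "budget")
  pool_size <- resolve_per_stratum(pool_size, strata, "pool_size")
  if (any(is.na(budget)) || any(budget < 0) || any(budget != floor(budget)))
    stop("`budget` must be non-negative integers", call. = FALSE)
  if (any(is.na(pool_size)) || any(pool_size < 1) ||
      any(pool_size != floor(pool_size)))
    stop("`pool_size` must be integers >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  pools <- vector("list", nrow(strata))
  members <- list()
  warn <- character(0)
  rec <- trial$records
  for (i in seq_len(nrow(strata))) {
    lab <- strata$label[i]
    idx <- which(stratum_member(rec, strata$treatment[i], strata$outcome[i]))
    n_s <- length(idx)
    m <- unname(budget[lab]); k <- unname(pool_size[lab])
    if (m == 0L || n_s == 0L) {
      pools[[i]] <- data.frame(stratum_treatment = integer(0),
                               stratum_outcome = integer(0),
                               pool_id = integer(0), pool_size = integer(0))
      if (m > 0L && n_s == 0L)
        warn <- c(warn, sprintf("stratum %s is empty; no pools formed", lab))
      next
    }
    want <- m * k
    take <- min(want, n_s)
    chosen <- if (take == n_s) sample(idx) else sample(idx, take)
    # greedy fill at target size k; the remainder becomes one smaller pool
    sizes <- rep.int(k, take %/% k)
    if (take %% k > 0L) sizes <- c(sizes, take %% k)
    sizes <- sizes[seq_len(min(length(sizes), m))]
    if (take < want)
      warn <- c(warn, sprintf(
        "stratum %s: budget %d pools of size %d needs %d subjects but only %d available; realized %d pools",
        lab, m, k, want, n_s, length(sizes)))
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    mem <- lapply(seq_along(sizes), function(j) chosen[starts[j]:ends[j]])
    pools[[i]] <- data.frame(stratum_treatment = strata$treatment[i],
                             stratum_outcome = strata$outcome[i],
                             pool_id = seq_along(sizes),
                             pool_size = as.integer(sizes))
    members <- c(members, mem)
  }
  pools <- do.call(rbind, pools)
  rownames(pools) <- NULL
  structure(list(pools = pools, members = members, warnings = warn,
                 mode = trial$mode),
            class = "pooling_plan")
}

#' @export
print.pooling_plan <- function(x, ...) {
  cat(sprintf("Pooling plan: %d pools over %d strata (%s mode)\n",
              nrow(x$pools),
              length(unique(stratum_label(x$pools$stratum_treatment,
                                          x$pools$stratum_outcome))),
              x$mode))
  tab <- table(stratum_label(x$pools$stratum_treatment, x$pools$stratum_outcome),
               x$pools$pool_size)
  print(tab)
  if (length(x$warnings)) cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Assay the pools of a pooling plan
#'
#' Produces the binary pooled test results. A pool containing at least one
#' marker-positive subject tests positive with probability `sensitivity`; a
#' pool of only marker-negative subjects tests positive with probability
#' `1 - specificity`. Under the perfect assay the result is exactly the
#' logical OR of the members' marker values.
#'
#' @param plan A [allocate_pools] plan.
#' @param trial The [trial_data] the plan was built from; every pooled subject
#'   must have a known marker value.
#' @param assay An [assay_model]; defaults to the perfect assay.
#' @param seed Optional integer seed for assay noise (unused by the perfect
#'   assay).
#' @return An object of class `"pooled_batch"`: a data frame with columns
#'   `stratum_treatment`, `stratum_outcome`, `pool_id`, `pool_size`, `result`.
#' @export
assay_pools <- function(plan, trial, assay = assay_model(), seed = NULL) {
  stopifnot(inherits(plan, "pooling_plan"), inherits(trial, "trial_data"))
  assay <- as_assay_model(assay)
  if (!is.null(seed)) set.seed(seed)
  marker <- trial$records$marker
  any_pos <- vapply(plan$members, function(mem) {
    x <- marker[mem]
    if (anyNA(x))
      stop("pooled subject has unknown marker status; pools can only be ",
           "simulated from subjects with known markers", call. = FALSE)
    any(x == 1L)
  }, logical(1))
  if (is_perfect_assay(assay)) {
    result <- as.integer(any_pos)
  } else {
    p_pos <- ifelse(any_pos, assay$sensitivity, 1 - assay$specificity)
    result <- stats::rbinom(length(p_pos), 1L, p_pos)
  }
  out <- plan$pools
  out$result <- result
  class(out) <- c("pooled_batch", "data.frame")
  out
}

as_pooled_batch <- function(df) {
  need <- c("stratum_outcome", "pool_id", "pool_size", "result")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pooled batch is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$stratum_treatment)) df$stratum_treatment <- NA_integer_
  check_binary(df$result, "result")
  if (any(df$pool_size < 1))
    stop("pool sizes must be >= 1", call. = FALSE)
  key <- paste(stratum_label(df$stratum_treatment, df$stratum_outcome),
               df$pool_id)
  if (anyDuplicated(key))
    stop("pool ids must be unique within a stratum", call. = FALSE)
  class(df) <- c("pooled_batch", "data.frame")
  df
}

batch_stratum <- function(batch, treatment, outcome) {
  sel <- if (is.na(treatment)) is.na(batch$stratum_treatment) &
    batch$stratum_outcome == outcome
  else !is.na(batch$stratum_treatment) &
    batch$stratum_treatment == treatment & batch$stratum_outcome == outcome
  batch[sel, , drop = FALSE]
}
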