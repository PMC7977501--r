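#' Read subject-level trial data from CSV
#'
#' Expects a comma-separated, UTF-8 file with a mandatory header
#' `subject_id,treatment,outcome,marker`. `treatment` and `marker` cells may
#' be empty (unknown); `outcome` is required for every subject; all coded
#' values must be 0 or 1 (string labels are rejected to avoid silent
#' recoding). An entirely empty `treatment` column yields a prognostic-mode
#' trial.
#'
#' @param path Path to the CSV file.
#' @return A [trial_data] object.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "treatment", "outcome", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  parse01 <- function(col, what, required) {
    v <- trimws(df[[col]])
    v[v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (required) bad <- bad | is.na(v)
    if (any(bad))
      stop(sprintf("column `%s` must be 0/1%s; offending line(s): %s",
                   what, if (required) "" else " or empty",
                   paste(utils::head(which(bad) + 1L, 5L), collapse = ", ")),
           call. = FALSE)
    as.integer(v)
  }
  outcome <- parse01("outcome", "outcome", required = TRUE)
  treatment <- parse01("treatment", "treatment", required = FALSE)
  marker <- parse01("marker", "marker", required = FALSE)
  if (all(is.na(treatment))) treatment <- NULL
  else if (anyNA(treatment))
    stop("column `treatment` must be all empty (prognostic mode) or fully ",
         "observed (predictive mode)", call. = FALSE)
  trial_data(outcome = outcome, treatment = treatment, marker = marker,
             subject_id = df$subject_id)
}

#' Write subject-level trial data to CSV
#'
#' Inverse of [read_subjects]; unknown values are written as empty cells.
#'
#' @param trial A [trial_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(trial, path) {
  stopifnot(inherits(trial, "trial_data"))
  rec <- trial$records
  df <- data.frame(subject_id = rec$subject_id,
                   treatment = ifelse(is.na(rec$treatment), "",
                                      as.character(rec$treatment)),
                   outcome = rec$outcome,
                   marker = ifelse(is.na(rec$marker), "",
                                   as.character(rec$marker)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pooled assay results from CSV
#'
#' Expects a header `stratum_treatment,stratum_outcome,pool_id,pool_size,result`
#' with `stratum_treatment` empty for outcome-only (prognostic) strata.
#'
#' @param path Path to the CSV file.
#' @return A `"pooled_batch"` data frame.
#' @export
read_pools <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("stratum_treatment", "stratum_outcome", "pool_id", "pool_size",
            "result")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pools file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr <- trimws(df$stratum_treatment); tr[tr == ""] <- NA_character_
  out <- data.frame(stratum_treatment = as.integer(tr),
                    stratum_outcome = as.integer(df$stratum_outcome),
                    pool_id = df$pool_id,
                    pool_size = as.integer(df$pool_size),
                    result = as.integer(df$result),
                    stringsAsFactors = FALSE)
  if (anyNA(out$stratum_outcome) || anyNA(out$pool_size) || anyNA(out$result))
    stop("pools file contains non-numeric stratum_outcome, pool_size or result",
         call. = FALSE)
  as_pooled_batch(out)
}

#' Write pooled assay results to CSV
#'
#' @param batch A `"pooled_batch"` data frame (see [assay_pools]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pools <- function(batch, path) {
  df <- as.data.frame(batch)
  df$stratum_treatment <- ifelse(is.na(df$stratum_treatment), "",
                                 as.character(df$stratum_treatment))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_payload <- function(report) {
  if (inherits(report, "design_comparison")) {
    list(kind = "design_comparison", table = report$table,
         n_total = report$n_total, n_kept = report$n_kept,
         failed = as.list(report$failed))
  } else if (inherits(report, "measure_estimate")) {
    prev <- report$prevalences
    list(kind = "measure_estimate", measure = report$measure,
         estimate = report$estimate, se = report$se,
         se_method = report$se_method, assay_count = report$assay_count,
         prevalences = if (!is.null(prev)) data.frame(
           stratum = names(prev),
           q_hat = vapply(prev, `[[`, numeric(1), "q_hat"),
           variance = vapply(prev, `[[`, numeric(1), "variance"),
           assays = vapply(prev, `[[`, numeric(1), "assay_count"),
           row.names = NULL) else NULL)
  } else if (inherits(report, "info_curve")) {
    list(kind = "info_curve",
         table = data.frame(q = report$grid,
                            report$info,
                            optimal = report$optimal,
                            check.names = FALSE),
         bands = report$bands, crossovers = report$crossovers)
  } else if (is.data.frame(report)) {
    list(kind = "table", table = report)
  } else {
    stop("unsupported report object of class ",
         paste(class(report), collapse = "/"), call. = FALSE)
  }
}

#' Write an analysis report to TSV or JSON
#'
#' Serializes a [run_designs] comparison, a measure estimate, an
#' [info_crossovers] curve, or a plain data frame. Both formats embed the
#' tool version and the seed used, and round-trip at full numeric precision
#' (TSV carries metadata in `#`-prefixed comment lines; JSON in a metadata
#' object).
#'
#' @param report The object to write.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param seed The seed the report was produced under (recorded in the
#'   output).
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path, format = c("tsv", "json"),
                          seed = NULL) {
  format <- match.arg(format)
  payload <- results_payload(report)
  meta <- list(tool = "gtbiomark",
               version = as.character(utils::packageVersion("gtbiomark")),
               seed = seed)
  if (format == "json") {
    jsonlite::write_json(c(list(metadata = meta), payload), path,
                         auto_unbox = TRUE, digits = I(17), na = "null",
                         dataframe = "rows")
  } else {
    tab <- payload$table
    if (is.null(tab))
      tab <- data.frame(field = names(payload)[-1],
                        value = vapply(payload[-1], function(v)
                          paste(format(v, digits = 17), collapse = ";"),
                          character(1)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# tool=gtbiomark version=%s seed=%s kind=%s",
                       meta$version,
                       if (is.null(seed)) "NA" else seed,
                       payload$kind), con)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a results file written by [write_results]
#'
#' @param path Path to the TSV or JSON file.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return For TSV, the data frame (metadata in attribute `"metadata"`); for
#'   JSON, the full parsed list.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") return(jsonlite::fromJSON(path))
  meta <- readLines(path, n = 1L)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  attr(df, "metadata") <- sub("^# ", "", meta)
  df
}

#' Generate synthetic fixture files
#'
#' Deterministic (under `seed`) generator of the small input files used in
#' tests and documentation: `"subjects"` writes a subject CSV with fully
#' known true markers (so pooled results can be regenerated under any
#' design), `"pools"` builds and assays a pooling design over an existing
#' subjects file, and `"scenario"` writes a YAML scenario that
#' [run_scenario_file] / the `simulate` subcommand accepts unchanged.
#'
#' @param kind `"subjects"`, `"pools"`, or `"scenario"`.
#' @param path Output file path.
#' @param params Named list of parameters. Subjects: `n`, `prevalence`,
#'   optional `response_probs` + `mode`/`treatment_prob` (defaults: marker
#'   and outcome independent Bernoulli). Pools: `subjects` (path), `budget`,
#'   `pool_size`, optional `sensitivity`/`specificity`. Scenario: any
#'   [scenario_spec] field override.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(kind = c("subjects", "pools", "scenario"),
                             path, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "subjects") {
    n <- params$n %||% 100L
    prevalence <- params$prevalence %||% 0.24
    mode <- params$mode %||% "prognostic"
    rp <- params$response_probs %||%
      (if (mode == "prognostic") c(p1 = 0.55, p0 = 0.45)
       else c(p11 = 0.65, p10 = 0.45, p01 = 0.50, p00 = 0.50))
    spec <- scenario_spec(mode, n = n, prevalence = prevalence,
                          response_probs = rp, designs = "RS-2", reps = 1,
                          seed = seed,
                          treatment_prob = params$treatment_prob %||% 0.5)
    trial <- simulate_trial(spec, seed = seed)
    write_subjects(trial, path)
  } else if (kind == "pools") {
    if (is.null(params$subjects))
      stop("pools fixture needs params$subjects (subject CSV path)",
           call. = FALSE)
    trial <- read_subjects(params$subjects)
    assay <- assay_model(params$sensitivity %||% 1, params$specificity %||% 1)
    plan <- allocate_pools(trial, budget = params$budget %||% 20L,
                           pool_size = params$pool_size %||% 2L, seed = seed)
    batch <- assay_pools(plan, trial, assay, seed = seed + 1L)
    write_pools(batch, path)
  } else {
    sc <- list(mode = params$mode %||% "predictive",
               n = as.integer(params$n %||% 657L),
               prevalence = params$prevalence %||% 0.24,
               response_probs = as.list(params$response_probs %||%
                 c(p11 = 0.65, p10 = 0.45, p01 = 0.50, p00 = 0.50)),
               designs = params$designs %||% c("RS-2", "RS-3", "GT-2", "GT-3"),
               reps = as.integer(params$reps %||% 2000L),
               seed = as.integer(seed),
               assay = list(sensitivity = params$sensitivity %||% 1,
                            specificity = params$specificity %||% 1),
               treatment_prob = params$treatment_prob %||% 0.5)
    yaml::write_yaml(sc, path)
  }
  invisible(path)
}

#' Load a scenario from a YAML file
#'
#' @param path YAML file as produced by [generate_fixture]`("scenario")`.
#' @param reps,seed Optional overrides.
#' @return A [scenario_spec].
#' @export
scenario_from_yaml <- function(path, reps = NULL, seed = NULL) {
  sc <- yaml::read_yaml(path)
  need <- c("mode", "n", "prevalence", "response_probs")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("scenario file is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  scenario_spec(mode = sc$mode, n = sc$n, prevalence = sc$prevalence,
                response_probs = unlist(sc$response_probs),
                designs = sc$designs %||% c("RS-2", "RS-3", "GT-2", "GT-3"),
                reps = reps %||% sc$reps %||% 10000L,
                seed = seed %||% sc$seed %||% 1L,
                links = sc$links %||% c("logit", "log", "identity"),
                assay = assay_model(sc$assay$sensitivity %||% 1,
                                    sc$assay$specificity %||% 1),
                treatment_prob = sc$treatment_prob %||% 0.5)
}

#' Run the design comparison described by a scenario YAML file
#'
#' @inheritParams scenario_from_yaml
#' @return A [run_designs] `"design_comparison"` object.
#' @export
run_scenario_file <- function(path, reps = NULL, seed = NULL) {
  run_designs(scenario_from_yaml(path, reps = reps, seed = seed))
}
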