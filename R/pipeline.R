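## Required columns and types for the CSV trial-table schemas.
TABLE_SCHEMAS <- list(
  adjustment = c(subject_id = "character", distance_cm = "numeric",
                 cue = "character", z_texture_mm = "numeric",
                 z_disparity_mm = "numeric", z_mm = "numeric",
                 rep = "numeric", probe_mm = "numeric"),
  twoifc = c(subject_id = "character", distance_cm = "numeric",
             cue = "character", size = "character", standard_mm = "numeric",
             comparison_mm = "numeric", staircase_rule = "character",
             trial_idx = "numeric", chose_comparison = "logical",
             is_reversal = "logical"),
  results = c(subject_id = "character", observed = "numeric",
              predicted = "numeric", model = "character")
)

#' Write a trial or results table to CSV
#'
#' @param df data.frame to write.
#' @param path destination path.
#' @param schema optional schema name (`"adjustment"`, `"twoifc"`,
#'   `"results"`) to validate against before writing.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) check_schema(df, schema, where = "in-memory table")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial or results table from CSV
#'
#' Round-trips tables written by [write_trial_table()]; extra columns are
#' preserved, missing or mistyped required columns raise descriptive
#' errors, and malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @param schema schema name (`"adjustment"`, `"twoifc"`, `"results"`).
#' @return a data.frame.
#' @export
read_trial_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, schema, where = path)
  df
}

check_schema <- function(df, schema, where) {
  sch <- TABLE_SCHEMAS[[match.arg(schema, names(TABLE_SCHEMAS))]]
  missing_cols <- setdiff(names(sch), names(df))
  if (length(missing_cols) > 0L) {
    stop(where, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ## columns that may legitimately contain NA (absent cues)
  na_ok <- c("z_texture_mm", "z_disparity_mm")
  for (col in names(sch)) {
    v <- df[[col]]
    ok <- switch(sch[[col]],
                 numeric = is.numeric(v),
                 character = is.character(v) || is.factor(v),
                 logical = is.logical(v))
    if (!ok) stop(where, ": column '", col, "' should be ", sch[[col]],
                  ", got ", class(v)[1L])
    if (!(col %in% na_ok) && anyNA(v)) {
      stop(where, ": malformed value(s) in column '", col, "' at row(s) ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Bundles the experimental design, cohort specification, staircase and
#' analysis options behind one master seed. Serialisable to/from JSON.
#'
#' @param observer_class `"ic"` or `"mle"`.
#' @param n_subjects cohort size.
#' @param seed master seed; all randomness derives from it.
#' @param design an [exp1_design()].
#' @param population optional population spec; defaults to
#'   [ic_population()] or [mle_population()] according to `observer_class`.
#' @param run_exp2 run the (slow) staircase experiment?
#' @param run_exp3 run the flatness-cue experiment (both variants)?
#' @param target_reversals staircase reversal target.
#' @param pooling psychometric pooling mode (see [analyze_exp2()]).
#' @param intercept_mode free intercept in cue-strength fits?
#' @param corrected_jnd_form `"scaled"` or `"unscaled"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(observer_class = c("ic", "mle"),
                            n_subjects = 12L, seed = 1L,
                            design = exp1_design(), population = NULL,
                            run_exp2 = TRUE, run_exp3 = TRUE,
                            target_reversals = 12L,
                            pooling = c("pooled", "per_staircase"),
                            intercept_mode = TRUE,
                            corrected_jnd_form = c("scaled", "unscaled")) {
  observer_class <- match.arg(observer_class)
  pooling <- match.arg(pooling)
  corrected_jnd_form <- match.arg(corrected_jnd_form)
  if (is.null(population)) {
    population <- if (observer_class == "ic") ic_population()
                  else mle_population()
  }
  structure(
    list(observer_class = observer_class, n_subjects = as.integer(n_subjects),
         seed = as.integer(seed), design = design, population = population,
         run_exp2 = isTRUE(run_exp2), run_exp3 = isTRUE(run_exp3),
         target_reversals = as.integer(target_reversals), pooling = pooling,
         intercept_mode = isTRUE(intercept_mode),
         corrected_jnd_form = corrected_jnd_form),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' Scalar fields override the [pipeline_config()] defaults; the optional
#' `population` object is interpreted per `observer_class` with range-valued
#' parameters given as two-element arrays.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        c("observer_class", "n_subjects", "seed", "run_exp2",
                          "run_exp3", "target_reversals", "pooling",
                          "intercept_mode", "corrected_jnd_form"))]
  if (!is.null(raw$design)) {
    args$design <- do.call(exp1_design, raw$design)
  }
  if (!is.null(raw$population)) {
    ctor <- if (identical(raw$observer_class, "mle")) mle_population
            else ic_population
    args$population <- do.call(ctor, raw$population)
  }
  do.call(pipeline_config, args)
}

#' Run the full simulate-analyze-predict pipeline
#'
#' Generates the probe-adjustment experiment, estimates cue strengths,
#' makes the parameter-free combined-cue predictions, runs the SD analysis
#' and (optionally) the staircase and flatness-cue experiments with their
#' model comparisons, writing every intermediate table as CSV when
#' `out_dir` is given. Deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for CSV tables and the JSON
#'   summary.
#' @param quiet suppress stage messages?
#' @return a results bundle (list of tables and summaries), invisibly when
#'   `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[icdepth] ", ...)
  emit <- function(df, name, schema = NULL) {
    if (!is.null(out_dir)) {
      write_trial_table(df, file.path(out_dir, paste0(name, ".csv")), schema)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list(config = config)

  say("drawing cohort of ", config$n_subjects, " ", config$observer_class,
      " observers")
  cohort <- make_cohort(config$population, config$n_subjects, config$seed)

  say("simulating adjustment experiment")
  exp1 <- generate_exp1(cohort, config$design, seed = config$seed)
  emit(exp1, "exp1_trials", "adjustment")
  res$exp1 <- exp1

  say("estimating cue strengths")
  strengths <- estimate_cue_strengths(exp1, intercept = config$intercept_mode)
  emit(strengths, "cue_strengths")
  res$strengths <- strengths

  say("parameter-free combined-cue predictions")
  comb <- predict_and_compare_combined(strengths)
  emit(comb$records, "combined_slope_predictions", "results")
  res$combined_prediction <- comb

  if (config$design$reps >= 3L) {
    say("adjustment-SD analysis")
    res$sd_analysis <- adjustment_sd_analysis(exp1)
    emit(res$sd_analysis$sd_table, "adjustment_sds")
  } else {
    warning("fewer than 3 repetitions: SD analysis skipped")
  }

  if (config$run_exp2) {
    say("selecting perceived-depth-matched standards")
    standards <- select_standards(exp1)
    emit(standards, "standards")
    res$standards <- standards
    say("simulating 2IFC staircases")
    exp2 <- generate_exp2(cohort, standards,
                          target_reversals = config$target_reversals,
                          seed = config$seed)
    emit(exp2, "exp2_trials", "twoifc")
    res$exp2 <- exp2
    say("psychometric fits")
    jnds <- analyze_exp2(exp2, mode = config$pooling)
    emit(jnds, "jnd_records")
    res$jnd_records <- jnds
    screened <- exclude_outlier_condition(jnds)
    res$jnd_exclusion <- screened$excluded
    res$jnd_pred_vector_sum <- predict_jnd_vector_sum(screened$records)
    res$jnd_pred_mle <- tryCatch(predict_jnd_mle(screened$records),
                                 error = function(e) NULL)
    emit(res$jnd_pred_vector_sum, "jnd_predictions_vector_sum", "results")
    say("Weber task-noise fits")
    res$weber_fits <- fit_weber_model(screened$records, strengths)
    emit(res$weber_fits, "weber_fits")
    wmean <- colMeans(res$weber_fits[, c("weber_W", "constant_c")])
    res$weber_summary <- list(
      weber_W_mean = unname(wmean[1L]),
      weber_W_se = stats::sd(res$weber_fits$weber_W) /
        sqrt(nrow(res$weber_fits)),
      constant_c_mean = unname(wmean[2L]),
      constant_c_se = stats::sd(res$weber_fits$constant_c) /
        sqrt(nrow(res$weber_fits)))
  }

  if (config$run_exp3) {
    say("simulating flatness-cue experiments")
    res$exp3 <- lapply(c(A = "A", B = "B"), function(v) {
      tab <- generate_exp3(cohort, experiment = v,
                           depths_mm = config$design$depths_mm,
                           distances_cm = config$design$distances_cm,
                           reps = config$design$reps, seed = config$seed)
      emit(tab, paste0("exp3", v, "_trials"))
      agg <- stats::aggregate(probe_mm ~ subject_id + distance_cm +
                                flatness_condition + z_mm,
                              data = tab, FUN = mean)
      f0 <- fit_random_intercept_lmm(
        agg, probe_mm ~ z_mm + factor(distance_cm), "subject_id")
      f1 <- fit_random_intercept_lmm(
        agg, probe_mm ~ z_mm + factor(distance_cm) + flatness_condition,
        "subject_id")
      list(trials = tab, bf = bic_bayes_factor(f0, f1))
    })
  }

  res$summary <- list(
    n_subjects = config$n_subjects, seed = config$seed,
    observer_class = config$observer_class,
    slope_regression = comb$regression,
    weber = res$weber_summary,
    flatness_bf01 = if (!is.null(res$exp3)) {
      lapply(res$exp3, function(e) e$bf$bf01)
    })
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Command-line entry point
#'
#' Thin wrapper over [run_pipeline()] used by `inst/cli/icdepth.R`.
#' Subcommands: `simulate` (runs generation + analysis end to end) and
#' `report` (prints the summary of an existing run directory).
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
icdepth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: icdepth.R <simulate|report> [--config FILE] [--seed N] ",
    "[--out DIR] [--observer ic|mle] [--n N]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- list(seed = 1L, out = "icdepth_out", observer = "ic", n = 12L,
              config = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (cmd == "simulate") {
    cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
           else pipeline_config(observer_class = opt$observer,
                                n_subjects = as.integer(opt$n),
                                seed = as.integer(opt$seed))
    run_pipeline(cfg, out_dir = opt$out)
    message("results written to ", opt$out)
    return(invisible(0L))
  }
  if (cmd == "report") {
    p <- file.path(opt$out, "summary.json")
    if (!file.exists(p)) { message("no summary at ", p); return(invisible(1L)) }
    cat(readLines(p), sep = "\n")
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
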