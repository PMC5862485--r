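#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (readable from JSON with
#' `jsonlite::read_json(..., simplifyVector = TRUE)`). Unknown keys are
#' rejected so typos fail loudly before any stage runs.
#'
#' Recognized keys: `seed` (integer, required), `out_dir` (required),
#' `stages` (subset of `"simulate"`, `"tabulate"`, `"fit"`, `"effects"`,
#' `"ttest"`, default the first four), `age_range`, `period_range`,
#' `deaths_file`, `births_file` (inputs for `tabulate` when not
#' simulating), `apc` (named list of [apc_spec()] arguments), `truth`
#' (named list of [true_effects()] arguments), `exposure_per_cell`,
#' `grid_step`, `ttest` (list with `by`, `levels`, `ci_level`).
#'
#' @param config named list.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  known <- c("seed", "out_dir", "stages", "age_range", "period_range",
             "deaths_file", "births_file", "apc", "truth",
             "exposure_per_cell", "grid_step", "ttest")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  defaults <- list(stages = c("simulate", "tabulate", "fit", "effects"),
                   age_range = c(10, 54), period_range = c(2002, 2014),
                   apc = list(), truth = list(),
                   exposure_per_cell = 1e5, grid_step = 0.25)
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$stages,
                 c("simulate", "tabulate", "fit", "effects", "ttest"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  config$seed <- as.integer(config$seed)
  config
}

#' Run the analysis pipeline
#'
#' Wires the stages end to end: `simulate` (synthetic records + Lexis
#' truth), `tabulate` (records to Lexis table, written to
#' `lexis.csv`), `fit` (APC model, coefficients and fit statistics to
#' `fit.json`), `effects` (age/period/cohort curves to
#' `curve_age.csv` etc.), `ttest` (group comparison to `ttest.json`).
#' Every run writes a `manifest.json` stamped with the package version,
#' a hash of the configuration and the seed; progress and row counts are
#' logged to standard error. On stage failure, partial artifacts are kept,
#' a `FAILED` marker file names the stage, and a non-zero status is
#' returned (2 config error, 3 fit error, 4 I/O error).
#'
#' @param config named list, see [validate_config()]; or a path to a JSON
#'   file holding one.
#' @return list with `status` (0 on success), `artifacts` (named file
#'   paths), and on failure `error` (the condition message).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) return(pipeline_fail(NULL, "config", 4,
                                     paste("config file not found:", config)))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- tryCatch(validate_config(config), error = function(e) e)
  if (inherits(config, "error"))
    return(pipeline_fail(NULL, "config", 2, conditionMessage(config)))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  log_msg <- function(...) message("[apcmort] ", sprintf(...))

  stamp <- list(package_version = as.character(utils::packageVersion("apcmort")),
                config_hash = config_hash(config), seed = config$seed,
                stages = config$stages)
  jsonlite::write_json(stamp, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  artifacts$manifest <- file.path(out, "manifest.json")

  env <- new.env(parent = emptyenv())
  stage_impl <- list(
    simulate = function() {
      truth <- do.call(true_effects, as.list(config$truth))
      sim <- simulate_lexis(truth, exposure_uniform(config$exposure_per_cell),
                            config$age_range, config$period_range,
                            seed = config$seed, records = TRUE)
      env$records <- sim$records
      env$births <- data.frame(
        mother_age = sim$table$age, year = sim$table$period,
        births = sim$table$exposure)
      log_msg("simulate: %d cells, %d death records",
              nrow(sim$table), nrow(sim$records))
    },
    tabulate = function() {
      if (is.null(env$records)) {
        env$records <- read_death_records(config$deaths_file)
        env$births <- read_birth_counts(config$births_file)
      }
      env$table <- build_lexis(env$records, env$births,
                               config$age_range, config$period_range)
      f <- file.path(out, "lexis.csv")
      utils::write.csv(as.data.frame(env$table), f, row.names = FALSE)
      artifacts$lexis <<- f
      log_msg("tabulate: %d cells, %d deaths",
              nrow(env$table), sum(env$table$deaths))
    },
    fit = function() {
      spec <- do.call(apc_spec, as.list(config$apc))
      env$fit <- apc_fit(env$table, spec)
      f <- file.path(out, "fit.json")
      fit <- env$fit
      jsonlite::write_json(list(
        coefficients = as.list(fit$beta),
        blocks = lapply(fit$design$blocks, function(i) colnames(fit$design$X)[i]),
        cov = fit$cov, loglik = fit$loglik, deviance = fit$deviance,
        aic = fit$aic, bic = fit$bic, n_obs = fit$n_obs,
        n_iter = fit$n_iter, drift = drift(fit)),
        f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      artifacts$fit <<- f
      log_msg("fit: %d cells, loglik %.2f, %d iterations",
              fit$n_obs, fit$loglik, fit$n_iter)
    },
    effects = function() {
      step <- config$grid_step
      tab <- env$fit$design$table
      curves <- list(
        age = age_effect(env$fit,
                         seq(min(tab$age), max(tab$age), by = step)),
        period = period_effect(env$fit,
                               seq(min(tab$period), max(tab$period), by = step)),
        cohort = cohort_effect(env$fit,
                               seq(min(tab$cohort), max(tab$cohort), by = step)))
      for (nm in names(curves)) {
        f <- file.path(out, paste0("curve_", nm, ".csv"))
        cdf <- as.data.frame(curves[[nm]])
        cdf$scale <- attr(curves[[nm]], "scale")
        utils::write.csv(cdf, f, row.names = FALSE)
        artifacts[[paste0("curve_", nm)]] <<- f
      }
      log_msg("effects: wrote age/period/cohort curves (step %.2f)", step)
    },
    ttest = function() {
      ts <- config$ttest
      if (is.null(ts$by) || is.null(ts$levels))
        stop("config$ttest needs 'by' and 'levels'")
      years <- seq.int(config$period_range[1], config$period_range[2])
      res <- compare_groups(env$records, ts$by, as.list(ts$levels), years,
                            ci_level = if (is.null(ts$ci_level)) 0.95
                                       else ts$ci_level)
      f <- file.path(out, "ttest.json")
      jsonlite::write_json(unclass(res), f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      artifacts$ttest <<- f
      log_msg("ttest: %s, t = %.4f", ts$by, res$t)
    }
  )

  for (st in config$stages) {
    res <- tryCatch({ stage_impl[[st]](); NULL }, error = function(e) e)
    if (!is.null(res)) {
      code <- if (st %in% c("fit", "effects")) 3 else 4
      return(pipeline_fail(out, st, code, conditionMessage(res), artifacts))
    }
  }
  list(status = 0L, artifacts = artifacts)
}

pipeline_fail <- function(out, stage, code, msg, artifacts = list()) {
  message("[apcmort] FAILED at stage '", stage, "': ", msg)
  if (!is.null(out) && dir.exists(out))
    writeLines(c(stage, msg), file.path(out, "FAILED"))
  list(status = as.integer(code), stage = stage, error = msg,
       artifacts = artifacts)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
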