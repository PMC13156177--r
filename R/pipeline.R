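# End-to-end runner: simulate | process | analyze from a single config,
# with per-stage logging, exclusion accounting that always reconciles, and
# JSON artifacts.

#' Pipeline configuration
#'
#' One structured config governs all stages. Estimator settings are
#' validated at construction ([estimator_config()] raises schema errors
#' naming the offending field), so an invalid config fails before any
#' computation.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param estimator_parent,estimator_child [estimator_config()]s; the child
#'   band has no safe default and must be stated (the default config uses
#'   0.24-1.04 Hz, matching the simulated child respiration).
#' @param rsa_outlier_sd Within-person RSA cleaning threshold (SD units).
#' @param synchrony List: `lag_s`, `min_overlap`, `outlier_sd` (dyad-level
#'   Fisher-z exclusion threshold).
#' @param behavior List: `uncodable_max`.
#' @param models Named list of model specs, each
#'   `list(outcome, focal, moderators, family)`.
#' @param covariates Covariate columns included in every model.
#' @param seed Seed for the simulate stage (overrides `sim$seed`).
#' @param outdir Output directory.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            estimator_parent = estimator_config(),
                            estimator_child = estimator_config(
                              band_lo = 0.24, band_hi = 1.04),
                            rsa_outlier_sd = 3,
                            synchrony = list(lag_s = 0, min_overlap = 30,
                                             outlier_sd = 3.92),
                            behavior = list(uncodable_max = 0.5),
                            models = list(
                              affect = list(outcome = "child_dep_T",
                                            focal = "affect_sync_any",
                                            moderators = c("ersb_any",
                                                           "parent_dep_T"),
                                            family = "linear"),
                              rsa = list(outcome = "child_dep_T",
                                         focal = "rsa_sync_z",
                                         moderators = c("parent_dep_T",
                                                        "ersb_any"),
                                         family = "linear")),
                            covariates = c("child_medication",
                                           "pubertal_status",
                                           "pandemic_cohort"),
                            seed = 1, outdir = tempfile("dyadsync_run")) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(estimator_parent, "estimator_config"),
            inherits(estimator_child, "estimator_config"))
  if (!is.numeric(synchrony$min_overlap) || synchrony$min_overlap < 2)
    stop("invalid config field synchrony$min_overlap")
  if (!is.numeric(synchrony$outlier_sd) || synchrony$outlier_sd <= 0)
    stop("invalid config field synchrony$outlier_sd")
  if (!is.numeric(behavior$uncodable_max) || behavior$uncodable_max < 0 ||
      behavior$uncodable_max > 1)
    stop("invalid config field behavior$uncodable_max")
  structure(list(sim = sim, estimator_parent = estimator_parent,
                 estimator_child = estimator_child,
                 rsa_outlier_sd = rsa_outlier_sd, synchrony = synchrony,
                 behavior = behavior, models = models,
                 covariates = covariates, seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline config from a JSON file
#'
#' Coerces the nested lists of a JSON config into validated
#' [pipeline_config()] components; schema violations (e.g. a band edge at
#' or above Nyquist) error before any computation, naming the field.
#'
#' @param path JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  for (nm in c("estimator_parent", "estimator_child"))
    if (!is.null(raw[[nm]]))
      args[[nm]] <- do.call(estimator_config, raw[[nm]])
  for (nm in c("rsa_outlier_sd", "synchrony", "behavior", "covariates",
               "seed", "outdir"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$models))
    args$models <- lapply(raw$models, function(m) m)
  do.call(pipeline_config, args)
}

stage_simulate <- function(cfg) {
  sim_cfg <- cfg$sim
  sim_cfg$seed <- cfg$seed
  sim <- simulate_study(sim_cfg)
  write_study(sim, file.path(cfg$outdir, "data"))
  list(n_dyads = length(sim$dyads))
}

stage_process <- function(cfg) {
  data_dir <- file.path(cfg$outdir, "data")
  man <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  cov <- utils::read.csv(file.path(data_dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  dyads <- assemble_dyads(man, cov, data_dir)

  sync <- vector("list", length(dyads))
  behav <- vector("list", length(dyads))
  rsa_rows <- list()
  n_pair <- 0L
  for (i in seq_along(dyads)) {
    d <- dyads[[i]]
    est <- structure(list(dyad_id = d$dyad_id, r = NA_real_, z = NA_real_,
                          n_pairs = 0L, lag_s = cfg$synchrony$lag_s,
                          reason = "IBI pair absent"),
                     class = "synchrony_estimate")
    if (!is.null(d$parent_ibi) && !is.null(d$child_ibi)) {
      n_pair <- n_pair + 1L
      pp <- rsa_pipeline(d$parent_ibi, cfg$estimator_parent,
                         cfg$rsa_outlier_sd)
      cc <- rsa_pipeline(d$child_ibi, cfg$estimator_child,
                         cfg$rsa_outlier_sd)
      est <- rsa_synchrony(pp$diff, cc$diff, dyad_id = d$dyad_id,
                           lag_s = cfg$synchrony$lag_s,
                           min_overlap = cfg$synchrony$min_overlap)
      rsa_rows[[length(rsa_rows) + 1L]] <- rbind(
        data.frame(dyad_id = d$dyad_id, person = "parent",
                   second = seq_along(pp$rsa$values) - 1L,
                   rsa = pp$rsa$values, valid = pp$rsa$valid),
        data.frame(dyad_id = d$dyad_id, person = "child",
                   second = seq_along(cc$rsa$values) - 1L,
                   rsa = cc$rsa$values, valid = cc$rsa$valid))
    }
    sync[[i]] <- est
    bs <- behavior_summary(d$parent_affect, d$child_affect, d$parent_ersb,
                           cfg$behavior$uncodable_max)
    bs$dyad_id <- d$dyad_id
    behav[[i]] <- bs
  }
  sync_df <- synchrony_table(sync)
  behav_df <- do.call(rbind, behav)

  proc_dir <- file.path(cfg$outdir, "processed")
  dir.create(proc_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sync_df, file.path(proc_dir, "synchrony.csv"),
                   row.names = FALSE)
  utils::write.csv(behav_df, file.path(proc_dir, "behavior.csv"),
                   row.names = FALSE)
  if (length(rsa_rows))
    utils::write.csv(do.call(rbind, rsa_rows),
                     file.path(proc_dir, "rsa_seconds.csv"),
                     row.names = FALSE)

  at <- merge(merge(sync_df[c("dyad_id", "r", "z", "n_pairs", "reason")],
                    behav_df[c("dyad_id", "shared_positive_any",
                               "shared_positive_prop", "unsupportive_any",
                               "unsupportive_prop")], by = "dyad_id"),
              cov, by = "dyad_id", all.x = TRUE)
  names(at)[names(at) == "z"] <- "rsa_sync_z"
  names(at)[names(at) == "shared_positive_any"] <- "affect_sync_any"
  names(at)[names(at) == "unsupportive_any"] <- "ersb_any"
  utils::write.csv(at, file.path(proc_dir, "analysis_table.csv"),
                   row.names = FALSE)
  list(dyads_in = nrow(man), with_ibi_pair = n_pair,
       synchrony_estimated = sum(!is.na(sync_df$z)),
       synchrony_missing = sum(is.na(sync_df$z)),
       missing_reasons = table(sync_df$reason[is.na(sync_df$z)]),
       affect_evaluable = sum(!is.na(at$affect_sync_any)),
       ersb_evaluable = sum(!is.na(at$ersb_any)))
}

probe_binary_levels <- c(0, 1)

probe_model <- function(fit, range_sd = 2) {
  probes <- list()
  regions <- list()
  for (m in fit$moderators) {
    st <- fit$term_stats[[m]]
    if (isTRUE(st$binary)) {
      for (lv in probe_binary_levels) {
        probes[[length(probes) + 1L]] <-
          simple_slope(fit, lv, focal = fit$focal, moderator = m)
        if (isTRUE(fit$term_stats[[fit$focal]]$binary))
          probes[[length(probes) + 1L]] <-
            simple_slope(fit, lv, focal = m, moderator = fit$focal)
      }
    } else {
      for (at in c(st$mean - st$sd, st$mean, st$mean + st$sd))
        probes[[length(probes) + 1L]] <-
          simple_slope(fit, at, focal = fit$focal, moderator = m)
      regions[[m]] <- region_of_significance(fit, range_sd = range_sd,
                                             focal = fit$focal,
                                             moderator = m)
    }
  }
  probe_df <- do.call(rbind, lapply(probes, function(p)
    data.frame(focal = p$focal, moderator = p$moderator,
               at_value = p$at_value, slope_est = p$slope_est,
               slope_se = p$slope_se, statistic = p$statistic, p = p$p)))
  list(probes = probe_df, regions = regions)
}

stage_analyze <- function(cfg) {
  proc_dir <- file.path(cfg$outdir, "processed")
  at <- utils::read.csv(file.path(proc_dir, "analysis_table.csv"),
                        stringsAsFactors = FALSE)
  flagged <- flag_outlier_dyads(
    data.frame(dyad_id = at$dyad_id, z = at$rsa_sync_z),
    threshold_sd = cfg$synchrony$outlier_sd)
  at$rsa_excluded <- flagged$excluded
  at$rsa_sync_z[flagged$excluded] <- NA  # excluded from primary analyses

  models <- list()
  for (nm in names(cfg$models)) {
    spec <- cfg$models[[nm]]
    fit <- tryCatch(
      fit_interaction_model(at, spec$outcome, spec$focal, spec$moderators,
                            covariates = cfg$covariates,
                            family = spec$family),
      error = function(e) e)
    if (inherits(fit, "error")) {
      models[[nm]] <- list(failed = TRUE, error = conditionMessage(fit))
      next
    }
    pr <- probe_model(fit)
    models[[nm]] <- list(
      failed = FALSE, outcome = spec$outcome, focal = spec$focal,
      moderators = spec$moderators, family = spec$family,
      n_used = fit$n_used, coef = as.list(fit$coef),
      vcov = fit$vcov, centering = as.list(fit$centering),
      probes = pr$probes,
      regions = lapply(pr$regions, function(r)
        list(moderator = r$moderator, crit = r$crit, range = r$range,
             bounds = r$region_bounds)))
  }
  res_dir <- file.path(cfg$outdir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(models, file.path(res_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  probe_rows <- do.call(rbind, Filter(Negate(is.null),
                                      lapply(models, `[[`, "probes")))
  if (!is.null(probe_rows))
    utils::write.csv(probe_rows, file.path(res_dir, "probes.csv"),
                     row.names = FALSE)
  list(dyads_in = nrow(at),
       rsa_outliers_excluded = sum(flagged$excluded),
       rsa_analyzed = sum(!is.na(at$rsa_sync_z)),
       models = lapply(models, function(m)
         if (isTRUE(m$failed)) list(failed = TRUE, error = m$error)
         else list(failed = FALSE, n_used = m$n_used)))
}

#' Run the pipeline
#'
#' Executes the requested stages in order (`simulate`, `process`,
#' `analyze`; `all` runs the three in sequence) under the config's seed,
#' writes stage artifacts beneath `config$outdir`, and returns (and writes)
#' a run report whose exclusion counts reconcile: every dyad entering a
#' stage is accounted for as analyzed or excluded-with-reason. A stage
#' failure leaves earlier artifacts in place and a `failed_stage` marker in
#' the report.
#'
#' @param config A [pipeline_config()] or path to a JSON config file.
#' @param mode One of `"all"`, `"simulate"`, `"process"`, `"analyze"`.
#' @param seed Optional seed override.
#' @param outdir Optional output-directory override.
#' @return The run report (list with class `run_report`), invisibly;
#'   also written to `outdir/results/run_report.json`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("all", "simulate", "process", "analyze"),
                         seed = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  stages <- if (mode == "all") c("simulate", "process", "analyze") else mode
  report <- list(mode = mode, seed = config$seed,
                 outdir = config$outdir,
                 package_version =
                   as.character(utils::packageVersion("dyadsync")),
                 config = list(
                   n_dyads = config$sim$n_dyads, rho = config$sim$rho,
                   task_s = config$sim$task_s,
                   band_parent = c(config$estimator_parent$band_lo,
                                   config$estimator_parent$band_hi),
                   band_child = c(config$estimator_child$band_lo,
                                  config$estimator_child$band_hi),
                   rsa_outlier_sd = config$rsa_outlier_sd,
                   synchrony = config$synchrony),
                 stages = list(), failed_stage = NULL)
  for (st in stages) {
    out <- tryCatch(switch(st,
                           simulate = stage_simulate(config),
                           process = stage_process(config),
                           analyze = stage_analyze(config)),
                    error = function(e) e)
    if (inherits(out, "error")) {
      report$failed_stage <- list(stage = st,
                                  error = conditionMessage(out))
      break
    }
    report$stages[[st]] <- out
  }
  class(report) <- "run_report"
  res_dir <- file.path(config$outdir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report),
                       file.path(res_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Check that a run report's exclusion accounting reconciles
#'
#' Every dyad entering the process stage must be accounted for: dyads with
#' an IBI pair split into synchrony-estimated vs missing-with-reason, and
#' the analyze stage's analyzed + outlier-excluded must equal the estimated
#' count.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return `TRUE` if counts reconcile, otherwise an error.
#' @export
check_report_counts <- function(report) {
  pr <- report$stages$process
  an <- report$stages$analyze
  if (is.null(pr)) stop("no process stage in report")
  if (pr$synchrony_estimated + pr$synchrony_missing != pr$dyads_in)
    stop("process counts do not reconcile")
  if (sum(pr$missing_reasons) != pr$synchrony_missing)
    stop("missing-reason counts do not reconcile")
  if (!is.null(an) &&
      an$rsa_analyzed + an$rsa_outliers_excluded != pr$synchrony_estimated)
    stop("analyze counts do not reconcile")
  TRUE
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report mode=", x$mode, " seed=", x$seed, ">\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("  ", nm, ": ",
        paste(names(st)[1:min(3, length(st))],
              unlist(lapply(st[1:min(3, length(st))], function(v)
                if (is.numeric(v) && length(v) == 1) v else "...")),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$failed_stage))
    cat("  FAILED at stage ", x$failed_stage$stage, ": ",
        x$failed_stage$error, "\n", sep = "")
  invisible(x)
}
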