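#' Configuration of a full pipeline run
#'
#' Bundles the settings of every stage.  Each stochastic stage derives its
#' seed deterministically from the global seed and the stage name, so a
#' run is reproducible from the config alone.
#'
#' @param out_dir Output directory of the run.
#' @param seed Global integer seed.
#' @param stages Stages to execute, a subset of
#'   `c("simulate", "preprocess", "fit", "ppc", "correlate", "report")`.
#' @param cohort List of arguments for [cohort_config()].  The default is
#'   a small demo cohort (16 persons, all 16 conditions, 20 trials per
#'   version) that runs end to end in minutes.
#' @param model List of arguments for [csddm_spec()].
#' @param ppc List with `n_sim` and `levels` for the predictive check.
#' @param correlate List with `parameters`, `groupings`, `prior_width`.
#' @param expected_per_participant Scheduled trials per participant used by
#'   the exclusion accounting; `NULL` derives it from the cohort settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = "csddm_run", seed = 1L,
                       stages = c("simulate", "preprocess", "fit", "ppc",
                                  "correlate", "report"),
                       cohort = list(n_participants = 16,
                                     trials_per_version = 20),
                       model = list(chains = 2, warmup = 400, draws = 400),
                       ppc = list(n_sim = 200,
                                  levels = c(0.1, 0.3, 0.5, 0.7, 0.9)),
                       correlate = list(parameters = c("drift", "bias_logit",
                                                       "boundary_log"),
                                        groupings = c("overall",
                                                      "whole_display",
                                                      "single_probe"),
                                        prior_width = 1),
                       expected_per_participant = NULL) {
  bad <- setdiff(stages, c("simulate", "preprocess", "fit", "ppc",
                           "correlate", "report"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, preprocess = 211L, fit = 307L, ppc = 401L,
            correlate = 503L, report = 601L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, fit, posterior predictive check,
#' correlation scan and report stages in order, writing each stage's
#' artifacts (CSV/JSON) under `config$out_dir` together with a manifest
#' recording the config, derived stage seeds, and session versions.
#' Stages absent from `config$stages` are skipped; `preprocess` can resume
#' from a previously written `trials.csv`, while `ppc` and `correlate`
#' require the `fit` stage in the same invocation (posterior draws are not
#' persisted in full).
#'
#' @param config A [run_config] (or path to a YAML file for it).
#' @return Invisibly, a list with the stage outputs that were produced
#'   (`cohort`, `preprocessed`, `fit`, `ppc_check`, `correlations`, paths).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(dir = config$out_dir)
  log_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[csddm] stage %-10s ...", stage))
    res <- expr
    message(sprintf("[csddm] stage %-10s done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  path <- function(f) file.path(config$out_dir, f)

  cohort <- NULL; trials <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- log_stage("simulate", {
      args <- config$cohort
      args$seed <- stage_seed(config$seed, "simulate")
      cc <- do.call(cohort_config, args)
      generate_cohort(cc)
    })
    write_trials_csv(cohort$trials, path("trials.csv"))
    write.csv(cohort$truth$person_params, path("ground_truth.csv"),
              row.names = FALSE)
    out$cohort <- cohort
    trials <- cohort$trials
  }

  pre <- NULL
  if ("preprocess" %in% config$stages) {
    pre <- log_stage("preprocess", {
      if (is.null(trials)) {
        if (!file.exists(path("trials.csv")))
          stop("preprocess: no trials in memory and no cached trials.csv")
        trials <- read_trials_csv(path("trials.csv"))
      }
      epp <- config$expected_per_participant
      if (is.null(epp)) {
        nver <- length(config$cohort$conditions %||% 1:16)
        tpv <- config$cohort$trials_per_version %||% 60L
        epp <- nver * tpv
      }
      filter_trials(trials, expected_per_participant = epp)
    })
    write_trials_csv(pre$retained, path("retained.csv"))
    write_json_file(list(counts = as.list(pre$report$counts),
                         rates = as.list(pre$report$rates)),
                    path("exclusion_report.json"))
    write.csv(accuracy_summary(pre$retained), path("accuracy_summary.csv"),
              row.names = FALSE)
    eng <- engagement_summary(trials, epp_of(config))
    write.csv(eng$distribution, path("engagement_distribution.csv"),
              row.names = FALSE)
    out$preprocessed <- pre
  }

  fit <- NULL
  if ("fit" %in% config$stages) {
    fit <- log_stage("fit", {
      if (is.null(pre)) stop("fit: requires the preprocess stage")
      args <- config$model
      args$seed <- stage_seed(config$seed, "fit")
      fit_csddm(pre$retained, do.call(csddm_spec, args))
    })
    sm <- summary(fit)
    write.csv(sm$conditions, path("condition_summaries.csv"), row.names = FALSE)
    write.csv(sm$contrasts, path("contrasts.csv"), row.names = FALSE)
    write.csv(sm$diagnostics, path("diagnostics.csv"), row.names = FALSE)
    write_json_file(list(
      conditions = sm$conditions, contrasts = sm$contrasts,
      max_rhat = max(sm$diagnostics$rhat, na.rm = TRUE)),
      path("fit_summary.json"))
    out$fit <- fit
  }

  if ("ppc" %in% config$stages && !is.null(fit)) {
    chk <- log_stage("ppc", {
      pp <- posterior_predictive(fit, n_sim = config$ppc$n_sim,
                                 seed = stage_seed(config$seed, "ppc"))
      rt_quantile_check(pre$retained, pp, levels = config$ppc$levels)
    })
    write.csv(chk$table, path("ppc_quantiles.csv"), row.names = FALSE)
    write_json_file(list(coverage = chk$coverage,
                         skipped_cells = if (is.null(chk$skipped)) 0L
                                         else nrow(chk$skipped)),
                    path("ppc_summary.json"))
    grDevices::png(path("ppc_quantiles.png"), width = 1600, height = 1200,
                   res = 120)
    plot(chk)
    grDevices::dev.off()
    out$ppc_check <- chk
  }

  if ("correlate" %in% config$stages && !is.null(fit)) {
    corr <- log_stage("correlate", {
      ages <- vapply(fit$data$persons, function(pid) {
        trials$age[match(pid, trials$participant_id)]
      }, 0)
      parameter_covariate_scan(fit, data.frame(age = ages),
                               parameters = config$correlate$parameters,
                               groupings = config$correlate$groupings,
                               prior_width = config$correlate$prior_width)
    })
    write.csv(corr, path("correlations.csv"), row.names = FALSE)
    out$correlations <- corr
  }

  if ("report" %in% config$stages) {
    log_stage("report", {
      manifest <- list(
        package_version = as.character(utils::packageVersion("csddm")),
        r_version = R.version.string,
        seed = config$seed,
        stage_seeds = lapply(setNames(nm = config$stages),
                             function(s) stage_seed(config$seed, s)),
        config = config[setdiff(names(config), "out_dir")],
        config_md5 = config_md5(config),
        artifacts = list.files(config$out_dir))
      write_json_file(manifest, path("manifest.json"))
    })
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

epp_of <- function(config) {
  config$expected_per_participant %||%
    (length(config$cohort$conditions %||% 1:16) *
       (config$cohort$trials_per_version %||% 60L))
}

config_md5 <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config[sort(setdiff(names(config), "out_dir"))], f)
  unname(tools::md5sum(f))
}
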