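#' Experiment configuration
#'
#' Bundles everything needed to run the full comparison experiment:
#' the synthetic-cohort configuration, the landmark grid, the model set,
#' the seeds, and the output directory.
#'
#' @param simulation an [sim_config()].
#' @param grid a [landmark_grid()].
#' @param models character vector of canonical model names (see
#'   [canonical_model_specs()]).
#' @param split_seed seed for the practice-level split.
#' @param boot_seed seed for bootstrap confidence intervals.
#' @param n_boot bootstrap replicates (0 disables CIs).
#' @param mode landmark eligibility mode.
#' @param referent model differences are reported against.
#' @param output_dir directory experiment artifacts are written to.
#' @return an object of class `lmv_experiment_config`.
#' @export
experiment_config <- function(simulation = sim_config(),
                              grid = landmark_grid(),
                              models = c("last", "mean", "current",
                                         "last_sd", "mean_sd", "current_sd"),
                              split_seed = 1L, boot_seed = 1L, n_boot = 200,
                              mode = "complete_case",
                              referent = "last",
                              output_dir = "landmarkvar_run") {
  unknown <- setdiff(models, names(canonical_model_specs()))
  if (length(unknown))
    stop("unknown model name(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!referent %in% models)
    stop("referent model '", referent, "' is not in the model list",
         call. = FALSE)
  structure(list(simulation = simulation, grid = grid, models = models,
                 split_seed = as.integer(split_seed),
                 boot_seed = as.integer(boot_seed),
                 n_boot = as.integer(n_boot), mode = mode,
                 referent = referent, output_dir = output_dir),
            class = "lmv_experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Scalar fields override the defaults of [experiment_config()] and
#' [sim_config()]; unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return an `lmv_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  for (nm in c("fixed_trajectory", "random_effects_cov", "within_person_sd_law"))
    if (!is.null(sim_args[[nm]]))
      sim_args[[nm]] <- lapply(sim_args[[nm]], function(v)
        if (nm == "random_effects_cov") matrix(unlist(v), 2, 2) else unlist(v))
  for (nm in c("visit_rate", "beta_current", "gamma_sd", "beta_binary",
               "ethnicity_probs", "hazard_baseline"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(sim_config, sim_args)
  grid_args <- y$grid %||% list()
  if (!is.null(grid_args$ages)) grid_args$ages <- unlist(grid_args$ages)
  grid <- do.call(landmark_grid, grid_args)
  args <- y[setdiff(names(y), c("simulation", "grid"))]
  do.call(experiment_config, c(list(simulation = sim, grid = grid), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a Cox fit to structured text (JSON)
#' @param fit an `lmv_cox_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  obj <- list(sex = fit$sex,
              spec = unclass(fit$spec),
              beta = as.list(fit$beta),
              robust_vcov = fit$robust_vcov,
              xbar = as.list(fit$xbar),
              basehaz = fit$basehaz,
              dropped = fit$dropped,
              n = fit$n, n_events = fit$n_events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Cox fit written by [write_cox_fit()]
#' @param path JSON file.
#' @return an `lmv_cox_fit` usable by [predict_risk()].
#' @export
read_cox_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(o$beta)
  spec <- covariate_spec(o$spec$summary_method,
                         include_sd = unlist(o$spec$include_sd) %||% character(0),
                         include_slope = isTRUE(o$spec$include_slope))
  structure(list(sex = o$sex, spec = spec, beta = beta,
                 robust_vcov = as.matrix(o$robust_vcov),
                 xbar = unlist(o$xbar),
                 basehaz = as.data.frame(o$basehaz),
                 dropped = unlist(o$dropped) %||% character(0),
                 n = o$n, n_events = o$n_events),
            class = "lmv_cox_fit")
}

#' Serialise a mixed-model fit to structured text (JSON)
#' @param fit an `lmv_mixed_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mixed_fit <- function(fit, path) {
  obj <- list(sex = fit$sex, spec = unclass(fit$spec),
              center = as.list(fit$center), scale = as.list(fit$scale),
              beta = as.list(fit$beta), G = fit$G,
              sigma2 = as.list(fit$sigma2), loglik = fit$loglik,
              iterations = fit$iterations, converged = fit$converged,
              ridged = fit$ridged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a mixed-model fit written by [write_mixed_fit()]
#' @param path JSON file.
#' @return an `lmv_mixed_fit` usable by [predict_current_slope()].
#' @export
read_mixed_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  G <- as.matrix(o$G)
  dimnames(G) <- list(re_names(), re_names())
  structure(list(sex = o$sex,
                 spec = mixed_model_spec(o$spec$cross_factor,
                                         o$spec$max_iter, o$spec$tol),
                 center = unlist(o$center), scale = unlist(o$scale),
                 beta = unlist(o$beta), G = G, sigma2 = unlist(o$sigma2),
                 loglik = o$loglik, iterations = o$iterations,
                 converged = o$converged, ridged = o$ridged),
            class = "lmv_mixed_fit")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_log(stage, sprintf("done in %.1fs",
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full simulate -> landmark -> fit -> evaluate experiment
#'
#' Executes every stage from one configuration with seeded
#' reproducibility, writing all intermediate artifacts as flat files so
#' each stage is independently inspectable: the cohort CSVs, the stacked
#' landmark datasets, the Stage-1 and Stage-2 fits as JSON, per-model
#' validation predictions, the model-comparison table, and a run manifest
#' with the seeds and MD5 content hashes of every artifact. Deterministic
#' stages are bit-identical across reruns of the same configuration.
#'
#' @param config an [experiment_config()].
#' @return invisibly, a list with the comparison table, the evaluation
#'   report and the manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "lmv_experiment_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- run_stage("simulate", {
    ch <- generate_cohort(config$simulation)
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })

  split <- run_stage("split", split_by_practice(cohort, seed = config$split_seed))

  lmk <- run_stage("landmark", {
    der <- build_landmark_dataset(split$derivation, config$grid, config$mode)
    val <- build_landmark_dataset(split$validation, config$grid, config$mode)
    list(der = der, val = val)
  })

  need_mixed <- any(grepl("current", config$models))
  mixed_fits <- NULL
  if (need_mixed) {
    mixed_fits <- run_stage("fit-mixed", {
      fits <- list(M = fit_mixed(split$derivation, "M"),
                   F = fit_mixed(split$derivation, "F"))
      write_mixed_fit(fits$M, file.path(out_dir, "mixed_fit_M.json"))
      write_mixed_fit(fits$F, file.path(out_dir, "mixed_fit_F.json"))
      fits
    })
    lmk <- run_stage("blup-summaries", {
      list(der = add_mixed_summaries(lmk$der, mixed_fits, split$derivation),
           val = add_mixed_summaries(lmk$val, mixed_fits, split$validation))
    })
  }
  utils::write.csv(lmk$der, file.path(out_dir, "landmark_derivation.csv"),
                   row.names = FALSE)
  utils::write.csv(lmk$val, file.path(out_dir, "landmark_validation.csv"),
                   row.names = FALSE)

  fits <- run_stage("fit-cox", {
    f <- fit_model_set(lmk$der, config$models)
    for (nm in names(f)) {
      write_cox_fit(f[[nm]]$M, file.path(out_dir, sprintf("cox_%s_M.json", nm)))
      write_cox_fit(f[[nm]]$F, file.path(out_dir, sprintf("cox_%s_F.json", nm)))
    }
    f
  })

  preds <- run_stage("predict", {
    pl <- lapply(fits, function(f) {
      out <- rep(NA_real_, nrow(lmk$val))
      sdf <- f$M$spec$include_sd
      ok <- if (length(sdf))
        stats::complete.cases(lmk$val[paste0(tolower(sdf), "_sd")])
      else rep(TRUE, nrow(lmk$val))
      out[ok] <- predict_risk_by_sex(f, lmk$val[ok, , drop = FALSE],
                                     w = config$grid$horizon)
      out
    })
    pd <- data.frame(subject_id = lmk$val$subject_id,
                     landmark_age = lmk$val$landmark_age,
                     sex = lmk$val$sex,
                     follow_time = lmk$val$follow_time,
                     event_in_horizon = lmk$val$event_in_horizon)
    for (nm in names(pl)) pd[[paste0("risk_", nm)]] <- pl[[nm]]
    utils::write.csv(pd, file.path(out_dir, "validation_predictions.csv"),
                     row.names = FALSE)
    pl
  })

  cmp <- run_stage("evaluate", {
    tab <- compare_models(lmk$val, fits, w = config$grid$horizon,
                          referent = config$referent,
                          n_boot = config$n_boot,
                          boot_seed = config$boot_seed)
    utils::write.csv(tab, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    tab
  })

  report <- run_stage("report", {
    ref <- config$referent
    alt <- if ("current_sd" %in% config$models) "current_sd" else
      utils::tail(config$models, 1)
    cal <- calibration_slope(preds[[ref]], lmk$val$follow_time,
                             lmk$val$event_in_horizon, lmk$val$landmark_age)
    ok <- !is.na(preds[[alt]]) & !is.na(preds[[ref]])
    nri <- if (alt != ref && any(ok))
      continuous_nri(preds[[alt]][ok], preds[[ref]][ok],
                     lmk$val$follow_time[ok],
                     lmk$val$event_in_horizon[ok], w = config$grid$horizon)
    else list(nri = 0, nri_events = 0, nri_nonevents = 0)
    rep <- list(referent = ref, comparison = cmp,
                calibration_by_age = cal,
                nri_vs_referent = list(model = alt, nri = nri$nri,
                                       nri_events = nri$nri_events,
                                       nri_nonevents = nri$nri_nonevents))
    jsonlite::write_json(rep, file.path(out_dir, "evaluation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    rep
  })

  manifest <- run_stage("manifest", {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    hashes <- tools::md5sum(files)
    names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
    man <- list(seeds = list(simulation = config$simulation$seed,
                             split = config$split_seed,
                             bootstrap = config$boot_seed),
                models = config$models, mode = config$mode,
                n_subjects = config$simulation$n_subjects,
                grid = unclass(config$grid), hashes = as.list(hashes))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(comparison = cmp, report = report, manifest = manifest,
                 fits = fits, mixed_fits = mixed_fits, landmark = lmk))
}
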