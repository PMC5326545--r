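#' Assemble a pipeline configuration
#'
#' @param dives path to the dive CSV, or a dive data frame.
#' @param sites path to the site CSV, or a site data frame.
#' @param fish optional per-fish CSV path or data frame (reporting only).
#' @param level confidence level for all intervals.
#' @param ci_method `"delta"` or `"bootstrap"` for the `N0` interval.
#' @param boot_reps bootstrap replicates when `ci_method = "bootstrap"`.
#' @param models subset of `names(default_model_suite())` to fit.
#' @param targets percent-reduction targets for the planner.
#' @param q_scenarios `"range"` (min/mean/max of the fitted catchabilities)
#'   or a named numeric vector of catchability values.
#' @param seed integer seed (bootstrap and optimizer starts).
#' @param out_dir optional output directory; reports are written when set.
#' @param verbose log progress to stderr.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dives, sites, fish = NULL, level = 0.95,
                            ci_method = c("delta", "bootstrap"),
                            boot_reps = 2000,
                            models = names(default_model_suite()),
                            targets = c(50, 90), q_scenarios = "range",
                            seed = 1, out_dir = NULL, verbose = FALSE) {
  ci_method <- match.arg(ci_method)
  bad <- names(default_model_suite())
  unknown <- setdiff(models, bad)
  if (length(unknown)) stop("unknown model spec(s): ", paste(unknown, collapse = ", "))
  if (any(targets < 0 | targets >= 100)) {
    stop("targets must be in [0, 100)")
  }
  structure(list(dives = dives, sites = sites, fish = fish, level = level,
                 ci_method = ci_method, boot_reps = boot_reps, models = models,
                 targets = targets, q_scenarios = q_scenarios,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

log_msg <- function(verbose, ...) {
  if (verbose) message("[deplete] ", ...)
}

#' Run the full depletion-analysis pipeline
#'
#' Standardize -> per-site Leslie fits -> residual diagnostics and the
#' cross-site catchability regression -> removal observations -> effort-model
#' suite -> AICc comparison -> effort planner. A failing site is reported
#' under `failures` and does not abort the others; the run fails only if no
#' site can be fitted.
#'
#' @param config a [pipeline_config()], or a list/file accepted by it.
#' @return Object of class `run_report`: list with `leslie` (per-site table),
#'   `fits`, `diagnostics`, `cross_site`, `model_comparison`, `best_fit`,
#'   `planner`, `failures`, `provenance`. Written to `config$out_dir` via
#'   [write_report()] when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  v <- config$verbose

  dives <- if (is.character(config$dives)) read_dive_table(config$dives) else
    validate_dive_table(config$dives)
  sites <- if (is.character(config$sites)) read_site_table(config$sites) else
    validate_site_table(config$sites)

  log_msg(v, "standardizing ", nrow(dives), " dives at ", nrow(sites), " sites")
  std <- standardize_dives(dives, sites)
  serieses <- split_series(std, sites)

  fits <- list(); failures <- list()
  for (ser in serieses) {
    f <- tryCatch(fit_leslie(ser, level = config$level,
                             n0_ci = config$ci_method,
                             boot_reps = config$boot_reps,
                             seed = config$seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures[[ser$site_id]] <- conditionMessage(f)
      log_msg(v, "site ", ser$site_id, " failed: ", conditionMessage(f))
    } else {
      fits[[ser$site_id]] <- f
    }
  }
  if (!length(fits)) {
    stop("all sites failed the Leslie fit: ",
         paste(unlist(failures), collapse = "; "))
  }
  leslie <- leslie_table(fits)
  diagnostics <- leslie_diagnostics(fits)
  cross <- if (length(fits) >= 3) catchability_density_regression(fits) else NULL

  comparison <- NULL; best <- NULL; planner <- NULL
  obs <- build_removal_observations(fits, serieses[names(fits)])
  suite <- default_model_suite()[config$models]
  model_fits <- list()
  for (nm in names(suite)) {
    log_msg(v, "fitting effort model '", nm, "'")
    mf <- tryCatch(fit_effort_model(obs, suite[[nm]], seed = config$seed),
                   error = function(e) e)
    if (inherits(mf, "error")) {
      failures[[paste0("model:", nm)]] <- conditionMessage(mf)
    } else {
      model_fits[[nm]] <- mf
    }
  }
  if (length(model_fits) >= 2) comparison <- compare_models(model_fits)
  if (length(model_fits)) {
    non_null <- model_fits[!vapply(model_fits, function(f) f$spec$null_model, TRUE)]
    if (length(non_null)) {
      aiccs <- vapply(non_null, `[[`, numeric(1), "aicc")
      best <- non_null[[which.min(aiccs)]]
      qsc <- config$q_scenarios
      if (identical(qsc, "range")) {
        qsc <- c(q_min = min(leslie$q), q_mean = mean(leslie$q),
                 q_max = max(leslie$q))
      }
      planner <- plan_removals(best, qsc, config$targets, config$level)
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("deplete")),
    seed = config$seed,
    config_hash = config_hash(config[setdiff(names(config),
                                             c("dives", "sites", "fish",
                                               "out_dir", "verbose"))]),
    n_sites = nrow(sites), n_dives = nrow(dives))

  report <- structure(list(leslie = leslie, fits = fits,
                           diagnostics = diagnostics, cross_site = cross,
                           observations = obs, model_fits = model_fits,
                           model_comparison = comparison, best_fit = best,
                           planner = planner, failures = failures,
                           provenance = provenance),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    log_msg(v, "writing reports to ", config$out_dir)
    write_report(report, config$out_dir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Depletion pipeline report:", nrow(x$leslie), "site fits")
  if (length(x$failures)) cat(",", length(x$failures), "failures")
  cat("\n\n")
  print(x$leslie, digits = 3)
  if (!is.null(x$model_comparison)) { cat("\n"); print(x$model_comparison) }
  if (!is.null(x$planner)) {
    cat("\nPlanner (diver-hours per 1,000 m2):\n")
    print(x$planner, digits = 3)
  }
  invisible(x)
}
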