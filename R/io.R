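#' Read a dive table
#'
#' CSV with header `site,dive,divers,minutes,catch` or
#' `site,dive,diver_minutes,catch` (UTF-8, comma separator, dot decimal).
#'
#' @param path CSV path.
#' @return Validated data frame `site`, `dive`, `diver_minutes`, `catch`.
#' @export
read_dive_table <- function(path) {
  if (!file.exists(path)) stop("dive table not found: ", path)
  validate_dive_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a site table
#'
#' CSV with header `site,area_m2[,depth_min,depth_max]`.
#'
#' @param path CSV path.
#' @return Validated site data frame.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  validate_site_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a per-fish table
#'
#' CSV with header `site,dive,tl_cm,mass_g`. Fish-level attributes are
#' carried for reporting only; they play no role in estimation.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_fish_table <- function(path) {
  if (!file.exists(path)) stop("fish table not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "dive", "tl_cm", "mass_g")
  if (!all(need %in% names(d))) {
    stop("fish table needs columns: ", paste(need, collapse = ", "))
  }
  d
}

#' Write a simulated study to CSVs plus a truth JSON
#'
#' Writes `dives.csv`, `sites.csv`, optionally `fish.csv`, and `truth.json`
#' in the same schemas the readers accept, so a simulated study round-trips
#' through the file interface.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$dives, file.path(dir, "dives.csv"), row.names = FALSE)
  write.csv(study$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  if (!is.null(study$fish)) {
    write.csv(study$fish, file.path(dir, "fish.csv"), row.names = FALSE)
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# 31-bit polynomial rolling hash over the JSON serialization; provenance only
config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a pipeline run report
#'
#' Writes `leslie_fits.csv`, `diagnostics.csv`, `model_comparison.csv`,
#' `planner.csv` and a combined `report.json` (per-site fits with a
#' `diagnostics` key, the cross-site regression block, the model table, the
#' planner table, and provenance) with stable column order.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$leslie, file.path(dir, "leslie_fits.csv"), row.names = FALSE)
  write.csv(report$diagnostics, file.path(dir, "diagnostics.csv"),
            row.names = FALSE)
  if (!is.null(report$model_comparison)) {
    write.csv(as.data.frame(report$model_comparison),
              file.path(dir, "model_comparison.csv"), row.names = FALSE)
  }
  if (!is.null(report$planner)) {
    write.csv(report$planner, file.path(dir, "planner.csv"), row.names = FALSE)
  }
  sites_json <- lapply(seq_len(nrow(report$leslie)), function(i) {
    row <- as.list(report$leslie[i, ])
    di <- report$diagnostics[report$diagnostics$site == row$site, ]
    row$diagnostics <- if (nrow(di)) as.list(di[1, -1]) else NULL
    row
  })
  json <- list(sites = sites_json,
               cross_site_regression = report$cross_site[
                 c("slope", "intercept", "r2", "p_value", "n_sites")],
               model_comparison = report$model_comparison,
               planner = report$planner,
               failures = report$failures,
               provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return Named list of configuration fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json: ", path)
  }
}
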