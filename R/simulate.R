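#' Configure a simulated multi-site depletion study
#'
#' Defaults reproduce the scale of a small Caribbean reef depletion study:
#' seven sites of 1,148-1,800 m2, initial densities of 11-29 fish per
#' 1,000 m2, catchability 0.43-0.91 per diver-hour per 1,000 m2, dives of
#' about one diver-hour, and removal continuing until two consecutive
#' zero-catch dives (or `max_dives`).
#'
#' @param n_sites number of sites.
#' @param N0_range range (low, high) of initial density, fish per 1,000 m2.
#' @param q_range range of catchability per diver-hour per 1,000 m2.
#' @param area_range range of site areas, m2.
#' @param effort_per_dive `c(mean, sd)` of diver-hours per dive (raw, not per
#'   area), truncated at 0.25.
#' @param max_dives cap on dives per site.
#' @param stopping `"two_consecutive_zeros"` (stop after the confirmation
#'   dive) or `"fixed_T"` (always `max_dives` dives).
#' @param noise_mode `"binomial"` (integer catches,
#'   `catch ~ Binomial(N, 1 - (1-q)^h)`) or `"expectation"` (deterministic
#'   `catch = q*h*N`, continuous fish, for exact-recovery tests).
#' @param alpha_true,sigma_b_true,sigma_true optional generative parameters
#'   for direct effort-model observations (percent scale; `alpha_true = NULL`
#'   disables them).
#' @param seed integer seed; a fixed seed makes [simulate_study()] output
#'   byte-identical.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 7,
                              N0_range = c(11, 29),
                              q_range = c(0.43, 0.91),
                              area_range = c(1148, 1800),
                              effort_per_dive = c(mean = 1.0, sd = 0.25),
                              max_dives = 10,
                              stopping = c("two_consecutive_zeros", "fixed_T"),
                              noise_mode = c("binomial", "expectation"),
                              alpha_true = NULL, sigma_b_true = 0.1,
                              sigma_true = 5, seed = 1) {
  stopping <- match.arg(stopping)
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_sites >= 1, max_dives >= 1,
            N0_range[1] <= N0_range[2], N0_range[1] > 0,
            q_range[1] <= q_range[2], q_range[1] > 0, q_range[2] <= 1,
            area_range[1] <= area_range[2], area_range[1] > 0,
            effort_per_dive[1] > 0)
  structure(list(n_sites = n_sites, N0_range = N0_range, q_range = q_range,
                 area_range = area_range, effort_per_dive = effort_per_dive,
                 max_dives = max_dives, stopping = stopping,
                 noise_mode = noise_mode, alpha_true = alpha_true,
                 sigma_b_true = sigma_b_true, sigma_true = sigma_true,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate removal dives at one site
#'
#' Runs the removal process the Leslie model assumes. In `"expectation"` mode
#' each dive removes exactly `q * h * N` fish (continuous fish allowed), so a
#' Leslie regression on the output recovers `(q, N0)` exactly. In
#' `"binomial"` mode each fish present is caught independently with
#' probability `1 - (1-q)^h`, keeping `q`'s meaning as the per-unit-effort
#' removal fraction, and catches are integers; the Leslie `q` is then
#' recovered approximately, not exactly.
#'
#' @param N0 initial population (per 1,000 m2, or absolute fish if efforts
#'   are already per-area for that site).
#' @param q catchability in (0, 1].
#' @param efforts vector of positive effort values (diver-hours per
#'   1,000 m2), one per dive.
#' @param mode `"expectation"` or `"binomial"`.
#' @param seed optional seed.
#' @return Data frame `dive`, `h`, `catch`, `N_before`.
#' @export
simulate_site <- function(N0, q, efforts, mode = c("expectation", "binomial"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(N0 > 0, q > 0, q <= 1, all(efforts > 0))
  if (!is.null(seed)) set.seed(seed)
  N <- N0
  out <- vector("list", length(efforts))
  for (t in seq_along(efforts)) {
    h <- efforts[t]
    if (mode == "expectation") {
      p <- q * h
      if (p > 1) {
        warning("q*h = ", format(p), " > 1; removal fraction clipped to 1")
        p <- 1
      }
      caught <- p * N
    } else {
      p <- 1 - (1 - q)^h
      caught <- rbinom(1, round(N), p)
      caught <- min(caught, N)  # guard round-up edge
    }
    out[[t]] <- data.frame(dive = t, h = h, catch = caught, N_before = N)
    N <- N - caught
  }
  do.call(rbind, out)
}

#' Simulate a whole multi-site depletion study
#'
#' Draws per-site initial density, catchability, area and dive efforts from
#' the config ranges, runs the removal process (binomial mode works on whole
#' fish at the site's absolute abundance), applies the stopping rule, and
#' returns raw dive records in the same schema the readers accept, along with
#' the generating truth. When `alpha_true` is set, also generates direct
#' effort-model observations `C = 100*(1 - exp(-(alpha + b_i) * q * t)) + eps`
#' on each site's cumulative-effort grid.
#'
#' @param config a [simulation_config()].
#' @return List of class `simulated_study`: `sites` (site table), `dives`
#'   (dive table with `site`, `dive`, `diver_minutes`, `catch`), `fish`
#'   (per-fish lengths/masses, binomial mode only), `truth` (per-site
#'   `N0_true` density and `q_true`, plus `alpha`, `sigma_b`, `sigma`,
#'   `seed`), and `effort_obs` when `alpha_true` is set.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$max_dives < 1) stop("max_dives must be >= 1")
  set.seed(config$seed)
  sid <- sprintf("S%d", seq_len(config$n_sites))
  area <- runif(config$n_sites, config$area_range[1], config$area_range[2])
  N0_dens <- runif(config$n_sites, config$N0_range[1], config$N0_range[2])
  q <- runif(config$n_sites, config$q_range[1], config$q_range[2])
  sites <- data.frame(site = sid, area_m2 = round(area),
                      depth_min = 15, depth_max = 30, stringsAsFactors = FALSE)

  dive_rows <- list(); fish_rows <- list(); achieved <- logical(config$n_sites)
  for (i in seq_len(config$n_sites)) {
    # absolute abundance at the site; binomial mode needs whole fish
    N_abs <- N0_dens[i] * sites$area_m2[i] / 1000
    if (config$noise_mode == "binomial") N_abs <- round(N_abs)
    N <- N_abs
    zeros <- 0L; t <- 0L
    while (t < config$max_dives) {
      t <- t + 1L
      raw_hours <- max(0.25, rnorm(1, config$effort_per_dive[1],
                                   config$effort_per_dive[2]))
      h_std <- raw_hours * 1000 / sites$area_m2[i]
      if (config$noise_mode == "expectation") {
        p <- min(1, q[i] * h_std)
        caught <- p * N
      } else {
        caught <- rbinom(1, N, 1 - (1 - q[i])^h_std)
      }
      dive_rows[[length(dive_rows) + 1L]] <-
        data.frame(site = sid[i], dive = t, diver_minutes = raw_hours * 60,
                   catch = caught, stringsAsFactors = FALSE)
      if (config$noise_mode == "binomial" && caught > 0) {
        tl <- rtruncnorm_vec(caught, 25.9, 5.9, 12, 41)
        fish_rows[[length(fish_rows) + 1L]] <-
          data.frame(site = sid[i], dive = t, tl_cm = round(tl, 1),
                     mass_g = round(0.0085 * tl^3.05), stringsAsFactors = FALSE)
      }
      N <- N - caught
      if (config$stopping == "two_consecutive_zeros") {
        zeros <- if (caught == 0) zeros + 1L else 0L
        if (zeros >= 2L) { achieved[i] <- TRUE; break }
      }
    }
  }
  dives <- do.call(rbind, dive_rows)
  fish <- if (length(fish_rows)) do.call(rbind, fish_rows) else NULL

  truth <- list(sites = data.frame(site = sid, N0_true = N0_dens, q_true = q,
                                   depletion_achieved = achieved,
                                   stringsAsFactors = FALSE),
                alpha = config$alpha_true, sigma_b = config$sigma_b_true,
                sigma = config$sigma_true, seed = config$seed)

  study <- list(sites = sites, dives = dives, fish = fish, truth = truth)
  if (!is.null(config$alpha_true)) {
    b <- rnorm(config$n_sites, 0, config$sigma_b_true)
    obs <- lapply(seq_len(config$n_sites), function(i) {
      d <- dives[dives$site == sid[i], ]
      tt <- cumsum(d$diver_minutes / 60 * 1000 / sites$area_m2[i])
      s <- q[i] * tt
      C <- 100 * (1 - exp(-(config$alpha_true + b[i]) * s)) +
        rnorm(length(s), 0, config$sigma_true)
      data.frame(site = sid[i], dive = d$dive, t = tt, s = s, C_obs = C,
                 stringsAsFactors = FALSE)
    })
    study$effort_obs <- do.call(rbind, obs)
    study$truth$site_effects <- b
  }
  structure(study, class = "simulated_study")
}

# truncated-normal draws by rejection; used only for fixture realism
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated depletion study:", nrow(x$sites), "sites,",
      nrow(x$dives), "dives,", sum(x$dives$catch), "fish removed\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Replicates [simulate_study()] under one configuration, refits the pipeline
#' each time, and summarizes estimator performance: bias, RMSE, and
#' confidence-interval coverage for `q` and `N0` from the Leslie fits, and
#' for `alpha` from the effort model when `alpha_true` is set (fitted to the
#' generative effort observations). Per-replicate fit failures (e.g. no
#' depletion signal in an unlucky binomial draw) are tallied, not fatal.
#'
#' @param config a [simulation_config()]; replicate r uses seed
#'   `config$seed + r`.
#' @param n_reps number of replicates (>= 10).
#' @return Data frame with one row per parameter: `parameter`, `truth_mean`,
#'   `est_mean`, `bias`, `rmse`, `coverage`, `mc_se` (Monte-Carlo standard
#'   error of `est_mean`), `n_est`, `n_fail`.
#' @export
recovery_experiment <- function(config = simulation_config(), n_reps = 200) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 10)
  qs <- q_true <- n0s <- n0_true <- numeric(0)
  q_cov <- n0_cov <- logical(0)
  alphas <- numeric(0)
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- config$seed + r
    study <- simulate_study(cfg)
    std <- standardize_dives(study$dives, study$sites)
    serieses <- split_series(std, study$sites)
    for (ser in serieses) {
      f <- tryCatch(fit_leslie(ser), error = function(e) NULL)
      if (is.null(f)) { n_fail <- n_fail + 1L; next }
      tr <- study$truth$sites[study$truth$sites$site == ser$site_id, ]
      qs <- c(qs, f$q); q_true <- c(q_true, tr$q_true)
      n0s <- c(n0s, f$N0); n0_true <- c(n0_true, tr$N0_true)
      q_cov <- c(q_cov, f$q_ci[1] <= tr$q_true && tr$q_true <= f$q_ci[2])
      n0_cov <- c(n0_cov, f$N0_ci[1] <= tr$N0_true && tr$N0_true <= f$N0_ci[2])
    }
    if (!is.null(config$alpha_true)) {
      ef <- tryCatch(
        fit_effort_model(study$effort_obs,
                         effort_model_spec("q_scaled", random_site = TRUE),
                         n_starts = 2, seed = cfg$seed),
        error = function(e) NULL)
      if (is.null(ef)) n_fail <- n_fail + 1L else alphas <- c(alphas, ef$alpha)
    }
  }
  row <- function(parameter, est, truth, cov) {
    data.frame(parameter = parameter, truth_mean = mean(truth),
               est_mean = mean(est), bias = mean(est - truth),
               rmse = sqrt(mean((est - truth)^2)),
               coverage = if (is.null(cov)) NA_real_ else mean(cov),
               mc_se = sd(est) / sqrt(length(est)),
               n_est = length(est), n_fail = n_fail,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("q", qs, q_true, q_cov), row("N0", n0s, n0_true, n0_cov))
  if (!is.null(config$alpha_true) && length(alphas)) {
    out <- rbind(out, row("alpha", alphas,
                          rep(config$alpha_true, length(alphas)), NULL))
  }
  rownames(out) <- NULL
  out
}
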