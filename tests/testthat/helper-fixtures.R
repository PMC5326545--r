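# Shared fixtures, built in code.

# Site descriptions from the seven-site Caribbean forereef depletion study:
# area (m2), depth range, number of depletion dives, fish caught, and whether
# two consecutive zero-catch dives were reached.
study_sites <- function() {
  data.frame(
    site = paste0("D", 1:7),
    area_m2 = c(1184, 1800, 1470, 1800, 1800, 1800, 1650),
    depth_min = c(20, 15, 20, 15, 15, 19, 20),
    depth_max = c(30, 30, 30, 30, 30, 35, 35),
    total_diver_hours = c(5.10, 7.03, 4.27, 5.23, 5.85, 5.67, 8.65),
    n_dives = c(5, 7, 4, 5, 6, 6, 6),
    total_catch = c(35, 43, 17, 27, 32, 32, 23),
    achieved = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Published per-site Leslie estimates from the same study (N0 per 1,000 m2,
# catchability per diver-hour per 1,000 m2, with 95% CIs).
study_estimates <- function() {
  data.frame(
    site = paste0("D", 1:7),
    N0 = c(29, 25, 11, 15, 23, 19, 14),
    N0_lo = c(26, 16, 7, 9, 17, 15, 13),
    N0_hi = c(33, 34, 16, 22, 29, 22, 15),
    q = c(0.70, 0.66, 0.91, 0.76, 0.43, 0.86, 0.54),
    q_lo = c(0.53, 0.20, 0.26, 0.15, 0.24, 0.58, 0.43),
    q_hi = c(0.87, 1.11, 1.56, 1.37, 0.62, 1.15, 0.65),
    r2 = c(0.98, 0.68, 0.92, 0.78, 0.88, 0.93, 0.97),
    p = c(0.0009, 0.0137, 0.0262, 0.0291, 0.0035, 0.0011, 0.0001),
    stringsAsFactors = FALSE)
}

# Published model-comparison rows: logLik, parameter count, AICc for the
# exponential removal-model suite fitted to n = 39 site-dive observations.
study_model_table <- function() {
  data.frame(
    model = c("q_scaled_random", "q_scaled", "unscaled_random", "unscaled",
              "null"),
    K = c(3, 2, 3, 2, 2),
    loglik = c(-116.56, -122.13, -122.51, -147.47, -173.08),
    aicc_printed = c(239.81, 248.59, 251.70, 299.27, 350.50),
    stringsAsFactors = FALSE)
}

# Exact expectation-mode depletion series as a standardized-dive data frame.
exact_std <- function(site = "A", N0 = 20, q = 0.5, T = 4, h = 1) {
  sim <- simulate_site(N0, q, rep(h, T), mode = "expectation")
  data.frame(site = site, dive = sim$dive, h = sim$h, c = sim$catch,
             cpue = sim$catch / sim$h, stringsAsFactors = FALSE)
}

# Noisy multi-site effort-model observations with known generative truth.
gen_effort_obs <- function(alpha = 1.4, sigma_b = 0.15, sigma = 5,
                           n_sites = 7, n_dives = 6, seed = 7) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sites), function(i) {
    b <- rnorm(1, 0, sigma_b)
    q <- runif(1, 0.43, 0.91)
    t <- cumsum(runif(n_dives, 0.4, 0.9))
    s <- q * t
    data.frame(site = paste0("S", i), t = t, s = s,
               C_obs = 100 * (1 - exp(-(alpha + b) * s)) +
                 rnorm(n_dives, 0, sigma),
               stringsAsFactors = FALSE)
  }))
}
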