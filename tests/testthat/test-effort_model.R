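test_that("removal observations accumulate effort and percent removed", {
  std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
                    cpue = c(10, 5, 2.5))
  ser <- build_series(std)
  f <- fit_leslie(ser)  # N0 = 20, q = 0.5 exactly
  obs <- build_removal_observations(list(f), list(ser))
  expect_equal(obs$t, c(1, 2, 3))
  expect_equal(obs$C_obs, c(50, 75, 87.5), tolerance = 1e-9)
  expect_equal(obs$s, 0.5 * c(1, 2, 3), tolerance = 1e-9)

  expect_error(build_removal_observations(list(), list(ser)), "no Leslie fit")
})

test_that("noiseless generative curves are recovered exactly", {
  obs <- do.call(rbind, lapply(1:3, function(i) {
    t <- 1:5; s <- 0.6 * t
    data.frame(site = paste0("S", i), t = t, s = s,
               C_obs = 100 * (1 - exp(-1.2 * s)))
  }))
  rf <- fit_effort_model(obs, effort_model_spec("q_scaled", random_site = TRUE))
  expect_equal(rf$alpha, 1.2, tolerance = 1e-6)
  expect_equal(rf$sigma_b, 0)
  expect_true(rf$boundary)
  expect_equal(rf$K, 3L)

  ff <- fit_effort_model(obs, effort_model_spec("q_scaled"))
  expect_equal(ff$alpha, 1.2, tolerance = 1e-8)
  expect_equal(ff$K, 2L)
})

test_that("null model is the sample mean with ML variance", {
  obs <- gen_effort_obs(seed = 3)
  nf <- fit_effort_model(obs, effort_model_spec(null_model = TRUE))
  expect_equal(nf$intercept, mean(obs$C_obs), tolerance = 1e-12)
  expect_equal(nf$sigma, sqrt(mean((obs$C_obs - mean(obs$C_obs))^2)),
               tolerance = 1e-12)
  expect_equal(nf$K, 2L)
  expect_equal(nf$loglik,
               sum(dnorm(obs$C_obs, mean(obs$C_obs), nf$sigma, log = TRUE)),
               tolerance = 1e-10)
})

test_that("mixed-model ML agrees with an independent nonlinear mixed-effects fitter", {
  skip_if_not_installed("nlme")
  obs <- gen_effort_obs(alpha = 1.4, sigma_b = 0.15, sigma = 5, seed = 7)
  mine <- fit_effort_model(obs, effort_model_spec("q_scaled", random_site = TRUE))
  ref <- nlme::nlme(C_obs ~ 100 * (1 - exp(-a * s)), fixed = a ~ 1,
                    random = a ~ 1 | site, data = obs, start = c(a = 1),
                    method = "ML")
  expect_equal(mine$alpha, unname(nlme::fixef(ref)), tolerance = 0.02)
  # adaptive quadrature should do at least as well as nlme's approximation
  expect_gte(mine$loglik, as.numeric(stats::logLik(ref)) - 0.05)
  expect_equal(mine$sigma, ref$sigma, tolerance = 0.05)
})

test_that("effort-model preconditions are enforced", {
  obs <- gen_effort_obs(seed = 1)
  one_site <- obs[obs$site == "S1", ]
  expect_error(fit_effort_model(one_site,
                                effort_model_spec("q_scaled", random_site = TRUE)),
               "at least 2 sites")
  expect_error(fit_effort_model(obs[1:2, ], effort_model_spec("q_scaled")),
               "at least 3")
  no_s <- obs[setdiff(names(obs), "s")]
  expect_error(fit_effort_model(no_s, effort_model_spec("q_scaled")),
               "scaled-effort")
})

test_that("AICc correction and guards", {
  expect_equal(aicc(-10, 2, 20), 20 + 4 + 12 / 17)
  expect_error(aicc(-10, 3, 4), "n > K \\+ 1")
})

test_that("model comparison sorts, normalizes weights and validates n", {
  obs <- gen_effort_obs(seed = 12)
  fits <- lapply(default_model_suite(), function(sp)
    fit_effort_model(obs, sp, seed = 2))
  cmp <- compare_models(fits)
  expect_equal(cmp$delta_aicc[1], 0)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(cmp$aicc) >= 0))
  expect_gte(cmp$weight[1], 1 / nrow(cmp))

  # closed-form two-model weights
  f1 <- fits[[1]]; f2 <- fits[[1]]
  f2$aicc <- f1$aicc + 8.78
  w2 <- compare_models(list(a = f1, b = f2))$weight[2]
  expect_equal(w2, exp(-4.39) / (1 + exp(-4.39)), tolerance = 1e-10)
  f2$aicc <- f1$aicc
  expect_equal(compare_models(list(a = f1, b = f2))$weight, c(0.5, 0.5))

  f3 <- f1; f3$n <- f1$n - 1
  expect_error(compare_models(list(a = f1, b = f3)), "different numbers")
})

test_that("q-scaling wins model selection when catchability varies across sites", {
  # fixed-effect variants only; generated under the q-scaled structure
  wins <- 0L
  n_reps <- 60
  for (r in seq_len(n_reps)) {
    obs <- gen_effort_obs(alpha = 1.4, sigma_b = 0, sigma = 6, seed = 1000 + r)
    qs <- fit_effort_model(obs, effort_model_spec("q_scaled"))
    us <- fit_effort_model(obs, effort_model_spec("unscaled"))
    if (qs$aicc < us$aicc) wins <- wins + 1L
  }
  expect_gt(wins / n_reps, 0.5)
})

test_that("alpha estimates are consistent over replicated studies", {
  cfg <- simulation_config(alpha_true = 1.4, sigma_b_true = 0.1,
                           sigma_true = 5, seed = 500)
  est <- numeric(40)
  for (r in seq_len(40)) {
    cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
    study <- simulate_study(cfg_r)
    fit <- fit_effort_model(study$effort_obs,
                            effort_model_spec("q_scaled", random_site = TRUE),
                            n_starts = 2, seed = cfg_r$seed)
    est[r] <- fit$alpha
  }
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.4), 3 * mc_se)
})

test_that("planner evaluation, inversion and intervals behave as a monotone pair", {
  fit <- effort_model_from_coefficients(alpha = 1.39, alpha_se = 0.08,
                                        n = 39, K = 3)
  expect_equal(predict_removal(fit, q = 0.5, t = 0)$C, 0)
  expect_equal(effort_for_target(fit, q = 0.5, target = 0)$t, 0)

  p <- predict_removal(fit, q = 0.694, t = 1)
  expect_equal(p$C, 100 * (1 - exp(-1.39 * 0.694)), tolerance = 1e-12)
  expect_true(p$ci[1] < p$C && p$C < p$ci[2])

  e <- effort_for_target(fit, q = 0.694, target = 50)
  expect_true(e$ci[1] < e$t && e$t < e$ci[2])

  expect_error(effort_for_target(fit, q = 0.694, target = 100), "asymptote")
  expect_error(predict_removal(fit, q = -1, t = 1), "positive")
})

test_that("plan_removals reports per-row failures without aborting", {
  fit <- effort_model_from_coefficients(alpha = 1.39, alpha_se = 0.08,
                                        n = 39, K = 3)
  tab <- plan_removals(fit, c(low = 0.43, high = 0.91), targets = c(50, 90))
  expect_equal(nrow(tab), 4)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$effort_hours_per_1000m2[tab$target_percent == 90] >
                    tab$effort_hours_per_1000m2[tab$target_percent == 50]))
})
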