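test_that("dive standardization converts effort and catch per 1,000 m2", {
  # 3 divers x 20 min on a 1,000 m2 site is one diver-hour
  s <- standardize_dive("A", 1, catch_count = 4, n_divers = 3,
                        minutes_each = 20, area = 1000)
  expect_equal(s$h, 1)
  expect_equal(s$c, 4)
  expect_equal(s$cpue, 4)

  # one diver-hour on 1,800 m2 scales by 1000/1800
  s <- standardize_dive("A", 1, catch_count = 9, diver_minutes = 60,
                        area = 1800)
  expect_equal(s$h, 1000 / 1800)
  expect_equal(s$c, 5)
  expect_equal(s$cpue, 9)

  # zero catch with positive effort has CPUE 0
  s <- standardize_dive("A", 2, catch_count = 0, diver_minutes = 45, area = 1500)
  expect_equal(s$c, 0)
  expect_equal(s$cpue, 0)
})

test_that("standardization rejects zero effort, bad area and bad catch", {
  expect_error(standardize_dive("A", 1, 3, diver_minutes = 0, area = 1000),
               "A.*1.*effort")
  expect_error(standardize_dive("B", 2, 3, diver_minutes = 30, area = 0),
               "B.*area")
  expect_error(standardize_dive("A", 1, -1, diver_minutes = 30, area = 1000),
               "negative")
  expect_error(standardize_dive("A", 1, 3, area = 1000), "diver_minutes")
})

test_that("build_series accumulates prior catch and orders by dive index", {
  std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
                    cpue = c(10, 5, 2.5))
  ser <- build_series(std)
  expect_equal(ser$dives$K_prior, c(0, 10, 15))
  expect_equal(ser$T, 3)

  # single dive
  one <- build_series(data.frame(site = "A", dive = 1, h = 1, c = 7, cpue = 7))
  expect_equal(one$dives$K_prior, 0)

  # input row order is irrelevant
  perm <- build_series(std[c(3, 1, 2), ])
  expect_identical(perm$dives, ser$dives)
})

test_that("build_series drops the second of two consecutive zero-catch dives", {
  std <- data.frame(site = "A", dive = 1:5, h = 1, c = c(8, 3, 0, 0, 0),
                    cpue = c(8, 3, 0, 0, 0))
  ser <- build_series(std)
  expect_equal(ser$T, 3)           # dives 1, 2 and the first zero
  expect_true(ser$depletion_achieved)
  expect_equal(ser$dives$n, c(8, 3, 0))

  # a single zero between positive catches is retained and nothing is dropped
  std2 <- data.frame(site = "A", dive = 1:4, h = 1, c = c(8, 0, 3, 1),
                     cpue = c(8, 0, 3, 1))
  ser2 <- build_series(std2)
  expect_equal(ser2$T, 4)
  expect_false(ser2$depletion_achieved)
})

test_that("build_series rejects duplicate, gappy or mixed-site input", {
  base <- data.frame(site = "A", dive = c(1, 2, 2), h = 1, c = 1, cpue = 1)
  expect_error(build_series(base), "duplicate")
  gap <- data.frame(site = "A", dive = c(1, 3), h = 1, c = 1, cpue = 1)
  expect_error(build_series(gap), "consecutive")
  mixed <- data.frame(site = c("A", "B"), dive = 1:2, h = 1, c = 1, cpue = 1)
  expect_error(build_series(mixed), "single site")
})

test_that("total catch estimate is the summed standardized catch", {
  std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
                    cpue = c(10, 5, 2.5))
  expect_equal(total_catch_estimate(build_series(std)), 17.5)
  z <- data.frame(site = "A", dive = 1, h = 1, c = 0, cpue = 0)
  expect_equal(total_catch_estimate(build_series(z)), 0)
  # 35 fish over 1,184 m2
  expect_equal(35 * 1000 / 1184, 29.56, tolerance = 1e-3)
})

test_that("Leslie fit solves the collinear case exactly", {
  std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
                    cpue = c(10, 5, 2.5))
  f <- fit_leslie(build_series(std))
  expect_equal(f$q, 0.5, tolerance = 1e-12)
  expect_equal(f$N0, 20, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$residuals, rep(0, 3), tolerance = 1e-10)
  expect_equal(f$N_t, c(20, 10, 5), tolerance = 1e-9)
})

test_that("Leslie fit recovers exact expectation-mode parameters", {
  set.seed(11)
  for (rep in 1:20) {
    q <- runif(1, 0.05, 0.95)
    N0 <- runif(1, 5, 50)
    T <- sample(3:7, 1)
    f <- fit_leslie(build_series(exact_std(N0 = N0, q = q, T = T)))
    expect_equal(f$q, q, tolerance = 1e-9)
    expect_equal(f$N0, N0, tolerance = 1e-9)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("Leslie fit matches a brute-force normal-equations oracle", {
  set.seed(3)
  for (rep in 1:10) {
    T <- sample(4:7, 1)
    K <- c(0, cumsum(runif(T - 1, 1, 5)))
    y <- 10 - 0.6 * K + rnorm(T, 0, 0.5)
    # catches chosen so the cumulative-prior-catch regressor equals K exactly
    ser <- build_series(data.frame(site = "A", dive = seq_len(T), h = 1,
                                   c = c(diff(K), 1), cpue = y))
    f <- fit_leslie(ser)
    X <- cbind(1, ser$dives$K_prior)
    beta <- solve(t(X) %*% X, t(X) %*% ser$dives$cpue)
    res <- ser$dives$cpue - X %*% beta
    r2 <- 1 - sum(res^2) / sum((ser$dives$cpue - mean(ser$dives$cpue))^2)
    se <- sqrt(drop(sum(res^2) / (T - 2)) * solve(t(X) %*% X)[2, 2])
    p <- 2 * pt(abs(beta[2] / se), T - 2, lower.tail = FALSE)
    expect_equal(f$q, -beta[2], tolerance = 1e-10)
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$r2, r2, tolerance = 1e-10)
    expect_equal(f$p_value, p, tolerance = 1e-10)
  }
})

test_that("area rescaling is dimensionally consistent", {
  # with raw records fixed, CPUE = catch/effort is area-free; doubling the
  # assumed area halves both density (N0) and per-area effort, so the
  # per-(diver-hour per 1,000 m2) catchability doubles while the intercept
  # q*N0 and the fitted CPUE are unchanged
  dives <- data.frame(site = "A", dive = 1:4, diver_minutes = 60,
                      catch = c(12, 7, 4, 2))
  fit_at <- function(area) {
    sites <- data.frame(site = "A", area_m2 = area)
    fit_leslie(build_series(standardize_dives(dives, sites)))
  }
  f1 <- fit_at(1000); f2 <- fit_at(2000)
  expect_equal(f2$q, 2 * f1$q, tolerance = 1e-9)
  expect_equal(f2$N0, f1$N0 / 2, tolerance = 1e-9)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-9)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("Leslie fit error paths: no depletion signal, too few dives, shaky CI", {
  up <- data.frame(site = "A", dive = 1:4, h = 1, c = c(2, 4, 6, 8),
                   cpue = c(2, 4, 6, 8))
  expect_error(fit_leslie(build_series(up)), "no depletion signal")

  two <- data.frame(site = "A", dive = 1:2, h = 1, c = c(5, 3), cpue = c(5, 3))
  expect_error(fit_leslie(build_series(two)), "at least 3")

  # weak signal: q CI spans zero, so the N0 interval is flagged unreliable
  set.seed(5)
  noisy <- data.frame(site = "A", dive = 1:5, h = 1,
                      c = c(6, 5.9, 5.2, 6.1, 5.0))
  noisy$cpue <- noisy$c
  f <- fit_leslie(build_series(noisy))
  expect_true(f$q_ci[1] < 0)
  expect_false(f$N0_ci_reliable)
})

test_that("bootstrap N0 interval brackets the estimate and is seed-stable", {
  set.seed(21)
  std <- exact_std(N0 = 25, q = 0.6, T = 5)
  std$cpue <- std$cpue + rnorm(5, 0, 0.4)
  std$c <- std$cpue * std$h
  ser <- build_series(std)
  b1 <- fit_leslie(ser, n0_ci = "bootstrap", boot_reps = 500, seed = 9)
  b2 <- fit_leslie(ser, n0_ci = "bootstrap", boot_reps = 500, seed = 9)
  expect_identical(b1$N0_ci, b2$N0_ci)
  expect_true(b1$N0_ci[1] < b1$N0 && b1$N0 < b1$N0_ci[2])
})

test_that("binomial-removal estimation is unbiased and the N0 interval calibrated", {
  # 500 binomial-removal sites at study-like densities and catchabilities,
  # one diver-hour per 1,000 m2 per dive, depletion-to-zeros stopping
  cfg <- simulation_config(n_sites = 5, area_range = c(1000, 1000),
                           effort_per_dive = c(1, 0), max_dives = 10,
                           stopping = "two_consecutive_zeros",
                           noise_mode = "binomial", seed = 100)
  tab <- recovery_experiment(cfg, n_reps = 100)
  q_row <- tab[tab$parameter == "q", ]
  n0_row <- tab[tab$parameter == "N0", ]
  expect_lt(abs(q_row$bias), 3 * q_row$mc_se)
  expect_gte(n0_row$coverage, 0.85)
})
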