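#' Specify an exponential removal-model variant
#'
#' The model suite relates the cumulative percent of the initial population
#' removed, `C`, to cumulative dive effort. Effort may be used raw
#' (diver-hours per 1,000 m2) or scaled by the site's catchability `q` so that
#' one unit means comparable removal power across sites of differing removal
#' efficacy; the rate coefficient `alpha` may carry a normal site random
#' effect; and a null (intercept-only) model completes the suite.
#'
#' @param scaling `"q_scaled"` (effort multiplied by site catchability) or
#'   `"unscaled"`.
#' @param random_site include a site random effect on `alpha`?
#' @param null_model intercept-only model (`C = mu + eps`); excludes the
#'   other options.
#' @return Object of class `effort_model_spec`.
#' @export
effort_model_spec <- function(scaling = c("q_scaled", "unscaled"),
                              random_site = FALSE, null_model = FALSE) {
  if (null_model) {
    spec <- list(scaling = NA_character_, random_site = FALSE, null_model = TRUE)
  } else {
    spec <- list(scaling = match.arg(scaling), random_site = isTRUE(random_site),
                 null_model = FALSE)
  }
  structure(spec, class = "effort_model_spec")
}

#' The default five-model suite
#'
#' q-scaled and unscaled effort, each with and without the site random effect,
#' plus the null model.
#' @return Named list of [effort_model_spec()] objects.
#' @export
default_model_suite <- function() {
  list(
    q_scaled_random   = effort_model_spec("q_scaled", random_site = TRUE),
    q_scaled          = effort_model_spec("q_scaled"),
    unscaled_random   = effort_model_spec("unscaled", random_site = TRUE),
    unscaled          = effort_model_spec("unscaled"),
    null              = effort_model_spec(null_model = TRUE)
  )
}

#' Build cumulative removal observations from depletion fits
#'
#' For every retained dive at every site, computes cumulative effort `t`
#' (diver-hours per 1,000 m2 through the end of that dive), catchability-
#' scaled effort `s = q * t`, and the observed cumulative percent of the
#' estimated initial population removed,
#' `C_obs = 100 * cumulative catch / N0`. `C_obs` may exceed 100 when the
#' regression `N0` underestimates the true total and is deliberately not
#' clipped.
#'
#' @param fits list of `leslie_fit` objects.
#' @param serieses list of `depletion_series` objects (same sites).
#' @return Data frame `site`, `dive`, `t`, `s`, `C_obs`.
#' @export
build_removal_observations <- function(fits, serieses) {
  fit_ids <- vapply(fits, `[[`, character(1), "site_id")
  out <- do.call(rbind, lapply(serieses, function(ser) {
    i <- match(ser$site_id, fit_ids)
    if (is.na(i)) stop("no Leslie fit for site '", ser$site_id, "'")
    f <- fits[[i]]
    d <- ser$dives
    data.frame(site = ser$site_id, dive = d$dive, t = cumsum(d$h),
               s = f$q * cumsum(d$h),
               C_obs = 100 * cumsum(d$n) / f$N0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- likelihood machinery ---------------------------------------------------

ghq_cache <- new.env(parent = emptyenv())

gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(ghq_cache[[key]])) ghq_cache[[key]] <- pracma::gaussHermite(nodes)
  ghq_cache[[key]]
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# per-site joint log density of data and random effect b, given theta
site_logjoint <- function(b, C, x, alpha, sigma_b, sigma) {
  mu <- 100 * (1 - exp(-(alpha + b) * x))
  v <- sum(dnorm(C, mu, sigma, log = TRUE)) + dnorm(b, 0, sigma_b, log = TRUE)
  if (!is.finite(v)) -1e12 else v  # keep the mode search finite
}

# marginal log-likelihood of one site by adaptive Gauss-Hermite quadrature;
# falls back to a Laplace approximation if the curvature estimate degenerates
site_loglik_agh <- function(C, x, alpha, sigma_b, sigma, rule) {
  f <- function(b) site_logjoint(b, C, x, alpha, sigma_b, sigma)
  span <- max(6 * sigma_b, 1e-3)
  opt <- optimize(f, interval = c(-span, span), maximum = TRUE, tol = 1e-10)
  bhat <- opt$maximum
  delta <- max(1e-5, sigma_b * 1e-3)
  h <- -(f(bhat + delta) - 2 * opt$objective + f(bhat - delta)) / delta^2
  if (!is.finite(h) || h <= 0) {
    # curvature dominated by the prior when sigma_b is tiny
    h <- 1 / sigma_b^2
  }
  s <- sqrt(2 / h)
  lvals <- log(rule$w) + rule$x^2 +
    vapply(rule$x, function(z) f(bhat + s * z), numeric(1))
  list(loglik = log(s) + log_sum_exp(lvals), bhat = bhat)
}

effort_x <- function(obs, spec) {
  if (identical(spec$scaling, "q_scaled")) obs$s else obs$t
}

#' Fit an exponential removal model by maximum likelihood
#'
#' Fits `C_obs = 100 * (1 - exp(-(alpha + b_i) * x)) + eps` where `x` is
#' catchability-scaled (`s = q*t`) or raw (`t`) cumulative effort,
#' `b_i ~ N(0, sigma_b^2)` is an optional site random effect on the rate
#' coefficient, and `eps ~ N(0, sigma^2)`. Estimation is by maximum
#' likelihood (not REML) so that models with different fixed-effect
#' structures remain comparable by AICc; the random effect is integrated out
#' by adaptive Gauss-Hermite quadrature (15 nodes by default, with a Laplace
#' fallback where the curvature estimate degenerates). The optimizer is
#' multi-started from 5 seeded initial points on a log parameterization of
#' the standard deviations. The null model fits `C_obs = mu + eps`.
#'
#' Parameter counts follow the usual accounting: fixed model `(alpha, sigma)`
#' K = 2; random model `(alpha, sigma_b, sigma)` K = 3; null `(mu, sigma)`
#' K = 2.
#'
#' @param obs observations from [build_removal_observations()] (columns
#'   `site`, `t`, `s`, `C_obs`).
#' @param spec an [effort_model_spec()].
#' @param gh_nodes Gauss-Hermite nodes for the random-effect integral.
#' @param n_starts number of optimizer starts.
#' @param seed seed for start-point jitter.
#' @param tol convergence tolerance on the log-likelihood.
#' @return Object of class `effort_model_fit` with elements `alpha`,
#'   `alpha_se`, `intercept` (null model mean), `sigma_b`, `sigma`, `loglik`,
#'   `K`, `n`, `aicc`, `df`, `site_effects` (predicted `b_i`), `boundary`
#'   (TRUE when `sigma_b` collapsed to its lower bound), `spec`,
#'   `convergence`.
#' @export
fit_effort_model <- function(obs, spec = effort_model_spec(), gh_nodes = 15,
                             n_starts = 5, seed = 1, tol = 1e-8) {
  stopifnot(inherits(spec, "effort_model_spec"))
  need <- c("site", "t", "C_obs")
  if (!all(need %in% names(obs))) {
    stop("observations need columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(obs)
  if (n < 3L) stop("need at least 3 observations")
  C <- obs$C_obs

  if (spec$null_model) {
    mu <- mean(C)
    sigma2 <- mean((C - mu)^2)              # ML variance
    ll <- sum(dnorm(C, mu, sqrt(sigma2), log = TRUE))
    K <- 2L
    fit <- list(alpha = NA_real_, alpha_se = NA_real_, intercept = mu,
                intercept_se = sd(C) / sqrt(n), sigma_b = NA_real_,
                sigma = sqrt(sigma2), loglik = ll, K = K, n = n,
                aicc = aicc(ll, K, n), df = n - K, site_effects = NULL,
                boundary = FALSE, spec = spec, convergence = 0L)
    return(structure(fit, class = "effort_model_fit"))
  }

  if (identical(spec$scaling, "q_scaled") && !"s" %in% names(obs)) {
    stop("q-scaled model needs the scaled-effort column s")
  }
  x <- effort_x(obs, spec)
  if (any(!is.finite(x)) || any(x < 0)) stop("effort values must be finite and >= 0")

  # fixed-effect-only profile fit: sigma^2 = SSE(alpha)/n in closed form.
  # SSE is flat for large alpha (the curve saturates at 100), so bracket the
  # minimum on a log grid before refining, rather than trusting unimodality
  # over the whole range.
  sse <- function(a) sum((C - 100 * (1 - exp(-a * x)))^2)
  grid <- exp(seq(log(1e-4), log(1e3), length.out = 81))
  i <- which.min(vapply(grid, sse, numeric(1)))
  prof <- optimize(sse, interval = c(grid[max(i - 1L, 1L)],
                                     grid[min(i + 1L, length(grid))]),
                   tol = 1e-12)
  alpha0 <- prof$minimum
  sigma0 <- sqrt(prof$objective / n)

  if (!spec$random_site) {
    negll <- function(par) {
      a <- par[1]; s <- exp(par[2])
      v <- -sum(dnorm(C, 100 * (1 - exp(-a * x)), s, log = TRUE))
      if (!is.finite(v)) 1e10 else v
    }
    par0 <- c(alpha0, log(max(sigma0, 1e-8)))
    opt <- nlminb(par0, negll, lower = c(1e-10, log(1e-9)),
                  control = list(abs.tol = tol, rel.tol = 1e-12))
    ll <- -opt$objective
    K <- 2L
    a_se <- se_from_hessian(opt$par, negll, 1)
    fit <- list(alpha = opt$par[1], alpha_se = a_se, intercept = NA_real_,
                sigma_b = NA_real_, sigma = exp(opt$par[2]), loglik = ll,
                K = K, n = n, aicc = aicc(ll, K, n), df = n - K,
                site_effects = NULL, boundary = FALSE, spec = spec,
                convergence = opt$convergence)
    return(structure(fit, class = "effort_model_fit"))
  }

  # random effect on alpha: theta = (alpha, log sigma_b, log sigma)
  if (length(unique(obs$site)) < 2L) {
    stop("site random effect needs at least 2 sites")
  }
  rule <- gh_rule(gh_nodes)
  by_site <- split(data.frame(C = C, x = x), obs$site)
  lsb_floor <- log(1e-6)

  # Degenerate data: all observations lie exactly on one curve. The mixed
  # likelihood is then unbounded in sigma -> 0 and sigma_b is unidentifiable;
  # return the boundary limit of the fixed fit instead of chasing it.
  if (sigma0^2 < 1e-14 * max(stats::var(C), 1)) {
    ll <- -sum(vapply(by_site, function(d) {
      site_loglik_agh(d$C, d$x, alpha0, exp(lsb_floor),
                      max(sigma0, 1e-9), rule)$loglik
    }, numeric(1)))
    fit <- list(alpha = alpha0, alpha_se = NA_real_, intercept = NA_real_,
                sigma_b = 0, sigma = sigma0, loglik = -ll, K = 3L, n = n,
                aicc = aicc(-ll, 3L, n), df = n - 3L,
                site_effects = setNames(rep(0, length(by_site)), names(by_site)),
                boundary = TRUE, spec = spec, convergence = 0L)
    return(structure(fit, class = "effort_model_fit"))
  }
  negll <- function(par) {
    a <- par[1]; sb <- exp(par[2]); s <- exp(par[3])
    ll <- sum(vapply(by_site, function(d) {
      site_loglik_agh(d$C, d$x, a, sb, s, rule)$loglik
    }, numeric(1)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- list(c(alpha0, log(max(0.1 * alpha0, 1e-3)), log(max(sigma0, 1e-6))))
  for (i in seq_len(max(0L, n_starts - 1L))) {
    starts[[i + 1L]] <- c(alpha0 * exp(rnorm(1, 0, 0.3)),
                          log(max(alpha0, 1e-3)) + rnorm(1, -2, 1),
                          log(max(sigma0, 1e-6)) + rnorm(1, 0, 0.5))
  }
  # boundary start: the sigma_b -> 0 limit (degenerate optimum of noiseless data)
  starts[[length(starts) + 1L]] <- c(alpha0, lsb_floor, log(max(sigma0, 1e-9)))
  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      nlminb(p0, negll, lower = c(1e-10, lsb_floor, log(1e-9)),
             upper = c(Inf, log(1e4), log(1e6)),
             control = list(abs.tol = tol, rel.tol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) best <- o
  }
  if (is.null(best)) {
    stop("effort-model optimization failed to converge from any start")
  }
  ll <- -best$objective
  K <- 3L
  sigma_b <- exp(best$par[2]); sigma <- exp(best$par[3])
  boundary <- best$par[2] <= lsb_floor + 1e-6
  a_se <- se_from_hessian(best$par, negll, 1)
  b_hat <- vapply(by_site, function(d) {
    site_loglik_agh(d$C, d$x, best$par[1], sigma_b, sigma, rule)$bhat
  }, numeric(1))
  fit <- list(alpha = best$par[1], alpha_se = a_se, intercept = NA_real_,
              sigma_b = sigma_b, sigma = sigma, loglik = ll, K = K, n = n,
              aicc = aicc(ll, K, n), df = n - K, site_effects = b_hat,
              boundary = boundary, spec = spec, convergence = best$convergence)
  structure(fit, class = "effort_model_fit")
}

# delta-free standard error for one coordinate from the observed information
se_from_hessian <- function(par, negll, index) {
  H <- tryCatch(optimHess(par, negll), error = function(e) NULL)
  if (is.null(H)) return(NA_real_)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || V[index, index] <= 0) return(NA_real_)
  sqrt(V[index, index])
}

#' Construct an effort-model fit from published coefficients
#'
#' Lets the planner run from a previously reported rate coefficient (for
#' example one estimated elsewhere on a comparable reef system) without
#' refitting, so [predict_removal()] and [effort_for_target()] can be used
#' as reference calculations when no local depletion data exist.
#'
#' @param alpha rate coefficient of the exponential removal curve.
#' @param alpha_se its standard error (optional; `NA` disables intervals).
#' @param n,K observation and parameter counts behind the published fit,
#'   used for the t-interval degrees of freedom.
#' @param scaling effort scaling the coefficient was estimated under.
#' @return An `effort_model_fit` (with no likelihood information).
#' @export
effort_model_from_coefficients <- function(alpha, alpha_se = NA_real_,
                                           n = Inf, K = 2,
                                           scaling = "q_scaled") {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  structure(list(alpha = alpha, alpha_se = alpha_se, intercept = NA_real_,
                 sigma_b = NA_real_, sigma = NA_real_, loglik = NA_real_,
                 K = K, n = n, aicc = NA_real_, df = n - K,
                 site_effects = NULL, boundary = FALSE,
                 spec = effort_model_spec(scaling),
                 convergence = NA_integer_),
            class = "effort_model_fit")
}

#' @export
print.effort_model_fit <- function(x, ...) {
  lab <- if (x$spec$null_model) "null (intercept only)" else
    paste0(x$spec$scaling, if (x$spec$random_site) " + site random effect" else "")
  cat("Exponential removal model [", lab, "]\n", sep = "")
  if (x$spec$null_model) {
    cat(sprintf("  intercept = %.2f +/- %.2f\n", x$intercept, x$intercept_se))
  } else {
    cat(sprintf("  alpha = %.3f%s\n", x$alpha,
                if (is.finite(x$alpha_se)) sprintf(" +/- %.3f", x$alpha_se) else ""))
    if (x$spec$random_site) {
      cat(sprintf("  sigma_b = %.3f%s\n", x$sigma_b,
                  if (x$boundary) " (boundary)" else ""))
    }
  }
  if (is.finite(x$loglik)) {
    cat(sprintf("  sigma = %.3f, logLik = %.2f, K = %d, n = %d, AICc = %.2f\n",
                x$sigma, x$loglik, x$K, x$n, x$aicc))
  }
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n number of observations; must exceed `K + 1`.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-116.56, 3, 39)
aicc <- function(loglik, K, n) {
  if (any(n <= K + 1)) stop("AICc undefined: need n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank effort models by AICc
#'
#' @param fits named list of `effort_model_fit` objects fitted to the same
#'   observations (equal `n`).
#' @return Object of class `model_comparison`: data frame sorted by AICc with
#'   columns `model`, `scaling`, `random`, `alpha`, `alpha_se`, `intercept`,
#'   `K`, `loglik`, `aicc`, `delta_aicc`, `weight`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, TRUE, "effort_model_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("models were fitted to different numbers of observations")
  }
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               scaling = if (f$spec$null_model) NA_character_ else f$spec$scaling,
               random = f$spec$random_site, alpha = f$alpha,
               alpha_se = f$alpha_se, intercept = f$intercept,
               K = f$K, loglik = f$loglik, aicc = f$aicc,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(tab, class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (AICc, best first):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
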