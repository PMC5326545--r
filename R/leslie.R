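#' Fit a Leslie depletion regression for one site
#'
#' Ordinary least squares of CPUE on cumulative prior catch:
#' `CPUE_t = q*N0 - q*K_{t-1}`. The slope is `-q` (catchability: the fraction
#' of the extant population removed by one diver-hour per 1,000 m2) and the
#' intercept is `q*N0`, so the initial population per 1,000 m2 is
#' `N0 = intercept / q`.
#'
#' The confidence interval for `q` is the t-based interval on the OLS slope
#' (sign-flipped). For `N0`, a ratio of coefficients, the default interval
#' uses the delta method on the OLS coefficient covariance; a seeded
#' percentile residual bootstrap is available as an alternative. When the `q`
#' interval includes zero the `N0` interval is effectively unbounded and is
#' flagged unreliable rather than silently reported.
#'
#' @param series a `depletion_series` from [build_series()] with at least 3
#'   dives and at least two distinct `K_prior` values.
#' @param level confidence level (default 0.95).
#' @param n0_ci `"delta"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates when `n0_ci = "bootstrap"`.
#' @param seed seed for the bootstrap resampling.
#'
#' @return Object of class `leslie_fit`: list with `site_id`, `q`, `N0`,
#'   `intercept`, `q_ci`, `N0_ci`, `N0_ci_reliable`, `r2`, `p_value`,
#'   `residuals`, `fitted`, `N_t` (estimated population remaining before each
#'   dive, `N0 - K_{t-1}`), `T`, `lm` (the underlying [stats::lm] fit) and the
#'   CI settings used.
#' @export
#' @examples
#' std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
#'                   cpue = c(10, 5, 2.5))
#' fit <- fit_leslie(build_series(std))
#' c(fit$q, fit$N0)  # 0.5, 20
fit_leslie <- function(series, level = 0.95, n0_ci = c("delta", "bootstrap"),
                       boot_reps = 2000, seed = NULL) {
  stopifnot(inherits(series, "depletion_series"))
  n0_ci <- match.arg(n0_ci)
  d <- series$dives
  if (nrow(d) < 3L) {
    stop("site '", series$site_id, "': need at least 3 dives for a Leslie fit")
  }
  if (any(d$h <= 0)) {
    stop("site '", series$site_id, "': all dives must have positive effort")
  }
  if (length(unique(d$K_prior)) < 2L) {
    stop("site '", series$site_id, "': cumulative catch never changes; no regressor")
  }

  fit <- lm(cpue ~ K_prior, data = d)
  b <- coef(fit)
  slope <- unname(b["K_prior"]); icept <- unname(b["(Intercept)"])
  if (!is.finite(slope) || slope >= 0) {
    stop("site '", series$site_id,
         "': no depletion signal (CPUE does not decline with cumulative catch)")
  }
  q <- -slope
  N0 <- icept / q
  sm <- suppressWarnings(summary(fit))  # exact fits trip lm's perfect-fit warning
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - level) / 2, df)
  se_slope <- sm$coefficients["K_prior", "Std. Error"]
  q_ci <- c(q - tcrit * se_slope, q + tcrit * se_slope)
  q_reliable <- q_ci[1] > 0

  if (n0_ci == "delta") {
    # N0 = -b0/b1; gradient (-1/b1, b0/b1^2)
    V <- suppressWarnings(vcov(fit))  # perfect fits trip the summary warning
    g <- c(-1 / slope, icept / slope^2)
    se_N0 <- sqrt(drop(t(g) %*% V %*% g))
    N0_ci <- c(N0 - tcrit * se_N0, N0 + tcrit * se_N0)
  } else {
    if (!is.null(seed)) set.seed(seed)
    res <- resid(fit); fitv <- fitted(fit)
    reps <- vapply(seq_len(boot_reps), function(i) {
      y <- fitv + sample(res, replace = TRUE)
      bb <- coef(lm(y ~ d$K_prior))
      if (bb[2] >= 0) return(NA_real_)
      -bb[1] / bb[2]
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    N0_ci <- unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }

  structure(list(
    site_id = series$site_id, q = q, N0 = N0, intercept = icept,
    q_ci = q_ci, N0_ci = N0_ci, N0_ci_reliable = q_reliable,
    r2 = sm$r.squared,
    p_value = sm$coefficients["K_prior", "Pr(>|t|)"],
    residuals = unname(resid(fit)), fitted = unname(fitted(fit)),
    N_t = N0 - d$K_prior, T = nrow(d), level = level, n0_ci_method = n0_ci,
    lm = fit
  ), class = "leslie_fit")
}

#' @export
print.leslie_fit <- function(x, ...) {
  cat(sprintf(
    "Leslie depletion fit, site %s (%d dives)\n  N0 = %.0f (%.0f-%.0f) fish per 1,000 m2\n  q  = %.2f (%.2f-%.2f) per diver-hour per 1,000 m2%s\n  r2 = %.2f, p = %.4g\n",
    x$site_id, x$T, x$N0, x$N0_ci[1], x$N0_ci[2],
    x$q, x$q_ci[1], x$q_ci[2],
    if (!x$N0_ci_reliable) "  [q CI spans 0; N0 CI unreliable]" else "",
    x$r2, x$p_value))
  invisible(x)
}

#' Tabulate Leslie fits across sites
#'
#' @param fits list of `leslie_fit` objects.
#' @return Data frame with one row per site: `site`, `N0`, `N0_lo`, `N0_hi`,
#'   `q`, `q_lo`, `q_hi`, `r2`, `p`, `T`, `N0_ci_reliable`.
#' @export
leslie_table <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "leslie_fit")))
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(site = f$site_id, N0 = f$N0, N0_lo = f$N0_ci[1],
               N0_hi = f$N0_ci[2], q = f$q, q_lo = f$q_ci[1], q_hi = f$q_ci[2],
               r2 = f$r2, p = f$p_value, T = f$T,
               N0_ci_reliable = f$N0_ci_reliable, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
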