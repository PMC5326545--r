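#' Shapiro-Wilk normality check for regression residuals
#'
#' @param residuals numeric vector, 3 to 5000 values with positive variance.
#' @return List `(shapiro_W, shapiro_p)`.
#' @export
residual_normality <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3L || length(residuals) > 5000L) {
    stop("Shapiro-Wilk needs between 3 and 5000 residuals")
  }
  if (sd(residuals) < max(1e-12, 1e-8 * max(abs(residuals)))) {
    stop("residuals have (numerically) zero variance")
  }
  sw <- shapiro.test(residuals)
  list(shapiro_W = unname(sw$statistic), shapiro_p = unname(sw$p.value))
}

#' Breusch-Pagan homoscedasticity check for a regression fit
#'
#' Uses the studentized (Koenker) variant by default, a chi-squared statistic
#' with one degree of freedom for a single regressor; the classic variant is
#' available with `studentize = FALSE`.
#'
#' @param fit an [stats::lm] fit or a `leslie_fit`.
#' @param studentize use the studentized variant (default TRUE).
#' @return List `(bp_stat, bp_p)`.
#' @export
residual_homoscedasticity <- function(fit, studentize = TRUE) {
  if (inherits(fit, "leslie_fit")) fit <- fit$lm
  if (!inherits(fit, "lm")) stop("fit must be an lm or leslie_fit")
  if (length(resid(fit)) < 3L) stop("need at least 3 residuals")
  x <- stats::model.matrix(fit)
  if (ncol(x) < 2L || stats::var(x[, 2]) == 0) stop("degenerate regressor")
  if (all(abs(resid(fit)) < 1e-12)) {
    # exact fit: squared residuals carry no signal, homoscedastic limit
    return(list(bp_stat = 0, bp_p = 1))
  }
  bp <- lmtest::bptest(fit, studentize = studentize)
  list(bp_stat = unname(bp$statistic), bp_p = unname(bp$p.value))
}

#' Residual diagnostics for a set of Leslie fits
#'
#' Runs Shapiro-Wilk and Breusch-Pagan per site. Diagnostics never abort the
#' pipeline: a site where a test cannot run (e.g. zero-variance residuals)
#' gets `NA` values and a warning string instead.
#'
#' @param fits list of `leslie_fit` objects.
#' @return Data frame `site`, `shapiro_W`, `shapiro_p`, `bp_stat`, `bp_p`,
#'   `warning`.
#' @export
leslie_diagnostics <- function(fits) {
  stopifnot(all(vapply(fits, inherits, TRUE, "leslie_fit")))
  out <- do.call(rbind, lapply(fits, function(f) {
    row <- data.frame(site = f$site_id, shapiro_W = NA_real_,
                      shapiro_p = NA_real_, bp_stat = NA_real_,
                      bp_p = NA_real_, warning = NA_character_,
                      stringsAsFactors = FALSE)
    sw <- tryCatch(residual_normality(f$residuals), error = function(e) e)
    if (inherits(sw, "error")) {
      row$warning <- conditionMessage(sw)
    } else {
      row$shapiro_W <- sw$shapiro_W; row$shapiro_p <- sw$shapiro_p
    }
    bp <- tryCatch(residual_homoscedasticity(f), error = function(e) e)
    if (inherits(bp, "error")) {
      row$warning <- paste(stats::na.omit(c(row$warning, conditionMessage(bp))),
                           collapse = "; ")
    } else {
      row$bp_stat <- bp$bp_stat; row$bp_p <- bp$bp_p
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Does initial density affect catchability?
#'
#' Linear regression of the catchability coefficient `q` on the estimated
#' initial population `N0` across sites. A flat, non-significant slope
#' supports treating catchability as density-independent over the observed
#' density range.
#'
#' @param fits list of at least 3 `leslie_fit` objects, or a data frame with
#'   columns `N0` and `q` (one row per site).
#' @return Object of class `cross_site_regression`: list with `slope`,
#'   `intercept`, `r2`, `p_value`, `n_sites`, `residuals`, `lm`.
#' @export
catchability_density_regression <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("N0", "q") %in% names(fits)))
    d <- fits[c("N0", "q")]
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "leslie_fit")))
    d <- data.frame(N0 = vapply(fits, `[[`, numeric(1), "N0"),
                    q = vapply(fits, `[[`, numeric(1), "q"))
  }
  if (nrow(d) < 3L) stop("need at least 3 sites for the cross-site regression")
  if (stats::var(d$q) == 0) {
    # identical catchability everywhere: flat line, nothing explained
    return(structure(list(slope = 0, intercept = d$q[1], r2 = 0, p_value = 1,
                          n_sites = nrow(d), residuals = rep(0, nrow(d)),
                          lm = NULL),
                     class = "cross_site_regression"))
  }
  fit <- lm(q ~ N0, data = d)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)["N0"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients["N0", "Pr(>|t|)"],
                 n_sites = nrow(d), residuals = unname(resid(fit)), lm = fit),
            class = "cross_site_regression")
}

#' @export
print.cross_site_regression <- function(x, ...) {
  cat(sprintf(
    "Catchability vs initial density across %d sites:\n  slope = %.4f per (fish per 1,000 m2), r2 = %.2f, p = %.2f\n",
    x$n_sites, x$slope, x$r2, x$p_value))
  invisible(x)
}
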