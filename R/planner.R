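alpha_ci <- function(fit, level = 0.95) {
  if (!is.finite(fit$alpha_se)) return(c(NA_real_, NA_real_))
  tcrit <- if (is.infinite(fit$df)) stats::qnorm(1 - (1 - level) / 2) else
    qt(1 - (1 - level) / 2, fit$df)
  fit$alpha + c(-1, 1) * tcrit * fit$alpha_se
}

#' Predict percent removed for a given effort
#'
#' Evaluates the removal curve `C = 100 * (1 - exp(-alpha * q * t))` at
#' catchability `q` and cumulative effort `t` diver-hours per 1,000 m2. The
#' 95% band propagates the t-interval of `alpha` (df = n - K) through the
#' curve, which is monotone in `alpha`; random-effect and residual
#' uncertainty are deliberately excluded, so the band reflects uncertainty in
#' the mean curve only.
#'
#' @param fit an `effort_model_fit` (a fitted non-null model, or
#'   [effort_model_from_coefficients()]).
#' @param q catchability coefficient (> 0). For an unscaled-effort model pass
#'   `q = 1`.
#' @param t cumulative effort, diver-hours per 1,000 m2 (>= 0).
#' @param level confidence level for the band.
#' @return Object of class `removal_prediction`: list with `q`, `t`, `C`
#'   (percent removed), `ci` (percent), `target = NA`.
#' @export
#' @examples
#' fit <- effort_model_from_coefficients(alpha = 1.39, alpha_se = 0.08,
#'                                       n = 39, K = 3)
#' predict_removal(fit, q = 0.694, t = 1)
predict_removal <- function(fit, q, t, level = 0.95) {
  stopifnot(inherits(fit, "effort_model_fit"))
  if (fit$spec$null_model) stop("the null model has no removal curve")
  if (!is.numeric(q) || q <= 0) stop("q must be positive")
  if (!is.numeric(t) || t < 0) stop("t must be >= 0")
  Cfun <- function(a) 100 * (1 - exp(-a * q * t))
  ci_a <- alpha_ci(fit, level)
  structure(list(q = q, t = t, C = Cfun(fit$alpha),
                 ci = c(Cfun(ci_a[1]), Cfun(ci_a[2])), target = NA_real_,
                 level = level),
            class = "removal_prediction")
}

#' Effort required to reach a target percent reduction
#'
#' Inverts the removal curve: `t = -log(1 - target/100) / (alpha * q)`. The
#' interval comes from the `alpha` confidence limits (the required effort is
#' monotone decreasing in `alpha`, so the upper `alpha` limit gives the lower
#' effort limit).
#'
#' @param fit an `effort_model_fit`.
#' @param q catchability coefficient (> 0).
#' @param target desired percent reduction, in `[0, 100)`; 100 is rejected
#'   because the curve only approaches complete removal asymptotically.
#' @param level confidence level.
#' @return `removal_prediction` with `t` the required effort (diver-hours per
#'   1,000 m2), `ci` an effort interval, and `C = target`.
#' @export
#' @examples
#' fit <- effort_model_from_coefficients(alpha = 1.39, alpha_se = 0.08,
#'                                       n = 39, K = 3)
#' effort_for_target(fit, q = 0.694, target = 50)$t
effort_for_target <- function(fit, q, target, level = 0.95) {
  stopifnot(inherits(fit, "effort_model_fit"))
  if (fit$spec$null_model) stop("the null model has no removal curve")
  if (!is.numeric(q) || q <= 0) stop("q must be positive")
  if (!is.numeric(target) || target < 0 || target >= 100) {
    stop("target must be in [0, 100): the asymptote at 100% is never reached")
  }
  tfun <- function(a) -log(1 - target / 100) / (a * q)
  ci_a <- alpha_ci(fit, level)
  structure(list(q = q, t = tfun(fit$alpha), C = target,
                 ci = c(tfun(ci_a[2]), tfun(ci_a[1])), target = target,
                 level = level),
            class = "removal_prediction")
}

#' @export
print.removal_prediction <- function(x, ...) {
  if (is.na(x$target)) {
    cat(sprintf(
      "Predicted removal: %.1f%% (%.1f-%.1f%%) after %.2f diver-hours per 1,000 m2 at q = %.2f\n",
      x$C, x$ci[1], x$ci[2], x$t, x$q))
  } else {
    cat(sprintf(
      "Effort for %.0f%% removal at q = %.2f: %.2f (%.2f-%.2f) diver-hours per 1,000 m2\n",
      x$target, x$q, x$t, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Plan removal effort over catchability scenarios and targets
#'
#' @param fit an `effort_model_fit`.
#' @param q_scenarios named or unnamed numeric vector of catchability values.
#' @param targets percent reductions to plan for.
#' @param level confidence level.
#' @return Data frame `scenario`, `q`, `target_percent`,
#'   `effort_hours_per_1000m2`, `ci_low`, `ci_high`, `error` (NA on success;
#'   a failing scenario/target carries its reason instead of aborting the
#'   rest).
#' @export
plan_removals <- function(fit, q_scenarios, targets = c(50, 90), level = 0.95) {
  if (is.null(names(q_scenarios))) {
    names(q_scenarios) <- paste0("q=", format(q_scenarios, digits = 3))
  }
  grid <- expand.grid(scenario = names(q_scenarios), target_percent = targets,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    qv <- q_scenarios[[grid$scenario[i]]]
    res <- tryCatch(effort_for_target(fit, qv, grid$target_percent[i], level),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(scenario = grid$scenario[i], q = qv,
                 target_percent = grid$target_percent[i],
                 effort_hours_per_1000m2 = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(scenario = grid$scenario[i], q = qv,
                 target_percent = grid$target_percent[i],
                 effort_hours_per_1000m2 = res$t, ci_low = res$ci[1],
                 ci_high = res$ci[2], error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
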