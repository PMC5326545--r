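#' Build an ordered depletion series for one site
#'
#' Orders a site's standardized dives chronologically, accumulates the catch
#' removed before each dive (`K_prior`, with `K_prior = 0` for the first
#' dive), and applies the depletion stopping convention: when a site reached
#' the depletion criterion of two consecutive zero-catch dives, only the first
#' of the two zeros counts as a depletion dive, so the second (and anything
#' after it) is dropped before analysis.
#'
#' @param std data frame of standardized dives for a single site, as produced
#'   by [standardize_dives()] (columns `site`, `dive`, `h`, `c`, `cpue`).
#'   Input row order is irrelevant; dives are sorted by `dive`.
#' @param raw_catch optional vector of unstandardized fish counts aligned with
#'   `std` rows; defaults to back-converting from `c` if omitted via
#'   `area_m2`.
#' @param area_m2 site area, used to recover raw fish counts when `raw_catch`
#'   is not supplied. Optional; if neither is given `raw_total_catch` is `NA`.
#'
#' @return An object of class `depletion_series`: a list with
#'   \describe{
#'     \item{site_id}{site label}
#'     \item{dives}{data frame `dive`, `h`, `n` (catch per 1,000 m2),
#'       `cpue`, `K_prior` for the retained dives}
#'     \item{T}{number of retained dives}
#'     \item{raw_total_catch}{total fish (unstandardized) over retained dives}
#'     \item{depletion_achieved}{TRUE if two consecutive zero-catch dives
#'       occurred}
#'   }
#' @export
#' @examples
#' std <- data.frame(site = "A", dive = 1:3, h = 1, c = c(10, 5, 2.5),
#'                   cpue = c(10, 5, 2.5))
#' build_series(std)$dives$K_prior  # 0, 10, 15
build_series <- function(std, raw_catch = NULL, area_m2 = NULL) {
  if (!is.data.frame(std) || nrow(std) < 1L) {
    stop("need at least one standardized dive")
  }
  need <- c("site", "dive", "h", "c", "cpue")
  if (!all(need %in% names(std))) {
    stop("standardized dive table needs columns: ", paste(need, collapse = ", "))
  }
  site <- unique(std$site)
  if (length(site) != 1L) {
    stop("build_series expects a single site, got: ", paste(site, collapse = ", "))
  }
  if (!is.null(raw_catch) && length(raw_catch) != nrow(std)) {
    stop("raw_catch length must match the number of dives")
  }
  ord <- order(std$dive)
  std <- std[ord, , drop = FALSE]
  if (!is.null(raw_catch)) raw_catch <- raw_catch[ord]
  idx <- std$dive
  if (anyDuplicated(idx)) {
    stop("site '", site, "': duplicate dive index ", idx[duplicated(idx)][1])
  }
  if (!identical(as.integer(idx), seq_len(nrow(std)))) {
    stop("site '", site, "': dive indices must be consecutive from 1")
  }

  # Depletion criterion: two consecutive zero-catch dives; keep only the first
  # zero of the pair.
  n <- std$c
  achieved <- FALSE
  keep <- length(n)
  if (length(n) >= 2L) {
    zz <- which(n[-length(n)] == 0 & n[-1] == 0)
    if (length(zz)) {
      achieved <- TRUE
      keep <- zz[1]
    }
  }
  std <- std[seq_len(keep), , drop = FALSE]
  if (!is.null(raw_catch)) raw_catch <- raw_catch[seq_len(keep)]

  if (is.null(raw_catch)) {
    raw_catch <- if (!is.null(area_m2)) std$c * area_m2 / 1000 else rep(NA_real_, keep)
  }
  dives <- data.frame(dive = as.integer(std$dive), h = std$h, n = std$c,
                      cpue = std$cpue,
                      K_prior = c(0, cumsum(std$c)[-keep]))
  rownames(dives) <- NULL
  structure(list(site_id = site, dives = dives, T = keep,
                 raw_total_catch = sum(raw_catch),
                 depletion_achieved = achieved),
            class = "depletion_series")
}

#' Split standardized dives into per-site depletion series
#'
#' @param std output of [standardize_dives()] covering one or more sites.
#' @param sites optional site table (for raw catch back-conversion).
#' @return Named list of [build_series()] objects, one per site.
#' @export
split_series <- function(std, sites = NULL) {
  out <- lapply(split(std, std$site), function(d) {
    area <- if (!is.null(sites)) sites$area_m2[match(d$site[1], sites$site)] else NULL
    build_series(d, area_m2 = area)
  })
  out[order(names(out))]
}

#' Minimum initial population: total standardized catch
#'
#' Sums the per-1,000 m2 catches over the retained dives. Because every fish
#' counted was physically removed, this is a lower bound on the initial
#' population per 1,000 m2; the regression estimate from [fit_leslie()] is the
#' canonical estimate.
#'
#' @param series a `depletion_series`.
#' @return Total catch per 1,000 m2 (scalar).
#' @export
total_catch_estimate <- function(series) {
  stopifnot(inherits(series, "depletion_series"))
  sum(series$dives$n)
}

#' @export
print.depletion_series <- function(x, ...) {
  cat("Depletion series for site", x$site_id, "-", x$T, "dives,",
      format(sum(x$dives$n), digits = 4), "fish per 1,000 m2 removed",
      if (isTRUE(x$depletion_achieved)) "(depletion criterion achieved)" else
        "(criterion not achieved)", "\n")
  print(x$dives, ...)
  invisible(x)
}
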