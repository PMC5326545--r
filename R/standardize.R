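#' Standardize one dive's effort and catch per 1,000 m2
#'
#' Converts a raw removal-dive record (diver-minutes of hunting time and fish
#' caught) into area-standardized units: diver-hours per 1,000 m2 of reef
#' (`h`), catch per 1,000 m2 (`c`), and their ratio, catch per unit effort
#' (`cpue`, fish per diver-hour). Three divers hunting for 20 minutes count as
#' one diver-hour.
#'
#' @param site_id site label.
#' @param dive_index 1-based chronological dive number within the site.
#' @param catch_count number of fish caught on the dive (non-negative).
#' @param diver_minutes total hunting minutes summed over divers. Either this
#'   or both `n_divers` and `minutes_each` must be given.
#' @param n_divers,minutes_each alternative effort specification: number of
#'   divers and minutes hunted by each.
#' @param area site area in m2 (positive).
#'
#' @return A one-row data frame with columns `site`, `dive`, `h`, `c`, `cpue`.
#'   CPUE is 0 when the catch is 0; zero effort is rejected rather than
#'   producing an undefined CPUE.
#' @seealso [standardize_dives()] for whole tables, [build_series()].
#' @export
#' @examples
#' standardize_dive("D1", 1, catch_count = 4, n_divers = 3, minutes_each = 20,
#'                  area = 1000)
standardize_dive <- function(site_id, dive_index, catch_count,
                             diver_minutes = NULL, n_divers = NULL,
                             minutes_each = NULL, area) {
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area <= 0) {
    stop("site '", site_id, "': area must be a positive number (m2)")
  }
  if (is.null(diver_minutes)) {
    if (is.null(n_divers) || is.null(minutes_each)) {
      stop("site '", site_id, "' dive ", dive_index,
           ": give diver_minutes or both n_divers and minutes_each")
    }
    diver_minutes <- n_divers * minutes_each
  }
  if (is.na(diver_minutes) || diver_minutes <= 0) {
    stop("site '", site_id, "' dive ", dive_index,
         ": zero or missing effort; CPUE is undefined without effort")
  }
  if (is.na(catch_count) || catch_count < 0) {
    stop("site '", site_id, "' dive ", dive_index, ": negative or missing catch")
  }
  h <- (diver_minutes / 60) * 1000 / area
  c_std <- catch_count * 1000 / area
  data.frame(site = as.character(site_id), dive = as.integer(dive_index),
             h = h, c = c_std, cpue = c_std / h, stringsAsFactors = FALSE)
}

#' Standardize a table of dive records
#'
#' Vectorized version of [standardize_dive()]: joins a dive table against a
#' site table and standardizes every row to per-1,000 m2 units.
#'
#' @param dives data frame with columns `site`, `dive`, `catch`, and either
#'   `diver_minutes` or both `divers` and `minutes`.
#' @param sites data frame with columns `site` and `area_m2` (and optionally
#'   `depth_min`, `depth_max`); see [read_site_table()].
#'
#' @return Data frame with one row per dive: `site`, `dive`, `h`, `c`, `cpue`.
#' @export
standardize_dives <- function(dives, sites) {
  dives <- validate_dive_table(dives)
  sites <- validate_site_table(sites)
  unknown <- setdiff(unique(dives$site), sites$site)
  if (length(unknown)) {
    stop("dive records reference unknown site(s): ",
         paste(unknown, collapse = ", "))
  }
  area <- sites$area_m2[match(dives$site, sites$site)]
  out <- do.call(rbind, lapply(seq_len(nrow(dives)), function(i) {
    standardize_dive(dives$site[i], dives$dive[i], dives$catch[i],
                     diver_minutes = dives$diver_minutes[i], area = area[i])
  }))
  rownames(out) <- NULL
  out
}

# Normalize a raw dive table to columns site, dive, diver_minutes, catch.
# Accepts the (divers, minutes) effort spelling. Errors name the row.
validate_dive_table <- function(dives) {
  if (!is.data.frame(dives)) stop("dives must be a data frame")
  need_base <- c("site", "dive", "catch")
  missing_cols <- setdiff(need_base, names(dives))
  if (length(missing_cols)) {
    stop("dive table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"diver_minutes" %in% names(dives)) {
    if (!all(c("divers", "minutes") %in% names(dives))) {
      stop("dive table needs either a diver_minutes column or divers + minutes")
    }
    dives$diver_minutes <- as.numeric(dives$divers) * as.numeric(dives$minutes)
  }
  dives$site <- as.character(dives$site)
  for (col in c("dive", "diver_minutes", "catch")) {
    v <- suppressWarnings(as.numeric(dives[[col]]))
    bad <- which(is.na(v) & !is.na(dives[[col]]))
    if (length(bad)) {
      stop("dive table column '", col, "' is non-numeric at row ", bad[1])
    }
    dives[[col]] <- v
  }
  bad <- which(is.na(dives$catch) | dives$catch < 0)
  if (length(bad)) stop("negative or missing catch at dive table row ", bad[1])
  bad <- which(is.na(dives$dive) | dives$dive < 1 | dives$dive != round(dives$dive))
  if (length(bad)) stop("dive index must be a positive integer at row ", bad[1])
  dives[c("site", "dive", "diver_minutes", "catch")]
}

validate_site_table <- function(sites) {
  if (!is.data.frame(sites)) stop("sites must be a data frame")
  if (!all(c("site", "area_m2") %in% names(sites))) {
    stop("site table needs columns site, area_m2")
  }
  sites$site <- as.character(sites$site)
  sites$area_m2 <- suppressWarnings(as.numeric(sites$area_m2))
  bad <- which(is.na(sites$area_m2) | sites$area_m2 <= 0)
  if (length(bad)) {
    stop("site '", sites$site[bad[1]], "': area_m2 must be a positive number")
  }
  if (anyDuplicated(sites$site)) {
    stop("duplicated site id in site table: ",
         sites$site[duplicated(sites$site)][1])
  }
  if (all(c("depth_min", "depth_max") %in% names(sites))) {
    both <- complete.cases(sites[c("depth_min", "depth_max")])
    if (any(both & sites$depth_min > sites$depth_max)) {
      stop("depth_min exceeds depth_max for site ",
           sites$site[which(both & sites$depth_min > sites$depth_max)][1])
    }
  }
  sites
}
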