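#' Read a daily climate series
#'
#' @param path CSV with header `site,date,tmean_c,prec_mm`, dates ISO-8601.
#' @return Data frame with `site`, `date` (class `Date`), `tmean_c`,
#'   `prec_mm`, validated for strictly increasing gap-free dates within each
#'   site and non-negative precipitation.
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "date", "tmean_c", "prec_mm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("climate file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in ", path, call. = FALSE)
  if (any(df$prec_mm < 0))
    stop("negative precipitation in ", path, call. = FALSE)
  for (s in unique(df$site)) {
    d <- df$date[df$site == s]
    if (any(diff(as.integer(d)) != 1L))
      stop("dates not strictly increasing and gap-free for site ", s,
           call. = FALSE)
  }
  df
}

#' Detect the thermal growing season in one year of daily means
#'
#' The season starts on the day after the first run of at least `window`
#' consecutive days with daily mean temperature at or above `base`, and ends
#' on the day after the first subsequent run of at least `window`
#' consecutive days below `base`. If no start run exists the year has no
#' growing season; if a start exists but no end run, the season extends to
#' the end of the year.
#'
#' @param tmean numeric vector of daily mean temperatures for one calendar
#'   year (365 or 366 values).
#' @param base threshold temperature in deg C (default 5).
#' @param window run length in days (default 10).
#' @return `list(start =, end =)` day-of-year indices, or `NULL` when no
#'   season exists.
#' @export
growing_season <- function(tmean, base = 5, window = 10) {
  n <- length(tmean)
  if (n < window)
    stop("series shorter than the detection window", call. = FALSE)
  run_end <- function(cond, from) {
    # index of the last day of the first run of `window` TRUEs at/after `from`
    run <- 0L
    for (i in from:n) {
      run <- if (cond[i]) run + 1L else 0L
      if (run >= window) return(i)
    }
    NA_integer_
  }
  warm <- tmean >= base
  w_end <- run_end(warm, 1L)
  if (is.na(w_end)) return(NULL)
  start <- w_end + 1L
  if (start > n) start <- n  # degenerate: run ends on the last day
  c_end <- run_end(!warm, start)
  end <- if (is.na(c_end)) n else min(c_end + 1L, n)
  list(start = start, end = end)
}

#' Thermal sum over a growing season
#'
#' Accumulated degree-days above the base temperature over the detected
#' growing season (`mode = "excess"`, the effective temperature sum
#' `sum(max(tmean - base, 0))`), or the literal sum of the daily mean
#' temperatures of above-base season days (`mode = "raw"`).
#'
#' @param tmean daily mean temperatures for one calendar year.
#' @param season a [growing_season()] result (or `NULL`).
#' @param base threshold in deg C (default 5).
#' @param mode `"excess"` (default) or `"raw"`.
#' @return Thermal sum in deg C days; 0 when `season` is `NULL`.
#' @export
thermal_sum <- function(tmean, season, base = 5, mode = c("excess", "raw")) {
  mode <- match.arg(mode)
  if (is.null(season)) return(0)
  x <- tmean[season$start:season$end]
  if (mode == "excess") sum(pmax(x - base, 0)) else sum(x[x > base])
}

#' Annual precipitation total
#' @param prec daily precipitation (mm) for one year.
#' @return Sum in mm.
#' @export
annual_precip <- function(prec) {
  if (any(prec < 0)) stop("negative precipitation", call. = FALSE)
  sum(prec)
}

#' Annual thermal sums and precipitation for one site
#'
#' @param clim climate data frame (see [read_climate()]) for a single site.
#' @param base,window,mode growing-season / thermal-sum settings.
#' @return Data frame `year`, `gdd`, `prec`, one row per complete calendar
#'   year in the series.
#' @export
annual_climate <- function(clim, base = 5, window = 10, mode = "excess") {
  yr <- as.integer(format(clim$date, "%Y"))
  out <- lapply(unique(yr), function(y) {
    sel <- yr == y
    ndays <- sum(sel)
    if (ndays < 365) return(NULL)  # incomplete year
    t <- clim$tmean_c[sel]
    season <- growing_season(t, base = base, window = window)
    data.frame(year = y,
               gdd = thermal_sum(t, season, base = base, mode = mode),
               prec = annual_precip(clim$prec_mm[sel]))
  })
  do.call(rbind, out)
}

#' Between-survey climate trend delta
#'
#' Ordinary least-squares regression of an annual quantity on year over the
#' survey interval; the between-survey change is the slope multiplied by the
#' number of years between the original survey and the resurvey, making
#' change values comparable across sites with different sampling intervals.
#'
#' @param years integer years of the annual values.
#' @param values annual quantity (thermal sum or precipitation).
#' @param year0,year1 original survey year and resurvey year.
#' @return `list(slope =, delta =, years =)` with
#'   `delta = slope * (year1 - year0)`.
#' @export
trend_delta <- function(years, values, year0, year1) {
  sel <- years >= year0 & years <= year1
  if (sum(sel) < 3)
    stop("need at least 3 annual values inside the survey interval",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, years[sel]), values[sel])
  slope <- unname(fit$coefficients[2])
  span <- year1 - year0
  list(slope = slope, delta = slope * span, years = span)
}

#' Climate change deltas for every site
#'
#' @param clim multi-site climate data frame (see [read_climate()]).
#' @param site_years data frame `site`, `year0`, `year1` giving each site's
#'   original survey and resurvey years.
#' @param base,window,mode passed to [annual_climate()].
#' @return Data frame `site`, `slope_gdd`, `delta_gdd`, `slope_prec`,
#'   `delta_prec`, `years`.
#' @export
climate_deltas <- function(clim, site_years, base = 5, window = 10,
                           mode = "excess") {
  out <- lapply(seq_len(nrow(site_years)), function(i) {
    s <- site_years$site[i]
    ann <- annual_climate(clim[clim$site == s, , drop = FALSE],
                          base = base, window = window, mode = mode)
    if (is.null(ann) || nrow(ann) < 3)
      stop("insufficient annual climate data for site ", s, call. = FALSE)
    g <- trend_delta(ann$year, ann$gdd, site_years$year0[i], site_years$year1[i])
    p <- trend_delta(ann$year, ann$prec, site_years$year0[i], site_years$year1[i])
    data.frame(site = s, slope_gdd = g$slope, delta_gdd = g$delta,
               slope_prec = p$slope, delta_prec = p$delta,
               years = g$years, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
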