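# Climate-station processing: 10-minute logs -> hourly -> gap-filled daily
# series -> period summaries.

# Lowe (1977) sixth-order polynomial for saturation vapour pressure over
# water. Input T in degrees C, output in hPa. Constant term is es(0 C).
.lowe_coef <- c(
  6.107799961,
  4.436518521e-01,
  1.428945805e-02,
  2.650648471e-04,
  3.031240396e-06,
  2.034080948e-08,
  6.136820929e-11
)

#' Saturation vapour pressure over water
#'
#' Evaluates the Lowe (1977) sixth-order polynomial approximation to the
#' saturation vapour pressure over a plane water surface.
#'
#' @param at Air temperature in degrees C. Vectorised.
#' @return Saturation vapour pressure in hPa.
#' @export
es_lowe <- function(at) {
  stopifnot(is.numeric(at))
  # Horner evaluation
  es <- rep(.lowe_coef[7], length(at))
  for (i in 6:1) es <- es * at + .lowe_coef[i]
  es
}

#' Vapour pressure deficit from air temperature and relative humidity
#'
#' VPD is the saturation vapour pressure at the air temperature minus the
#' actual vapour pressure: `es(at) * (1 - rh/100)`. Computed on hourly
#' values, never on daily means, because `es` is nonlinear in temperature.
#'
#' @param at Air temperature, degrees C (sensor range -20 to 40).
#' @param rh Relative humidity, percent in \[0, 100\].
#' @return VPD in hPa; 0 at saturation (`rh = 100`). `NA` inputs give `NA`.
#' @export
#' @examples
#' compute_vpd(10, 50) # half the saturation pressure at 10 C
compute_vpd <- function(at, rh) {
  bad <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad)) {
    stop("relative humidity outside [0, 100]: ", rh[which(bad)[1]])
  }
  out_range <- !is.na(at) & (at < -20 | at > 40)
  if (any(out_range)) {
    stop("air temperature outside sensor range [-20, 40]: ",
         at[which(out_range)[1]])
  }
  es_lowe(at) * (1 - rh / 100)
}

#' Aggregate 10-minute station records to hourly values
#'
#' AT, RH and SM are averaged over the 10-minute points available within
#' each clock hour; RF is summed. Hours with no points are absent from the
#' output. Hourly VPD is computed from the hourly AT and RH means.
#'
#' @param records Tibble with columns `station_id`, `timestamp` (POSIXct),
#'   `at`, `rf`, `rh`, `sm`. One station per call; timestamps must be
#'   strictly increasing.
#' @return Tibble with columns `station_id`, `hour` (POSIXct, floored),
#'   `at`, `rh`, `sm`, `rf`, `vpd`, `n_points`.
#' @export
aggregate_to_hourly <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("station_id", "timestamp", "at", "rf", "rh", "sm")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(records$station_id)) > 1) {
    stop("aggregate_to_hourly expects a single station")
  }
  ts <- records$timestamp
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1
    stop("timestamps not strictly increasing at ",
         format(ts[i], "%Y-%m-%d %H:%M"))
  }
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  out <- records |>
    dplyr::mutate(hour = lubridate_floor_hour(.data$timestamp)) |>
    dplyr::group_by(.data$station_id, .data$hour) |>
    dplyr::summarise(
      n_points = sum(!is.na(.data$at) | !is.na(.data$rf) |
                       !is.na(.data$rh) | !is.na(.data$sm)),
      at = mean_na(.data$at),
      rh = mean_na(.data$rh),
      sm = mean_na(.data$sm),
      rf = sum_na(.data$rf),
      .groups = "drop"
    )
  out$vpd <- ifelse(is.na(out$at) | is.na(out$rh), NA_real_,
                    compute_vpd(out$at, out$rh))
  out
}

# floor a POSIXct to the hour without pulling in lubridate
lubridate_floor_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
             origin = "1970-01-01", tz = attr(x, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.daily_vars <- c("at", "rh", "sm", "vpd", "rf")

#' Aggregate hourly records to a daily climate series
#'
#' A day enters the series as observed only if at least `min_hours` hourly
#' records are present (default 23); otherwise the day is emitted with all
#' values missing. AT, RH, SM and VPD are daily means; RF is the daily
#' total. Days are local calendar days.
#'
#' @param hourly Output of [aggregate_to_hourly()] for one station.
#' @param min_hours Minimum hourly records for an observed day.
#' @return A daily series tibble: `station_id`, `date`, the five variables,
#'   `hours_present`, and per-variable `<var>_source` / `<var>_donor`
#'   provenance columns (`"observed"` or `NA`; donors filled by
#'   [gap_fill()]).
#' @export
aggregate_to_daily <- function(hourly, min_hours = 23) {
  stopifnot(is.data.frame(hourly))
  if (length(unique(hourly$station_id)) > 1) {
    stop("aggregate_to_daily expects a single station")
  }
  day <- as.Date(hourly$hour, tz = attr(hourly$hour, "tzone") %||% "UTC")
  agg <- hourly |>
    dplyr::mutate(date = day) |>
    dplyr::group_by(.data$station_id, .data$date) |>
    dplyr::summarise(
      at = mean(.data$at, na.rm = TRUE),
      rh = mean(.data$rh, na.rm = TRUE),
      sm = mean(.data$sm, na.rm = TRUE),
      vpd = mean(.data$vpd, na.rm = TRUE),
      rf = sum(.data$rf, na.rm = TRUE),
      hours_present = dplyr::n(),
      .groups = "drop"
    )
  # fill the full calendar span so missing days exist as rows
  span <- seq(min(agg$date), max(agg$date), by = "day")
  out <- tibble::tibble(
    station_id = agg$station_id[1],
    date = span
  ) |>
    dplyr::left_join(agg, by = c("station_id", "date"))
  out$hours_present[is.na(out$hours_present)] <- 0L
  ok <- out$hours_present >= min_hours
  for (v in .daily_vars) {
    out[[v]][!ok] <- NA_real_
    out[[v]][is.nan(out[[v]])] <- NA_real_
    out[[paste0(v, "_source")]] <-
      ifelse(ok & !is.na(out[[v]]), "observed", NA_character_)
    out[[paste0(v, "_donor")]] <- NA_character_
  }
  out
}

#' Build a daily series directly from daily values
#'
#' Convenience constructor for a daily series in the shape produced by
#' [aggregate_to_daily()], for workflows that start from daily data.
#'
#' @param station_id Station identifier.
#' @param date Vector of dates.
#' @param ... Named daily values among `at`, `rh`, `sm`, `vpd`, `rf`;
#'   unsupplied variables are missing.
#' @return A daily series tibble.
#' @export
daily_series <- function(station_id, date, ...) {
  vals <- list(...)
  bad <- setdiff(names(vals), .daily_vars)
  if (length(bad)) stop("unknown variables: ", paste(bad, collapse = ", "))
  out <- tibble::tibble(station_id = station_id, date = as.Date(date))
  for (v in .daily_vars) {
    out[[v]] <- if (v %in% names(vals)) as.numeric(vals[[v]]) else NA_real_
  }
  out$hours_present <- ifelse(rowSums(!is.na(out[.daily_vars])) > 0, 24L, 0L)
  for (v in .daily_vars) {
    out[[paste0(v, "_source")]] <-
      ifelse(is.na(out[[v]]), NA_character_, "observed")
    out[[paste0(v, "_donor")]] <- NA_character_
  }
  out
}

#' Rank donor stations for gap-filling one variable
#'
#' For each target station, candidate donors are ordered by decreasing
#' Pearson correlation of the variable on jointly observed days. Pairs with
#' fewer than `min_overlap` joint days are excluded. Ties are broken by
#' larger overlap count, then lexically by station id.
#'
#' @param series_list Named list of daily series (one per station).
#' @param variable One of `"at"`, `"rh"`, `"sm"`, `"vpd"`, `"rf"`.
#' @param min_overlap Minimum jointly observed days (default 3).
#' @return Named list: per target station a tibble with columns `donor`,
#'   `r`, `n_overlap`, sorted by rank. A station with no eligible donor
#'   gets a zero-row tibble (unfillable for this variable).
#' @export
rank_donors <- function(series_list, variable, min_overlap = 3) {
  stopifnot(variable %in% .daily_vars)
  if (length(series_list) < 2) stop("need at least 2 stations")
  ids <- names(series_list)
  if (is.null(ids) || any(ids == "")) stop("series_list must be named")
  src <- paste0(variable, "_source")
  obs <- lapply(series_list, function(s) {
    keep <- !is.na(s[[variable]]) & !is.na(s[[src]]) & s[[src]] == "observed"
    stats::setNames(s[[variable]][keep], as.character(s$date[keep]))
  })
  out <- list()
  for (tgt in ids) {
    rows <- lapply(setdiff(ids, tgt), function(dn) {
      joint <- intersect(names(obs[[tgt]]), names(obs[[dn]]))
      if (length(joint) < min_overlap) return(NULL)
      x <- obs[[tgt]][joint]; y <- obs[[dn]][joint]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
      tibble::tibble(donor = dn, r = stats::cor(x, y),
                     n_overlap = length(joint))
    })
    tab <- dplyr::bind_rows(rows)
    if (nrow(tab)) {
      tab <- tab[order(-tab$r, -tab$n_overlap, tab$donor), ]
    } else {
      tab <- tibble::tibble(donor = character(), r = numeric(),
                            n_overlap = integer())
    }
    out[[tgt]] <- tab
  }
  out
}

#' Gap-fill missing days of one variable from ranked donor stations
#'
#' Each missing day is filled by the ordinary-least-squares prediction from
#' the best-ranked donor that has an observed value on that day and at
#' least `min_overlap` jointly observed days with the target (for the
#' regression fit); lower-ranked donors are tried in turn when the best is
#' also missing. For rainfall, a no-rain condition overrides the
#' regression: when the donor's daily total is exactly zero the filled
#' value is zero, and negative regression predictions are floored at zero.
#' Filled days get `<var>_source = "gap_filled"` and the donor id recorded.
#'
#' @param target Daily series for the target station.
#' @param donors Named list of daily series for donor stations, ordered by
#'   rank (e.g. built from [rank_donors()] output).
#' @param variable Variable to fill.
#' @param min_overlap Minimum joint observed days for the regression.
#' @return The target series with fillable missing days imputed. Days no
#'   donor can fill remain missing.
#' @export
gap_fill <- function(target, donors, variable, min_overlap = 3) {
  stopifnot(variable %in% .daily_vars)
  src <- paste0(variable, "_source")
  dnr <- paste0(variable, "_donor")
  miss <- is.na(target[[variable]])
  if (!any(miss)) return(target)
  if (length(donors) == 0) return(target)
  if (is.null(names(donors)) || any(names(donors) == "")) {
    stop("donors must be a named list, ordered by rank")
  }
  t_obs_keep <- !is.na(target[[variable]]) & target[[src]] == "observed"
  for (dn in names(donors)) {
    miss <- is.na(target[[variable]])
    if (!any(miss)) break
    d <- donors[[dn]]
    d_src <- d[[paste0(variable, "_source")]]
    d_obs <- !is.na(d[[variable]]) & !is.na(d_src) & d_src == "observed"
    joint <- as.Date(intersect(target$date[t_obs_keep], d$date[d_obs]),
                     origin = "1970-01-01")
    if (length(joint) < min_overlap) next
    x <- d[[variable]][match(joint, d$date)]
    y <- target[[variable]][match(joint, target$date)]
    if (stats::sd(x) == 0) next
    fit <- stats::lm(y ~ x)
    b <- stats::coef(fit)
    fill_days <- target$date[miss][target$date[miss] %in% d$date[d_obs]]
    if (!length(fill_days)) next
    xd <- d[[variable]][match(fill_days, d$date)]
    pred <- b[1] + b[2] * xd
    if (variable == "rf") {
      pred[xd == 0] <- 0   # no-rain condition
      pred <- pmax(pred, 0)
    }
    idx <- match(fill_days, target$date)
    target[[variable]][idx] <- pred
    target[[src]][idx] <- "gap_filled"
    target[[dnr]][idx] <- dn
  }
  target
}

#' Gap-fill all variables across a station network
#'
#' Ranks donors per station and variable with [rank_donors()] and fills
#' with [gap_fill()], cascading through the donor ranking.
#'
#' @inheritParams rank_donors
#' @param variables Variables to fill (default all five).
#' @return List with elements `series` (the filled named list) and
#'   `report`, a tibble of fill provenance (station, variable, days filled
#'   per donor).
#' @export
gap_fill_network <- function(series_list,
                             variables = .daily_vars,
                             min_overlap = 3) {
  filled <- series_list
  for (v in variables) {
    ranks <- rank_donors(series_list, v, min_overlap)
    for (tgt in names(filled)) {
      ord <- ranks[[tgt]]$donor
      if (!length(ord)) next
      filled[[tgt]] <- gap_fill(filled[[tgt]], series_list[ord], v,
                                min_overlap)
    }
  }
  report <- dplyr::bind_rows(lapply(names(filled), function(id) {
    s <- filled[[id]]
    dplyr::bind_rows(lapply(variables, function(v) {
      d <- s[[paste0(v, "_donor")]]
      f <- !is.na(d)
      if (!any(f)) return(NULL)
      tibble::tibble(station_id = id, variable = v,
                     donor = names(table(d[f])),
                     days_filled = as.integer(table(d[f])))
    }))
  }))
  list(series = filled, report = report)
}

#' Summarise a daily series over a period
#'
#' Means of the daily values over non-missing days in the window; rainfall
#' is reported as the mean of daily totals (mm/day). Coverage is the
#' fraction of window days with a non-missing value (after any filling),
#' per variable the minimum across variables that have any data.
#'
#' @param series Daily series tibble.
#' @param start,end Window bounds (inclusive), coercible to `Date`.
#' @return One-row tibble: `station_id`, `start`, `end`, `at_mean`,
#'   `rf_mean_daily`, `rh_mean`, `sm_mean`, `vpd_mean`, `coverage`.
#' @export
summarize_period <- function(series, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("window end precedes start")
  w <- series[series$date >= start & series$date <= end, ]
  if (nrow(w) == 0 || all(is.na(w[.daily_vars]))) {
    stop("no non-missing days in window for station ",
         series$station_id[1])
  }
  ndays <- as.integer(end - start) + 1L
  m <- vapply(.daily_vars, function(v) {
    x <- w[[v]]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  cov <- vapply(.daily_vars, function(v) sum(!is.na(w[[v]])) / ndays,
                numeric(1))
  cov <- cov[!is.na(m)]
  tibble::tibble(
    station_id = series$station_id[1],
    start = start, end = end,
    at_mean = m[["at"]], rf_mean_daily = m[["rf"]],
    rh_mean = m[["rh"]], sm_mean = m[["sm"]], vpd_mean = m[["vpd"]],
    coverage = if (length(cov)) min(cov) else 0
  )
}

#' Read long-format raw station records
#'
#' Long delimited text with columns `station_id`, `timestamp` (ISO-8601),
#' `variable`, `value` is pivoted to the wide per-record shape used by
#' [aggregate_to_hourly()].
#'
#' @param path Delimited text file.
#' @return Named list of per-station record tibbles.
#' @export
read_station_long <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("station_id", "timestamp", "variable", "value")
  if (!all(req %in% names(raw))) {
    stop("expected columns: ", paste(req, collapse = ", "))
  }
  wide <- tidyr::pivot_wider(raw, names_from = "variable",
                             values_from = "value")
  for (v in c("at", "rf", "rh", "sm")) {
    if (!v %in% names(wide)) wide[[v]] <- NA_real_
  }
  wide$timestamp <- as.POSIXct(wide$timestamp, tz = "UTC")
  wide <- wide[order(wide$station_id, wide$timestamp), ]
  split(wide, wide$station_id) |>
    lapply(tibble::as_tibble)
}

#' Write a daily series (with provenance columns) to delimited text
#'
#' @param series Daily series tibble.
#' @param path Output file.
#' @export
write_daily_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}
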