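# Spatial projection of the chosen survival model: raster bias correction,
# bounded suitability indices, per-cell historical trends, and forward
# extrapolation.

#' Fit a station-vs-raster bias correction
#'
#' OLS regression of station-observed values on co-located raster values,
#' paired by station and year. The correction is applied as
#' `corrected = slope * raster + intercept`, so corrected rasters predict
#' station-equivalent values.
#'
#' @param station_values Observed per-station-year values.
#' @param raster_values Co-located raster values, same pairing and order.
#' @param variable `"AT"` or `"RF"` (carried as metadata).
#' @return A `bias_correction` list: `variable`, `slope`, `intercept`,
#'   `n_station_years`, `r`.
#' @export
fit_bias_correction <- function(station_values, raster_values,
                                variable = c("AT", "RF")) {
  variable <- match.arg(variable)
  ok <- !is.na(station_values) & !is.na(raster_values)
  if (sum(ok) < 3) stop("need at least 3 station-year pairs")
  x <- raster_values[ok]; y <- station_values[ok]
  if (stats::sd(x) == 0) stop("degenerate variance in raster values")
  fit <- stats::lm(y ~ x)
  structure(list(
    variable = variable,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_station_years = sum(ok),
    r = stats::cor(x, y)
  ), class = "bias_correction")
}

#' Identity bias correction (no adjustment)
#' @param variable `"AT"` or `"RF"`.
#' @return A `bias_correction` with slope 1, intercept 0.
#' @export
identity_correction <- function(variable = c("AT", "RF")) {
  variable <- match.arg(variable)
  structure(list(variable = variable, slope = 1, intercept = 0,
                 n_station_years = NA_integer_, r = NA_real_),
            class = "bias_correction")
}

#' Apply a bias correction to a grid
#' @param grid A `climate_grid`.
#' @param correction A `bias_correction` (or `NULL` for identity).
#' @return The corrected grid.
#' @export
apply_bias_correction <- function(grid, correction) {
  if (is.null(correction)) return(grid)
  grid$values <- correction$slope * grid$values + correction$intercept
  grid
}

#' Project percent-survival model coefficients over a climate stack
#'
#' Per cell, percent survival is predicted from bias-corrected AT and RF
#' via the linear model, divided by 100, and clamped to \[0, 1\] to form
#' the relative climatic suitability index. Clamp flags are recorded and
#' nodata propagates.
#'
#' @param stack A `climate_stack` (AT in degC, RF in mm/day).
#' @param coefficients Named vector with `"(Intercept)"` (or first
#'   element), `"AT"`, `"RF"` — e.g. from [fit_ols()] or
#'   [read_model_config()].
#' @param corrections Optional list with elements `AT` and/or `RF`, each a
#'   `bias_correction`.
#' @param clamp Clamp predictions into \[0, 1\] (default TRUE; FALSE is
#'   used internally for linearity checks).
#' @return A `suitability_map`: list with `index` (a `climate_grid` in
#'   \[0, 1\]), `clamped_low`/`clamped_high` flag matrices, `period`.
#' @export
predict_suitability <- function(stack, coefficients, corrections = NULL,
                                clamp = TRUE) {
  stopifnot(inherits(stack, "climate_stack"))
  cf <- coefficients
  ic <- if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else cf[[1]]
  if (!all(c("AT", "RF") %in% names(cf))) {
    stop("coefficients must carry AT and RF slopes")
  }
  at <- apply_bias_correction(stack$at, corrections$AT)
  rf <- apply_bias_correction(stack$rf, corrections$RF)
  pred <- (ic + cf[["AT"]] * at$values + cf[["RF"]] * rf$values) / 100
  lo <- !is.na(pred) & pred < 0
  hi <- !is.na(pred) & pred > 1
  idx <- pred
  if (clamp) {
    idx[lo] <- 0
    idx[hi] <- 1
  }
  structure(list(
    index = climate_grid(idx, stack$at$xll, stack$at$yll,
                         stack$at$cellsize, stack$at$crs),
    clamped_low = lo, clamped_high = hi,
    period = stack$period
  ), class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$index$values
  cat("<suitability_map> ", nrow(v), " x ", ncol(v), " cells, index ",
      sprintf("[%.3f, %.3f]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)),
      ", ", sum(x$clamped_low), " clamped low, ", sum(x$clamped_high),
      " clamped high\n", sep = "")
  invisible(x)
}

#' Restrict a suitability map to a region
#'
#' Cells whose centres fall outside the union of the polygons become
#' nodata.
#'
#' @param map A `suitability_map`.
#' @param region_polygons List of (x, y) ring matrices in the map's CRS.
#' @return The masked map. Warns if nothing remains.
#' @export
mask_region <- function(map, region_polygons) {
  ctr <- grid_centers(map$index)
  inside <- if (length(region_polygons) == 0) {
    rep(FALSE, nrow(ctr))
  } else {
    points_in_polygons(ctr$x, ctr$y, region_polygons)
  }
  keep <- matrix(inside, nrow = nrow(map$index$values), byrow = TRUE)
  map$index$values[!keep] <- NA
  map$clamped_low[!keep] <- FALSE
  map$clamped_high[!keep] <- FALSE
  if (all(is.na(map$index$values))) {
    warning("region mask removed every cell")
  }
  map
}

#' Suitability maps for a sequence of climate windows
#'
#' One bounded suitability map per climate stack, as in
#' [predict_suitability()]. Windows follow the study design: multi-year
#' averaging periods (57 months ending in October) at five-year steps.
#'
#' @param stacks Named or unnamed list of `climate_stack`s, one per
#'   window; a `NULL` entry is rejected naming the window.
#' @param coefficients,corrections As in [predict_suitability()].
#' @return List of `suitability_map`s.
#' @export
suitability_time_series <- function(stacks, coefficients,
                                    corrections = NULL) {
  nm <- names(stacks) %||% as.character(seq_along(stacks))
  lapply(seq_along(stacks), function(i) {
    if (is.null(stacks[[i]])) stop("missing raster stack for window ", nm[i])
    predict_suitability(stacks[[i]], coefficients, corrections)
  })
}

#' Per-cell linear trend in suitability over time
#'
#' Simple OLS of the suitability index on window end-year for every grid
#' cell, giving a slope in suitability units per year and a two-sided
#' p-value from the slope t-test. No serial-autocorrelation correction is
#' applied and no multiple-testing correction is made across cells;
#' significance classes are mapped at alpha = 0.1 and 0.2 to suit the
#' short (n = 6) series. Zero-variance (constant) cell series get slope 0
#' and p = 1 by convention. Cells with fewer than 3 non-missing periods
#' are nodata.
#'
#' @param series List of `suitability_map`s sharing geometry.
#' @param years Numeric end-years, one per map.
#' @return A `trend_map`: `slope`, `p_value` (`climate_grid`s),
#'   `sig_class` (`climate_grid` coded 0 = ns, 1 = alpha <= 0.2,
#'   2 = alpha <= 0.1), `n_periods`.
#' @export
fit_trend <- function(series, years) {
  stopifnot(length(series) == length(years), length(series) >= 3)
  g0 <- series[[1]]$index
  y <- vapply(series, function(m) as.vector(t(m$index$values)),
              numeric(length(g0$values)))  # cells x periods
  x <- as.numeric(years)
  npd <- rowSums(!is.na(y))
  slope <- p <- rep(NA_real_, nrow(y))
  use <- npd >= 3
  if (any(use)) {
    for (i in which(use)) {
      ok <- !is.na(y[i, ])
      xi <- x[ok]; yi <- y[i, ok]
      sxx <- sum((xi - mean(xi))^2)
      b <- sum((xi - mean(xi)) * (yi - mean(yi))) / sxx
      a <- mean(yi) - b * mean(xi)
      res <- yi - a - b * xi
      df <- length(xi) - 2
      if (stats::sd(yi) == 0) {
        slope[i] <- 0; p[i] <- 1
      } else {
        s2 <- sum(res^2) / df
        se <- sqrt(s2 / sxx)
        slope[i] <- b
        p[i] <- if (se == 0) 0 else
          2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
      }
    }
  }
  to_grid <- function(v) {
    climate_grid(matrix(v, nrow = nrow(g0$values), byrow = TRUE),
                 g0$xll, g0$yll, g0$cellsize, g0$crs)
  }
  sig <- ifelse(is.na(p), NA_real_,
                ifelse(p <= 0.1, 2, ifelse(p <= 0.2, 1, 0)))
  structure(list(
    slope = to_grid(slope),
    p_value = to_grid(p),
    sig_class = to_grid(sig),
    n_periods = to_grid(npd)
  ), class = "trend_map")
}

#' Extrapolate suitability forward along fitted trends
#'
#' Per cell, `index + slope * (target_year - base_year)`, re-clamped to
#' \[0, 1\] (the index is bounded by definition).
#'
#' @param current A `suitability_map` for the base window.
#' @param trend A `trend_map` sharing geometry.
#' @param target_year Year to project to (> `base_year`).
#' @param base_year End-year of the final historical window.
#' @return A `suitability_map` for `target_year`.
#' @export
extrapolate_suitability <- function(current, trend, target_year,
                                    base_year) {
  if (target_year <= base_year) stop("target_year must exceed base_year")
  pred <- current$index$values +
    trend$slope$values * (target_year - base_year)
  lo <- !is.na(pred) & pred < 0
  hi <- !is.na(pred) & pred > 1
  pred[lo] <- 0; pred[hi] <- 1
  out <- current
  out$index$values <- pred
  out$clamped_low <- lo
  out$clamped_high <- hi
  out$period <- c(base_year, target_year)
  out
}

#' Fraction of a region above or below a suitability threshold
#'
#' Cell-count-weighted fraction (the grid is equal-area) of non-nodata
#' cells inside the polygon meeting the threshold comparison. Direction
#' `"below"` uses `index <= threshold` (unsuitable), `"above"` uses
#' `index > threshold` (suitable), so the two directions partition the
#' cells.
#'
#' @param map A `suitability_map`.
#' @param polygons Optional list of ring polygons; `NULL` uses all
#'   non-nodata cells.
#' @param threshold Suitability cutoff (default 0.7, the demographic
#'   stability threshold).
#' @param direction `"above"` or `"below"`.
#' @return Fraction in \[0, 1\].
#' @export
area_fraction <- function(map, polygons = NULL, threshold = 0.7,
                          direction = c("above", "below")) {
  direction <- match.arg(direction)
  v <- as.vector(t(map$index$values))
  keep <- !is.na(v)
  if (!is.null(polygons)) {
    ctr <- grid_centers(map$index)
    keep <- keep & points_in_polygons(ctr$x, ctr$y, polygons)
  }
  if (!any(keep)) stop("polygon overlaps no non-nodata cell")
  if (direction == "above") {
    sum(v[keep] > threshold) / sum(keep)
  } else {
    sum(v[keep] <= threshold) / sum(keep)
  }
}
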