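# Synthetic study system with known ground truth: a volcano-like grid
# world, a station network logging 10-minute weather, an out-plant cohort
# with Bernoulli survival driven by site climate, and gridded climate
# series with imposed trends and injectable raster bias. Every generator
# is a pure function of (parameters, seed).

#' Published-model survival coefficients
#'
#' The chosen two-predictor survival model: percent survival =
#' 298.48 - 24.22 * AT + 3.68 * RF, with AT in degC and RF in mm/day.
#' Used as the default generating model throughout the synthetic world.
#' @return Named coefficient vector.
#' @export
default_survival_coefficients <- function() {
  c("(Intercept)" = 298.48, AT = -24.22, RF = 3.68)
}

#' Build a synthetic study world
#'
#' A rectangular grid carrying a conical volcano elevation field; air
#' temperature follows a fixed lapse rate from a sea-level mean, and mean
#' daily rainfall follows a windward-to-leeward (west-east) orographic
#' gradient. Nine station sites are placed to span the AT (~7-13 degC)
#' and RF (~2-10 mm/day) gradients while keeping the two only weakly
#' correlated, so their separate effects are estimable. Linear per-year
#' climate drifts define the true suitability trend.
#'
#' @param seed Integer seed (placement and any stochastic fields).
#' @param nx,ny Grid dimensions (cells).
#' @param cellsize Cell size in metres (default 250).
#' @param at_sea_level Sea-level mean air temperature, degC.
#' @param lapse_rate Lapse rate, degC per km of elevation.
#' @param peak_elevation Summit elevation, m.
#' @param rf_range Mean daily rainfall at the west and east edges,
#'   mm/day.
#' @param trend Named per-year drifts: `at` (degC/yr), `rf` (mm/day/yr).
#'   Defaults emulate a warming, drying climate.
#' @param n_sites Number of station/out-plant sites (default 9).
#' @return A `synth_world`: grids `elevation`, `at`, `rf`
#'   (`climate_grid`s), the parameters, a `stations` tibble with true
#'   site climate, and `truth` (per-site survival probabilities under the
#'   default model and the true per-cell suitability trend slope).
#' @export
synth_world <- function(seed = 1, nx = 40, ny = 40, cellsize = 250,
                        at_sea_level = 24, lapse_rate = 6.5,
                        peak_elevation = 3000, rf_range = c(2, 10),
                        trend = c(at = 0.03, rf = -0.02),
                        n_sites = 9) {
  xfrac <- matrix(rep((seq_len(nx) - 0.5) / nx, each = ny), nrow = ny,
                  byrow = FALSE)
  # cone centred slightly west of centre
  cx <- 0.4 * nx; cy <- 0.5 * ny
  dist <- sqrt(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+"))
  elev <- peak_elevation * pmax(1 - dist / (0.75 * nx), 0)
  at <- at_sea_level - lapse_rate * elev / 1000
  rf <- rf_range[1] + (rf_range[2] - rf_range[1]) * xfrac
  g <- function(m) climate_grid(m, xll = 0, yll = 0, cellsize = cellsize)
  # stations: factorial targets over the two gradients
  at_targets <- seq(7.5, 12.5, length.out = 3)
  rf_targets <- seq(2.5, 9.5, length.out = 3)
  combos <- expand.grid(at = at_targets, rf = rf_targets)[seq_len(n_sites), ]
  taken <- integer(0)
  idx <- vapply(seq_len(nrow(combos)), function(i) {
    d2 <- (at - combos$at[i])^2 + ((rf - combos$rf[i]) / 2)^2
    d2[taken] <- Inf
    j <- which.min(d2)
    taken <<- c(taken, j)
    j
  }, integer(1))
  rc <- arrayInd(idx, dim(at))
  stations <- tibble::tibble(
    station_id = sprintf("S%02d", seq_len(n_sites)),
    row = rc[, 1], col = rc[, 2],
    x = (rc[, 2] - 0.5) * cellsize,
    y = (ny - rc[, 1] + 0.5) * cellsize,
    elevation = elev[idx],
    at_true = at[idx],
    rf_true = rf[idx]
  )
  cf <- default_survival_coefficients()
  p <- (cf[[1]] + cf[["AT"]] * stations$at_true +
          cf[["RF"]] * stations$rf_true) / 100
  truth <- list(
    site_survival_prob = pmin(1, pmax(0, p)),
    suitability_trend_per_year =
      (cf[["AT"]] * trend[["at"]] + cf[["RF"]] * trend[["rf"]]) / 100
  )
  structure(list(
    seed = seed, elevation = g(elev), at = g(at), rf = g(rf),
    at_sea_level = at_sea_level, lapse_rate = lapse_rate,
    rf_range = rf_range, trend = trend, cellsize = cellsize,
    stations = stations, truth = truth
  ), class = "synth_world")
}

# shared daily weather process for the network: seasonal cycle + regional
# AR(1) anomaly (shared across stations, inducing high cross-correlation)
# + site noise; rainfall as regionally shared wet days with site-level
# intensity multipliers (so donor-zero implies target-zero).
.gen_daily_truth <- function(world, dates, noise_sd, shared_weight, seed) {
  nd <- length(dates)
  ns <- nrow(world$stations)
  withr::with_seed(seed, {
    doy <- as.numeric(format(dates, "%j"))
    season <- 1.5 * sin(2 * pi * (doy - 120) / 365.25)
    anom <- stats::filter(stats::rnorm(nd, sd = 1.0), 0.8,
                          method = "recursive")
    anom <- as.numeric(anom) * sqrt(1 - 0.8^2)
    wet <- stats::runif(nd) < 0.35
    event <- ifelse(wet, stats::rexp(nd, rate = 1), 0)  # regional intensity
    # site mean rf = rf_true => multiplier = rf_true / E[event]
    e_event <- 0.35 * 1
    at <- rh <- sm <- rf <- matrix(NA_real_, nd, ns)
    for (s in seq_len(ns)) {
      site_noise <- stats::rnorm(nd, sd = noise_sd)
      at[, s] <- world$stations$at_true[s] + season +
        shared_weight * anom + sqrt(max(0, 1 - shared_weight^2)) *
        site_noise
      rf[, s] <- event * world$stations$rf_true[s] / e_event *
        exp(stats::rnorm(nd, sd = 0.1 * noise_sd)) * as.numeric(wet)
      rh[, s] <- pmin(100, pmax(20, 75 + 10 * wet - 2 *
                                  (at[, s] - world$stations$at_true[s]) +
                                  stats::rnorm(nd, sd = 3)))
      smv <- numeric(nd)
      smv[1] <- 0.15
      for (d in 2:nd) {
        smv[d] <- 0.9 * smv[d - 1] + 0.01 * rf[d, s] + 0.012
      }
      sm[, s] <- pmin(0.5, smv)
    }
  })
  list(at = at, rh = rh, sm = sm, rf = rf, dates = dates)
}

# contiguous missing-day blocks totalling ~gap_fraction of the window,
# staggered across stations so donors usually have data
.gap_days <- function(nd, ns, gap_fraction, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(ns), function(s) {
      total <- round(gap_fraction * nd)
      gaps <- integer(0)
      while (length(gaps) < total) {
        len <- min(sample(3:10, 1), total - length(gaps))
        start <- sample(nd - len + 1, 1)
        gaps <- unique(c(gaps, seq(start, start + len - 1)))
      }
      sort(gaps)
    })
  })
}

#' Generate a synthetic station network at 10-minute resolution
#'
#' Produces raw 10-minute records for every station in the world: diurnal
#' air-temperature cycles superimposed on a seasonal cycle and a shared
#' regional anomaly (giving high cross-station correlation), rainfall as a
#' regionally shared wet-day process with site intensity multipliers,
#' relative humidity consistent with temperature and wet days, and a slow
#' rainfall-driven soil-moisture store. Missing data are inserted as
#' contiguous whole-day blocks.
#'
#' @param world A `synth_world`.
#' @param start,end Window bounds (dates). Sub-multi-year windows keep
#'   generation fast; the process statistics do not depend on the length.
#' @param gap_fraction Fraction of days removed per station, in \[0, 1).
#' @param noise_sd Site-level AT noise s.d., degC.
#' @param shared_weight Weight of the shared regional anomaly in \[0, 1\];
#'   1 gives perfectly correlated stations.
#' @param seed Integer seed.
#' @return List: `records` (named list of per-station 10-minute tibbles
#'   with `station_id`, `timestamp`, `at`, `rf`, `rh`, `sm`), `truth`
#'   (per-station true daily matrices and the gap-day indices).
#' @export
gen_station_network <- function(world, start, end, gap_fraction = 0.1,
                                noise_sd = 0.3, shared_weight = 0.95,
                                seed = 1) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("window must span at least one day")
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("gap_fraction must be in [0, 1)")
  }
  dates <- seq(start, end, by = "day")
  nd <- length(dates); ns <- nrow(world$stations)
  daily <- .gen_daily_truth(world, dates, noise_sd, shared_weight,
                            seed + 1)
  gaps <- .gap_days(nd, ns, gap_fraction, seed + 2)
  tod <- seq(0, 24 * 3600 - 600, by = 600)               # 144 per day
  hour_frac <- tod / 3600
  diurnal <- 4 * sin(2 * pi * (hour_frac - 9) / 24) / 2  # +-2 degC
  records <- list()
  withr::with_seed(seed + 3, {
    for (s in seq_len(ns)) {
      keep <- setdiff(seq_len(nd), gaps[[s]])
      ts0 <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
      n_per_day <- length(tod)
      day_idx <- rep(keep, each = n_per_day)
      stamp <- rep(ts0[keep], each = n_per_day) + rep(tod, length(keep))
      at10 <- daily$at[day_idx, s] + rep(diurnal, length(keep)) +
        stats::rnorm(length(day_idx), sd = 0.05)
      rh10 <- pmin(100, pmax(10,
        daily$rh[day_idx, s] - rep(diurnal, length(keep)) * 2 +
          stats::rnorm(length(day_idx), sd = 0.5)))
      sm10 <- daily$sm[day_idx, s]
      # distribute the daily rain total over a random burst of intervals
      rf10 <- numeric(length(day_idx))
      for (d in keep) {
        tot <- daily$rf[d, s]
        if (tot > 0) {
          k <- sample(3:12, 1)
          slots <- sample(n_per_day, k)
          w <- stats::rexp(k); w <- w / sum(w)
          pos <- (match(d, keep) - 1) * n_per_day + slots
          rf10[pos] <- tot * w
        }
      }
      records[[world$stations$station_id[s]]] <- tibble::tibble(
        station_id = world$stations$station_id[s],
        timestamp = stamp,
        at = at10, rf = rf10, rh = rh10, sm = sm10
      )
    }
  })
  list(records = records,
       truth = list(daily = daily, gap_days = gaps, dates = dates))
}

#' Generate a synthetic daily-resolution station network
#'
#' Same daily weather process as [gen_station_network()] but emitted
#' directly as daily series (as if already aggregated), for workflows and
#' tests that operate at daily resolution. Gap days are missing entirely.
#'
#' @inheritParams gen_station_network
#' @return List: `series` (named list of daily series tibbles), `truth`
#'   (true daily matrices including values behind the gaps, and gap
#'   indices).
#' @export
gen_daily_network <- function(world, start, end, gap_fraction = 0.1,
                              noise_sd = 0.3, shared_weight = 0.95,
                              seed = 1) {
  start <- as.Date(start); end <- as.Date(end)
  dates <- seq(start, end, by = "day")
  nd <- length(dates); ns <- nrow(world$stations)
  daily <- .gen_daily_truth(world, dates, noise_sd, shared_weight,
                            seed + 1)
  gaps <- .gap_days(nd, ns, gap_fraction, seed + 2)
  series <- list()
  for (s in seq_len(ns)) {
    id <- world$stations$station_id[s]
    at <- daily$at[, s]; rh <- daily$rh[, s]
    sm <- daily$sm[, s]; rf <- daily$rf[, s]
    vpd <- compute_vpd(at, rh)
    at[gaps[[s]]] <- rh[gaps[[s]]] <- sm[gaps[[s]]] <- NA
    rf[gaps[[s]]] <- vpd[gaps[[s]]] <- NA
    series[[id]] <- daily_series(id, dates, at = at, rh = rh, sm = sm,
                                 vpd = vpd, rf = rf)
  }
  list(series = series,
       truth = list(daily = daily, gap_days = gaps, dates = dates))
}

#' Generate a synthetic out-plant cohort
#'
#' Allocates plants to sites with [build_design()] (10 maternal lines in
#' two source-elevation groups, per-site quotas 14 mid + 28 high, 2-8
#' siblings per line per site) and simulates monitoring: survival at the
#' assessment date is Bernoulli per plant with the site's clamped
#' model-predicted probability; rosette diameters shrink over the first
#' months after transplant then stabilise, with a site growth offset;
#' deaths occur at a random interim census; a small fraction of survivors
#' at high-survival sites flower late in the study and are recorded with
#' status `"flowered"`.
#'
#' @param world A `synth_world`.
#' @param per_site Plants per site (default 42).
#' @param coefficients Survival-model coefficients (default the published
#'   model).
#' @param planting_date Out-planting date.
#' @param months Study length in months (default 57).
#' @param seed Integer seed.
#' @return List: `plants` (with `initial_diameter`), `events`, `truth`
#'   (tibble of per-site survival probabilities and climate),
#'   `planting_date`, `assessment_date`.
#' @export
gen_outplant_cohort <- function(world, per_site = 42,
                                coefficients =
                                  default_survival_coefficients(),
                                planting_date = "2017-01-24",
                                months = 57, seed = 1) {
  planting_date <- as.Date(planting_date)
  assessment_date <- seq(planting_date, by = "month",
                         length.out = months + 1)[months + 1]
  st <- world$stations
  n_sites <- nrow(st)
  mid_q <- round(per_site / 3); high_q <- per_site - mid_q
  lines <- tibble::tibble(
    maternal_id = sprintf("M%02d", 1:10),
    source_elevation = rep(c("mid", "high"), each = 5),
    n_seedlings = rep(c(ceiling(mid_q * n_sites / 5) + 5,
                        ceiling(high_q * n_sites / 5) + 5), each = 5)
  )
  plants <- build_design(lines, n_sites = n_sites,
                         per_site_by_source =
                           c(mid = mid_q, high = high_q),
                         seed = seed)
  plants$site_id <- st$station_id[plants$site_id]
  p_site <- stats::setNames(
    pmin(1, pmax(0, (coefficients[[1]] +
                       coefficients[["AT"]] * st$at_true +
                       coefficients[["RF"]] * st$rf_true) / 100)),
    st$station_id)
  # twice-yearly censuses (end of wet/dry seasons)
  census <- seq(planting_date, by = "6 months",
                length.out = floor(months / 6) + 1)[-1]
  census[length(census)] <- assessment_date
  # site growth offset: sites with the best climate recover fully
  growth_off <- (p_site - mean(p_site)) * 0.4
  withr::with_seed(seed + 10, {
    plants$initial_diameter <- round(pmax(5, stats::rnorm(nrow(plants),
                                                          15.5, 2)), 1)
    events <- lapply(seq_len(nrow(plants)), function(i) {
      p <- plants[i, ]
      surv <- stats::runif(1) < p_site[[p$site_id]]
      # shrink ~35% over the first 9 months, then plateau + site offset
      frac <- as.numeric(census - planting_date) / 365.25
      shape <- 1 - 0.35 * pmin(1, frac / 0.75) +
        growth_off[[p$site_id]] * pmin(frac, 3)
      diam <- round(pmax(1, p$initial_diameter * shape *
                           exp(stats::rnorm(length(census), sd = 0.03))), 1)
      if (surv) {
        status <- rep("alive", length(census))
        if (p_site[[p$site_id]] > 0.6 && stats::runif(1) < 0.02) {
          status[length(status)] <- "flowered"
        }
        tibble::tibble(plant_id = p$plant_id, date = census,
                       diameter = diam, status = status)
      } else {
        dth <- sample(length(census), 1)
        keep <- seq_len(dth)
        status <- c(rep("alive", dth - 1), "dead")
        diam <- c(diam[seq_len(dth - 1)], NA)
        tibble::tibble(plant_id = p$plant_id, date = census[keep],
                       diameter = diam, status = status)
      }
    })
  })
  list(
    plants = plants,
    events = dplyr::bind_rows(events),
    truth = tibble::tibble(site_id = st$station_id,
                           p_survival = unname(p_site),
                           at = st$at_true, rf = st$rf_true),
    planting_date = planting_date,
    assessment_date = assessment_date
  )
}

# 3x3 box smoothing with edge replication, for spatially smooth noise
.smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + pad[di + 1:nr, dj + 1:nc]
  }
  out / 9
}

#' Generate a series of climate raster stacks with imposed trends
#'
#' One AT/RF stack per window end-year: the world's base fields plus the
#' linear per-year drift plus optional spatially smooth noise. An
#' optional affine raster bias can be injected (raster values distorted
#' relative to station truth) so that bias correction is testable: with
#' `bias = list(AT = c(slope = a, intercept = b))`, regressing station
#' truth on the raster recovers `(a, b)` exactly in the noise-free case.
#'
#' @param world A `synth_world`.
#' @param end_years Window end-years (>= 2), e.g. `seq(1995, 2020, 5)`.
#' @param noise_sd S.d. of the smooth field noise (0 for deterministic).
#' @param bias Optional named list (`AT`, `RF`) of `c(slope, intercept)`
#'   distortions.
#' @param base_year Year at which the base fields apply (default the
#'   first end-year).
#' @param seed Integer seed.
#' @return List: `stacks` (named list of `climate_stack`s keyed by
#'   end-year), `station_pairs` (tibble of station truth vs raster value
#'   per station-year, for [fit_bias_correction()]), `truth` (per-cell
#'   true suitability slope per year and the trend parameters).
#' @export
gen_raster_series <- function(world, end_years, noise_sd = 0,
                              bias = NULL, base_year = NULL, seed = 1) {
  if (length(end_years) < 2) stop("need at least 2 windows")
  base_year <- base_year %||% end_years[1]
  distort <- function(m, b) {
    if (is.null(b)) m else (m - b[[2]]) / b[[1]]
  }
  stacks <- list()
  pairs <- list()
  st <- world$stations
  sidx <- cbind(st$row, st$col)
  for (i in seq_along(end_years)) {
    yr <- end_years[i]
    at_true <- world$at$values + world$trend[["at"]] * (yr - base_year)
    rf_true <- pmax(world$rf$values +
                      world$trend[["rf"]] * (yr - base_year), 0.01)
    if (noise_sd > 0) {
      withr::with_seed(seed + i, {
        at_true <- at_true +
          .smooth3(matrix(stats::rnorm(length(at_true), sd = noise_sd * 3),
                          nrow(at_true)))
        rf_true <- pmax(rf_true +
          .smooth3(matrix(stats::rnorm(length(rf_true), sd = noise_sd * 3),
                          nrow(rf_true))), 0.01)
      })
    }
    at_r <- distort(at_true, bias$AT)
    rf_r <- distort(rf_true, bias$RF)
    g <- function(m) climate_grid(m, 0, 0, world$cellsize)
    stacks[[as.character(yr)]] <- climate_stack(g(at_r), g(rf_r),
                                                period = c(yr - 5, yr))
    pairs[[i]] <- tibble::tibble(
      station_id = st$station_id, year = yr,
      at_station = at_true[sidx], rf_station = rf_true[sidx],
      at_raster = at_r[sidx], rf_raster = rf_r[sidx]
    )
  }
  cf <- default_survival_coefficients()
  list(
    stacks = stacks,
    station_pairs = dplyr::bind_rows(pairs),
    truth = list(
      suitability_slope_per_year =
        (cf[["AT"]] * world$trend[["at"]] +
           cf[["RF"]] * world$trend[["rf"]]) / 100,
      trend = world$trend, base_year = base_year
    )
  )
}
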