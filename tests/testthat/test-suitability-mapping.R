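# Spatial projection: bias correction, bounded suitability, region masks,
# per-cell trends, extrapolation, area fractions.

cf <- published_coefficients

test_that("bias correction recovers injected affine distortions", {
  r <- seq(5, 12, length.out = 8)
  # unbiased pairs: identity correction
  bc0 <- fit_bias_correction(r, r, "AT")
  expect_equal(c(bc0$slope, bc0$intercept), c(1, 0), tolerance = 1e-12)
  # uniform 0.5 degC warm bias
  bc1 <- fit_bias_correction(r, r + 0.5, "AT")
  expect_equal(bc1$slope, 1, tolerance = 1e-12)
  expect_equal(bc1$intercept, -0.5, tolerance = 1e-12)
  g <- make_grid(matrix(r[1:6], 2, 3))
  gc <- apply_bias_correction(make_grid(matrix(r[1:6] + 0.5, 2, 3)), bc1)
  expect_equal(gc$values, g$values, tolerance = 1e-12)
  # mixed offset + scale: station = 0.9 * raster + 1
  bc2 <- fit_bias_correction(0.9 * r + 1, r, "AT")
  expect_equal(c(bc2$slope, bc2$intercept), c(0.9, 1), tolerance = 1e-12)
  expect_error(fit_bias_correction(r[1:2], r[1:2], "AT"), "3 station-year")
  expect_error(fit_bias_correction(r, rep(1, 8), "AT"), "degenerate")
})

test_that("suitability prediction evaluates the model, scales and clamps", {
  stk <- make_stack(at = 9, rf = 3, nr = 2, nc = 2)
  m <- predict_suitability(stk, cf)
  expect_equal(m$index$values[1, 1], (298.48 - 24.22 * 9 + 3.68 * 3) / 100)
  expect_equal(m$index$values[1, 1], 0.9154)
  # prediction above 100% clamps to exactly 1 with the flag set
  cold <- make_stack(at = 6, rf = 8, nr = 2, nc = 2)
  mc <- predict_suitability(cold, cf)
  expect_true(all(mc$index$values == 1))
  expect_true(all(mc$clamped_high))
  # negative prediction clamps to exactly 0
  hot <- make_stack(at = 14, rf = 2, nr = 2, nc = 2)
  mh <- predict_suitability(hot, cf)
  expect_true(all(mh$index$values == 0))
  expect_true(all(mh$clamped_low))
  # nodata propagates
  atm <- matrix(9, 2, 2); atm[1, 1] <- NA
  rfm <- matrix(3, 2, 2); rfm[1, 1] <- NA
  mn <- predict_suitability(make_stack(atm, rfm, 2, 2), cf)
  expect_true(is.na(mn$index$values[1, 1]))
  expect_false(mn$clamped_low[1, 1] || mn$clamped_high[1, 1])
})

test_that("clamping is idempotent and the index never leaves [0, 1]", {
  w <- synth_world(seed = 21)
  rs <- gen_raster_series(w, c(2015, 2020), noise_sd = 0.2, seed = 21)
  maps <- suitability_time_series(rs$stacks, cf)
  for (m in maps) {
    v <- m$index$values
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
    again <- predict_suitability(rs$stacks[[1]], cf)
    expect_equal(again$index$values, maps[[1]]$index$values)
  }
})

test_that("prediction is linear in AT through the bias-correction chain", {
  # without clamping, an affine change of the AT field moves every cell by
  # slope_AT * delta / 100 (chain rule through the correction)
  stk <- make_stack(at = matrix(seq(8, 11, length.out = 6), 2, 3),
                    rf = 5, nr = 2, nc = 3)
  bc <- structure(list(variable = "AT", slope = 0.9, intercept = 1,
                       n_station_years = 6L, r = 1),
                  class = "bias_correction")
  m1 <- predict_suitability(stk, cf, corrections = list(AT = bc),
                            clamp = FALSE)
  stk2 <- stk; stk2$at$values <- stk$at$values + 2
  m2 <- predict_suitability(stk2, cf, corrections = list(AT = bc),
                            clamp = FALSE)
  expect_equal(m2$index$values - m1$index$values,
               matrix(cf[["AT"]] * 0.9 * 2 / 100, 2, 3),
               tolerance = 1e-12)
})

test_that("region masks keep cells by centre and warn on empty results", {
  stk <- make_stack(at = 9, rf = 3, nr = 4, nc = 5)
  m <- predict_suitability(stk, cf)
  full <- square_ring(-10, -10, 5000, 5000)
  expect_equal(mask_region(m, list(full))$index$values, m$index$values)
  expect_warning(empty <- mask_region(m, list()), "every cell")
  expect_true(all(is.na(empty$index$values)))
  # half-plane: cells with centre x < 640 remain; brute-force count
  half <- square_ring(-10, -10, 640, 5000)
  mm <- mask_region(m, list(half))
  ctr <- grid_centers(m$index)
  expect_equal(sum(!is.na(mm$index$values)), sum(ctr$x < 640))
  expect_equal(sum(!is.na(mm$index$values)), 4 * 3)  # 3 of 5 columns
})

test_that("a window series yields one bounded map per window", {
  w <- synth_world(seed = 22)
  yrs <- seq(1995, 2020, 5)
  rs <- gen_raster_series(w, yrs, seed = 22)
  maps <- suitability_time_series(rs$stacks, cf)
  expect_length(maps, 6L)
  # identical climate in all windows -> identical maps
  w0 <- synth_world(seed = 22, trend = c(at = 0, rf = 0))
  rs0 <- gen_raster_series(w0, yrs, seed = 22)
  maps0 <- suitability_time_series(rs0$stacks, cf)
  for (i in 2:6) expect_equal(maps0[[i]]$index$values,
                              maps0[[1]]$index$values)
  # linearly drifting AT with fixed RF: per-cell index linear in window
  # index before clamping
  wl <- synth_world(seed = 22, trend = c(at = 0.05, rf = 0))
  rsl <- gen_raster_series(wl, yrs, seed = 22)
  raw <- lapply(rsl$stacks, predict_suitability, coefficients = cf,
                clamp = FALSE)
  steps <- vapply(2:6, function(i) {
    d <- raw[[i]]$index$values - raw[[i - 1]]$index$values
    unique(round(as.vector(d), 12))
  }, numeric(1))
  expect_equal(steps, rep(cf[["AT"]] * 0.05 * 5 / 100, 5),
               tolerance = 1e-9)
  expect_error(suitability_time_series(c(rsl$stacks, list(`2099` = NULL)),
                                       cf), "2099")
})

test_that("per-cell trends match constructed lines and conventions", {
  mk_map <- function(v) {
    structure(list(index = make_grid(v, 2, 2),
                   clamped_low = matrix(FALSE, 2, 2),
                   clamped_high = matrix(FALSE, 2, 2),
                   period = NULL), class = "suitability_map")
  }
  yrs <- seq(1995, 2020, 5)
  # constant series: slope 0 and p = 1 by convention
  tr0 <- fit_trend(lapply(yrs, function(y) mk_map(0.5)), yrs)
  expect_equal(tr0$slope$values, matrix(0, 2, 2))
  expect_equal(tr0$p_value$values, matrix(1, 2, 2))
  expect_equal(tr0$sig_class$values, matrix(0, 2, 2))
  # exact line at -0.01/yr: slope recovered, p ~ 0
  trl <- fit_trend(lapply(yrs, function(y) {
    mk_map(0.8 - 0.01 * (y - 1995))
  }), yrs)
  expect_equal(trl$slope$values, matrix(-0.01, 2, 2), tolerance = 1e-12)
  expect_true(all(trl$p_value$values < 1e-10))
  expect_equal(trl$sig_class$values, matrix(2, 2, 2))
  # cells with fewer than 3 periods are nodata
  series <- lapply(yrs, function(y) mk_map(0.8 - 0.01 * (y - 1995)))
  for (i in 1:4) series[[i]]$index$values[1, 1] <- NA
  trn <- fit_trend(series, yrs)
  expect_true(is.na(trn$slope$values[1, 1]))
  expect_false(is.na(trn$slope$values[2, 2]))
})

test_that("trend estimates are unbiased with a calibrated false-positive rate", {
  # 1000 synthetic cells: half with a true slope drawn around the world's
  # imposed drift, half null; iid noise per period
  yrs <- seq(1995, 2020, 5)
  n_cells <- 1000
  withr::with_seed(23, {
    true_slope <- c(rnorm(n_cells / 2, -0.008, 0.002),
                    rep(0, n_cells / 2))
    base <- runif(n_cells, 0.3, 0.7)
    mk <- function(y) {
      v <- base + true_slope * (y - 1995) + rnorm(n_cells, sd = 0.02)
      structure(list(index = climate_grid(matrix(v, 25, 40, byrow = TRUE)),
                     clamped_low = matrix(FALSE, 25, 40),
                     clamped_high = matrix(FALSE, 25, 40), period = NULL),
                class = "suitability_map")
    }
    series <- lapply(yrs, mk)
  })
  tr <- fit_trend(series, yrs)
  est <- as.vector(t(tr$slope$values))
  err <- est - true_slope
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(n_cells))  # unbiased
  # alpha = 0.1 mask false-positive rate on null cells near 0.1
  p_null <- as.vector(t(tr$p_value$values))[true_slope == 0]
  fpr <- mean(p_null <= 0.1)
  expect_lt(abs(fpr - 0.1), 0.04)
  # significance classes consistent with p-values
  p_all <- as.vector(t(tr$p_value$values))
  s_all <- as.vector(t(tr$sig_class$values))
  expect_equal(s_all, ifelse(p_all <= 0.1, 2, ifelse(p_all <= 0.2, 1, 0)))
})

test_that("extrapolation shifts by slope-years and re-clamps", {
  mk_map <- function(v) {
    structure(list(index = make_grid(v, 2, 2),
                   clamped_low = matrix(FALSE, 2, 2),
                   clamped_high = matrix(FALSE, 2, 2), period = NULL),
              class = "suitability_map")
  }
  mk_trend <- function(s) {
    structure(list(slope = make_grid(s, 2, 2)), class = "trend_map")
  }
  cur <- mk_map(0.5)
  expect_equal(extrapolate_suitability(cur, mk_trend(0), 2051,
                                       2020)$index$values,
               cur$index$values)
  expect_equal(extrapolate_suitability(cur, mk_trend(-0.02), 2030,
                                       2020)$index$values,
               matrix(0.3, 2, 2), tolerance = 1e-12)
  clamped <- extrapolate_suitability(cur, mk_trend(-0.06), 2030, 2020)
  expect_equal(clamped$index$values, matrix(0, 2, 2))
  expect_true(all(clamped$clamped_low))
  expect_error(extrapolate_suitability(cur, mk_trend(0), 2019, 2020),
               "exceed")
})

test_that("area fractions count cell centres and partition by direction", {
  v <- matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2)  # half above 0.7
  m <- structure(list(index = make_grid(v, 2, 2),
                      clamped_low = matrix(FALSE, 2, 2),
                      clamped_high = matrix(FALSE, 2, 2), period = NULL),
                 class = "suitability_map")
  expect_equal(area_fraction(m, threshold = 0.7, direction = "below"), 0.5)
  expect_equal(area_fraction(m, threshold = 0.7, direction = "above"), 0.5)
  expect_equal(area_fraction(m, threshold = 0, direction = "above"), 1)
  # complementary directions always sum to 1
  withr::with_seed(24, {
    v2 <- matrix(runif(20), 4, 5)
  })
  m2 <- structure(list(index = make_grid(v2, 4, 5),
                       clamped_low = matrix(FALSE, 4, 5),
                       clamped_high = matrix(FALSE, 4, 5), period = NULL),
                  class = "suitability_map")
  poly <- list(square_ring(-1, -1, 700, 1100))
  expect_equal(area_fraction(m2, poly, 0.7, "above") +
                 area_fraction(m2, poly, 0.7, "below"), 1)
  expect_error(area_fraction(m2, list(square_ring(9000, 9000, 9100, 9100)),
                             0.7, "above"), "overlap")
})

test_that("the pipeline recovers the true suitability field end to end", {
  # stations -> gap-fill -> period summaries -> survival fit -> map,
  # compared against the world's true (clamped) suitability field
  w <- synth_world(seed = 25)
  net <- gen_daily_network(w, "2019-01-01", "2019-12-31",
                           gap_fraction = 0.08, noise_sd = 0.3, seed = 25)
  filled <- gap_fill_network(net$series, variables = c("at", "rf"))$series
  summaries <- dplyr::bind_rows(lapply(filled, summarize_period,
                                       start = "2019-01-01",
                                       end = "2019-12-31"))
  coh <- gen_outplant_cohort(w, seed = 25)
  perf <- site_performance(coh$plants, coh$events, coh$assessment_date,
                           coh$planting_date)
  obs <- tibble::tibble(
    site_id = summaries$station_id,
    AT = summaries$at_mean,
    RF = summaries$rf_mean_daily,
    response = perf$percent_survival[match(summaries$station_id,
                                           perf$site_id)]
  )
  fit <- fit_ols(obs, list(vars = c("AT", "RF"), interaction = FALSE))
  stk <- climate_stack(w$at, w$rf)
  est <- predict_suitability(stk, fit$coefficients)
  truth <- pmin(pmax((cf[[1]] + cf[["AT"]] * w$at$values +
                        cf[["RF"]] * w$rf$values) / 100, 0), 1)
  err <- est$index$values - truth
  expect_lt(sqrt(mean(err^2)), 0.15)  # binomial + imputation noise budget
  expect_gt(cor(as.vector(est$index$values), as.vector(truth)), 0.9)
})
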