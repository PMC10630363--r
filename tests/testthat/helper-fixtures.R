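# Shared fixture builders; everything is generated in code.

# a daily series with given values for a subset of variables
make_series <- function(id, dates, ...) {
  daily_series(id, dates, ...)
}

# 10-minute records for one station from a function of time-of-day index
make_raw <- function(id, start, n, at = NULL, rf = NULL, rh = NULL,
                     sm = NULL) {
  ts <- as.POSIXct(start, tz = "UTC") + 600 * (seq_len(n) - 1)
  tibble::tibble(
    station_id = id,
    timestamp = ts,
    at = at %||% rep(10, n),
    rf = rf %||% rep(0, n),
    rh = rh %||% rep(50, n),
    sm = sm %||% rep(0.2, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# square ring polygon
square_ring <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0), ncol = 2,
         byrow = TRUE)
}

# grid filled with a constant (or matrix), default geometry
make_grid <- function(v, nr = 4, nc = 5, cellsize = 250) {
  if (!is.matrix(v)) v <- matrix(v, nr, nc)
  climate_grid(v, xll = 0, yll = 0, cellsize = cellsize)
}

make_stack <- function(at, rf, nr = 4, nc = 5, period = c(2015, 2020)) {
  climate_stack(make_grid(at, nr, nc), make_grid(rf, nr, nc), period)
}

# independent normal-equations OLS oracle (no lm)
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force all-pairs AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

published_coefficients <- c("(Intercept)" = 298.48, AT = -24.22,
                            RF = 3.68)

# nine noise-free site observations on the published survival plane;
# sites form a 3 x 3 factorial over the two gradients, mirroring the
# design goal of spanning both while keeping them uncorrelated
make_noise_free_sites <- function() {
  grid <- expand.grid(AT = c(7, 10, 13), RF = c(2, 6, 10))
  tibble::tibble(
    site_id = sprintf("S%02d", 1:9),
    AT = grid$AT, RF = grid$RF,
    response = published_coefficients[[1]] +
      published_coefficients[["AT"]] * grid$AT +
      published_coefficients[["RF"]] * grid$RF
  )
}
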