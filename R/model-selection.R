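# Candidate climate-model enumeration, site-level OLS fits, and AICc
# ranking.

#' Enumerate candidate climate models
#'
#' All one-variable models, plus additive and interaction models for every
#' unordered pair whose predictors are not excluded as collinear. A pair is
#' excluded when `|r| > r_threshold` in `pairwise_r`, or when listed in
#' `exclude`. With five variables and three excluded pairs this yields
#' 5 + 7 + 7 = 19 specifications.
#'
#' @param variables Character vector of predictor names.
#' @param pairwise_r Optional symmetric correlation matrix (unit diagonal,
#'   dimnames = variables) from which exclusions are derived.
#' @param exclude Optional explicit exclusions: list of length-2 character
#'   vectors, or strings `"A:B"`.
#' @param r_threshold Collinearity threshold on `|r|`, in (0, 1].
#' @return Tibble of specs: `model_id`, `vars` (list column),
#'   `interaction` (logical), `k` (parameter count incl. intercept and
#'   error variance).
#' @export
#' @examples
#' enumerate_models(c("AT", "RF", "RH", "SM", "VPD"),
#'                  exclude = list(c("RH", "RF"), c("RH", "VPD"),
#'                                 c("RF", "VPD")))
enumerate_models <- function(variables, pairwise_r = NULL, exclude = NULL,
                             r_threshold = 0.7) {
  if (r_threshold <= 0 || r_threshold > 1) {
    stop("r_threshold must be in (0, 1]")
  }
  variables <- unique(variables)
  excl <- character()
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")
  if (!is.null(pairwise_r)) {
    if (!isTRUE(all.equal(pairwise_r, t(pairwise_r))) ||
        !isTRUE(all.equal(unname(diag(pairwise_r)),
                          rep(1, nrow(pairwise_r))))) {
      stop("pairwise_r must be symmetric with unit diagonal")
    }
    for (i in seq_along(variables)) {
      for (j in seq_along(variables)) {
        if (i < j && abs(pairwise_r[variables[i], variables[j]]) >
              r_threshold) {
          excl <- c(excl, pair_key(variables[i], variables[j]))
        }
      }
    }
  }
  if (!is.null(exclude)) {
    excl <- c(excl, vapply(exclude, function(e) {
      if (is.character(e) && length(e) == 1) e <- strsplit(e, ":")[[1]]
      pair_key(e[1], e[2])
    }, character(1)))
  }
  excl <- unique(excl)
  specs <- lapply(variables, function(v) {
    list(vars = v, interaction = FALSE)
  })
  if (length(variables) >= 2) {
    pairs <- utils::combn(variables, 2, simplify = FALSE)
    for (p in pairs) {
      if (pair_key(p[1], p[2]) %in% excl) next
      specs <- c(specs,
                 list(list(vars = p, interaction = FALSE)),
                 list(list(vars = p, interaction = TRUE)))
    }
  }
  tibble::tibble(
    model_id = vapply(specs, function(s) {
      paste0(paste(s$vars, collapse = "+"),
             if (s$interaction) paste0("+", paste(s$vars, collapse = ":"))
             else "")
    }, character(1)),
    vars = lapply(specs, `[[`, "vars"),
    interaction = vapply(specs, `[[`, "interaction", FUN.VALUE = logical(1)),
    # parameters: intercept + slopes (+ interaction) + error variance
    k = vapply(specs, function(s) {
      1L + length(s$vars) + as.integer(s$interaction) + 1L
    }, integer(1))
  )
}

.spec_formula <- function(spec, response = "response") {
  rhs <- paste(spec$vars, collapse = " + ")
  if (isTRUE(spec$interaction)) {
    rhs <- paste0(rhs, " + ", paste(spec$vars, collapse = ":"))
  }
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit one candidate model by ordinary least squares
#'
#' Interaction terms use raw (uncentered) products. The parameter count
#' `k` used downstream by [aicc()] counts the intercept, all slopes, and
#' the error variance.
#'
#' @param observations Site-level table: one row per site with a
#'   `response` column and one column per predictor named in the spec.
#' @param spec One spec: a list with `vars` and `interaction` (a row of
#'   [enumerate_models()] output works via `spec = specs[i, ]`).
#' @return A `candidate_fit` list: `spec`, `coefficients`, `rss`,
#'   `r_squared`, `aicc`, `n_sites`, `k`.
#' @export
fit_ols <- function(observations, spec) {
  if (is.data.frame(spec)) {
    spec <- list(vars = spec$vars[[1]], interaction = spec$interaction[1])
  }
  miss <- setdiff(spec$vars, names(observations))
  if (length(miss)) {
    stop("observations missing predictors: ", paste(miss, collapse = ", "))
  }
  n <- nrow(observations)
  k <- 1L + length(spec$vars) + as.integer(isTRUE(spec$interaction)) + 1L
  if (n <= k - 1L) stop("need more sites than estimated coefficients")
  fit <- stats::lm(.spec_formula(spec), data = observations)
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit))) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((observations$response - mean(observations$response))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  structure(list(
    spec = spec,
    coefficients = stats::coef(fit),
    rss = rss,
    r_squared = r2,
    # the small-sample correction needs n > k + 1; smaller fits carry NA
    aicc = if (n > k + 1) aicc(rss, n, k) else NA_real_,
    n_sites = n,
    k = k,
    lm_fit = fit
  ), class = "candidate_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' Least-squares form:
#' `AICc = n * log(rss / n) + 2k + 2k(k + 1) / (n - k - 1)`,
#' with `k` counting all estimated parameters including the intercept and
#' the error variance. Only differences in AICc are meaningful, so any
#' self-consistent constant convention preserves rankings. An exact fit
#' (`rss = 0`) returns `-Inf` and ranks first.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Parameter count (intercept + slopes + error variance).
#' @return The AICc score.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  if (rss < 0) stop("rss must be nonnegative")
  if (rss == 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate fits by AICc
#'
#' @param fits List of `candidate_fit` objects (from [fit_ols()] or
#'   [fit_logit_variant()]).
#' @return Tibble sorted by ascending AICc with `delta_aicc` relative to
#'   the best model and candidate-set flags at the conventional cutoffs
#'   `delta <= 2`, `<= 4` and `<= 4.5` (the widest retains a model at
#'   delta 4.24).
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) stop("no fits to rank")
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      model_id = paste0(paste(f$spec$vars, collapse = "+"),
                        if (isTRUE(f$spec$interaction))
                          paste0("+", paste(f$spec$vars, collapse = ":"))
                        else ""),
      k = f$k,
      r_squared = f$r_squared,
      rss = f$rss,
      aicc = f$aicc,
      coefficients = list(f$coefficients)
    )
  }))
  tab <- tab[order(tab$aicc, tab$model_id), ]
  best <- tab$aicc[1]
  tab$delta_aicc <- if (is.infinite(best)) {
    ifelse(is.infinite(tab$aicc), 0, Inf)
  } else {
    tab$aicc - best
  }
  tab$in_set_2 <- tab$delta_aicc <= 2
  tab$in_set_4 <- tab$delta_aicc <= 4
  tab$in_set_4.5 <- tab$delta_aicc <= 4.5
  tab
}

#' Fit all candidate specs and rank them
#'
#' @param observations Site-level table with a `response` column.
#' @param specs Output of [enumerate_models()].
#' @return Ranked tibble as from [rank_models()].
#' @export
fit_candidates <- function(observations, specs) {
  fits <- lapply(seq_len(nrow(specs)), function(i) {
    fit_ols(observations, specs[i, ])
  })
  rank_models(fits)
}

#' Fit a candidate model to logit-transformed percent survival
#'
#' OLS on `logit(p)` with `p = response / 100`. Provided for comparison
#' only and flagged non-default: on the logit scale, sites near the
#' survival bounds are stretched out and gain undue influence, so the
#' untransformed percent response is used for suitability projection.
#' Responses exactly at 0 or 100 are rejected unless `adjust = TRUE`, in
#' which case `p` is replaced by `(x + 0.5) / (n_trials + 1)` at the
#' boundaries (with `x` the survivor count).
#'
#' @inheritParams fit_ols
#' @param adjust Apply the boundary adjustment.
#' @param n_trials Plants per site, needed for the adjustment.
#' @return A `candidate_fit` on the logit scale, with `scale = "logit"`
#'   and `default = FALSE` recorded in the spec.
#' @export
fit_logit_variant <- function(observations, spec, adjust = FALSE,
                              n_trials = NULL) {
  if (is.data.frame(spec)) {
    spec <- list(vars = spec$vars[[1]], interaction = spec$interaction[1])
  }
  p <- observations$response / 100
  at_bound <- p <= 0 | p >= 1
  if (any(at_bound)) {
    if (!adjust) {
      stop("response at 0 or 100 requires adjust = TRUE")
    }
    if (is.null(n_trials)) stop("boundary adjustment needs n_trials")
    x <- p * n_trials
    p[at_bound] <- (x[at_bound] + 0.5) / (n_trials + 1)
  }
  obs <- observations
  obs$response <- log(p / (1 - p))
  out <- fit_ols(obs, spec)
  out$spec$scale <- "logit"
  out$spec$default <- FALSE
  out
}

#' Export chosen-model coefficients for suitability mapping
#'
#' Writes intercept and slopes (with predictor units) as a small JSON
#' config consumed by [predict_suitability()].
#'
#' @param fit A `candidate_fit` for the chosen model.
#' @param path Output file.
#' @param units Named character vector documenting predictor units.
#' @export
write_model_config <- function(fit, path,
                               units = c(AT = "degC", RF = "mm/day")) {
  cfg <- list(
    response = "percent_survival",
    coefficients = as.list(fit$coefficients),
    r_squared = fit$r_squared,
    n_sites = fit$n_sites,
    units = as.list(units)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model config written by [write_model_config()]
#'
#' @param path JSON file.
#' @return Named numeric coefficient vector with a `units` attribute.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(cfg$coefficients)
  attr(coefs, "units") <- cfg$units
  coefs
}
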