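# Simplified occurrence-based SDM comparison: pseudo-absence sampling,
# presence/background evaluation metrics (TSS, Cohen's kappa, ROC AUC),
# and a TSS-weighted ensemble over pluggable base learners.

#' Sample pseudo-absence cells outside a buffer around presences
#'
#' Uniform random sample without replacement from grid cells whose centres
#' lie more than `buffer_m` from every presence polygon.
#'
#' @param grid A `climate_grid` defining the candidate cells (nodata cells
#'   are never eligible).
#' @param presence_polygons List of (x, y) ring matrices delineating
#'   population areas, in the grid's CRS.
#' @param buffer_m Exclusion distance from the polygons (default 250).
#' @param n Number of pseudo-absences to draw.
#' @param seed Integer seed; the draw is reproducible.
#' @return Tibble of sampled cells: `row`, `col`, `x`, `y`.
#' @export
sample_pseudo_absences <- function(grid, presence_polygons, buffer_m = 250,
                                   n, seed = 1) {
  ctr <- grid_centers(grid)
  vals <- as.vector(t(grid$values))
  d <- distance_to_polygons(ctr$x, ctr$y, presence_polygons)
  eligible <- which(!is.na(vals) & d > buffer_m)
  if (n > length(eligible)) {
    stop("requested ", n, " pseudo-absences but only ", length(eligible),
         " eligible cells")
  }
  pick <- withr::with_seed(seed, sample(eligible, n))
  ctr[pick, ]
}

#' Threshold-based evaluation metrics for presence/absence predictions
#'
#' From the 2x2 confusion table at `threshold`:
#' TSS = sensitivity + specificity - 1; Cohen's kappa from observed vs
#' chance agreement; ROC AUC from the Mann-Whitney rank statistic
#' (threshold-free, ties counted half).
#'
#' @param predicted Numeric scores (higher = more presence-like).
#' @param observed Binary labels (1/TRUE presence, 0/FALSE absence); both
#'   classes must be present.
#' @param threshold Scores > `threshold` predict presence.
#' @return Tibble: `tss`, `kappa`, `roc_auc`, `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
confusion_metrics <- function(predicted, observed, threshold = 0.5) {
  obs <- as.integer(as.logical(observed))
  if (length(unique(obs)) < 2) {
    stop("observed labels contain a single class")
  }
  pred <- as.integer(predicted > threshold)
  tp <- sum(pred == 1 & obs == 1)
  fn <- sum(pred == 0 & obs == 1)
  tn <- sum(pred == 0 & obs == 0)
  fp <- sum(pred == 1 & obs == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  n <- length(obs)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  # rank-statistic AUC
  r <- rank(predicted)
  n1 <- sum(obs == 1); n0 <- n - n1
  auc <- (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble::tibble(tss = sens + spec - 1, kappa = kappa, roc_auc = auc,
                 sensitivity = sens, specificity = spec,
                 threshold = threshold)
}

#' Threshold maximising TSS
#'
#' Evaluates TSS at every distinct score (as candidate cutpoints) and
#' returns the maximiser; ties go to the lowest threshold.
#'
#' @inheritParams confusion_metrics
#' @return List with `threshold` and the `metrics` row at that threshold.
#' @export
tss_optimal_threshold <- function(predicted, observed) {
  cand <- sort(unique(predicted))
  # cut just below each score so every split is reachable
  cand <- c(min(cand) - 1e-9, (cand[-length(cand)] + cand[-1]) / 2)
  tss <- vapply(cand, function(th) {
    confusion_metrics(predicted, observed, th)$tss
  }, numeric(1))
  best <- cand[which.max(tss)]
  list(threshold = best,
       metrics = confusion_metrics(predicted, observed, best))
}

#' TSS-weighted ensemble average of model predictions
#'
#' Per-cell weighted mean with weights proportional to each model's TSS,
#' floored at zero (models with TSS <= 0 get no influence) and normalised
#' to sum to one.
#'
#' @param per_model_predictions Matrix, cells x models (or a list of
#'   equal-length vectors).
#' @param per_model_tss Numeric TSS per model.
#' @return List: `prediction` (per-cell weighted mean), `weights`,
#'   `n_models` (models with positive weight).
#' @export
ensemble_average <- function(per_model_predictions, per_model_tss) {
  if (is.list(per_model_predictions) &&
      !is.matrix(per_model_predictions)) {
    per_model_predictions <- do.call(cbind, per_model_predictions)
  }
  stopifnot(ncol(per_model_predictions) == length(per_model_tss))
  w <- pmax(per_model_tss, 0)
  if (sum(w) == 0) stop("all models have TSS <= 0; no usable weights")
  w <- w / sum(w)
  list(
    prediction = as.vector(per_model_predictions %*% w),
    weights = w,
    n_models = sum(w > 0)
  )
}

#' Simple presence/background base learner
#'
#' Ridge-regularised logistic regression of presence on the two climate
#' covariates (AT, RF). This built-in learner exists so the ensemble path
#' can be exercised end-to-end; tuned boosted trees or maximum-entropy
#' learners can be plugged in through the same interface (a function of
#' `(train, newdata)` returning scores in \[0, 1\]).
#'
#' @param train Tibble with columns `presence` (0/1), `AT`, `RF`.
#' @param newdata Tibble with `AT`, `RF` to score.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Numeric presence scores in \[0, 1\] for `newdata`.
#' @export
fit_presence_learner <- function(train, newdata, lambda = 1e-3) {
  x <- as.matrix(train[, c("AT", "RF")])
  fit <- glmnet::glmnet(x, train$presence, family = "binomial",
                        alpha = 0, lambda = lambda)
  as.vector(stats::predict(fit, as.matrix(newdata[, c("AT", "RF")]),
                           type = "response"))
}
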