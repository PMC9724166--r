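#' Ten-fold cross-validated LARS-lasso predictions
#'
#' Randomly partitions the events into `k` nearly equal folds. For each
#' fold, the training covariates are re-standardized from scratch (no
#' information leakage), a LARS-lasso path is fitted on the training rows,
#' the minimum-Cp sub-model is selected, and the withheld fold is predicted
#' with the training-fold standardization. Every observation is predicted
#' exactly once.
#'
#' @param frame A [build_model_frame()] result.
#' @param k Number of folds, default 10.
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `cv_predictions`: data frame with columns
#'   `index`, `fold`, `observed`, `predicted`, plus attributes `k` and `seed`.
#' @export
kfold_predict <- function(frame, k = 10, seed = 1L) {
  stopifnot(inherits(frame, "model_frame"))
  n <- nrow(frame$X_raw)
  if (k < 2) stopf("`k` must be >= 2")
  if (n < k) stopf("n = %d observations cannot be split into k = %d folds", n, k)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    std <- standardize_covariates(frame$X_raw[!test, , drop = FALSE])
    path <- lars_fit(std$Z, frame$y[!test])
    model <- select_min_cp(path)
    Ztest <- standardize_covariates(frame$X_raw[test, , drop = FALSE],
                                    params = std$params)$Z
    pred[test] <- predict(model, Ztest)
  }
  out <- data.frame(index = seq_len(n), fold = folds,
                    observed = frame$y, predicted = pred)
  structure(out, k = k, seed = seed, class = c("cv_predictions", "data.frame"))
}

#' Standardized root mean squared error of prediction
#'
#' `SRMSEP = sqrt(mean((P_i - O_i)^2)) / C_bar`, where `C_bar` is the mean
#' log10 concentration of the modeled microbial metric (computed over the
#' full substituted response, not the withheld folds).
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param mean_log10_concentration `C_bar`; must be non-zero.
#' @return A single number; 0 iff predictions equal observations.
#' @export
srmsep <- function(predicted, observed,
                   mean_log10_concentration = mean(observed)) {
  stopifnot(length(predicted) == length(observed))
  if (!is_scalar_number(mean_log10_concentration) ||
      mean_log10_concentration == 0) {
    stopf("mean log10 concentration is zero: SRMSEP standardization undefined")
  }
  sqrt(mean((predicted - observed)^2)) / mean_log10_concentration
}

#' Predictive R-squared
#'
#' Coefficient of determination of the simple linear regression of observed
#' on cross-validated predicted values; equals the squared Pearson
#' correlation between the two.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return A value in [0, 1]; 0 (with a warning) when the predictions are
#'   constant and the regression is degenerate.
#' @export
r2_pred <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (stats::sd(observed) == 0) stopf("observed values have zero variance")
  if (stats::sd(predicted) == 0) {
    warnf("predictions have zero variance; returning R2_pred = 0")
    return(0)
  }
  stats::cor(predicted, observed)^2
}

#' Overall Performance composite
#'
#' `standardized R2_pred + (1 - standardized SRMSEP)`; the SRMSEP term is
#' reversed because large SRMSEP means poor performance. Ranges over
#' [0, 2] when both standardized metrics lie in [0, 1].
#'
#' @param std_r2_pred,std_srmsep Standardized metrics (each metric divided
#'   by its maximum across the compared model set).
#' @return Composite score.
#' @export
overall_performance <- function(std_r2_pred, std_srmsep) {
  std_r2_pred + (1 - std_srmsep)
}

#' Cross-model performance board
#'
#' Standardizes each model's R2_pred and SRMSEP by the maximum observed
#' across the supplied model set and computes the Overall Performance
#' composite. The standardization is defined over whatever model set is
#' supplied, so the set must be explicit and complete for the scores to be
#' comparable.
#'
#' @param metrics Data frame with columns `site`, `indicator`, `rpred2`,
#'   `srmsep` (one row per model).
#' @return An object of class `performance_board`: the input plus
#'   `std_rpred2`, `std_srmsep` and `overall_performance` columns, sorted by
#'   decreasing overall performance; attributes `max_rpred2`/`max_srmsep`
#'   record the standardization maxima.
#' @export
build_board <- function(metrics) {
  req <- c("site", "indicator", "rpred2", "srmsep")
  if (!all(req %in% names(metrics))) {
    stopf("`metrics` needs columns %s", paste(req, collapse = ", "))
  }
  if (nrow(metrics) < 1) stopf("at least one model row required")
  max_r2 <- max(metrics$rpred2)
  max_sr <- max(metrics$srmsep)
  if (max_r2 <= 0 || max_sr <= 0) stopf("standardization maxima must be positive")
  out <- metrics
  out$std_rpred2 <- metrics$rpred2 / max_r2
  out$std_srmsep <- metrics$srmsep / max_sr
  out$overall_performance <- overall_performance(out$std_rpred2, out$std_srmsep)
  out <- out[order(-out$overall_performance), , drop = FALSE]
  structure(out, max_rpred2 = max_r2, max_srmsep = max_sr,
            class = c("performance_board", "data.frame"))
}

#' Fit, cross-validate and score a set of model frames
#'
#' Convenience wrapper: runs [kfold_predict()] on each frame, computes
#' [srmsep()] and [r2_pred()], and assembles the [build_board()] result.
#'
#' @param frames List of [build_model_frame()] objects (the full model set
#'   over which standardization is defined).
#' @param k,seed Passed to [kfold_predict()].
#' @return A `performance_board`; the per-frame `cv_predictions` are
#'   attached as attribute `"cv"`.
#' @export
evaluate_models <- function(frames, k = 10, seed = 1L) {
  cvs <- lapply(seq_along(frames), function(i) {
    kfold_predict(frames[[i]], k = k, seed = child_seed(seed, i))
  })
  metrics <- do.call(rbind, lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]; cv <- cvs[[i]]
    data.frame(site = fr$site, indicator = fr$indicator,
               rpred2 = r2_pred(cv$predicted, cv$observed),
               srmsep = srmsep(cv$predicted, cv$observed, mean(fr$y)),
               cbar = mean(fr$y))
  }))
  board <- build_board(metrics)
  attr(board, "cv") <- cvs
  board
}
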