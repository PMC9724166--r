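#' Coefficients of the full-data minimum-Cp model
#'
#' Fits one LARS-lasso path on all available measurements of a model frame
#' (no cross-validation) and returns the coefficient vector of the
#' minimum-Cp step. These are the per-model coefficients that covariate
#' influence scores and heatmaps summarize.
#'
#' @param frame A [build_model_frame()] result.
#' @return Named numeric vector on the standardized-covariate scale (zeros
#'   for covariates shrunk out of the model).
#' @export
full_data_coefficients <- function(frame) {
  stopifnot(inherits(frame, "model_frame"))
  coef(select_min_cp(lars_fit(frame$X, frame$y)))
}

#' Aggregate related covariates into influence groups
#'
#' Replaces each group's member coefficients by a single entry whose
#' magnitude is the sum of the members' absolute coefficients. For
#' occurrence counting downstream, a group is non-zero in a model whenever
#' any member is (union semantics), so a proportion can never exceed 1.
#' Typical groups: 24 h and 72 h cumulative rainfall as "Rainfall";
#' alongshore and onshore/offshore wind as "Wind Speed/Direction".
#'
#' @param coef_list Named list of per-model coefficient vectors.
#' @param groups Named list: group name -> character vector of member
#'   covariate names.
#' @return List of coefficient vectors with member entries replaced by the
#'   group entry (magnitude only; signs are not meaningful for a group).
#' @export
aggregate_covariates <- function(coef_list, groups) {
  lapply(coef_list, function(b) {
    for (g in names(groups)) {
      members <- groups[[g]]
      present <- intersect(members, names(b))
      unknown <- setdiff(members, names(b))
      if (length(unknown) && length(present) == 0) {
        stopf("group '%s' members not found in coefficients: %s",
              g, paste(unknown, collapse = ", "))
      }
      if (length(present)) {
        val <- sum(abs(b[present]))
        b <- b[setdiff(names(b), present)]
        b[g] <- val
      }
    }
    b
  })
}

#' Covariate influence scores across models
#'
#' For each covariate (or aggregated group): (1) the sum over models of
#' absolute regression coefficients; (2) the proportion of models in which
#' the coefficient is non-zero; and (3) the Total Score, the sum of the two.
#' A covariate measured only at some sites is scored over the models where
#' it was available, not the full model set.
#'
#' @param coef_list Named list of per-model coefficient vectors (possibly
#'   after [aggregate_covariates()]). A covariate is "available" in a model
#'   iff it appears in that model's vector; pass `availability` to override.
#' @param availability Optional named list: model name -> character vector
#'   of available covariates.
#' @return An `influence_table` data frame: `covariate`,
#'   `summed_coefficients`, `proportion_occurrence`, `total_score`,
#'   `n_models`, sorted by decreasing total score.
#' @export
influence_scores <- function(coef_list, availability = NULL) {
  if (!length(coef_list)) stopf("at least one model required")
  if (is.null(availability)) availability <- lapply(coef_list, names)
  covs <- sort(unique(unlist(lapply(coef_list, names))))
  rows <- lapply(covs, function(v) {
    avail <- vapply(seq_along(coef_list), function(i) v %in% availability[[i]],
                    logical(1))
    vals <- vapply(which(avail), function(i) {
      b <- coef_list[[i]]
      if (v %in% names(b)) unname(b[v]) else 0
    }, numeric(1))
    data.frame(covariate = v,
               summed_coefficients = sum(abs(vals)),
               proportion_occurrence = mean(vals != 0),
               total_score = sum(abs(vals)) + mean(vals != 0),
               n_models = sum(avail))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("influence_table", "data.frame")
  out
}

#' Signed-coefficient heatmap matrix for one site
#'
#' Arranges per-indicator coefficient vectors into a covariate-by-indicator
#' matrix, covariates in alphabetical order. Covariates not available for a
#' model are marked `NA` (never zero): a zero cell means the lasso shrunk
#' the coefficient out, an `NA` cell means no covariate data existed.
#'
#' @param models Named list: indicator name -> named coefficient vector.
#' @param covariates Optional character vector fixing the row universe
#'   (e.g. the union across sites); defaults to the union over `models`.
#' @return An object of class `coefficient_heatmap`: numeric matrix with
#'   `NA` marking unavailable cells.
#' @export
heatmap_matrix <- function(models, covariates = NULL) {
  if (is.null(covariates)) covariates <- unique(unlist(lapply(models, names)))
  covariates <- sort(covariates)
  M <- matrix(NA_real_, length(covariates), length(models),
              dimnames = list(covariates, names(models)))
  for (ind in names(models)) {
    b <- models[[ind]]
    M[intersect(names(b), covariates), ind] <- b[intersect(names(b), covariates)]
  }
  class(M) <- c("coefficient_heatmap", class(M))
  M
}

#' @export
print.influence_table <- function(x, ...) {
  cat("Covariate influence across models:\n")
  print.data.frame(cbind(x[1], round(x[2:4], 3), x[5]), row.names = FALSE)
  invisible(x)
}
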