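#' Least-angle regression with the lasso modification
#'
#' Computes the full piecewise-linear lasso coefficient path by least-angle
#' regression. Starting from the null model, the covariate most correlated
#' with the residual enters the active set and coefficients move along the
#' equiangular direction of the active covariates until either an inactive
#' covariate's correlation with the residual catches up (entry) or an active
#' coefficient crosses zero (the lasso modification: that covariate is
#' dropped and the direction recomputed). When `n > p` and the design has
#' full rank, the final step is the ordinary least-squares solution.
#'
#' Mallows' Cp is tracked along the path (see [mallows_cp()]), with the
#' error variance estimated from the full OLS residuals,
#' `RSS_full / (n - p - 1)`, unless `sigma2` is supplied.
#'
#' The intercept is handled by centering `y`; coefficients are reported on
#' the standardized-covariate scale.
#'
#' @param X Numeric matrix with standardized columns (mean 0, sd 1). An
#'   error is raised otherwise unless `check_standardized = FALSE` (columns
#'   must still be centered).
#' @param y Numeric response vector.
#' @param sigma2 Optional error-variance estimate for Cp.
#' @param max_steps Safety cap on path steps; default `min(n - 1, 8 * p)`
#'   breakpoints, guaranteeing termination on degenerate inputs.
#' @param check_standardized Verify column means/sds; see above.
#' @param tol Numerical tolerance for correlation ties and zero crossings.
#' @return An object of class `lars_path`: a list with `steps` (each with
#'   `active`, `beta`, `rss`, `df`), `cp` (per-step Mallows' Cp),
#'   `sigma2_hat`, `selected_step` (1-based index of the minimum-Cp step),
#'   `intercept` (mean of `y`), `column_names`, `n`, and `notes` (entry-tie
#'   and rank-deficiency messages).
#' @seealso [select_min_cp()], [predict.lars_selected()]
#' @export
lars_fit <- function(X, y, sigma2 = NULL, max_steps = NULL,
                     check_standardized = TRUE, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stopf("need at least 2 observations")
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  cm <- colMeans(X)
  if (check_standardized) {
    cs <- apply(X, 2, stats::sd)
    if (any(abs(cm) > 1e-6) || any(abs(cs - 1) > 1e-6)) {
      stopf("X columns must be standardized (mean 0, sd 1); see standardize_covariates()")
    }
  } else if (any(abs(cm) > 1e-6)) {
    stopf("X columns must at least be centered")
  }
  if (is.null(max_steps)) max_steps <- min(n - 1, 8L * p)

  ybar <- mean(y)
  resid <- y - ybar
  beta <- stats::setNames(numeric(p), colnames(X))
  active <- integer(0)
  ignored <- integer(0)        # entrants skipped for rank deficiency
  k_max <- min(p, n - 1)       # saturation: LARS fits at most n-1 covariates
  notes <- character(0)

  steps <- list(list(active = character(0), beta = beta, rss = sum(resid^2),
                     df = 1L))
  just_dropped <- FALSE

  while (length(steps) <= max_steps) {
    cvec <- drop(crossprod(X, resid))
    Cmax <- max(abs(cvec))
    if (Cmax < tol * max(1, sum(y^2))) break

    if (!just_dropped) {
      entered <- FALSE
      repeat {
        candidates <- setdiff(which(abs(cvec) > Cmax - tol * max(1, Cmax)),
                              c(active, ignored))
        if (length(candidates) == 0 || length(active) >= k_max) break
        if (length(candidates) > 1) {
          notes <- c(notes, sprintf(
            "entry tie at |c| = %.6g between %s; '%s' entered (column order)",
            Cmax, paste(colnames(X)[candidates], collapse = ", "),
            colnames(X)[candidates[1]]))
        }
        entrant <- candidates[1]
        trial <- c(active, entrant)
        G <- crossprod(X[, trial, drop = FALSE])
        ok <- tryCatch({solve(G, rep(1, length(trial))); TRUE},
                       error = function(e) FALSE)
        if (ok && rcond(G) >= 1e-12) {
          active <- trial
          entered <- TRUE
          break
        }
        # skip the offending entrant and keep moving with the current set
        notes <- c(notes, sprintf(
          "covariate '%s' skipped: adding it makes the active Gram matrix rank deficient",
          colnames(X)[entrant]))
        warnf("covariate '%s' skipped (rank-deficient active set)",
              colnames(X)[entrant])
        ignored <- c(ignored, entrant)
      }
      if (!entered && length(active) == 0) break
      if (!entered && length(active) >= k_max) break
    }
    just_dropped <- FALSE

    s <- sign(cvec[active])
    Xa <- sweep(X[, active, drop = FALSE], 2, s, "*")
    G <- crossprod(Xa)
    w <- solve(G, rep(1, length(active)))
    Anorm <- 1 / sqrt(sum(w))
    w <- Anorm * w
    u <- drop(Xa %*% w)                 # equiangular unit vector
    d <- stats::setNames(s * w, colnames(X)[active])  # move in beta space

    inactive <- setdiff(seq_len(p), c(active, ignored))
    if (length(inactive)) {
      a <- drop(crossprod(X[, inactive, drop = FALSE], u))
      cj <- cvec[inactive]
      g1 <- (Cmax - cj) / (Anorm - a)
      g2 <- (Cmax + cj) / (Anorm + a)
      gammas <- c(g1, g2)
      gammas <- gammas[is.finite(gammas) & gammas > tol]
      gamma <- if (length(gammas)) min(gammas, Cmax / Anorm) else Cmax / Anorm
    } else {
      gamma <- Cmax / Anorm             # drive straight to the LS solution
    }

    # Lasso modification: an active coefficient hitting zero exits the set.
    drop_idx <- NA_integer_
    zcross <- -beta[active] / d
    pos <- which(is.finite(zcross) & zcross > tol)
    if (length(pos)) {
      gmin <- min(zcross[pos])
      if (gmin < gamma - tol) {
        gamma <- gmin
        drop_idx <- active[pos[which.min(zcross[pos])]]
      }
    }

    beta[active] <- beta[active] + gamma * d
    resid <- resid - gamma * u

    if (!is.na(drop_idx)) {
      beta[drop_idx] <- 0
      active <- setdiff(active, drop_idx)
      just_dropped <- TRUE
      ignored <- integer(0)             # a dropped variable may re-enter
    }

    steps[[length(steps) + 1L]] <- list(active = colnames(X)[active],
                                        beta = beta, rss = sum(resid^2),
                                        df = length(active) + 1L)
  }

  if (is.null(sigma2)) {
    if (n > p + 1) {
      fit <- stats::lm.fit(cbind(1, X), y)
      sigma2 <- max(sum(fit$residuals^2) / (n - p - 1), .Machine$double.eps)
    } else {
      stopf("n <= p + 1: supply `sigma2` explicitly for Cp")
    }
  }
  path <- structure(list(steps = steps, sigma2_hat = sigma2,
                         intercept = ybar, column_names = colnames(X),
                         n = n, notes = notes),
                    class = "lars_path")
  path$cp <- mallows_cp(path, sigma2)
  path$selected_step <- which.min(path$cp)  # first index on ties: sparser model
  path
}

#' Mallows' Cp along a regularization path
#'
#' `Cp_k = RSS_k / sigma2 - n + 2 * df_k`, with `df_k` the number of active
#' covariates plus one for the intercept at step `k`. Under the classical
#' variance estimator `RSS_full / (n - p - 1)`, the full OLS step has
#' `Cp = p + 1` exactly.
#'
#' @param path A [lars_fit()] result (or any list of steps with `rss`, `df`).
#' @param sigma2 Error-variance estimate; must be positive.
#' @return Numeric vector of Cp values, one per step.
#' @export
mallows_cp <- function(path, sigma2 = path$sigma2_hat) {
  if (!is_scalar_number(sigma2) || sigma2 <= 0) stopf("`sigma2` must be > 0")
  vapply(path$steps, function(st) st$rss / sigma2 - path$n + 2 * st$df,
         numeric(1))
}

#' Select the minimum-Cp model from a LARS-lasso path
#'
#' Returns the coefficients of the first path step attaining the minimal
#' Mallows' Cp; ties are broken toward the earlier (sparser) step.
#'
#' @param path A [lars_fit()] result.
#' @return An object of class `lars_selected`: `coefficients` (full named
#'   vector, zeros for inactive covariates), `intercept`, `active_set`,
#'   `step`, `cp`.
#' @export
select_min_cp <- function(path) {
  stopifnot(inherits(path, "lars_path"))
  if (!length(path$steps)) stopf("empty path")
  k <- which.min(path$cp)
  st <- path$steps[[k]]
  structure(list(coefficients = st$beta, intercept = path$intercept,
                 active_set = st$active, step = k, cp = path$cp[k]),
            class = "lars_selected")
}

#' @export
coef.lars_selected <- function(object, ...) object$coefficients

#' Predict from a minimum-Cp LARS-lasso model
#'
#' @param object A [select_min_cp()] result.
#' @param newdata Covariate matrix on the same standardized scale the model
#'   was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 responses.
#' @export
predict.lars_selected <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  b <- object$coefficients[colnames(newdata)]
  drop(object$intercept + newdata %*% b)
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("LARS-lasso path: %d steps, n = %d, p = %d\n",
              length(x$steps), x$n, length(x$column_names)))
  cat(sprintf("  sigma2_hat = %.4g; min Cp = %.3f at step %d (%d active)\n",
              x$sigma2_hat, min(x$cp), x$selected_step,
              length(x$steps[[x$selected_step]]$active)))
  invisible(x)
}

#' @export
print.lars_selected <- function(x, ...) {
  cat(sprintf("Minimum-Cp model (step %d, Cp = %.3f)\n", x$step, x$cp))
  if (length(x$active_set)) {
    print(round(x$coefficients[x$active_set], 4))
  } else {
    cat("  (intercept-only model)\n")
  }
  invisible(x)
}
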