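#' Censoring-aware Pearson correlation by repeated random imputation
#'
#' Left-censored entries (non-detects) are replaced, independently in each
#' of `n_reps` repetitions, by a fresh Uniform(0, limit) draw on the linear
#' concentration scale; each repetition's values are log-transformed with
#' the indicator's own transform and a Pearson r is computed. The reported
#' correlation is the average r over repetitions, with its standard
#' deviation; significance comes from a t-test on the averaged r,
#' `t = mean_r * sqrt(n - 2) / sqrt(1 - mean_r^2)` against Student's t with
#' `n - 2` degrees of freedom (two-sided).
#'
#' With no censored entries the imputation is inert: `mean_r` equals the
#' plain Pearson r exactly and `sd_r = 0`.
#'
#' @param x,y Linear-scale concentration vectors (equal length).
#' @param x_censored,y_censored Logical censoring flags.
#' @param x_limit,y_limit Detection limit / LLQ per series (linear units).
#' @param x_transform,y_transform `"log10"` or `"log10_plus1"` per series.
#' @param n_reps Number of imputation repetitions, default 100.
#' @param seed Integer seed.
#' @param impute_scale `"linear"` (default; Uniform(0, limit) on the
#'   concentration scale) or `"log"` (uniform on the log10 scale between
#'   `log10(limit) - 2` and `log10(limit)`).
#' @return An object of class `censored_correlation`: `mean_r`, `sd_r`,
#'   `p_value`, `n_pairs`, `n_reps`, `seed`, `r_reps`.
#' @export
censored_pearson <- function(x, y, x_censored = rep(FALSE, length(x)),
                             y_censored = rep(FALSE, length(y)),
                             x_limit = NA_real_, y_limit = NA_real_,
                             x_transform = "log10", y_transform = "log10",
                             n_reps = 100, seed = 1L,
                             impute_scale = c("linear", "log")) {
  impute_scale <- match.arg(impute_scale)
  stopifnot(length(x) == length(y))
  complete <- !is.na(x) & !is.na(y)
  x <- x[complete]; y <- y[complete]
  xc <- x_censored[complete]; yc <- y_censored[complete]
  n <- length(x)
  if (n < 3) stopf("fewer than 3 complete pairs (%d)", n)
  if (any(xc) && (!is_scalar_number(x_limit) || x_limit <= 0)) {
    stopf("x has censored entries but no positive `x_limit`")
  }
  if (any(yc) && (!is_scalar_number(y_limit) || y_limit <= 0)) {
    stopf("y has censored entries but no positive `y_limit`")
  }

  trans <- function(v, transform) {
    if (transform == "log10_plus1") log10(v + 1) else log10(v)
  }
  draw <- function(k, limit) {
    if (impute_scale == "linear") stats::runif(k, 0, limit)
    else 10^stats::runif(k, log10(limit) - 2, log10(limit))
  }

  lx <- trans(ifelse(xc, NA, x), x_transform)
  ly <- trans(ifelse(yc, NA, y), y_transform)

  r_reps <- with_seed(seed, vapply(seq_len(n_reps), function(rep) {
    xi <- lx; yi <- ly
    if (any(xc)) xi[xc] <- trans(draw(sum(xc), x_limit), x_transform)
    if (any(yc)) yi[yc] <- trans(draw(sum(yc), y_limit), y_transform)
    stats::cor(xi, yi)
  }, numeric(1)))

  mean_r <- mean(r_reps)
  sd_r <- if (any(xc) || any(yc)) stats::sd(r_reps) else 0
  if (abs(mean_r) >= 1) {
    p <- .Machine$double.xmin
    warnf("|mean_r| = 1: p-value underflows to the smallest representable positive value")
  } else {
    tstat <- mean_r * sqrt(n - 2) / sqrt(1 - mean_r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  structure(list(mean_r = mean_r, sd_r = sd_r, p_value = p,
                 n_pairs = n, n_reps = n_reps, seed = seed, r_reps = r_reps),
            class = "censored_correlation")
}

#' @export
print.censored_correlation <- function(x, ...) {
  cat(sprintf("Censored Pearson correlation: mean r = %.3f (sd %.4f over %d reps), n = %d, p = %.3g\n",
              x$mean_r, x$sd_r, x$n_reps, x$n_pairs, x$p_value))
  invisible(x)
}

#' Repeated-imputation correlation matrix for a set of indicators
#'
#' Applies [censored_pearson()] to every indicator pair of a
#' [beach_season], using pairwise-complete observations.
#'
#' @param season A [beach_season].
#' @param n_reps,seed,impute_scale Passed to [censored_pearson()].
#' @return List of symmetric matrices `mean_r` (unit diagonal), `sd_r`, and
#'   `p` (diagonal the smallest representable positive value).
#' @export
correlation_matrix <- function(season, n_reps = 100, seed = 1L,
                               impute_scale = "linear") {
  stopifnot(inherits(season, "beach_season"))
  inds <- season$indicators
  m <- length(inds)
  if (m < 2) stopf("need at least 2 indicators")
  R <- diag(m); S <- matrix(0, m, m)
  P <- matrix(.Machine$double.xmin, m, m)
  dimnames(R) <- dimnames(S) <- dimnames(P) <- list(inds, inds)
  pair_seed <- 0L
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      pair_seed <- pair_seed + 1L
      a <- inds[i]; b <- inds[j]
      ca <- season$events[[paste0(a, "_censored")]]
      cb <- season$events[[paste0(b, "_censored")]]
      if (all(ca, na.rm = TRUE) || all(cb, na.rm = TRUE)) {
        warnf("indicator pair %s/%s has an all-censored member; all its values are imputed", a, b)
      }
      cc <- censored_pearson(season$events[[paste0(a, "_conc")]],
                             season$events[[paste0(b, "_conc")]],
                             ca, cb,
                             season$limits[[a]], season$limits[[b]],
                             season$transforms[[a]], season$transforms[[b]],
                             n_reps = n_reps,
                             seed = child_seed(seed, pair_seed),
                             impute_scale = impute_scale)
      R[i, j] <- R[j, i] <- cc$mean_r
      S[i, j] <- S[j, i] <- cc$sd_r
      P[i, j] <- P[j, i] <- cc$p_value
    }
  }
  list(mean_r = R, sd_r = S, p = P, n_reps = n_reps, seed = seed)
}
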