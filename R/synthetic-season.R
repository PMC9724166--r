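#' Configuration for a simulated beach season
#'
#' Defines the generative model for one site-season of sampling events:
#' covariate marginals, target pairwise correlations among covariates
#' (imposed through a Gaussian copula), a sparse linear signal on the
#' standardized covariates in log10 response units, Gaussian noise, and a
#' left-censoring limit on the linear concentration scale.
#'
#' @param n_events Number of sampling events (rows); must be at least 10.
#' @param covariates List of covariate specifications, each a list with
#'   elements `name`, `family` (one of `"gaussian"`, `"lognormal"`,
#'   `"nbinom"`, `"direction"`), `mean` and `dispersion`. For `gaussian`,
#'   `mean`/`dispersion` are the mean and standard deviation; for
#'   `lognormal` the log-scale mean and sd; for `nbinom` the mean and size;
#'   `direction` ignores both and is uniform on [0, 360).
#' @param target_correlations Data frame (or list of 3-element lists) with
#'   columns `a`, `b`, `r`: target Pearson correlations between named
#'   covariate pairs on the latent Gaussian scale. Unlisted pairs are
#'   independent.
#' @param true_coefficients Named numeric vector: coefficient of each named
#'   covariate on the standardized scale, in log10 response units.
#'   Covariates not named get coefficient zero.
#' @param intercept Intercept of the log10 response.
#' @param noise_sd Standard deviation of the Gaussian noise on the log10
#'   response; must be positive.
#' @param censor_limit Left-censoring limit in linear concentration units.
#' @param response_transform `"log10"` or `"log10_plus1"`: how observed
#'   concentrations relate to the log10-scale response.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `season_sim_config`.
#' @export
season_sim_config <- function(n_events,
                              covariates,
                              target_correlations = NULL,
                              true_coefficients = numeric(0),
                              intercept = 2,
                              noise_sd = 0.4,
                              censor_limit = 0,
                              response_transform = c("log10", "log10_plus1"),
                              seed = 1L) {
  response_transform <- match.arg(response_transform)
  if (!is_scalar_number(n_events) || n_events < 10) {
    stopf("`n_events` must be a single number >= 10 (got %s)", format(n_events))
  }
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    stopf("`noise_sd` must be > 0")
  }
  if (!is_scalar_number(censor_limit) || censor_limit < 0) {
    stopf("`censor_limit` must be >= 0")
  }
  covariates <- lapply(covariates, function(cv) {
    cv$family <- match.arg(cv$family, c("gaussian", "lognormal", "nbinom", "direction"))
    if (is.null(cv$name)) stopf("every covariate spec needs a `name`")
    cv
  })
  names(covariates) <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(names(covariates))) stopf("duplicate covariate names")
  if (!is.null(target_correlations)) {
    target_correlations <- as.data.frame(do.call(rbind, lapply(
      if (is.data.frame(target_correlations)) split(target_correlations, seq_len(nrow(target_correlations)))
      else target_correlations,
      function(p) data.frame(a = as.character(p[[1]]), b = as.character(p[[2]]),
                             r = as.numeric(p[[3]]))
    )))
    bad <- setdiff(unique(c(target_correlations$a, target_correlations$b)),
                   names(covariates))
    if (length(bad)) stopf("target correlation names not in covariates: %s",
                           paste(bad, collapse = ", "))
    if (any(abs(target_correlations$r) > 1)) stopf("correlations must lie in [-1, 1]")
  }
  unknown <- setdiff(names(true_coefficients), names(covariates))
  if (length(unknown)) {
    stopf("true_coefficients name unknown covariates: %s", paste(unknown, collapse = ", "))
  }
  structure(list(n_events = as.integer(n_events), covariates = covariates,
                 target_correlations = target_correlations,
                 true_coefficients = true_coefficients, intercept = intercept,
                 noise_sd = noise_sd, censor_limit = censor_limit,
                 response_transform = response_transform, seed = as.integer(seed)),
            class = "season_sim_config")
}

# Assemble the latent Gaussian correlation matrix and verify it is PSD.
latent_correlation <- function(config) {
  nm <- names(config$covariates)
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  tc <- config$target_correlations
  if (!is.null(tc)) {
    for (i in seq_len(nrow(tc))) {
      fam_a <- config$covariates[[tc$a[i]]]$family
      fam_b <- config$covariates[[tc$b[i]]]$family
      if (abs(tc$r[i]) >= 1 - 1e-12 && fam_a != fam_b) {
        stopf("correlation %.2f between '%s' and '%s' is unattainable: perfect correlation conflicts with differing marginal families (%s vs %s)",
              tc$r[i], tc$a[i], tc$b[i], fam_a, fam_b)
      }
      R[tc$a[i], tc$b[i]] <- R[tc$b[i], tc$a[i]] <- tc$r[i]
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stopf("target correlations are not jointly attainable (matrix not positive semi-definite); check pair '%s'/'%s' and its companions",
            tc$a[1], tc$b[1])
    }
  }
  R
}

#' Simulate correlated beach-season covariates
#'
#' Draws `n_events` rows of covariates via a Gaussian copula: latent
#' multivariate normal variates with the configured correlation structure are
#' pushed through each covariate's marginal quantile function. Gaussian
#' marginals reproduce the target Pearson correlations exactly in
#' distribution; count and circular marginals reproduce them approximately.
#'
#' @param config A [season_sim_config()].
#' @return A data frame with `n_events` rows, one column per covariate.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "season_sim_config"))
  R <- latent_correlation(config)
  nm <- names(config$covariates)
  p <- length(nm)
  with_seed(child_seed(config$seed, 1L), {
    # Draw latent normals through a (PSD-safe) square root of R.
    es <- eigen(R, symmetric = TRUE)
    L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p)
    Z <- matrix(stats::rnorm(config$n_events * p), config$n_events, p) %*% t(L)
    colnames(Z) <- nm
    out <- as.data.frame(lapply(nm, function(v) {
      cv <- config$covariates[[v]]
      u <- stats::pnorm(Z[, v])
      switch(cv$family,
        gaussian  = cv$mean + cv$dispersion * Z[, v],
        lognormal = stats::qlnorm(u, meanlog = cv$mean, sdlog = cv$dispersion),
        nbinom    = stats::qnbinom(pmin(u, 1 - 1e-12), mu = cv$mean, size = cv$dispersion),
        direction = (u * 360) %% 360
      )
    }))
    names(out) <- nm
    out
  })
}

#' Simulate censored indicator concentrations for a covariate table
#'
#' The log10 response is a sparse linear model in the standardized
#' covariates plus Gaussian noise; the observed concentration is its
#' back-transform, and left-censoring is applied at the configured limit
#' after the noise (measurement-level censoring, as detection limits act on
#' assays).
#'
#' @param covariates Data frame from [simulate_covariates()].
#' @param config A [season_sim_config()].
#' @return An object of class `simulated_season` with elements `covariates`,
#'   `true_log10_response`, `linear_predictor`, `observed_concentration`,
#'   `censored`, and `truth` (coefficients, intercept, noise_sd,
#'   censor_limit, transform).
#' @export
simulate_indicators <- function(covariates, config) {
  stopifnot(inherits(config, "season_sim_config"))
  unknown <- setdiff(names(config$true_coefficients), names(covariates))
  if (length(unknown)) {
    stopf("coefficients name covariates absent from the table: %s",
          paste(unknown, collapse = ", "))
  }
  n <- nrow(covariates)
  eta <- rep(config$intercept, n)
  for (v in names(config$true_coefficients)) {
    x <- covariates[[v]]
    eta <- eta + config$true_coefficients[[v]] * (x - mean(x)) / stats::sd(x)
  }
  resp <- with_seed(child_seed(config$seed, 2L),
                    eta + stats::rnorm(n, 0, config$noise_sd))
  conc <- switch(config$response_transform,
                 log10 = 10^resp,
                 log10_plus1 = pmax(10^resp - 1, 0))
  censored <- conc < config$censor_limit
  structure(list(covariates = covariates,
                 true_log10_response = resp,
                 linear_predictor = eta,
                 observed_concentration = conc,
                 censored = censored,
                 truth = list(coefficients = config$true_coefficients,
                              intercept = config$intercept,
                              noise_sd = config$noise_sd,
                              censor_limit = config$censor_limit,
                              transform = config$response_transform)),
            class = "simulated_season")
}

#' Simulate a complete beach season for one indicator
#'
#' Convenience wrapper: covariates plus one censored indicator, packaged as a
#' [beach_season] object ready for [build_model_frame()].
#'
#' @inheritParams simulate_indicators
#' @param site Site identifier.
#' @param indicator Indicator name used for the concentration columns.
#' @param beach_orientation Onshore (water-to-land) azimuth of the beach, degrees.
#' @return A `beach_season` object; the generating `simulated_season` is
#'   attached as attribute `"truth"`.
#' @export
simulate_season <- function(config, site = "site1", indicator = "indicator",
                            beach_orientation = 180) {
  cov <- simulate_covariates(config)
  sim <- simulate_indicators(cov, config)
  events <- cbind(
    data.frame(date = as.Date("2021-06-01") + seq_len(config$n_events) - 1L),
    cov
  )
  events[[paste0(indicator, "_conc")]] <- sim$observed_concentration
  events[[paste0(indicator, "_censored")]] <- sim$censored
  season <- beach_season(site = site, events = events,
                         indicators = indicator,
                         limits = stats::setNames(config$censor_limit, indicator),
                         transforms = stats::setNames(config$response_transform, indicator),
                         beach_orientation = beach_orientation)
  attr(season, "truth") <- sim
  season
}

#' @export
print.simulated_season <- function(x, ...) {
  cat(sprintf("Simulated beach season: %d events, %d covariates, %.1f%% censored\n",
              nrow(x$covariates), ncol(x$covariates), 100 * mean(x$censored)))
  invisible(x)
}
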