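#' One site-season of beach monitoring data
#'
#' Container for a raw beach-season table: one row per sampling event with
#' covariate measurements plus, per microbial indicator, a linear-scale
#' concentration column `<indicator>_conc` and a censoring flag
#' `<indicator>_censored` (TRUE when the measurement fell below the
#' detection limit or lower limit of quantification).
#'
#' @param site Site identifier.
#' @param events Data frame of events: a `date` column, covariate columns,
#'   and `<indicator>_conc` / `<indicator>_censored` pairs.
#' @param indicators Character vector of indicator names present.
#' @param limits Named numeric vector: detection limit or LLQ per indicator,
#'   linear units.
#' @param transforms Named character vector per indicator: `"log10"` or
#'   `"log10_plus1"` (the latter for coliphage counts that can fall below 1).
#' @param beach_orientation Onshore azimuth (degrees, water to land) used for
#'   wind decomposition; NA if unknown.
#' @return An object of class `beach_season`.
#' @export
beach_season <- function(site, events, indicators, limits, transforms,
                         beach_orientation = NA_real_) {
  for (ind in indicators) {
    cc <- paste0(ind, "_conc")
    fc <- paste0(ind, "_censored")
    if (!cc %in% names(events) || !fc %in% names(events)) {
      stopf("events lack columns '%s'/'%s' for indicator '%s'", cc, fc, ind)
    }
    if (any(events[[cc]] < 0, na.rm = TRUE)) {
      stopf("negative concentrations for indicator '%s'", ind)
    }
    if (!ind %in% names(limits)) stopf("no detection limit given for '%s'", ind)
    if (!ind %in% names(transforms)) stopf("no transform given for '%s'", ind)
  }
  structure(list(site = site, events = events, indicators = indicators,
                 limits = limits, transforms = transforms,
                 beach_orientation = beach_orientation),
            class = "beach_season")
}

#' @export
print.beach_season <- function(x, ...) {
  cat(sprintf("Beach season '%s': %d events, indicators: %s\n",
              x$site, nrow(x$events), paste(x$indicators, collapse = ", ")))
  invisible(x)
}

# Covariate columns of a beach_season = everything except date/site and the
# indicator concentration/censoring pairs.
season_covariate_names <- function(season) {
  drop <- c("date", "site",
            paste0(season$indicators, "_conc"),
            paste0(season$indicators, "_censored"))
  setdiff(names(season$events), drop)
}

#' Log10 response transform with half-limit substitution for censored values
#'
#' Censored entries are replaced, on the linear scale, by one half of the
#' detection limit / LLQ (or by the limit itself when
#' `censored_substitution = "limit"`), then the chosen transform is applied.
#' The `log10_plus1` variant is intended for coliphage counts, where
#' concentrations below 1 would otherwise give negative log10 values.
#'
#' @param concentration Numeric vector, linear units.
#' @param censored Logical vector of the same length.
#' @param limit Detection limit or LLQ in linear units; must be positive
#'   when any value is censored.
#' @param transform `"log10"` or `"log10_plus1"`.
#' @param censored_substitution `"half_limit"` (default) or `"limit"`.
#' @return Numeric vector of log10-scale responses.
#' @export
transform_response <- function(concentration, censored,
                               limit,
                               transform = c("log10", "log10_plus1"),
                               censored_substitution = c("half_limit", "limit")) {
  transform <- match.arg(transform)
  censored_substitution <- match.arg(censored_substitution)
  stopifnot(length(concentration) == length(censored))
  if (any(censored) && (!is_scalar_number(limit) || limit <= 0)) {
    stopf("`limit` must be a positive number when censored values are present")
  }
  sub <- if (censored_substitution == "half_limit") limit / 2 else limit
  v <- ifelse(censored, sub, concentration)
  if (transform == "log10") {
    bad <- !censored & concentration <= 0
    if (any(bad, na.rm = TRUE)) {
      stopf("non-positive uncensored concentration under a plain log10 transform (row %d); such an observation should carry a censoring flag",
            which(bad)[1])
    }
    log10(v)
  } else {
    log10(v + 1)
  }
}

#' Decompose wind into alongshore and onshore/offshore components
#'
#' Wind direction follows the meteorological convention (degrees the wind
#' blows *from*); it is converted to the direction the wind blows *toward*
#' before projection. `beach_orientation_deg` is the shore-normal azimuth
#' pointing from the water onto the land, so `wind_o > 0` means onshore flow
#' and `wind_a` is the alongshore component (positive to the right of an
#' observer facing the land).
#'
#' @param speed Wind speed (any unit), non-negative.
#' @param direction_deg Meteorological wind direction, degrees.
#' @param beach_orientation_deg Onshore shore-normal azimuth, degrees.
#' @return Data frame with columns `wind_a` (alongshore) and `wind_o`
#'   (onshore/offshore); `wind_a^2 + wind_o^2 = speed^2` identically.
#' @export
decompose_wind <- function(speed, direction_deg, beach_orientation_deg) {
  if (any(speed < 0, na.rm = TRUE)) stopf("wind speed must be non-negative")
  toward <- (direction_deg + 180) %% 360
  theta <- (toward - beach_orientation_deg) * pi / 180
  data.frame(wind_a = speed * sin(theta), wind_o = speed * cos(theta))
}

#' Standardize covariate columns to mean zero and unit standard deviation
#'
#' @param X Numeric matrix or data frame.
#' @param params Optional list of `mean`/`sd` vectors from a previous call;
#'   when given, those parameters are applied instead of being re-estimated
#'   (used to score new data with a training-set standardization).
#' @return List with `Z` (standardized matrix) and `params`
#'   (`list(mean =, sd =)` enabling exact inversion).
#' @export
standardize_covariates <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(params)) {
    m <- colMeans(X)
    s <- apply(X, 2, stats::sd)
    zero <- which(s == 0 | !is.finite(s))
    if (length(zero)) {
      stopf("zero-variance column(s): %s", paste(colnames(X)[zero], collapse = ", "))
    }
    params <- list(mean = m, sd = s)
  }
  Z <- sweep(sweep(X, 2, params$mean[colnames(X)]), 2, params$sd[colnames(X)], "/")
  list(Z = Z, params = params)
}

#' Invert a standardization
#'
#' @param Z Standardized matrix.
#' @param params `list(mean =, sd =)` as returned by
#'   [standardize_covariates()].
#' @return Matrix on the original scale.
#' @export
invert_standardization <- function(Z, params) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("x", seq_len(ncol(Z)))
  sweep(sweep(Z, 2, params$sd[colnames(Z)], "*"), 2, params$mean[colnames(Z)], "+")
}

#' Drop one member of each highly collinear covariate pair
#'
#' Flags every covariate pair with `|r| >= threshold` and drops exactly one
#' member per flagged pair. A covariate named in `exclude` is always the one
#' dropped from its pairs; otherwise the member with the larger mean
#' absolute correlation to all other covariates is dropped. The procedure is
#' greedy and repeats until no retained pair exceeds the threshold, so a
#' mutually collinear triple keeps exactly one survivor.
#'
#' @param X Numeric matrix or data frame of covariates.
#' @param threshold Absolute Pearson correlation at or above which a pair is
#'   flagged; in (0, 1].
#' @param exclude Character vector of covariates to drop preferentially when
#'   they appear in a flagged pair.
#' @param pairs Optional two-column matrix/data frame restricting which
#'   pairs are checked; default all pairs.
#' @return List with `retained` (character), `dropped` (character) and
#'   `report` (data frame: var_a, var_b, r, dropped).
#' @export
collinearity_filter <- function(X, threshold = 0.8, exclude = NULL, pairs = NULL) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    stopf("`threshold` must lie in (0, 1]")
  }
  X <- as.matrix(X)
  vars <- colnames(X)
  R <- stats::cor(X, use = "pairwise.complete.obs")
  allowed <- function(a, b) {
    if (is.null(pairs)) return(TRUE)
    any((pairs[, 1] == a & pairs[, 2] == b) | (pairs[, 1] == b & pairs[, 2] == a))
  }
  retained <- vars
  report <- data.frame(var_a = character(0), var_b = character(0),
                       r = numeric(0), dropped = character(0))
  repeat {
    flagged <- NULL
    for (i in seq_along(retained)) {
      for (j in seq_along(retained)) {
        if (j <= i) next
        a <- retained[i]; b <- retained[j]
        if (!allowed(a, b)) next
        if (abs(R[a, b]) >= threshold) { flagged <- c(a, b); break }
      }
      if (!is.null(flagged)) break
    }
    if (is.null(flagged)) break
    a <- flagged[1]; b <- flagged[2]
    drop <- if (a %in% exclude && !(b %in% exclude)) a
            else if (b %in% exclude && !(a %in% exclude)) b
            else {
      # fall back: drop the member more entangled with everything else
      ma <- mean(abs(R[a, setdiff(retained, a)]))
      mb <- mean(abs(R[b, setdiff(retained, b)]))
      if (ma >= mb) a else b
    }
    report <- rbind(report, data.frame(var_a = a, var_b = b, r = R[a, b],
                                       dropped = drop))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, dropped = setdiff(vars, retained), report = report)
}

#' Summary statistics for indicator log10 concentrations
#'
#' Computes, per indicator, the sample size, censored count, and the
#' minimum, maximum, mean, standard deviation and coefficient of variation
#' of the log10 values after half-limit substitution of censored entries.
#'
#' @param season A [beach_season].
#' @param censored_substitution Passed to [transform_response()].
#' @return Data frame with one row per indicator: `indicator`, `n`,
#'   `n_censored`, `min`, `max`, `mean`, `sd`, `cv`, `all_censored`.
#' @export
describe_indicators <- function(season, censored_substitution = "half_limit") {
  stopifnot(inherits(season, "beach_season"))
  rows <- lapply(season$indicators, function(ind) {
    conc <- season$events[[paste0(ind, "_conc")]]
    cens <- season$events[[paste0(ind, "_censored")]]
    keep <- !is.na(conc) & !is.na(cens)
    conc <- conc[keep]; cens <- cens[keep]
    if (length(conc) < 2) stopf("indicator '%s' has fewer than 2 usable values", ind)
    lg <- transform_response(conc, cens, season$limits[[ind]],
                             season$transforms[[ind]], censored_substitution)
    data.frame(indicator = ind, n = length(lg), n_censored = sum(cens),
               min = min(lg), max = max(lg), mean = mean(lg),
               sd = stats::sd(lg), cv = stats::sd(lg) / mean(lg),
               all_censored = all(cens))
  })
  do.call(rbind, rows)
}

#' Pooled non-detect frequency across sites
#'
#' The percentage of measurements below the detection limit / LLQ when
#' per-site censored counts and totals are pooled.
#'
#' @param n_censored Integer vector of below-limit counts, one per site.
#' @param n_total Integer vector of total measurement counts, same length.
#' @return Percentage in [0, 100].
#' @export
nondetect_frequency <- function(n_censored, n_total) {
  stopifnot(length(n_censored) == length(n_total), all(n_total > 0))
  100 * sum(n_censored) / sum(n_total)
}

#' Build a modeling frame from a beach season
#'
#' Full preprocessing for one indicator: optional wind decomposition
#' (replacing `wind_speed`/`wind_direction` with `wind_a`/`wind_o`),
#' row-wise deletion of events with missing covariates or response,
#' collinearity filtering, covariate standardization, and the censoring-aware
#' log10 response transform.
#'
#' @param season A [beach_season].
#' @param indicator Which indicator to model.
#' @param collinearity_threshold Passed to [collinearity_filter()].
#' @param exclude Covariates to drop preferentially from collinear pairs.
#' @param censored_substitution Passed to [transform_response()].
#' @return An object of class `model_frame`: standardized matrix `X`, raw
#'   matrix `X_raw`, response `y`, `column_names`, `standardization_params`,
#'   `dropped_covariates` (with reasons), `site`, `indicator`, `n_dropped_rows`.
#' @export
build_model_frame <- function(season, indicator,
                              collinearity_threshold = 0.8,
                              exclude = NULL,
                              censored_substitution = "half_limit") {
  stopifnot(inherits(season, "beach_season"))
  if (!indicator %in% season$indicators) stopf("unknown indicator '%s'", indicator)
  ev <- season$events
  covs <- season_covariate_names(season)

  if (all(c("wind_speed", "wind_direction") %in% covs) &&
      is.finite(season$beach_orientation)) {
    w <- decompose_wind(ev$wind_speed, ev$wind_direction, season$beach_orientation)
    ev$wind_a <- w$wind_a
    ev$wind_o <- w$wind_o
    ev$wind_speed <- ev$wind_direction <- NULL
    covs <- c(setdiff(covs, c("wind_speed", "wind_direction")), "wind_a", "wind_o")
  }

  conc <- ev[[paste0(indicator, "_conc")]]
  cens <- ev[[paste0(indicator, "_censored")]]
  keep <- stats::complete.cases(ev[covs]) & !is.na(conc) & !is.na(cens)
  n_dropped_rows <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]

  X_raw <- as.matrix(ev[covs])
  rownames(X_raw) <- NULL
  filt <- collinearity_filter(X_raw, threshold = collinearity_threshold,
                              exclude = exclude)
  X_raw <- X_raw[, filt$retained, drop = FALSE]
  std <- standardize_covariates(X_raw)
  y <- transform_response(conc[keep], cens[keep], season$limits[[indicator]],
                          season$transforms[[indicator]], censored_substitution)
  dropped <- if (nrow(filt$report)) {
    data.frame(covariate = filt$report$dropped,
               reason = sprintf("|r| = %.3f with %s",
                                abs(filt$report$r),
                                ifelse(filt$report$dropped == filt$report$var_a,
                                       filt$report$var_b, filt$report$var_a)))
  } else {
    data.frame(covariate = character(0), reason = character(0))
  }
  structure(list(X = std$Z, X_raw = X_raw, y = y,
                 column_names = colnames(std$Z),
                 standardization_params = std$params,
                 dropped_covariates = dropped,
                 censored = cens[keep],
                 site = season$site, indicator = indicator,
                 n_dropped_rows = n_dropped_rows),
            class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf("Model frame: %s / %s, %d events x %d covariates (%d dropped: %s)\n",
              x$site, x$indicator, nrow(x$X), ncol(x$X),
              nrow(x$dropped_covariates),
              if (nrow(x$dropped_covariates)) paste(x$dropped_covariates$covariate, collapse = ", ")
              else "none"))
  invisible(x)
}
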