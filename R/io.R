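# CSV/JSON round-trip I/O. Dialect: UTF-8, comma separator, "." decimal,
# ISO-8601 dates, "ND" sentinel for undetected Ct, "NA" for unavailable
# covariate cells.

#' Write a beach season to CSV (with a JSON sidecar)
#'
#' One row per event: `site`, `date`, covariate columns, then per-indicator
#' `<name>_conc` / `<name>_censored` pairs. Limits, transforms and beach
#' orientation (and simulation ground truth, when present) go to
#' `<path>.json`.
#'
#' @param season A [beach_season].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_season_csv <- function(season, path) {
  stopifnot(inherits(season, "beach_season"))
  df <- cbind(data.frame(site = season$site), season$events)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(site = season$site, indicators = season$indicators,
                  limits = as.list(season$limits),
                  transforms = as.list(season$transforms),
                  beach_orientation = season$beach_orientation)
  truth <- attr(season, "truth")
  if (!is.null(truth)) {
    sidecar$truth <- list(coefficients = as.list(truth$truth$coefficients),
                          intercept = truth$truth$intercept,
                          noise_sd = truth$truth$noise_sd,
                          censor_limit = truth$truth$censor_limit)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a beach season written by [write_season_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist.
#' @return A [beach_season].
#' @export
read_season_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  site <- df$site[1]
  df$site <- NULL
  for (ind in meta$indicators) {
    df[[paste0(ind, "_censored")]] <- as.logical(df[[paste0(ind, "_censored")]])
  }
  beach_season(site = site, events = df, indicators = meta$indicators,
               limits = unlist(meta$limits), transforms = unlist(meta$transforms),
               beach_orientation = meta$beach_orientation)
}

#' Write a qPCR run to long-format CSV
#'
#' Columns: `well`, `role`, `assay`, `sample_id`, `run_id`,
#' `log10_copies`, `ct`; undetected Ct is written as `"ND"`. Gate reference
#' thresholds and scaling factors go to `<path>.json`.
#'
#' @param run A [qpcr_run].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_csv <- function(run, path) {
  stopifnot(inherits(run, "qpcr_run"))
  w <- run$wells
  w$ct <- ifelse(is.na(w$ct), "ND", sprintf("%.15g", w$ct))
  utils::write.csv(w, path, row.names = FALSE)
  jsonlite::write_json(list(gate_thresholds = run$gate_thresholds,
                            extract_fraction = run$extract_fraction,
                            volume_scaling = run$volume_scaling),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a qPCR run written by [write_qpcr_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist.
#' @return A [qpcr_run].
#' @export
read_qpcr_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(ct = "character"))
  ct <- rep(NA_real_, nrow(w))
  num <- w$ct != "ND"
  ct[num] <- as.numeric(w$ct[num])
  w$ct <- ct
  w$log10_copies <- as.numeric(w$log10_copies)
  qpcr_run(w, gate_thresholds = as.list(meta$gate_thresholds),
           extract_fraction = meta$extract_fraction,
           volume_scaling = meta$volume_scaling)
}

#' Write a model frame to CSV (with standardization sidecar)
#'
#' The CSV holds the raw (unstandardized) retained covariates and the log10
#' response; the sidecar records the standardization parameters, dropped
#' covariates and metadata, so the standardized matrix is reproduced
#' exactly on read.
#'
#' @param frame A [build_model_frame()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_frame <- function(frame, path) {
  stopifnot(inherits(frame, "model_frame"))
  df <- as.data.frame(frame$X_raw)
  df$.y <- frame$y
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(site = frame$site, indicator = frame$indicator,
         column_names = frame$column_names,
         standardization = list(mean = as.list(frame$standardization_params$mean),
                                sd = as.list(frame$standardization_params$sd)),
         dropped_covariates = frame$dropped_covariates,
         n_dropped_rows = frame$n_dropped_rows),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model frame written by [write_model_frame()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist.
#' @return A `model_frame`.
#' @export
read_model_frame <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  y <- df$.y
  X_raw <- as.matrix(df[setdiff(names(df), ".y")])
  params <- list(mean = unlist(meta$standardization$mean),
                 sd = unlist(meta$standardization$sd))
  Z <- standardize_covariates(X_raw, params = params)$Z
  dropped <- as.data.frame(meta$dropped_covariates)
  if (!nrow(dropped)) {
    dropped <- data.frame(covariate = character(0), reason = character(0))
  }
  structure(list(X = Z, X_raw = X_raw, y = y,
                 column_names = meta$column_names,
                 standardization_params = params,
                 dropped_covariates = dropped,
                 site = meta$site, indicator = meta$indicator,
                 n_dropped_rows = meta$n_dropped_rows),
            class = "model_frame")
}

#' Write a LARS-lasso path as a long CSV
#'
#' Columns: `step`, `covariate`, `coefficient`, `cp`.
#'
#' @param path_obj A [lars_fit()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lars_path_csv <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "lars_path"))
  rows <- do.call(rbind, lapply(seq_along(path_obj$steps), function(k) {
    st <- path_obj$steps[[k]]
    data.frame(step = k, covariate = names(st$beta),
               coefficient = unname(st$beta), cp = path_obj$cp[k])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a coefficient heatmap matrix
#'
#' Unavailable cells are written as `"NA"`; signs and the availability mask
#' round-trip exactly.
#'
#' @param M A [heatmap_matrix()] result.
#' @param path CSV path.
#' @return `path` (write) or a `coefficient_heatmap` matrix (read).
#' @export
write_heatmap_csv <- function(M, path) {
  utils::write.csv(as.data.frame(unclass(M)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
read_heatmap_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  class(M) <- c("coefficient_heatmap", class(M))
  M
}
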