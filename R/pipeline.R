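#' Default beach-season covariate suite
#'
#' The covariate set routinely measured for statistical water-quality
#' modeling, with plausible marginals, plus the three strongly collinear
#' pairs observed in Great Lakes monitoring data: UV254 absorbance with
#' dissolved organic carbon (r = 0.81), 24 h with 48 h cumulative rainfall
#' (r = 0.84), and 48 h with 72 h cumulative rainfall (r = 0.89).
#'
#' @return List with `covariates` (marginal specs for
#'   [season_sim_config()]) and `target_correlations`.
#' @export
default_covariate_suite <- function() {
  g <- function(name, mean, sd) list(name = name, family = "gaussian",
                                     mean = mean, dispersion = sd)
  ln <- function(name, meanlog, sdlog) list(name = name, family = "lognormal",
                                            mean = meanlog, dispersion = sdlog)
  nb <- function(name, mu, size) list(name = name, family = "nbinom",
                                      mean = mu, dispersion = size)
  list(
    covariates = list(
      g("water_temp", 21, 3),
      ln("turbidity", 1.5, 0.8),          # NTU, right-skewed
      g("dissolved_oxygen", 8.5, 1.2),
      g("conductivity", 300, 40),
      g("ph", 8.2, 0.25),
      ln("doc", 1.6, 0.35),
      ln("uv254", -2.4, 0.35),            # 1/m
      ln("wind_speed", 2.2, 0.45),        # km/h
      list(name = "wind_direction", family = "direction",
           mean = NA, dispersion = NA),
      g("air_temp", 23, 4),
      ln("wave_height", -1.3, 0.6),       # m
      g("humidity", 70, 10),
      ln("rain_24h", 0.3, 1.1),           # mm, very skewed
      ln("rain_48h", 0.8, 1.1),
      ln("rain_72h", 1.1, 1.1),
      g("par", 1.1, 0.35),
      nb("humans", 25, 2),
      nb("birds", 40, 1.5),
      nb("dogs", 2, 1)
    ),
    # the 24h/72h pair is implied by the two stated rainfall overlaps; 0.75
    # keeps the three-way block positive definite and physically coherent
    target_correlations = data.frame(
      a = c("uv254", "rain_24h", "rain_48h", "rain_24h"),
      b = c("doc", "rain_48h", "rain_72h", "rain_72h"),
      r = c(0.81, 0.84, 0.89, 0.75)
    )
  )
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Can also be loaded from a
#' YAML or JSON file via `pipeline_config_from_file()`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; every source of randomness in the
#'   pipeline derives from it.
#' @param sites Character vector of site names to simulate.
#' @param n_events Sampling events per site-season.
#' @param indicators Named list: indicator name -> list with `coefficients`
#'   (named, standardized scale), `intercept`, `noise_sd`, `censor_limit`,
#'   `transform`. Defaults to a seven-indicator suite mixing censored
#'   coliphage-like and qPCR-like responses.
#' @param k Cross-validation folds.
#' @param n_reps Imputation repetitions for censored correlations.
#' @param collinearity_threshold,exclude Passed to [build_model_frame()].
#' @param qpcr A [qpcr_sim_config()] for the qPCR stage, or `NULL` to skip.
#' @param dry_run Validate everything and list planned stages without
#'   computing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sites = c("east_beach", "west_beach"),
                            n_events = 70,
                            indicators = NULL,
                            k = 10,
                            n_reps = 100,
                            collinearity_threshold = 0.8,
                            exclude = c("uv254", "rain_48h"),
                            qpcr = qpcr_sim_config(),
                            dry_run = FALSE) {
  if (!is_scalar_number(seed) || seed != round(seed)) {
    stopf("config field `seed` must be an integer")
  }
  if (!is_scalar_number(n_events) || n_events < 10) {
    stopf("config field `n_events` must be >= 10")
  }
  if (!is_scalar_number(k) || k < 2) stopf("config field `k` must be >= 2")
  if (is.null(indicators)) indicators <- default_indicator_suite()
  suite <- default_covariate_suite()
  cov_names <- vapply(suite$covariates, `[[`, character(1), "name")
  for (ind in names(indicators)) {
    sp <- indicators[[ind]]
    bad <- setdiff(names(sp$coefficients), cov_names)
    if (length(bad)) {
      stopf("config field `indicators$%s$coefficients` names unknown covariates: %s",
            ind, paste(bad, collapse = ", "))
    }
    if (!sp$transform %in% c("log10", "log10_plus1")) {
      stopf("config field `indicators$%s$transform` must be log10 or log10_plus1", ind)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sites = sites,
                 n_events = as.integer(n_events), indicators = indicators,
                 k = k, n_reps = n_reps,
                 collinearity_threshold = collinearity_threshold,
                 exclude = exclude, qpcr = qpcr, dry_run = isTRUE(dry_run)),
            class = "pipeline_config")
}

# Seven indicators spanning the censoring/transform regimes the pipeline
# supports: two coliphage-like (log10(C+1), detection-limit censored), two
# cultured and three qPCR-like (plain log10, LLQ-censored).
default_indicator_suite <- function() {
  list(
    fplus_coliphage = list(
      coefficients = c(rain_72h = 0.20, wave_height = 0.15),
      intercept = 0.5, noise_sd = 0.55, censor_limit = 1.6,
      transform = "log10_plus1"),
    somatic_coliphage = list(
      coefficients = c(rain_72h = 0.30, turbidity = 0.25, wave_height = 0.20),
      intercept = 2.0, noise_sd = 0.45, censor_limit = 1.6,
      transform = "log10_plus1"),
    ecoli_culture = list(
      coefficients = c(turbidity = 0.30, rain_72h = 0.20, birds = 0.15),
      intercept = 2.0, noise_sd = 0.45, censor_limit = 1,
      transform = "log10"),
    entero_culture = list(
      coefficients = c(turbidity = 0.25, wave_height = 0.25, birds = 0.20),
      intercept = 1.8, noise_sd = 0.5, censor_limit = 1,
      transform = "log10"),
    ecoli_qpcr = list(
      coefficients = c(turbidity = 0.15, rain_72h = 0.10),
      intercept = 3.6, noise_sd = 0.5, censor_limit = 679,
      transform = "log10"),
    entero_qpcr = list(
      coefficients = c(turbidity = 0.30, wave_height = 0.30, doc = 0.20),
      intercept = 2.2, noise_sd = 0.45, censor_limit = 48,
      transform = "log10"),
    bacteroidales_qpcr = list(
      coefficients = c(turbidity = 0.25, rain_72h = 0.25),
      intercept = 4.7, noise_sd = 0.45, censor_limit = 720,
      transform = "log10")
  )
}

# Simulate one site-season carrying every configured indicator over a shared
# covariate table.
simulate_site_season <- function(config, site, site_idx) {
  suite <- default_covariate_suite()
  seed0 <- child_seed(config$seed, 100L * site_idx)
  base_cfg <- season_sim_config(
    n_events = config$n_events, covariates = suite$covariates,
    target_correlations = suite$target_correlations, seed = seed0)
  cov <- simulate_covariates(base_cfg)
  events <- cbind(
    data.frame(date = as.Date("2021-06-01") + seq_len(config$n_events) - 1L),
    cov)
  limits <- transforms <- NULL
  for (j in seq_along(config$indicators)) {
    ind <- names(config$indicators)[j]
    sp <- config$indicators[[ind]]
    icfg <- season_sim_config(
      n_events = config$n_events, covariates = suite$covariates,
      target_correlations = suite$target_correlations,
      true_coefficients = sp$coefficients, intercept = sp$intercept,
      noise_sd = sp$noise_sd, censor_limit = sp$censor_limit,
      response_transform = sp$transform,
      seed = child_seed(config$seed, 100L * site_idx + j))
    sim <- simulate_indicators(cov, icfg)
    events[[paste0(ind, "_conc")]] <- sim$observed_concentration
    events[[paste0(ind, "_censored")]] <- sim$censored
    limits <- c(limits, stats::setNames(sp$censor_limit, ind))
    transforms <- c(transforms, stats::setNames(sp$transform, ind))
  }
  beach_season(site = site, events = events,
               indicators = names(config$indicators),
               limits = limits, transforms = transforms,
               beach_orientation = 180)
}

#' Run the full forecasting pipeline
#'
#' Orchestrates simulate -> preprocess -> fit -> evaluate -> correlate ->
#' influence -> qpcr over the configured sites and indicators, writing every
#' artifact under `config$out_dir` and returning a manifest of produced
#' files with MD5 content hashes. With `dry_run = TRUE` the configuration is
#' validated and the planned stages listed, but nothing is computed.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (data frame: file, md5), `board`
#'   (performance board), `influence` (influence table), and `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "preprocess", "fit", "evaluate", "correlate",
              "influence", if (!is.null(config$qpcr)) "qpcr")
  if (config$dry_run) {
    return(list(manifest = data.frame(file = character(0), md5 = character(0)),
                board = NULL, influence = NULL,
                log = sprintf("dry run: stage '%s' validated", stages)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logline <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    message(msg)
  }
  out <- function(...) file.path(config$out_dir, sprintf(...))
  t0 <- Sys.time()
  note("pipeline start: seed %d, %d site(s), %d indicator(s)",
       config$seed, length(config$sites), length(config$indicators))

  seasons <- lapply(seq_along(config$sites), function(i) {
    s <- simulate_site_season(config, config$sites[i], i)
    write_season_csv(s, out("season_%s.csv", config$sites[i]))
    s
  })
  names(seasons) <- config$sites
  note("simulate: %d seasons written", length(seasons))

  frames <- list()
  for (s in config$sites) {
    for (ind in names(config$indicators)) {
      fr <- build_model_frame(seasons[[s]], ind,
                              collinearity_threshold = config$collinearity_threshold,
                              exclude = config$exclude)
      write_model_frame(fr, out("frame_%s_%s.csv", s, ind))
      frames[[paste(s, ind, sep = ".")]] <- fr
    }
  }
  note("preprocess: %d model frames", length(frames))

  coefs <- list()
  for (nm in names(frames)) {
    path_obj <- lars_fit(frames[[nm]]$X, frames[[nm]]$y)
    model <- select_min_cp(path_obj)
    write_lars_path_csv(path_obj, out("path_%s.csv", gsub("\\.", "_", nm)))
    jsonlite::write_json(
      list(site = frames[[nm]]$site, indicator = frames[[nm]]$indicator,
           intercept = model$intercept, step = model$step, cp = model$cp,
           coefficients = as.list(model$coefficients)),
      out("model_%s.json", gsub("\\.", "_", nm)), auto_unbox = TRUE, digits = NA)
    coefs[[nm]] <- coef(model)
  }
  note("fit: %d minimum-Cp models", length(coefs))

  board <- evaluate_models(frames, k = config$k,
                           seed = child_seed(config$seed, 7L))
  utils::write.csv(as.data.frame(board)[, c("site", "indicator", "rpred2",
                                            "srmsep", "std_rpred2",
                                            "std_srmsep", "overall_performance")],
                   out("performance_board.csv"), row.names = FALSE)
  cvs <- attr(board, "cv")
  cv_all <- do.call(rbind, lapply(seq_along(frames), function(i) {
    cbind(data.frame(site = frames[[i]]$site, indicator = frames[[i]]$indicator),
          as.data.frame(cvs[[i]]))
  }))
  utils::write.csv(cv_all, out("cv_predictions.csv"), row.names = FALSE)
  note("evaluate: board of %d models (best overall %.2f)",
       nrow(board), max(board$overall_performance))

  for (i in seq_along(config$sites)) {
    s <- config$sites[i]
    cm <- correlation_matrix(seasons[[s]], n_reps = config$n_reps,
                             seed = child_seed(config$seed, 11L + i))
    utils::write.csv(cm$mean_r, out("correlation_mean_r_%s.csv", s))
    utils::write.csv(cm$sd_r, out("correlation_sd_r_%s.csv", s))
    utils::write.csv(cm$p, out("correlation_p_%s.csv", s))
  }
  note("correlate: matrices for %d sites", length(config$sites))

  groups <- list("rainfall" = intersect(c("rain_24h", "rain_72h"),
                                        unique(unlist(lapply(coefs, names)))),
                 "wind" = c("wind_a", "wind_o"))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  infl <- influence_scores(aggregate_covariates(coefs, groups))
  utils::write.csv(as.data.frame(infl), out("influence_table.csv"),
                   row.names = FALSE)
  for (s in config$sites) {
    models <- coefs[grep(paste0("^", s, "\\."), names(coefs))]
    names(models) <- sub(paste0("^", s, "\\."), "", names(models))
    write_heatmap_csv(heatmap_matrix(models), out("heatmap_%s.csv", s))
  }
  note("influence: %d covariates scored", nrow(infl))

  if (!is.null(config$qpcr)) {
    qcfg <- config$qpcr
    qcfg$seed <- child_seed(config$seed, 23L)
    run <- simulate_qpcr_run(qcfg)
    write_qpcr_csv(run, out("qpcr_run.csv"))
    std <- run$wells[run$wells$role == "standard" & run$wells$assay == "target", ]
    curve <- fit_composite_curve(std[c("log10_copies", "ct")])
    qc <- run_qc(run, curve)
    utils::write.csv(as.data.frame(qc), out("qpcr_qc.csv"), row.names = FALSE)
    ref <- calibrator_reference(run, curve)
    tests <- run$wells[run$wells$role == "test", ]
    quant <- do.call(rbind, lapply(unique(tests$sample_id), function(sid) {
      tt <- tests[tests$sample_id == sid, ]
      q <- ddct_quantify(mean(tt$ct[tt$assay == "target"]),
                         mean(tt$ct[tt$assay == "Sketa22"]),
                         curve = curve, reference = ref)
      data.frame(sample_id = sid, copies_per_100ml = q$copies_per_100ml,
                 log10_value = q$log10_value, below_llq = q$below_llq,
                 method = q$method)
    }))
    utils::write.csv(quant, out("qpcr_quant.csv"), row.names = FALSE)
    note("qpcr: QC %s, %d test samples quantified",
         if (attr(qc, "overall_pass")) "pass" else "FAIL", nrow(quant))
  }

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  note("done in %.1f s: %d artifacts", as.numeric(Sys.time() - t0, "secs"),
       nrow(manifest))
  list(manifest = manifest, board = board, influence = infl, log = logline)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`) whose top-level keys
#'   match the arguments of [pipeline_config()].
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_file <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(raw$indicators)) {
    raw$indicators <- lapply(raw$indicators, function(sp) {
      sp$coefficients <- unlist(sp$coefficients)
      sp
    })
  }
  do.call(pipeline_config, raw)
}
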