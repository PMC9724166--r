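#' Configuration for a simulated qPCR run
#'
#' Defines the true standard-curve line, the dilution-series layout, control
#' counts, Ct noise, and any quality-control gate violations to inject
#' deliberately (so that downstream QC can be shown to flag exactly them).
#'
#' @param true_slope True Ct per log10 copies; must be negative.
#' @param true_intercept True Ct at 1 copy per reaction.
#' @param standards_log10_copies Dilution-series levels, log10 copies per
#'   reaction; default six ten-fold levels down to `log10(6)`. At least 3
#'   distinct levels are required.
#' @param replicates_per_level Replicate reactions per level per run.
#' @param n_standard_runs Instrument runs contributing standards to the
#'   composite curve (>= 2 makes the ANCOVA gate evaluable).
#' @param ct_noise_sd Gaussian Ct noise, cycles; 0 gives a noiseless run.
#' @param n_calibrators,n_negatives,n_test_samples Control/test sample counts.
#' @param calibrator_log10_copies Nominal calibrator concentration.
#' @param test_log10_copies_range Range the per-sample true test
#'   concentrations are drawn from (uniform).
#' @param sketa_mean_ct,iac_mean_ct Nominal Sketa22 and IAC Ct.
#' @param extract_fraction Fraction of extract per reaction (LLQ scaling).
#' @param inject_failures Character vector of gate names to violate:
#'   any of `standard_curve_ancova`, `calibrator_target_window`,
#'   `calibrator_sketa_window`, `sketa_window`, `iac_window`,
#'   `negative_llq`, `duplicate_spread`.
#' @param seed Integer seed.
#' @return An object of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(true_slope = -3.49, true_intercept = 37.93,
                            standards_log10_copies = log10(6) + 0:5,
                            replicates_per_level = 3,
                            n_standard_runs = 2,
                            ct_noise_sd = 0.1,
                            n_calibrators = 3, n_negatives = 3,
                            n_test_samples = 4,
                            calibrator_log10_copies = 4,
                            test_log10_copies_range = c(2, 4.5),
                            sketa_mean_ct = 24, iac_mean_ct = 30,
                            extract_fraction = 1 / 120,
                            inject_failures = character(0),
                            seed = 1L) {
  if (!is_scalar_number(true_slope) || true_slope >= 0) {
    stopf("`true_slope` must be negative")
  }
  if (length(unique(standards_log10_copies)) < 3) {
    stopf("standards must span at least 3 log10 levels")
  }
  if (ct_noise_sd < 0) stopf("`ct_noise_sd` must be >= 0")
  gates <- c("standard_curve_ancova", "calibrator_target_window",
             "calibrator_sketa_window", "sketa_window", "iac_window",
             "negative_llq", "duplicate_spread")
  bad <- setdiff(inject_failures, gates)
  if (length(bad)) stopf("unknown gate name(s): %s", paste(bad, collapse = ", "))
  structure(list(true_slope = true_slope, true_intercept = true_intercept,
                 standards_log10_copies = sort(unique(standards_log10_copies)),
                 replicates_per_level = as.integer(replicates_per_level),
                 n_standard_runs = as.integer(n_standard_runs),
                 ct_noise_sd = ct_noise_sd,
                 n_calibrators = as.integer(n_calibrators),
                 n_negatives = as.integer(n_negatives),
                 n_test_samples = as.integer(n_test_samples),
                 calibrator_log10_copies = calibrator_log10_copies,
                 test_log10_copies_range = test_log10_copies_range,
                 sketa_mean_ct = sketa_mean_ct, iac_mean_ct = iac_mean_ct,
                 extract_fraction = extract_fraction,
                 inject_failures = inject_failures, seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR run with standards, controls, and test samples
#'
#' Standards follow the configured true line plus Gaussian Ct noise,
#' replicated across `n_standard_runs` pseudo-runs for the composite curve.
#' Calibrator samples sit at the nominal calibrator concentration;
#' negative-control target reactions are undetected; test samples get
#' duplicate target wells plus paired IAC and Sketa22 wells. Requested gate
#' violations are injected as Ct shifts sized to breach exactly the
#' corresponding threshold.
#'
#' The reference means/sds for the calibrator-window gate are stored in the
#' run's `gate_thresholds` from the true nominal values (standing in for the
#' "preliminary analyses" that establish them in practice), with a floor of
#' 0.2 Ct on the reference sd so the window is never degenerate.
#'
#' @param config A [qpcr_sim_config()].
#' @return A [qpcr_run]; the true per-sample test concentrations are
#'   attached as attribute `"truth"`.
#' @export
simulate_qpcr_run <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  inj <- config$inject_failures
  with_seed(config$seed, {
    slope <- config$true_slope
    icpt <- config$true_intercept
    nz <- function(n) stats::rnorm(n, 0, config$ct_noise_sd)
    rows <- list()
    wid <- 0L
    add <- function(role, assay, sample_id, run_id, log10_copies, ct) {
      wid <<- wid + 1L
      rows[[wid]] <<- data.frame(well = sprintf("W%03d", wid), role = role,
                                 assay = assay, sample_id = sample_id,
                                 run_id = run_id, log10_copies = log10_copies,
                                 ct = ct)
    }

    for (r in seq_len(config$n_standard_runs)) {
      run_slope <- slope
      if ("standard_curve_ancova" %in% inj && r == config$n_standard_runs) {
        run_slope <- slope + 0.5
      }
      for (l in config$standards_log10_copies) {
        for (k in seq_len(config$replicates_per_level)) {
          add("standard", "target", sprintf("std_run%d", r), r, l,
              icpt + run_slope * l + nz(1))
        }
      }
    }

    cal_shift <- if ("calibrator_target_window" %in% inj) {
      3 * max(config$ct_noise_sd, 0.2) + 1
    } else 0
    cal_sk_shift <- if ("calibrator_sketa_window" %in% inj) {
      3 * max(config$ct_noise_sd, 0.2) + 1
    } else 0
    for (i in seq_len(config$n_calibrators)) {
      sid <- sprintf("cal%d", i)
      add("calibrator", "target", sid, 1, config$calibrator_log10_copies,
          icpt + slope * config$calibrator_log10_copies + nz(1) + cal_shift)
      add("calibrator", "Sketa22", sid, 1, NA,
          config$sketa_mean_ct + nz(1) + cal_sk_shift)
      add("calibrator", "IAC", sid, 1, NA, config$iac_mean_ct + nz(1))
    }

    llq_ct <- icpt + slope * log10(6)
    for (i in seq_len(config$n_negatives)) {
      sid <- sprintf("neg%d", i)
      neg_ct <- if ("negative_llq" %in% inj) llq_ct - 5 else NA_real_
      add("negative", "target", sid, 1, NA, neg_ct)
      add("negative", "Sketa22", sid, 1, NA, config$sketa_mean_ct + nz(1))
      add("negative", "IAC", sid, 1, NA, config$iac_mean_ct + nz(1))
    }

    test_truth <- stats::runif(config$n_test_samples,
                               config$test_log10_copies_range[1],
                               config$test_log10_copies_range[2])
    sk_shift <- if ("sketa_window" %in% inj) 4 else 0
    iac_shift <- if ("iac_window" %in% inj) 2 else 0
    for (i in seq_len(config$n_test_samples)) {
      sid <- sprintf("test%d", i)
      ct1 <- icpt + slope * test_truth[i] + nz(1)
      ct2 <- icpt + slope * test_truth[i] + nz(1)
      if ("duplicate_spread" %in% inj && i == 1) ct2 <- ct1 + 1.5 * sqrt(2)
      add("test", "target", sid, 1, NA, ct1)
      add("test", "target", sid, 1, NA, ct2)
      add("test", "Sketa22", sid, 1, NA, config$sketa_mean_ct + nz(1) + sk_shift)
      add("test", "Sketa22", sid, 1, NA, config$sketa_mean_ct + nz(1) + sk_shift)
      add("test", "IAC", sid, 1, NA, config$iac_mean_ct + nz(1) + iac_shift)
      add("test", "IAC", sid, 1, NA, config$iac_mean_ct + nz(1) + iac_shift)
    }

    run <- qpcr_run(
      wells = do.call(rbind, rows),
      gate_thresholds = list(
        cal_target_mean = icpt + slope * config$calibrator_log10_copies,
        cal_target_sd = max(config$ct_noise_sd, 0.2),
        cal_sketa_mean = config$sketa_mean_ct,
        cal_sketa_sd = max(config$ct_noise_sd, 0.2)),
      extract_fraction = config$extract_fraction)
    attr(run, "truth") <- list(test_log10_copies = test_truth,
                               slope = slope, intercept = icpt)
    run
  })
}
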