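#' qPCR run container
#'
#' Plate-level Ct data for one instrument run in long format. Undetected
#' reactions are encoded as `NA` Ct (written as `"ND"` in CSV), which is
#' distinct from any numeric Ct; the value 40 is substituted for undetected
#' Ct only inside averaging steps of the quality-control gates.
#'
#' @param wells Data frame with columns `well`, `role` (one of `standard`,
#'   `calibrator`, `negative`, `test`), `assay` (`target`, `IAC`,
#'   `Sketa22`), `sample_id`, `run_id`, `log10_copies` (nominal, standards
#'   only; else `NA`), `ct` (`NA` = undetected).
#' @param gate_thresholds List of reference statistics for the control-window
#'   gate, from preliminary analyses: `cal_target_mean`, `cal_target_sd`,
#'   `cal_sketa_mean`, `cal_sketa_sd`.
#' @param extract_fraction Fraction of the total DNA extract analyzed per
#'   reaction (1/120 for a 5 uL aliquot of a 600 uL extract); scales
#'   per-reaction copies to per-sample copies.
#' @param volume_scaling Reactions-to-100 mL scale factor for reporting
#'   concentrations per 100 mL of water.
#' @return An object of class `qpcr_run`.
#' @export
qpcr_run <- function(wells, gate_thresholds = list(),
                     extract_fraction = 1 / 120, volume_scaling = 1) {
  req <- c("well", "role", "assay", "sample_id", "run_id", "log10_copies", "ct")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stopf("wells lack columns: %s", paste(miss, collapse = ", "))
  if (!all(wells$role %in% c("standard", "calibrator", "negative", "test"))) {
    stopf("unknown role in wells")
  }
  if (!all(wells$assay %in% c("target", "IAC", "Sketa22"))) {
    stopf("unknown assay in wells")
  }
  for (sid in unique(wells$sample_id[wells$role == "test"])) {
    w <- wells[wells$role == "test" & wells$sample_id == sid, ]
    if (!all(c("target", "IAC", "Sketa22") %in% w$assay)) {
      stopf("test sample '%s' lacks paired IAC/Sketa22 measurements", sid)
    }
  }
  structure(list(wells = wells, gate_thresholds = gate_thresholds,
                 extract_fraction = extract_fraction,
                 volume_scaling = volume_scaling),
            class = "qpcr_run")
}

#' @export
print.qpcr_run <- function(x, ...) {
  tab <- table(x$wells$role, x$wells$assay)
  cat(sprintf("qPCR run: %d wells\n", nrow(x$wells)))
  print(tab)
  invisible(x)
}

# Ct averaging with the undetected -> 40 substitution used by the QC gates.
ct_for_averaging <- function(ct) ifelse(is.na(ct), 40, ct)

#' Fit a composite weighted-regression standard curve
#'
#' Replicate Ct measurements of plasmid DNA standards (possibly composited
#' over multiple instrument runs) are averaged per concentration level and a
#' weighted linear regression of mean Ct on log10 copies per reaction is
#' fitted. The default weight of a level is its replicate count, which makes
#' the fit identical to an unweighted per-replicate regression; inverse
#' within-level variance weighting is available as an option.
#'
#' @param standards Data frame with columns `log10_copies` and `ct` (one row
#'   per replicate reaction); undetected (`NA`) Ct rows are dropped with a
#'   warning.
#' @param weights `"replicates"` (default), `"inverse_variance"`, or a
#'   numeric vector of per-level weights in increasing order of
#'   concentration.
#' @param llq_copies Lower limit of quantification in copies per reaction
#'   (the lowest standard concentration, 6 copies by default).
#' @return An object of class `standard_curve`: `slope` (Ct per log10
#'   copies, negative), `intercept` (Ct at 1 copy per reaction),
#'   `efficiency` (`10^(-1/slope) - 1`), `amp_base` (`efficiency + 1`),
#'   `llq_copies_per_reaction`, `llq_ct`, `n_levels`, `levels`.
#' @export
fit_composite_curve <- function(standards, weights = "replicates",
                                llq_copies = 6) {
  if (!all(c("log10_copies", "ct") %in% names(standards))) {
    stopf("`standards` needs columns log10_copies and ct")
  }
  nd <- is.na(standards$ct)
  if (any(nd)) {
    warnf("%d undetected standard reactions dropped from the curve fit", sum(nd))
    standards <- standards[!nd, , drop = FALSE]
  }
  levels_ <- sort(unique(standards$log10_copies))
  if (length(levels_) < 3) {
    stopf("need at least 3 distinct standard concentration levels, got %d",
          length(levels_))
  }
  agg <- do.call(rbind, lapply(levels_, function(l) {
    ct <- standards$ct[standards$log10_copies == l]
    data.frame(log10_copies = l, mean_ct = mean(ct), n = length(ct),
               var_ct = if (length(ct) > 1) stats::var(ct) else NA_real_)
  }))
  w <- if (is.numeric(weights)) {
    if (length(weights) != nrow(agg)) {
      stopf("numeric `weights` must have one entry per concentration level (%d)",
            nrow(agg))
    }
    weights
  } else if (identical(weights, "replicates")) {
    agg$n
  } else if (identical(weights, "inverse_variance")) {
    v <- agg$var_ct
    if (anyNA(v) || any(v == 0)) {
      stopf("inverse-variance weights need >= 2 replicates with spread at every level")
    }
    agg$n / v
  } else {
    stopf("unknown weights scheme '%s'", weights)
  }
  fit <- stats::lm(mean_ct ~ log10_copies, data = agg, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    stopf("fitted slope %.3f is not negative: standards invalid", slope)
  }
  structure(list(slope = slope, intercept = intercept,
                 efficiency = amplification_efficiency(slope),
                 amp_base = amplification_efficiency(slope) + 1,
                 llq_copies_per_reaction = llq_copies,
                 llq_ct = intercept + slope * log10(llq_copies),
                 n_levels = nrow(agg), levels = agg, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Ct = %.2f %+.2f * log10(copies); efficiency %.2f\n",
              x$intercept, x$slope, x$efficiency))
  cat(sprintf("  LLQ: %g copies/reaction (Ct %.2f), %d levels\n",
              x$llq_copies_per_reaction, x$llq_ct, x$n_levels))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `efficiency = 10^(-1/slope) - 1`; a slope of `-1/log10(2)` (about -3.32)
#' corresponds to perfect per-cycle doubling (efficiency 1).
#'
#' @param slope Standard-curve slope, Ct per log10 copies; must be negative.
#' @return Efficiency as a dimensionless fraction.
#' @export
amplification_efficiency <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stopf("slope must be negative (got %s)", paste(slope, collapse = ", "))
  }
  10^(-1 / slope) - 1
}

#' Calibrator reference statistics for delta-delta-Ct quantification
#'
#' Mean target and Sketa22 Ct over the calibrator wells (undetected Ct
#' averaged as 40) and the median over calibrator wells of the
#' curve-derived target copies per reaction.
#'
#' @param run A [qpcr_run] containing calibrator wells.
#' @param curve A [fit_composite_curve()] result.
#' @return List `mean_target_ct`, `mean_sketa_ct`, `median_copies`.
#' @export
calibrator_reference <- function(run, curve) {
  w <- run$wells[run$wells$role == "calibrator", ]
  tc <- w$ct[w$assay == "target"]
  sk <- w$ct[w$assay == "Sketa22"]
  if (!length(tc) || !length(sk)) {
    stopf("run has no calibrator target/Sketa22 wells")
  }
  tct <- ct_for_averaging(tc)
  list(mean_target_ct = mean(tct),
       mean_sketa_ct = mean(ct_for_averaging(sk)),
       median_copies = stats::median(10^((tct - curve$intercept) / curve$slope)))
}

quant_result <- function(copies_per_reaction, curve, volume_scaling, method,
                         extract_fraction = NA_real_) {
  below <- is.na(copies_per_reaction) ||
    copies_per_reaction < curve$llq_copies_per_reaction
  copies_100ml <- if (is.na(copies_per_reaction)) NA_real_
                  else copies_per_reaction * volume_scaling
  structure(list(copies_per_reaction = copies_per_reaction,
                 copies_per_100ml = copies_100ml,
                 log10_value = if (!below) log10(copies_100ml) else NA_real_,
                 below_llq = below, method = method),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  if (x$below_llq) {
    cat(sprintf("<LLQ (%s method)\n", x$method))
  } else {
    cat(sprintf("%.3g copies/100 mL (log10 %.2f, %s method)\n",
                x$copies_per_100ml, x$log10_value, x$method))
  }
  invisible(x)
}

#' Delta-delta comparative Ct quantification
#'
#' `ddCt = (sample target Ct - calibrator mean target Ct) - (sample Sketa22
#' Ct - calibrator mean Sketa22 Ct)`; estimated copies are the median
#' calibrator copies times `amp_base^(-ddCt)`, where `amp_base =
#' 10^(-1/slope)` is the per-cycle amplification factor of the assay's
#' composite curve (not an assumed 2). The Sketa22 term corrects for DNA
#' recovery and amplification interference. An undetected sample target Ct
#' yields a below-LLQ result.
#'
#' @param sample_target_ct,sample_sketa_ct Sample Ct values (`NA` =
#'   undetected target).
#' @param run A [qpcr_run] with calibrator wells (used via
#'   [calibrator_reference()]); alternatively pass `reference` directly.
#' @param curve A [fit_composite_curve()] result.
#' @param reference Optional precomputed [calibrator_reference()] list.
#' @param volume_scaling Reactions-to-100 mL factor; default taken from `run`.
#' @return A `quant_result` with `method = "ddct"`.
#' @export
ddct_quantify <- function(sample_target_ct, sample_sketa_ct, run = NULL,
                          curve, reference = NULL,
                          volume_scaling = if (!is.null(run)) run$volume_scaling else 1) {
  if (is.null(reference)) {
    if (is.null(run)) stopf("supply `run` (with calibrators) or `reference`")
    reference <- calibrator_reference(run, curve)
  }
  if (is.na(sample_target_ct)) {
    return(quant_result(NA_real_, curve, volume_scaling, "ddct"))
  }
  ddct <- (sample_target_ct - reference$mean_target_ct) -
          (sample_sketa_ct - reference$mean_sketa_ct)
  copies <- reference$median_copies * curve$amp_base^(-ddct)
  out <- quant_result(copies, curve, volume_scaling, "ddct")
  out$ddct <- ddct
  out
}

#' Direct standard-curve quantification with Sketa22 recovery adjustment
#'
#' Copies per reaction are `10^((target Ct - intercept) / slope)`, scaled by
#' `amp_base^(sketa_delta_ct)` to adjust for DNA recovery (a positive
#' Sketa22 delta Ct, i.e. poorer recovery than the calibrator mean, scales
#' the estimate up), then converted to copies per 100 mL by
#' `volume_scaling`.
#'
#' @param target_ct Sample target Ct (`NA` = undetected).
#' @param sketa_delta_ct Sample Sketa22 Ct minus the calibrator-mean
#'   Sketa22 Ct; 0 disables the adjustment.
#' @param curve A [fit_composite_curve()] result.
#' @param volume_scaling Reactions-to-100 mL factor, positive.
#' @return A `quant_result` with `method = "curve_direct"`.
#' @export
curve_direct_quantify <- function(target_ct, sketa_delta_ct = 0, curve,
                                  volume_scaling = 1) {
  if (!is_scalar_number(volume_scaling) || volume_scaling <= 0) {
    stopf("`volume_scaling` must be > 0")
  }
  if (is.na(target_ct)) {
    return(quant_result(NA_real_, curve, volume_scaling, "curve_direct"))
  }
  copies <- 10^((target_ct - curve$intercept) / curve$slope) *
    curve$amp_base^(sketa_delta_ct)
  quant_result(copies, curve, volume_scaling, "curve_direct")
}

#' Sample-level lower limit of quantification
#'
#' The per-reaction LLQ (lowest standard concentration) divided by the
#' fraction of the total DNA extract analyzed per reaction: 6 copies per
#' reaction with 1/120 of the extract per reaction gives an LLQ of 720
#' copies per sample.
#'
#' @param llq_copies_per_reaction Copies per reaction, default 6.
#' @param extract_fraction Fraction of the extract per reaction, default 1/120.
#' @return Copies per sample.
#' @export
llq_per_sample <- function(llq_copies_per_reaction = 6,
                           extract_fraction = 1 / 120) {
  if (!is_scalar_number(extract_fraction) || extract_fraction <= 0) {
    stopf("`extract_fraction` must be > 0")
  }
  llq_copies_per_reaction / extract_fraction
}

#' ANCOVA parallelism test for composite standard curves
#'
#' Nested-F comparisons across the individual runs contributing to a
#' composite curve: `p_slope` compares separate-slopes against common-slope
#' models, `p_intercept` compares common-slope separate-intercepts against a
#' single line. Both p-values must exceed 0.05 for the runs to be composited.
#' When the runs are numerically identical lines (zero incremental and
#' residual sums of squares) the F statistic is 0/0 and both p-values are 1
#' by convention.
#'
#' @param standards Data frame with columns `log10_copies`, `ct`, `run`
#'   (run identifier), or a list of per-run data frames with
#'   `log10_copies`/`ct`.
#' @return List `p_slope`, `p_intercept`.
#' @export
ancova_parallelism <- function(standards) {
  if (is.list(standards) && !is.data.frame(standards)) {
    standards <- do.call(rbind, lapply(seq_along(standards), function(i) {
      data.frame(log10_copies = standards[[i]]$log10_copies,
                 ct = standards[[i]]$ct, run = i)
    }))
  }
  nd <- is.na(standards$ct)
  if (any(nd)) standards <- standards[!nd, , drop = FALSE]
  standards$run <- factor(standards$run)
  if (nlevels(standards$run) < 2) stopf("need standards from at least 2 runs")
  for (r in levels(standards$run)) {
    if (length(unique(standards$log10_copies[standards$run == r])) < 3) {
      stopf("run '%s' has fewer than 3 concentration levels", r)
    }
  }
  fit_full <- stats::lm(ct ~ log10_copies * run, data = standards)
  fit_par <- stats::lm(ct ~ log10_copies + run, data = standards)
  fit_one <- stats::lm(ct ~ log10_copies, data = standards)
  scale <- sum((standards$ct - mean(standards$ct))^2)
  pval <- function(reduced, full) {
    rss_r <- sum(stats::resid(reduced)^2)
    rss_f <- sum(stats::resid(full)^2)
    # numerically identical lines: zero incremental SS over zero residual SS
    if (rss_f <= 1e-10 * scale && (rss_r - rss_f) <= 1e-10 * scale) return(1)
    a <- stats::anova(reduced, full)
    p <- a[["Pr(>F)"]][2]
    if (is.na(p) || is.nan(p)) 1 else p
  }
  list(p_slope = pval(fit_par, fit_full),
       p_intercept = pval(fit_one, fit_par))
}

#' Data-acceptance quality-control gates for a qPCR run
#'
#' Evaluates the automatic acceptance checks applied before any run's test
#' data are used: (1) ANCOVA parallelism of the per-run standard curves
#' (`p > 0.05` for slopes and intercepts); (2) calibrator target and
#' Sketa22 mean Ct within +/- 3 reference standard deviations of the
#' reference means; (3) test-sample Sketa22 Ct within 3 units of the
#' calibrator-sample Sketa22 mean; (4) test-sample IAC Ct within 1.5 units
#' of the negative-control IAC mean; (5) negative-control target copy
#' estimates below the sample-level LLQ prior to any Sketa22 adjustment;
#' (6) standard deviation of duplicate test-well target Ct within 1.414.
#' Undetected Ct values are averaged as 40 throughout. A gate whose
#' required controls are absent is reported not-evaluable (`NA`), never
#' silently passed.
#'
#' @param run A [qpcr_run].
#' @param curve A [fit_composite_curve()] result for the run's assay.
#' @return An object of class `qc_report`: data frame with columns `gate`,
#'   `statistic`, `threshold`, `pass` (`NA` = not evaluable); attribute
#'   `overall_pass` is the conjunction of the evaluable gates.
#' @export
run_qc <- function(run, curve) {
  stopifnot(inherits(run, "qpcr_run"), inherits(curve, "standard_curve"))
  w <- run$wells
  gth <- run$gate_thresholds
  rows <- list()
  add <- function(gate, statistic, threshold, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gate = gate, statistic = statistic, threshold = threshold, pass = pass)
  }

  # 1. standard-curve ANCOVA across contributing runs
  std <- w[w$role == "standard" & w$assay == "target" & !is.na(w$ct), ]
  if (nrow(std) && length(unique(std$run_id)) >= 2) {
    anc <- ancova_parallelism(data.frame(log10_copies = std$log10_copies,
                                         ct = std$ct, run = std$run_id))
    p <- min(anc$p_slope, anc$p_intercept)
    add("standard_curve_ancova", p, 0.05, p > 0.05)
  } else {
    add("standard_curve_ancova", NA_real_, 0.05, NA)
  }

  # 2. calibrator control windows (+/- 3 reference sd)
  cal <- w[w$role == "calibrator", ]
  cal_window <- function(assay, mean_name, sd_name, gate) {
    ct <- cal$ct[cal$assay == assay]
    if (length(ct) && !is.null(gth[[mean_name]]) && !is.null(gth[[sd_name]])) {
      dev <- abs(mean(ct_for_averaging(ct)) - gth[[mean_name]])
      add(gate, dev, 3 * gth[[sd_name]], dev <= 3 * gth[[sd_name]])
    } else {
      add(gate, NA_real_, NA_real_, NA)
    }
  }
  cal_window("target", "cal_target_mean", "cal_target_sd", "calibrator_target_window")
  cal_window("Sketa22", "cal_sketa_mean", "cal_sketa_sd", "calibrator_sketa_window")

  # 3. test Sketa22 within 3 Ct of the calibrator Sketa22 mean
  tw <- w[w$role == "test", ]
  cal_sk <- cal$ct[cal$assay == "Sketa22"]
  if (nrow(tw) && length(cal_sk)) {
    ref <- mean(ct_for_averaging(cal_sk))
    devs <- vapply(split(tw$ct[tw$assay == "Sketa22"],
                         tw$sample_id[tw$assay == "Sketa22"]),
                   function(ct) abs(mean(ct_for_averaging(ct)) - ref), numeric(1))
    add("sketa_window", max(devs), 3, max(devs) <= 3)
  } else {
    add("sketa_window", NA_real_, 3, NA)
  }

  # 4. test IAC within 1.5 Ct of the negative-control IAC mean
  neg <- w[w$role == "negative", ]
  neg_iac <- neg$ct[neg$assay == "IAC"]
  if (nrow(tw) && length(neg_iac)) {
    ref <- mean(ct_for_averaging(neg_iac))
    devs <- vapply(split(tw$ct[tw$assay == "IAC"],
                         tw$sample_id[tw$assay == "IAC"]),
                   function(ct) abs(mean(ct_for_averaging(ct)) - ref), numeric(1))
    add("iac_window", max(devs), 1.5, max(devs) <= 1.5)
  } else {
    add("iac_window", NA_real_, 1.5, NA)
  }

  # 5. negative-control copy estimates below the sample-level LLQ
  neg_t <- neg[neg$assay == "target", ]
  if (nrow(neg_t)) {
    llq_sample <- llq_per_sample(curve$llq_copies_per_reaction,
                                 run$extract_fraction)
    est <- vapply(split(neg_t$ct, neg_t$sample_id), function(ct) {
      mct <- mean(ct_for_averaging(ct))
      10^((mct - curve$intercept) / curve$slope) / run$extract_fraction
    }, numeric(1))
    add("negative_llq", max(est), llq_sample, max(est) < llq_sample)
  } else {
    add("negative_llq", NA_real_, NA_real_, NA)
  }

  # 6. duplicate test-well target Ct spread
  tt <- tw[tw$assay == "target" & !is.na(tw$ct), ]
  if (nrow(tt)) {
    sds <- vapply(split(tt$ct, tt$sample_id), function(ct) {
      if (length(ct) > 1) stats::sd(ct) else 0
    }, numeric(1))
    add("duplicate_spread", max(sds), 1.414, max(sds) <= 1.414)
  } else {
    add("duplicate_spread", NA_real_, 1.414, NA)
  }

  report <- do.call(rbind, rows)
  evaluable <- !is.na(report$pass)
  structure(report,
            overall_pass = all(report$pass[evaluable]),
            n_not_evaluable = sum(!evaluable),
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$pass <- ifelse(is.na(df$pass), "not evaluable", ifelse(df$pass, "PASS", "FAIL"))
  print.data.frame(df, row.names = FALSE, digits = 4)
  cat(sprintf("overall: %s\n", if (attr(x, "overall_pass")) "PASS" else "FAIL"))
  invisible(x)
}
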