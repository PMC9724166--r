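test_that("noiseless standards recover the exact line and its efficiency", {
  lv <- log10(6) + 0:5
  std <- data.frame(log10_copies = rep(lv, each = 3),
                    ct = rep(37.93 - 3.49 * lv, each = 3))
  curve <- fit_composite_curve(std)
  expect_equal(curve$slope, -3.49, tolerance = 1e-10)
  expect_equal(curve$intercept, 37.93, tolerance = 1e-10)
  expect_equal(round(curve$efficiency, 2), 0.93)
  expect_equal(curve$amp_base, curve$efficiency + 1)
  expect_equal(curve$llq_ct, 37.93 - 3.49 * log10(6), tolerance = 1e-10)
})

test_that("duplicated standard points fit identically to doubled level weights", {
  set.seed(3)
  lv <- 1:4
  ct <- 38 - 3.4 * lv + rnorm(4, 0, 0.2)
  dup <- data.frame(log10_copies = rep(lv, each = 2), ct = rep(ct, each = 2))
  single <- data.frame(log10_copies = lv, ct = ct)
  f1 <- fit_composite_curve(dup)
  f2 <- fit_composite_curve(single, weights = rep(2, 4))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("the weighted fit matches the closed-form WLS oracle", {
  set.seed(11)
  lv <- log10(6) + 0:5
  std <- data.frame(log10_copies = rep(lv, each = 3),
                    ct = 37.9 - 3.5 * rep(lv, each = 3) + rnorm(18, 0, 0.3))
  curve <- fit_composite_curve(std)
  # independent oracle: weighted normal equations on the level means
  m <- as.numeric(tapply(std$ct, std$log10_copies, mean))
  w <- as.numeric(tapply(std$ct, std$log10_copies, length))
  x <- sort(unique(std$log10_copies))
  A <- cbind(1, x)
  beta <- solve(t(A) %*% (w * A), t(A) %*% (w * m))
  expect_equal(curve$intercept, unname(beta[1, 1]), tolerance = 1e-10)
  expect_equal(curve$slope, unname(beta[2, 1]), tolerance = 1e-10)
})

test_that("standard-curve preconditions are enforced", {
  expect_error(fit_composite_curve(data.frame(log10_copies = c(1, 2),
                                              ct = c(34, 31))), "3 distinct")
  up <- data.frame(log10_copies = 1:4, ct = c(30, 32, 34, 36))
  expect_error(fit_composite_curve(up), "not negative")
})

test_that("amplification efficiency follows 10^(-1/slope) - 1", {
  expect_equal(round(amplification_efficiency(-3.49), 2), 0.93)
  expect_equal(round(amplification_efficiency(-3.58), 2), 0.90)
  expect_equal(round(amplification_efficiency(-3.54), 2), 0.92)
  expect_equal(round(amplification_efficiency(-1 / log10(2)), 2), 1.00)
  expect_error(amplification_efficiency(3.3), "negative")
  # strictly decreasing in |slope| on the negative axis
  slopes <- -seq(3.1, 4.0, by = 0.1)
  expect_true(all(diff(amplification_efficiency(slopes)) < 0))
})

test_that("delta-delta Ct quantification has the calibrator identities", {
  lv <- 1:5
  curve <- fit_composite_curve(data.frame(log10_copies = lv, ct = 38 - 2 * lv),
                               llq_copies = 1)
  ref <- list(mean_target_ct = 30, mean_sketa_ct = 24, median_copies = 1000)
  # ddCt = 0 returns the median calibrator copies
  q0 <- ddct_quantify(30, 24, curve = curve, reference = ref)
  expect_equal(q0$copies_per_reaction, 1000)
  # one cycle earlier with amp_base forced to 2 doubles the estimate
  curve2 <- curve
  curve2$amp_base <- 2
  q1 <- ddct_quantify(29, 24, curve = curve2, reference = ref)
  expect_equal(q1$copies_per_reaction, 2000)
  # an undetected target Ct is a below-LLQ result
  qnd <- ddct_quantify(NA, 24, curve = curve, reference = ref)
  expect_true(qnd$below_llq)
  expect_error(ddct_quantify(30, 24, curve = curve), "calibrator")
})

test_that("ddct and curve-direct methods agree when anchored to the same curve", {
  cfg <- noiseless_qpcr_config(seed = 4)
  run <- simulate_qpcr_run(cfg)
  std <- run$wells[run$wells$role == "standard" & run$wells$assay == "target", ]
  curve <- fit_composite_curve(std[c("log10_copies", "ct")])
  ref <- calibrator_reference(run, curve)
  tests <- run$wells[run$wells$role == "test", ]
  for (sid in unique(tests$sample_id)) {
    tt <- tests[tests$sample_id == sid, ]
    tct <- mean(tt$ct[tt$assay == "target"])
    sct <- mean(tt$ct[tt$assay == "Sketa22"])
    qd <- ddct_quantify(tct, sct, curve = curve, reference = ref)
    qc <- curve_direct_quantify(tct, sct - ref$mean_sketa_ct, curve)
    expect_equal(qd$copies_per_reaction / qc$copies_per_reaction, 1,
                 tolerance = 1e-6)
  }
})

test_that("curve-direct quantification satisfies the curve definition", {
  curve <- fit_composite_curve(
    data.frame(log10_copies = 0:4, ct = 37.93 - 3.49 * (0:4)), llq_copies = 1)
  expect_equal(curve_direct_quantify(curve$intercept, 0, curve)$copies_per_reaction,
               1, tolerance = 1e-10)
  expect_equal(curve_direct_quantify(curve$intercept + curve$slope, 0,
                                     curve)$copies_per_reaction,
               10, tolerance = 1e-10)
  # monotone: lower Ct, strictly more copies
  cts <- seq(36, 20, by = -1)
  est <- vapply(cts, function(ct) {
    curve_direct_quantify(ct, 0, curve)$copies_per_reaction
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("quantifying a Ct synthesized at K copies returns K exactly", {
  curve <- fit_composite_curve(
    data.frame(log10_copies = log10(6) + 0:4, ct = 37.5 - 3.4 * (log10(6) + 0:4)))
  for (K in c(10, 720, 5e4)) {
    ct <- curve$intercept + curve$slope * log10(K)
    expect_equal(curve_direct_quantify(ct, 0, curve)$copies_per_reaction, K,
                 tolerance = 1e-8 * K)
  }
})

test_that("sample-level LLQ derives from the lowest standard and extract fraction", {
  expect_equal(llq_per_sample(6, 1 / 120), 720)
  expect_equal(llq_per_sample(6, 1 / 100), 600)
})

test_that("ANCOVA parallelism p-values behave at the boundary and match a nested-F oracle", {
  lv <- 1:6
  ident <- data.frame(log10_copies = rep(lv, 4),
                      ct = rep(38 - 3.5 * lv, 4),
                      run = rep(1:2, each = 12))
  pp <- ancova_parallelism(ident)
  expect_equal(pp$p_slope, 1)
  expect_equal(pp$p_intercept, 1)

  set.seed(2)
  diff_sl <- data.frame(
    log10_copies = rep(lv, 4),
    ct = c(rep(38 - 3.2 * lv, 2), rep(38 - 3.9 * lv, 2)) + rnorm(24, 0, 0.05),
    run = rep(1:2, each = 12))
  expect_lt(ancova_parallelism(diff_sl)$p_slope, 0.05)

  # independent nested-F computation from residual sums of squares
  set.seed(5)
  d <- data.frame(log10_copies = rep(lv, 4),
                  ct = 38 - 3.5 * rep(lv, 4) + rnorm(24, 0, 0.2),
                  run = factor(rep(1:2, each = 12)))
  pp <- ancova_parallelism(d)
  rss <- function(f) sum(resid(lm(f, data = d))^2)
  r_full <- rss(ct ~ log10_copies * run)
  r_par <- rss(ct ~ log10_copies + run)
  r_one <- rss(ct ~ log10_copies)
  n <- nrow(d)
  f_slope <- (r_par - r_full) / 1 / (r_full / (n - 4))
  f_int <- (r_one - r_par) / 1 / (r_par / (n - 3))
  expect_equal(pp$p_slope, pf(f_slope, 1, n - 4, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(pp$p_intercept, pf(f_int, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_error(ancova_parallelism(d[d$run == 1, ]), "2 runs")
})

test_that("an on-nominal synthetic run passes every QC gate", {
  run <- simulate_qpcr_run(noiseless_qpcr_config(seed = 7))
  std <- run$wells[run$wells$role == "standard" & run$wells$assay == "target", ]
  curve <- fit_composite_curve(std[c("log10_copies", "ct")])
  qc <- run_qc(run, curve)
  expect_true(all(qc$pass, na.rm = TRUE))
  expect_identical(attr(qc, "n_not_evaluable"), 0L)
  expect_true(attr(qc, "overall_pass"))
})

test_that("each injected violation flips exactly its own gate", {
  gates <- c("standard_curve_ancova", "calibrator_target_window",
             "calibrator_sketa_window", "sketa_window", "iac_window",
             "negative_llq", "duplicate_spread")
  for (g in gates) {
    run <- simulate_qpcr_run(noiseless_qpcr_config(inject_failures = g, seed = 7))
    std <- run$wells[run$wells$role == "standard" & run$wells$assay == "target", ]
    curve <- fit_composite_curve(std[c("log10_copies", "ct")])
    qc <- run_qc(run, curve)
    expect_identical(qc$gate[!qc$pass], g)
    expect_false(attr(qc, "overall_pass"))
  }
})

test_that("gate thresholds match the acceptance rules they implement", {
  # test IAC shifted +2.0 Ct from the negative-control mean: only the 1.5-unit
  # IAC gate fails
  run <- simulate_qpcr_run(noiseless_qpcr_config(inject_failures = "iac_window",
                                                 seed = 3))
  w <- run$wells
  iac_test <- w$ct[w$role == "test" & w$assay == "IAC"]
  iac_neg <- w$ct[w$role == "negative" & w$assay == "IAC"]
  expect_equal(unique(iac_test) - mean(iac_neg), 2)
  std <- w[w$role == "standard" & w$assay == "target", ]
  qc <- run_qc(run, fit_composite_curve(std[c("log10_copies", "ct")]))
  expect_identical(qc$gate[!qc$pass], "iac_window")

  # duplicate Ct standard deviation of 1.5 exceeds the 1.414 limit
  run2 <- simulate_qpcr_run(noiseless_qpcr_config(inject_failures = "duplicate_spread",
                                                  seed = 3))
  tt <- run2$wells[run2$wells$role == "test" & run2$wells$assay == "target", ]
  sds <- tapply(tt$ct, tt$sample_id, sd)
  expect_equal(unname(max(sds)), 1.5, tolerance = 1e-12)
  std2 <- run2$wells[run2$wells$role == "standard" & run2$wells$assay == "target", ]
  qc2 <- run_qc(run2, fit_composite_curve(std2[c("log10_copies", "ct")]))
  expect_identical(qc2$gate[!qc2$pass], "duplicate_spread")
})

test_that("a gate without its required controls is not evaluable, never passed", {
  run <- simulate_qpcr_run(noiseless_qpcr_config(seed = 2))
  w <- run$wells[run$wells$role != "negative", ]
  run2 <- qpcr_run(w, gate_thresholds = run$gate_thresholds,
                   extract_fraction = run$extract_fraction)
  std <- w[w$role == "standard" & w$assay == "target", ]
  qc <- run_qc(run2, fit_composite_curve(std[c("log10_copies", "ct")]))
  na_gates <- qc$gate[is.na(qc$pass)]
  expect_true(all(c("iac_window", "negative_llq") %in% na_gates))
})

test_that("noisy simulated standards refit close to the generating slope", {
  cfg <- qpcr_sim_config(ct_noise_sd = 0.2, seed = 21)
  run <- simulate_qpcr_run(cfg)
  std <- run$wells[run$wells$role == "standard" & run$wells$assay == "target", ]
  curve <- fit_composite_curve(std[c("log10_copies", "ct")])
  # 36 replicate reactions across 6 decades: the slope standard error is
  # about ct_noise_sd / (sd(levels) * sqrt(36)) ~ 0.02, so 0.1 is ~5 se
  expect_lt(abs(curve$slope - cfg$true_slope), 0.1)
  expect_lt(abs(curve$intercept - cfg$true_intercept), 0.3)
})

test_that("simulation is reproducible and undetected wells stay distinct from Ct 40", {
  r1 <- simulate_qpcr_run(qpcr_sim_config(seed = 9))
  r2 <- simulate_qpcr_run(qpcr_sim_config(seed = 9))
  expect_identical(r1$wells, r2$wells)
  neg <- r1$wells[r1$wells$role == "negative" & r1$wells$assay == "target", ]
  expect_true(all(is.na(neg$ct)))
})
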