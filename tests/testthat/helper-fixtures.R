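# Fixtures built in code; no data files.

# Orthogonal standardized design: columns are mutually orthogonal, centered,
# sd exactly 1 (so X'X = (n-1) I), the regime where the lasso has the
# soft-threshold closed form.
orthogonal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * (p + 1)), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))[, seq_len(p), drop = FALSE]   # orthonormal, orthogonal to 1
  X <- Q * sqrt(n - 1)
  colnames(X) <- paste0("v", seq_len(p))
  X
}

# Small standardized regression problem with known sparse truth.
toy_problem <- function(n = 30, p = 6, coefs = c(v1 = 1, v3 = -0.8),
                        noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  X <- standardize_covariates(X)$Z
  y <- 2 + drop(X[, names(coefs), drop = FALSE] %*% coefs) +
    rnorm(n, 0, noise_sd)
  list(X = X, y = y, coefs = coefs)
}

# Beach season with two indicators and controllable censoring.
toy_season <- function(n = 40, seed = 1, censor_frac = 0.2) {
  set.seed(seed)
  turb <- exp(rnorm(n, 1.5, 0.6))
  wave <- exp(rnorm(n, -1.2, 0.5))
  lg_a <- 2 + 0.4 * scale(log(turb))[, 1] + rnorm(n, 0, 0.4)
  lg_b <- 1.8 + 0.3 * scale(wave)[, 1] + rnorm(n, 0, 0.4)
  conc_a <- 10^lg_a
  conc_b <- 10^lg_b
  lim_a <- unname(quantile(conc_a, censor_frac))
  lim_b <- unname(quantile(conc_b, censor_frac))
  ev <- data.frame(date = as.Date("2021-06-01") + seq_len(n) - 1,
                   turbidity = turb, wave_height = wave,
                   ind_a_conc = conc_a, ind_a_censored = conc_a < lim_a,
                   ind_b_conc = conc_b, ind_b_censored = conc_b < lim_b)
  beach_season(site = "toy", events = ev, indicators = c("ind_a", "ind_b"),
               limits = c(ind_a = lim_a, ind_b = lim_b),
               transforms = c(ind_a = "log10", ind_b = "log10"),
               beach_orientation = 180)
}

# Noiseless qPCR simulation config used by round-trip and QC-gate tests.
noiseless_qpcr_config <- function(..., seed = 1) {
  qpcr_sim_config(ct_noise_sd = 0, seed = seed, ...)
}
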