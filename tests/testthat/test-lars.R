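test_that("single covariate gives a two-step path ending at the OLS slope", {
  tp <- toy_problem(n = 25, p = 1, coefs = c(v1 = 0.7), seed = 3)
  path <- lars_fit(tp$X, tp$y, sigma2 = 0.09)
  expect_length(path$steps, 2)
  expect_identical(path$steps[[1]]$active, character(0))
  ols <- unname(coef(lm(tp$y ~ tp$X))[2])
  expect_equal(unname(path$steps[[2]]$beta["v1"]), ols, tolerance = 1e-10)
})

test_that("orthogonal designs reproduce the soft-threshold closed form", {
  n <- 40; p <- 5
  X <- orthogonal_design(n, p, seed = 11)
  set.seed(12)
  y <- drop(X %*% c(1.2, -0.8, 0.5, 0, 0)) + rnorm(n, 0, 0.4)
  path <- lars_fit(X, y)
  # with X'X = (n-1) I the lasso solution at inner-product threshold lambda is
  # beta_j = sign(z_j) * max(|z_j| - lambda, 0) / (n-1), z = X'(y - ybar)
  z <- drop(crossprod(X, y - mean(y)))
  for (k in seq_along(path$steps)) {
    beta <- path$steps[[k]]$beta
    lambda <- max(abs(crossprod(X, (y - mean(y)) - X %*% beta)))
    expected <- sign(z) * pmax(abs(z) - lambda, 0) / (n - 1)
    expect_equal(unname(beta), unname(expected), tolerance = 1e-10)
  }
})

test_that("path coefficients agree with a coordinate-descent lasso oracle", {
  library(glmnet)
  tp <- toy_problem(n = 30, p = 6, seed = 5)
  path <- lars_fit(tp$X, tp$y)
  n <- nrow(tp$X)
  for (k in seq(2, length(path$steps) - 1)) {
    beta <- path$steps[[k]]$beta
    r <- tp$y - mean(tp$y) - drop(tp$X %*% beta)
    lambda <- max(abs(crossprod(tp$X, r))) / n
    g <- glmnet(tp$X, tp$y, standardize = FALSE, lambda = lambda,
                thresh = 1e-14)
    expect_equal(unname(beta), as.numeric(coef(g))[-1], tolerance = 1e-6)
  }
})

test_that("first entrant is the covariate most correlated with the response", {
  for (seed in 1:5) {
    tp <- toy_problem(n = 40, p = 8,
                      coefs = c(v2 = 0.9, v5 = -0.4), seed = seed)
    path <- lars_fit(tp$X, tp$y)
    best <- names(which.max(abs(cor(tp$X, tp$y))[, 1]))
    expect_identical(path$steps[[2]]$active, best)
  }
})

test_that("active coefficient signs match their residual correlations along the path", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 35; p <- 7
    S <- 0.6^abs(outer(1:p, 1:p, "-"))
    X <- matrix(rnorm(n * p), n, p) %*% chol(S)
    colnames(X) <- paste0("v", 1:p)
    X <- standardize_covariates(X)$Z
    y <- drop(X %*% c(1, -1, 0.5, 0, 0, 0, 0)) + rnorm(n, 0, 0.5)
    path <- lars_fit(X, y)
    for (st in path$steps) {
      if (!length(st$active)) next
      r <- y - mean(y) - drop(X %*% st$beta)
      cvec <- drop(crossprod(X, r))
      # at the terminal OLS step the residual correlations are numerically
      # zero and their signs are noise; the invariant applies on the interior
      nz <- st$active[st$beta[st$active] != 0 & abs(cvec[st$active]) > 1e-6]
      expect_true(all(sign(st$beta[nz]) == sign(cvec[nz])))
    }
    # RSS is non-increasing along the path
    rss <- vapply(path$steps, `[[`, numeric(1), "rss")
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("a dropped coefficient is exactly zero and the path continues", {
  found_drop <- FALSE
  for (seed in 150:300) {
    set.seed(seed)
    n <- 25; p <- 6
    S <- 0.8^abs(outer(1:p, 1:p, "-"))
    X <- standardize_covariates(matrix(rnorm(n * p), n, p,
                                       dimnames = list(NULL, paste0("v", 1:p))) %*% chol(S))$Z
    y <- drop(X %*% c(2, -2, 1.5, 0, 0, 0)) + rnorm(n, 0, 0.6)
    path <- lars_fit(X, y)
    sizes <- vapply(path$steps, function(s) length(s$active), integer(1))
    if (any(diff(sizes) < 0)) {
      found_drop <- TRUE
      k <- which(diff(sizes) < 0)[1] + 1
      gone <- setdiff(path$steps[[k - 1]]$active, path$steps[[k]]$active)
      expect_identical(unname(path$steps[[k]]$beta[gone]), 0)
    }
  }
  expect_true(found_drop)  # the lasso modification is actually exercised
})

test_that("final path step equals OLS when n > p and X has full rank", {
  tp <- toy_problem(n = 50, p = 6, seed = 9)
  path <- lars_fit(tp$X, tp$y)
  ols <- coef(lm(tp$y ~ tp$X))
  expect_equal(unname(path$steps[[length(path$steps)]]$beta),
               unname(ols[-1]), tolerance = 1e-8)
  expect_equal(path$intercept + drop(tp$X %*% path$steps[[length(path$steps)]]$beta),
               unname(fitted(lm(tp$y ~ tp$X))), tolerance = 1e-8)
})

test_that("non-standardized input is rejected", {
  tp <- toy_problem(seed = 2)
  expect_error(lars_fit(tp$X * 3, tp$y), "standardized")
  expect_error(lars_fit(tp$X + 1, tp$y), "standardized")
})

test_that("full-model Cp equals p + 1 under the classical variance estimator", {
  for (seed in 1:5) {
    tp <- toy_problem(n = 45, p = 7, coefs = c(v1 = 0.6), seed = seed)
    path <- lars_fit(tp$X, tp$y)
    expect_equal(path$cp[length(path$cp)], ncol(tp$X) + 1, tolerance = 1e-8)
  }
})

test_that("null-model Cp on pure noise has expectation about 1 under exact sigma2", {
  set.seed(101)
  n <- 50
  cp0 <- replicate(1000, {
    y <- rnorm(n)
    rss0 <- sum((y - mean(y))^2)
    mallows_cp(list(steps = list(list(rss = rss0, df = 1L)), n = n), sigma2 = 1)
  })
  # Cp0 = RSS0 - n + 2 with RSS0 ~ chisq(n-1): mean 1, sd sqrt(2(n-1))
  expect_lt(abs(mean(cp0) - 1), 3 * sqrt(2 * (n - 1)) / sqrt(1000))
})

test_that("the RSS/sigma2 term is linear in 1/sigma2", {
  tp <- toy_problem(seed = 4)
  path <- lars_fit(tp$X, tp$y)
  cp1 <- mallows_cp(path, sigma2 = 0.1)
  cp2 <- mallows_cp(path, sigma2 = 0.2)
  rss <- vapply(path$steps, `[[`, numeric(1), "rss")
  df <- vapply(path$steps, `[[`, numeric(1), "df")
  expect_equal(cp1 - (2 * df - path$n), 2 * (cp2 - (2 * df - path$n)),
               tolerance = 1e-10)
})

test_that("minimum-Cp selection honours the first-minimum tie rule", {
  tp <- toy_problem(seed = 6)
  path <- lars_fit(tp$X, tp$y)
  # strictly decreasing Cp selects the last step
  path$cp <- rev(seq_along(path$steps))
  expect_identical(select_min_cp(path)$step, length(path$steps))
  # an exact tie selects the earlier, sparser step
  path$cp <- c(5, 1, 1, rep(9, length(path$steps) - 3))
  expect_identical(select_min_cp(path)$step, 2L)
  # coefficients outside the active set are exactly zero
  sel <- select_min_cp(lars_fit(tp$X, tp$y))
  expect_identical(unname(sel$coefficients[setdiff(names(sel$coefficients),
                                                   sel$active_set)]),
                   rep(0, length(sel$coefficients) - length(sel$active_set)))
})

test_that("a nearly collinear entrant is skipped with a warning and the path continues", {
  set.seed(8)
  n <- 30
  X <- standardize_covariates(cbind(v1 = rnorm(n), v2 = rnorm(n),
                                    v3 = rnorm(n)))$Z
  near <- X[, "v1"] + rnorm(n, 0, 1e-9)
  X2 <- cbind(X, v_near = standardize_covariates(cbind(near))$Z[, 1])
  y <- 2 + X2[, "v1"] + 0.5 * X2[, "v2"] + rnorm(n, 0, 0.3)
  expect_warning(path <- lars_fit(X2, y, sigma2 = 0.09), "rank-deficient")
  # the survivor of the collinear pair carries the signal and the other
  # covariates still enter
  final <- path$steps[[length(path$steps)]]
  expect_true(all(c("v2", "v3") %in% final$active))
  expect_true(xor("v1" %in% final$active, "v_near" %in% final$active))
})
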