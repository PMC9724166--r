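test_that("response transform applies the half-limit substitution rule", {
  expect_equal(transform_response(100, FALSE, 1, "log10"), 2)
  # censored coliphage at detection limit 1.6 under log10(C+1)
  expect_equal(transform_response(0, TRUE, 1.6, "log10_plus1"),
               log10(0.8 + 1), tolerance = 1e-12)
  # censored qPCR response at LLQ 679
  expect_equal(transform_response(0, TRUE, 679, "log10"),
               log10(339.5), tolerance = 1e-12)
  # the substitution switch: substitute the limit itself
  expect_equal(transform_response(0, TRUE, 679, "log10",
                                  censored_substitution = "limit"),
               log10(679), tolerance = 1e-12)
  expect_error(transform_response(0, FALSE, 1, "log10"), "censoring flag")
})

test_that("response transform is monotone in concentration for fixed censoring", {
  conc <- sort(runif(50, 0.01, 1000))
  for (tr in c("log10", "log10_plus1")) {
    v <- transform_response(conc, rep(FALSE, 50), 1, tr)
    expect_true(all(diff(v) > 0))
  }
})

test_that("wind decomposition has the stated geometry and preserves speed", {
  expect_equal(unlist(decompose_wind(0, 123, 45)), c(wind_a = 0, wind_o = 0))
  # wind blowing from offshore straight onto a south-facing beach
  w <- decompose_wind(10, 0, 180)
  expect_equal(w$wind_a, 0, tolerance = 1e-12)
  expect_equal(abs(w$wind_o), 10, tolerance = 1e-12)
  # 45 degrees off the shore-normal splits the speed equally
  w45 <- decompose_wind(5, 45, 180)
  expect_equal(abs(w45$wind_a), 5 / sqrt(2), tolerance = 1e-12)
  expect_equal(abs(w45$wind_o), 5 / sqrt(2), tolerance = 1e-12)
  # Pythagorean identity for arbitrary inputs
  set.seed(1)
  sp <- runif(100, 0, 40); dir <- runif(100, 0, 360); bo <- runif(100, 0, 360)
  w <- decompose_wind(sp, dir, bo)
  expect_equal(w$wind_a^2 + w$wind_o^2, sp^2, tolerance = 1e-10)
  expect_error(decompose_wind(-1, 0, 0), "non-negative")
})

test_that("standardization is exact, invertible and shift-invariant", {
  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize_covariates(X)
  expect_true(all(abs(colMeans(st$Z)) < 1e-10))
  expect_true(all(abs(apply(st$Z, 2, sd) - 1) < 1e-10))
  # location shift leaves Z unchanged
  st2 <- standardize_covariates(X + 100)
  expect_equal(st$Z, st2$Z, tolerance = 1e-10)
  # applying stored params to new data and inverting recovers the input
  Xnew <- matrix(rnorm(30, 5, 3), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  Znew <- standardize_covariates(Xnew, params = st$params)$Z
  expect_equal(invert_standardization(Znew, st$params), Xnew, tolerance = 1e-12)
  X[, "b"] <- 7
  expect_error(standardize_covariates(X), "b")
})

test_that("collinearity filtering drops one member per flagged pair", {
  set.seed(3)
  n <- 200
  base <- rnorm(n)
  X <- cbind(uv254 = base + rnorm(n, 0, 0.55),
             doc = base + rnorm(n, 0, 0.55),
             other = rnorm(n))
  stopifnot(abs(cor(X[, 1], X[, 2])) >= 0.7)
  res <- collinearity_filter(X, threshold = 0.7, exclude = "uv254")
  expect_identical(res$dropped, "uv254")
  expect_true(all(c("doc", "other") %in% res$retained))
  # nothing flagged, nothing dropped
  res2 <- collinearity_filter(matrix(rnorm(300), 100, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  expect_length(res2$dropped, 0)
  expect_error(collinearity_filter(X, threshold = 0), "0, 1")
})

test_that("a mutually collinear triple keeps exactly one survivor", {
  set.seed(4)
  n <- 300
  base <- rnorm(n)
  X <- cbind(p = base + rnorm(n, 0, 0.2),
             q = base + rnorm(n, 0, 0.2),
             r = base + rnorm(n, 0, 0.2),
             indep = rnorm(n))
  res <- collinearity_filter(X, threshold = 0.8)
  expect_length(intersect(res$retained, c("p", "q", "r")), 1)
  expect_true("indep" %in% res$retained)
  expect_length(res$dropped, 2)
})

test_that("filtering commutes with standardization", {
  set.seed(5)
  n <- 150
  base <- rnorm(n)
  X <- cbind(a = base + rnorm(n, 0, 0.3), b = base + rnorm(n, 0, 0.3),
             c = rnorm(n))
  f_raw <- collinearity_filter(X, threshold = 0.8)
  f_std <- collinearity_filter(standardize_covariates(X)$Z, threshold = 0.8)
  expect_identical(f_raw$retained, f_std$retained)
  expect_identical(f_raw$dropped, f_std$dropped)
})

test_that("indicator summaries match hand-computed log10 statistics", {
  n <- 6
  conc <- c(10, 1000, 10, 1000, 5, 5)     # log10: 1,3,1,3 and two censored
  cens <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ev <- data.frame(date = as.Date("2021-06-01") + 1:n,
                   turbidity = runif(n),
                   ind_conc = conc, ind_censored = cens)
  season <- beach_season("s", ev, "ind", c(ind = 20), c(ind = "log10"))
  d <- describe_indicators(season)
  lg <- c(1, 3, 1, 3, 1, 1)               # censored -> log10(20/2) = 1
  expect_equal(d$mean, mean(lg))
  expect_equal(d$sd, sd(lg))
  expect_equal(d$cv, sd(lg) / mean(lg))
  expect_identical(d$n_censored, 2L)
  expect_false(d$all_censored)

  # two uncensored log10 values {1, 3}: mean 2, sd sqrt(2), cv ~ 0.707
  ev2 <- data.frame(date = as.Date("2021-06-01") + 1:2, turbidity = 1:2,
                    ind_conc = c(10, 1000), ind_censored = c(FALSE, FALSE))
  s2 <- beach_season("s", ev2, "ind", c(ind = 1), c(ind = "log10"))
  d2 <- describe_indicators(s2)
  expect_equal(d2$mean, 2)
  expect_equal(d2$sd, sqrt(2))
  expect_equal(d2$cv, sqrt(2) / 2, tolerance = 1e-12)

  # a single repeated value has sd 0 and cv 0
  ev3 <- data.frame(date = as.Date("2021-06-01") + 1:3, turbidity = 1:3,
                    ind_conc = rep(100, 3), ind_censored = rep(FALSE, 3))
  d3 <- describe_indicators(beach_season("s", ev3, "ind", c(ind = 1),
                                         c(ind = "log10")))
  expect_equal(d3$sd, 0)
  expect_equal(d3$cv, 0)
})

test_that("pooled non-detect frequency is the ratio of summed counts", {
  expect_equal(nondetect_frequency(c(2, 3), c(10, 10)), 25)
  expect_equal(nondetect_frequency(0, 50), 0)
})

test_that("build_model_frame assembles a standardized, filtered frame", {
  season <- toy_season(n = 50, seed = 6)
  fr <- build_model_frame(season, "ind_a")
  expect_s3_class(fr, "model_frame")
  expect_true(all(abs(colMeans(fr$X)) < 1e-10))
  expect_true(all(abs(apply(fr$X, 2, sd) - 1) < 1e-10))
  expect_identical(nrow(fr$X), nrow(season$events))
  # censored responses carry the half-limit substitution
  i <- which(fr$censored)[1]
  expect_equal(fr$y[i], log10(season$limits[["ind_a"]] / 2))
  # wind decomposition replaces speed/direction when orientation is known
  ev <- season$events
  ev$wind_speed <- runif(50, 0, 30)
  ev$wind_direction <- runif(50, 0, 360)
  s2 <- beach_season("toy", ev, season$indicators, season$limits,
                     season$transforms, beach_orientation = 200)
  fr2 <- build_model_frame(s2, "ind_a")
  expect_true(all(c("wind_a", "wind_o") %in% fr2$column_names))
  expect_false(any(c("wind_speed", "wind_direction") %in% fr2$column_names))
})
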