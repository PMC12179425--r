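test_that("a standard-normal complete pair contributes 2*log(2*pi)", {
  d <- data.frame(pair_id = "p1", zygosity = "MZ", y_t1 = 0, y_t2 = 0)
  m2ll <- fiml_minus2ll(d, list(mean = c(0, 0), cov = diag(2)), traits = "y")
  expect_equal(m2ll, 2 * log(2 * pi), tolerance = 1e-12)
})

test_that("FIML equals the brute-force MVN density oracle with missing data", {
  set.seed(55)
  for (rep in 1:10) {
    p <- random_ace_params()
    d <- simulate_twin_data(sim_spec(12, 8, p, missing_rate = 0.25,
                                     seed = rep))
    mean_fn <- function(z) rep(p$means, 2)
    cov_fn <- function(z) build_pair_covariance(p, z)
    expect_equal(fiml_minus2ll(d, p),
                 oracle_m2ll(d, p$traits, mean_fn, cov_fn),
                 tolerance = 1e-10)
  }
})

test_that("an incomplete pair contributes exactly its marginal density", {
  p <- ace_params("y", A = 0.3, C = 0.4, E = 0.3, means = 1, total_var = 2)
  d <- data.frame(pair_id = "p1", zygosity = "DZ", y_t1 = 0.7,
                  y_t2 = NA_real_)
  expect_equal(fiml_minus2ll(d, p),
               -2 * dnorm(0.7, mean = 1, sd = sqrt(2), log = TRUE),
               tolerance = 1e-12)
})

test_that("saturated FIML reproduces closed-form complete-data moments", {
  d <- biv_data(n_mz = 120, n_dz = 100, seed = 6)
  f <- fit_saturated(d)
  expect_equal(f$k, 28L)
  expect_true(f$converged)
  cols <- c("motor_t1", "soccom_t1", "motor_t2", "soccom_t2")
  for (z in c("MZ", "DZ")) {
    Y <- as.matrix(d[d$zygosity == z, cols])
    n <- nrow(Y)
    expect_equal(unname(f$params[[z]]$mean), unname(colMeans(Y)),
                 tolerance = 1e-4)
    ml_cov <- cov(Y) * (n - 1) / n
    expect_equal(unname(f$params[[z]]$cov), unname(ml_cov),
                 tolerance = 1e-3)
  }
  ## the FIML optimum equals the closed-form saturated -2LL
  closed <- 0
  for (z in c("MZ", "DZ")) {
    Y <- as.matrix(d[d$zygosity == z, cols])
    n <- nrow(Y); S <- cov(Y) * (n - 1) / n
    closed <- closed + n * (4 * log(2 * pi) + log(det(S)) + 4)
  }
  expect_equal(f$minus2LL, closed, tolerance = 1e-4)
})

test_that("model parameter counts match the design", {
  d <- biv_data(n_mz = 80, n_dz = 70, seed = 12)
  expect_equal(fit_saturated(d, "motor")$k, 10L)
  expect_equal(fit_univariate_ace(d, "motor")$k, 4L)
  expect_equal(fit_bivariate_correlated_factors(d)$k, 11L)
})

test_that("the nested model ladder is monotone in -2LL", {
  d <- biv_data(n_mz = 100, n_dz = 80, missing_rate = 0.02, seed = 14)
  sat_uni <- fit_saturated(d, "motor")
  at <- suppressWarnings(assumption_tests(d, "motor"))
  prev <- sat_uni$minus2LL
  for (f in at$fits) {
    expect_gte(f$minus2LL, prev - 1e-6)
    prev <- f$minus2LL
  }
  uni <- fit_univariate_ace(d, "motor")
  expect_gte(uni$minus2LL, at$fits$model4$minus2LL - 1e-6)
  sat_biv <- fit_saturated(d)
  cf <- fit_bivariate_correlated_factors(d)
  expect_gte(cf$minus2LL, sat_biv$minus2LL - 1e-6)
  cmp <- compare_models(sat_biv, cf)
  expect_gte(cmp$delta_LL, 0)
  expect_equal(cmp$delta_df, 17L)
})

test_that("assumption tests detect a shifted co-twin mean", {
  d <- uni_data(n_mz = 250, n_dz = 200, seed = 16)
  d$y_t2 <- d$y_t2 + 1  # one SD shift of twin 2
  expect_warning(at <- assumption_tests(d, "y"), "rejected")
  expect_lt(at$comparisons$p[1], 1e-6)
})

test_that("fits are invariant to rescaling the traits", {
  d <- biv_data(n_mz = 90, n_dz = 70, seed = 18)
  d10 <- d
  for (cl in c("motor_t1", "motor_t2", "soccom_t1", "soccom_t2"))
    d10[[cl]] <- d[[cl]] * 10
  f1 <- fit_bivariate_correlated_factors(d)
  f10 <- fit_bivariate_correlated_factors(d10)
  expect_lt(max(abs(f1$params$A - f10$params$A)), 5e-4)
  expect_lt(max(abs(f1$params$C - f10$params$C)), 5e-4)
  expect_lt(abs(f1$params$r_c - f10$params$r_c), 5e-4)
  sat1 <- fit_saturated(d); sat10 <- fit_saturated(d10)
  expect_lt(abs((sat1$minus2LL - f1$minus2LL) -
                (sat10$minus2LL - f10$minus2LL)), 1e-3)
})

test_that("degenerate designs and models are rejected", {
  d <- uni_data(n_mz = 60, n_dz = 0, seed = 20)
  expect_error(fit_univariate_ace(d, "y"), "not jointly identified")
  d2 <- biv_data(n_mz = 60, n_dz = 50, seed = 20)
  f <- fit_univariate_ace(d2, "motor")
  sat <- fit_saturated(d2, "motor")
  expect_error(compare_models(f, sat), "not nested")
})

test_that("pure unique environment yields near-zero A and C", {
  d <- simulate_twin_data(sim_spec(400, 300,
                                   ace_params("y", A = 0, C = 0, E = 1),
                                   missing_rate = 0, seed = 22))
  f <- fit_univariate_ace(d, "y")
  expect_lt(f$params$A, 0.08)
  expect_lt(f$params$C, 0.08)
})

test_that("information criteria follow their definitions", {
  d <- uni_data(seed = 24)
  f <- fit_univariate_ace(d, "y")
  expect_equal(f$aic, f$minus2LL + 2 * f$k, tolerance = 1e-9)
  expect_equal(f$bic, f$minus2LL + f$k * log(f$n_pairs), tolerance = 1e-9)
  expect_equal(f$df, f$n_obs - f$k)
})

test_that("profile CIs are near-symmetric in the quadratic regime and shrink with n", {
  d_small <- uni_data(n_mz = 164, n_dz = 131, A = 0.3, C = 0.4, seed = 26)
  d_large <- uni_data(n_mz = 656, n_dz = 524, A = 0.3, C = 0.4, seed = 26)
  f_s <- fit_univariate_ace(d_small, "y")
  f_l <- fit_univariate_ace(d_large, "y")
  ci_s <- profile_ci(f_s, "C")
  ci_l <- profile_ci(f_l, "C")
  est_l <- f_l$params$C
  ## near-quadratic likelihood at the larger n: roughly symmetric bounds
  expect_lt(abs((est_l - ci_l[["low"]]) - (ci_l[["high"]] - est_l)), 0.04)
  ratio <- (ci_s[["high"]] - ci_s[["low"]]) / (ci_l[["high"]] - ci_l[["low"]])
  expect_lt(abs(ratio - 2), 0.7)
})

test_that("profile bounds respect and flag the parameter domain", {
  d <- biv_data(n_mz = 164, n_dz = 131, seed = 28)
  f <- fit_bivariate_correlated_factors(d)
  ci <- profile_ci(f, "rA")
  expect_gte(ci[["low"]], -1)
  expect_lte(ci[["high"]], 1)
  if (attr(ci, "pinned_low")) expect_equal(ci[["low"]], -1)
})
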