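test_that("GEE on singleton clusters reduces to OLS with HC0 errors", {
  set.seed(11)
  n <- 80
  d <- data.frame(pair_id = sprintf("p%03d", 1:n), zygosity = "MZ",
                  y_t1 = rnorm(n), y_t2 = NA_real_,
                  x_t1 = rnorm(n), x_t2 = NA_real_)
  f <- fit_gee(d, "y", "x", working_correlation = "exchangeable",
               standardize = FALSE)
  m <- lm(y_t1 ~ x_t1, data = d)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-8)
  hc0 <- sqrt(diag(sandwich::vcovHC(m, type = "HC0")))
  expect_equal(unname(f$robust_se), unname(hc0), tolerance = 1e-8)
})

test_that("GEE matches the cluster-robust sandwich oracle on twin data", {
  d <- simulate_twin_data(batss_sim_spec(seed = 13))
  f <- fit_gee(d, "motor", c("age", "income"),
               working_correlation = "independence", standardize = FALSE)
  long <- rbind(
    data.frame(pair_id = d$pair_id, motor = d$motor_t1, age = d$age_t1,
               income = d$income_t1),
    data.frame(pair_id = d$pair_id, motor = d$motor_t2, age = d$age_t2,
               income = d$income_t2))
  long <- long[complete.cases(long), ]
  m <- lm(motor ~ age + income, data = long)
  v <- sandwich::vcovCL(m, cluster = long$pair_id, type = "HC0",
                        cadjust = FALSE)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-8)
  expect_equal(unname(f$robust_se), unname(sqrt(diag(v))), tolerance = 1e-8)
})

test_that("fitted coefficients solve the estimating equations", {
  ## tiny 3-cluster dataset checked against the estimating equations directly
  d <- data.frame(pair_id = c("p1", "p2", "p3"), zygosity = "DZ",
                  y_t1 = c(1.2, -0.5, 2.2), y_t2 = c(0.8, 0.1, 1.7),
                  x_t1 = c(0.3, -1.1, 0.9), x_t2 = c(0.5, -0.7, 1.4))
  f <- fit_gee(d, "y", "x", working_correlation = "exchangeable",
               standardize = FALSE)
  ## residual score per cluster under the fitted working correlation
  score <- numeric(2)
  for (i in 1:3) {
    Xi <- cbind(1, c(d$x_t1[i], d$x_t2[i]))
    yi <- c(d$y_t1[i], d$y_t2[i])
    Ri <- matrix(c(1, f$alpha, f$alpha, 1), 2, 2)
    score <- score + drop(t(Xi) %*% solve(Ri, yi - Xi %*% f$coefficients))
  }
  expect_equal(score, c(0, 0), tolerance = 1e-8)
})

test_that("sandwich covariance is symmetric PSD and exchangeable agrees with independence", {
  d <- simulate_twin_data(batss_sim_spec(seed = 17))
  for (wc in c("exchangeable", "independence")) {
    f <- fit_gee(d, "soccom", c("age", "term_age", "income"), wc)
    expect_true(isSymmetric(f$vcov, tol = 1e-10))
    expect_gte(min(eigen(f$vcov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
    expect_true(f$converged)
  }
  fe <- fit_gee(d, "motor", "age", "exchangeable")
  fi <- fit_gee(d, "motor", "age", "independence")
  expect_lt(abs(unname(fe$coefficients["age"]) -
                unname(fi$coefficients["age"])), 0.02)
})

test_that("rank-deficient and degenerate designs are rejected with names", {
  d <- simulate_twin_data(batss_sim_spec(seed = 19))
  d$age2_t1 <- d$age_t1; d$age2_t2 <- d$age_t2
  expect_error(fit_gee(d, "motor", c("age", "age2")), "age2")
  d$flat_t1 <- 1; d$flat_t2 <- 1
  expect_error(fit_gee(d, "motor", c("age", "flat")), "flat")
})

test_that("a generating covariate effect is recovered with CI excluding zero", {
  p <- batss_ace_params(unit_scale = TRUE)
  cov_age <- list(covariate_spec("age", "normal", mean = 167.29, sd = 8.88,
                                 effects = c(motor = 0.28), level = "pair"))
  d <- simulate_twin_data(sim_spec(164, 131, p, missing_rate = 0.01,
                                   covariates = cov_age, seed = 23))
  f <- fit_gee(d, "motor", "age")
  expect_lt(abs(unname(f$coefficients["age"]) - 0.28), 0.08)
  expect_gt(unname(f$ci_low["age"]), 0)
})

test_that("covariate screening retains the generating effects", {
  d <- simulate_twin_data(batss_sim_spec(seed = 30))
  cand <- c("age", "term_age", "sex", "parental_age", "parental_education",
            "income")
  sc <- screen_covariates(d, c("motor", "soccom"), cand)
  expect_true(all(c("age", "income") %in% sc$retained))
  ## null covariates may slip in at roughly the alpha rate, but not en masse
  expect_lte(length(setdiff(sc$retained,
                            c("age", "term_age", "income"))), 1)
  ## marginal mode produces one row per candidate and trait too
  scm <- screen_covariates(d, "motor", c("age", "income"), joint = FALSE)
  expect_equal(nrow(scm$table), 2)
})

test_that("residualization centres scores and removes covariate signal", {
  d <- simulate_twin_data(batss_sim_spec(seed = 31))
  r <- residualize(d, "motor", c("age", "term_age", "income"))
  res <- c(r$motor_t1, r$motor_t2)
  expect_lt(abs(mean(res, na.rm = TRUE)), 1e-9)
  for (cv in c("age", "term_age", "income")) {
    x <- c(d[[paste0(cv, "_t1")]], d[[paste0(cv, "_t2")]])
    keep <- !is.na(res) & !is.na(x)
    expect_lt(abs(cor(res[keep], x[keep])), 1e-9)
  }
  ## trait that is an exact linear function of a covariate residualizes to 0
  d$lin_t1 <- 2 * d$age_t1; d$lin_t2 <- 2 * d$age_t2
  r2 <- residualize(d, "lin", "age")
  expect_lt(max(abs(c(r2$lin_t1, r2$lin_t2)), na.rm = TRUE), 1e-9)
})

test_that("residualization leaves ACE estimates invariant to covariate effects", {
  p <- batss_ace_params(unit_scale = TRUE)
  base <- sim_spec(164, 131, p, missing_rate = 0, seed = 37)
  d_plain <- simulate_twin_data(base)
  d_cov <- simulate_twin_data(sim_spec(164, 131, p, missing_rate = 0,
                                       covariates = batss_covariates(),
                                       seed = 37))
  for (tr in c("motor", "soccom"))
    d_cov <- residualize(d_cov, tr, c("age", "term_age", "income"))
  f1 <- fit_univariate_ace(d_plain, "motor")
  f2 <- fit_univariate_ace(d_cov, "motor")
  expect_lt(abs(f1$params$A - f2$params$A), 0.06)
  expect_lt(abs(f1$params$C - f2$params$C), 0.06)
})

test_that("null PGS association is calibrated around zero", {
  d <- simulate_twin_data(batss_sim_spec(seed = 41))
  d <- simulate_pgs_columns(d, "null_score", effect_sizes = 0, seed = 42)
  f <- pgs_association(d, "soccom", "pgs_null_score")
  expect_lt(abs(unname(f$coefficients["pgs_null_score"])),
            2.5 * unname(f$robust_se["pgs_null_score"]) + 0.01)
  d$pgs_dup_t1 <- d$pgs_null_score_t1; d$pgs_dup_t2 <- d$pgs_null_score_t2
  expect_error(fit_gee(d, "soccom", c("pgs_null_score", "pgs_dup")), "dup")
})
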