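## hand-written five-pair fixture used for arithmetic oracles
five_pairs <- data.frame(
  pair_id = paste0("p", 1:5),
  zygosity = "MZ",
  y_t1 = c(1.0, 2.5, 3.0, 4.5, 5.0),
  y_t2 = c(1.2, 2.0, 3.5, 4.0, 5.5))

test_that("twin-twin correlation matches sufficient-statistics arithmetic", {
  x <- c(five_pairs$y_t1, five_pairs$y_t2)  # double-entered
  y <- c(five_pairs$y_t2, five_pairs$y_t1)
  n <- length(x)
  r_hand <- (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  rep <- twin_twin_correlation(five_pairs, "y", "MZ")
  expect_equal(rep$estimate, r_hand, tolerance = 1e-12)
  expect_equal(rep$n_pairs, 5)

  ## raw single-order estimator equals plain Pearson
  rep_raw <- twin_twin_correlation(five_pairs, "y", "MZ",
                                   double_entry = FALSE)
  expect_equal(rep_raw$estimate, cor(five_pairs$y_t1, five_pairs$y_t2),
               tolerance = 1e-12)
})

test_that("twin-twin correlation is invariant to twin labels and perfect for copies", {
  d <- uni_data(n_mz = 40, n_dz = 30, seed = 2)
  swapped <- d
  flip <- seq(1, nrow(d), by = 2)
  swapped[flip, c("y_t1", "y_t2")] <- d[flip, c("y_t2", "y_t1")]
  expect_equal(twin_twin_correlation(d, "y", "MZ")$estimate,
               twin_twin_correlation(swapped, "y", "MZ")$estimate,
               tolerance = 1e-12)
  copy <- d; copy$y_t2 <- copy$y_t1
  expect_equal(twin_twin_correlation(copy, "y", "MZ")$estimate, 1.0)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(twin_twin_correlation(five_pairs[1:2, ], "y", "MZ"),
               "fewer than 3")
  const <- five_pairs; const$y_t1 <- 1
  expect_error(twin_twin_correlation(const, "y", "MZ"), "zero variance")
})

test_that("Fisher-z CI brackets the estimate and narrows with n", {
  widths <- sapply(c(30, 120, 480), function(n) {
    d <- uni_data(n_mz = n, n_dz = 10, seed = 5)
    r <- twin_twin_correlation(d, "y", "MZ")
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
    r$ci_high - r$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("cross-twin cross-trait correlation behaves at its degenerate limits", {
  d <- biv_data(seed = 3)
  ## same trait twice: double-entered twin-twin correlation
  expect_equal(
    cross_twin_cross_trait_correlation(d, "motor", "motor", "MZ")$estimate,
    twin_twin_correlation(d, "motor", "MZ")$estimate,
    tolerance = 1e-12)
  ## independent traits: near zero
  p0 <- ace_params(c("a", "b"), A = c(0.4, 0.4), C = c(0.3, 0.3),
                   E = c(0.3, 0.3), r_a = 0, r_c = 0, r_e = 0)
  d0 <- simulate_twin_data(sim_spec(3000, 0, p0, missing_rate = 0, seed = 9))
  expect_lt(abs(cross_twin_cross_trait_correlation(d0, "a", "b",
                                                   "MZ")$estimate), 0.05)
})

test_that("phenotypic correlation is exact for identical traits and near zero for independent ones", {
  d <- biv_data(n_mz = 100, n_dz = 80, seed = 4)
  d$same_t1 <- d$motor_t1; d$same_t2 <- d$motor_t2
  expect_equal(phenotypic_correlation(d, "motor", "same",
                                      n_boot = 50)$estimate, 1.0)
  p0 <- ace_params(c("a", "b"), A = c(0.4, 0.4), C = c(0.3, 0.3),
                   E = c(0.3, 0.3), r_a = 0, r_c = 0, r_e = 0)
  d0 <- simulate_twin_data(sim_spec(2000, 2000, p0, missing_rate = 0,
                                    seed = 10))
  r0 <- phenotypic_correlation(d0, "a", "b", n_boot = 200, seed = 2)
  expect_lt(abs(r0$estimate), 0.04)
  expect_lte(r0$ci_low, r0$estimate)
  expect_gte(r0$ci_high, r0$estimate)
})

test_that("moments match hand-computed adjusted Fisher-Pearson estimators", {
  v <- c(2.1, 3.7, 1.4, 5.9, 4.2, 2.8, 6.3)
  d <- data.frame(pair_id = paste0("p", 1:4), zygosity = "MZ",
                  y_t1 = c(v[1:3], NA), y_t2 = v[4:7])
  n <- length(v); m <- mean(v); s2 <- sum((v - m)^2) / n
  g1 <- (sum((v - m)^3) / n) / s2^1.5
  skew_hand <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- (sum((v - m)^4) / n) / s2^2 - 3
  kurt_hand <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  out <- moment_descriptives(d, "y")
  expect_equal(out$mean, m, tolerance = 1e-12)
  expect_equal(out$sd, sd(v), tolerance = 1e-12)
  expect_equal(out$skewness, skew_hand, tolerance = 1e-10)
  expect_equal(out$kurtosis, kurt_hand, tolerance = 1e-10)
  const <- d; const$y_t1 <- 1; const$y_t2 <- 1
  expect_error(moment_descriptives(const, "y"), "constant")
})

test_that("MZ-DZ twin correlation gap estimates half the heritability", {
  d <- simulate_twin_data(sim_spec(20000, 20000,
                                   ace_params("y", A = 0.5, C = 0.3, E = 0.2),
                                   missing_rate = 0, seed = 77))
  gap <- twin_twin_correlation(d, "y", "MZ")$estimate -
    twin_twin_correlation(d, "y", "DZ")$estimate
  expect_lt(abs(gap - 0.25), 0.02)
})
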