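test_that("pair covariance carries the biometric structure", {
  p <- ace_params("motor", A = 0.21, C = 0.67, E = 0.12)
  mz <- build_pair_covariance(p, "MZ")
  dz <- build_pair_covariance(p, "DZ")
  expect_equal(mz["motor_t1", "motor_t2"], 0.88)
  expect_equal(dz["motor_t1", "motor_t2"], 0.775)
  expect_equal(diag(mz), c(motor_t1 = 1, motor_t2 = 1))

  ## pure unique environment: independent twins
  e_only <- ace_params("y", A = 0, C = 0, E = 1)
  expect_equal(build_pair_covariance(e_only, "MZ"),
               diag(2), ignore_attr = TRUE)
  expect_equal(build_pair_covariance(e_only, "DZ"),
               diag(2), ignore_attr = TRUE)
})

test_that("pair covariance is PSD and MZ-DZ cross block equals half Sigma_A", {
  set.seed(42)
  for (rep in 1:25) {
    p <- random_ace_params()
    for (z in c("MZ", "DZ")) {
      ev <- eigen(build_pair_covariance(p, z), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
    cross_mz <- build_pair_covariance(p, "MZ")[1:2, 3:4]
    cross_dz <- build_pair_covariance(p, "DZ")[1:2, 3:4]
    sig <- sqrt(p$total_var)
    S_A <- p$r_a * sqrt(p$A[1] * p$A[2]) * sig[1] * sig[2]
    S_A <- matrix(c(p$A[1] * p$total_var[1], S_A, S_A,
                    p$A[2] * p$total_var[2]), 2, 2)
    expect_equal(cross_mz - cross_dz, 0.5 * S_A, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("ACE parameter validation rejects inconsistent inputs", {
  expect_error(ace_params("y", A = 0.5, C = 0.6, E = 0.2), "equal 1")
  expect_error(ace_params("y", A = -0.1, C = 0.9, E = 0.2), "A >= 0")
  expect_error(ace_params(c("a", "b"), A = c(0.3, 0.3), C = c(0.3, 0.3),
                          E = c(0.4, 0.4), r_a = 1.2), "\\[-1, 1\\]")
  expect_error(sim_spec(0, 0, ace_params("y", A = 0.3, C = 0.3, E = 0.4)),
               "at least one pair")
})

test_that("simulated twin correlations recover the generating values", {
  p <- ace_params("y", A = 0.5, C = 0.3, E = 0.2)
  d <- simulate_twin_data(sim_spec(5000, 5000, p, missing_rate = 0,
                                   seed = 101))
  rmz <- twin_twin_correlation(d, "y", "MZ")$estimate
  rdz <- twin_twin_correlation(d, "y", "DZ")$estimate
  expect_lt(abs(rmz - 0.80), 0.02)
  expect_lt(abs(rdz - 0.55), 0.02)
})

test_that("large-sample empirical covariance matches the implied matrix", {
  p <- batss_ace_params(unit_scale = TRUE)
  d <- simulate_twin_data(sim_spec(25000, 25000, p, missing_rate = 0,
                                   seed = 1))
  cols <- c("motor_t1", "soccom_t1", "motor_t2", "soccom_t2")
  for (z in c("MZ", "DZ")) {
    emp <- cov(d[d$zygosity == z, cols])
    imp <- build_pair_covariance(p, z)[cols, cols]
    expect_lt(max(abs(emp - imp)), 0.02)
  }
})

test_that("missingness behaves as configured", {
  d0 <- simulate_twin_data(sim_spec(50, 50, batss_ace_params(),
                                    missing_rate = 0, seed = 3))
  expect_false(anyNA(d0[, c("motor_t1", "motor_t2", "soccom_t1", "soccom_t2")]))
  d1 <- simulate_twin_data(sim_spec(300, 300, batss_ace_params(),
                                    missing_rate = 0.2, seed = 3))
  trait_cols <- c("motor_t1", "motor_t2", "soccom_t1", "soccom_t2")
  expect_true(anyNA(d1[, trait_cols]))
  ## no pair is entirely missing
  expect_true(all(rowSums(!is.na(d1[, trait_cols])) > 0))
})

test_that("generation is deterministic under a fixed seed (byte-identical file)", {
  spec <- batss_sim_spec(seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pairs(simulate_twin_data(spec), f1)
  write_pairs(simulate_twin_data(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d3 <- simulate_twin_data(batss_sim_spec(seed = 100))
  expect_false(identical(read_pairs(f1)$motor_t1, d3$motor_t1))
})

test_that("pairs round-trip through CSV with sidecar metadata", {
  d <- simulate_twin_data(batss_sim_spec(n_mz = 20, n_dz = 15, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_pairs(d, f)
  expect_true(file.exists(paste0(f, ".json")))
  d2 <- read_pairs(f)
  expect_equal(attr(d2, "traits"), c("motor", "soccom"))
  expect_equal(d2$motor_t1, d$motor_t1, tolerance = 1e-12)
})

test_that("simulated polygenic scores respect genetic sharing", {
  d <- simulate_twin_data(batss_sim_spec(n_mz = 2000, n_dz = 2000,
                                         missing_rate = 0, seed = 8))
  d <- simulate_pgs_columns(d, "adhd", effect_sizes = 0, seed = 21)
  mz <- d$zygosity == "MZ"
  expect_identical(d$pgs_adhd_t1[mz], d$pgs_adhd_t2[mz])
  expect_lt(abs(cor(d$pgs_adhd_t1[!mz], d$pgs_adhd_t2[!mz]) - 0.5), 0.05)
  expect_true(all(paste0("pc", 1:10, "_t1") %in% names(d)))
  expect_error(simulate_pgs_columns(d, character(0)), "at least one")
})

test_that("a generated PGS effect is recovered by the GEE association", {
  d <- simulate_twin_data(sim_spec(1500, 1500,
                                   batss_ace_params(unit_scale = TRUE),
                                   missing_rate = 0, seed = 31))
  d <- simulate_pgs_columns(d, "risk", effect_sizes = 0.3, seed = 32)
  f <- pgs_association(d, "motor", "pgs_risk")
  expect_lt(abs(unname(f$coefficients["pgs_risk"]) - 0.3), 0.05)
})
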