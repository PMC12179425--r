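## Shared fixtures and independent oracles for the test suite.

## Brute-force FIML oracle: per-pair multivariate-normal -2 log density via
## generic solve()/det() linear algebra, independent of the pattern-grouped
## sufficient-statistic implementation.
oracle_m2ll <- function(data, traits, mean_fn, cov_fn) {
  cols <- c(paste0(traits, "_t1"), paste0(traits, "_t2"))
  total <- 0
  for (i in seq_len(nrow(data))) {
    y <- as.numeric(data[i, cols])
    obs <- which(!is.na(y))
    if (!length(obs)) next
    z <- as.character(data$zygosity[i])
    mu <- mean_fn(z)[obs]
    S <- cov_fn(z)[obs, obs, drop = FALSE]
    r <- y[obs] - mu
    total <- total + length(obs) * log(2 * pi) +
      log(det(S)) + drop(t(r) %*% solve(S) %*% r)
  }
  total
}

## random valid bivariate ACE parameter set (fixed-seed property loops)
random_ace_params <- function(two_traits = TRUE) {
  n_t <- if (two_traits) 2 else 1
  raw <- matrix(runif(3 * n_t, 0.05, 1), 3, n_t)
  prop <- sweep(raw, 2, colSums(raw), "/")
  ace_params(paste0("tr", seq_len(n_t)),
             means = rnorm(n_t, 0, 2),
             total_var = runif(n_t, 0.5, 4),
             A = prop[1, ], C = prop[2, ], E = prop[3, ],
             r_a = if (two_traits) runif(1, -1, 1) else 0,
             r_c = if (two_traits) runif(1, -1, 1) else 0,
             r_e = if (two_traits) runif(1, -0.95, 0.95) else 0)
}

## small simulated dataset helpers
uni_data <- function(n_mz = 80, n_dz = 60, A = 0.3, C = 0.4,
                     missing_rate = 0, seed = 1) {
  p <- ace_params("y", A = A, C = C, E = 1 - A - C)
  simulate_twin_data(sim_spec(n_mz, n_dz, p, missing_rate = missing_rate,
                              seed = seed))
}

biv_data <- function(n_mz = 164, n_dz = 131, missing_rate = 0, seed = 1) {
  simulate_twin_data(sim_spec(n_mz, n_dz, batss_ace_params(unit_scale = TRUE),
                              missing_rate = missing_rate, seed = seed))
}

## null twin-clustered regression dataset: pair-level covariate with no
## effect, within-pair trait correlation `icc`
null_gee_data <- function(n_pairs = 60, icc = 0.8) {
  shared <- rnorm(n_pairs)
  y1 <- sqrt(icc) * shared + sqrt(1 - icc) * rnorm(n_pairs)
  y2 <- sqrt(icc) * shared + sqrt(1 - icc) * rnorm(n_pairs)
  x <- rnorm(n_pairs)
  data.frame(pair_id = sprintf("p%03d", seq_len(n_pairs)),
             zygosity = rep(c("MZ", "DZ"), length.out = n_pairs),
             y_t1 = y1, y_t2 = y2, x_t1 = x, x_t2 = x)
}
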