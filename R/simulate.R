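#' ACE parameter set for one or two traits
#'
#' Bundles the biometric parameters of the (bivariate) ACE model: per-trait
#' means, total phenotypic variances, standardized variance proportions for
#' additive genetics (A), shared environment (C) and unique environment (E),
#' and — for two traits — the aetiological correlations `r_a`, `r_c`, `r_e`
#' between like-type factors.
#'
#' @param traits character vector of 1 or 2 trait names.
#' @param means per-trait phenotype means (score units).
#' @param total_var per-trait total phenotypic variances.
#' @param A,C,E per-trait standardized proportions; each trait must satisfy
#'   `A + C + E = 1`, `A >= 0`, `C >= 0`, `E > 0`.
#' @param r_a,r_c,r_e aetiological correlations in `[-1, 1]` (ignored for a
#'   single trait).
#' @return an object of class `ace_params`.
#' @examples
#' ace_params("motor", A = 0.21, C = 0.67, E = 0.12)
#' @export
ace_params <- function(traits, means = rep(0, length(traits)),
                       total_var = rep(1, length(traits)),
                       A, C, E, r_a = 0, r_c = 0, r_e = 0) {
  traits <- as.character(traits)
  n_t <- length(traits)
  if (!n_t %in% 1:2) stopf("1 or 2 traits supported, got %d", n_t)
  for (nm in c("means", "total_var", "A", "C", "E")) {
    v <- get(nm)
    if (length(v) != n_t) stopf("`%s` must have length %d", nm, n_t)
  }
  if (any(A < 0) || any(C < 0) || any(E <= 0))
    stopf("require A >= 0, C >= 0, E > 0")
  if (any(abs(A + C + E - 1) > 1e-8))
    stopf("A + C + E must equal 1 for every trait (off by %.3g)",
          max(abs(A + C + E - 1)))
  if (any(total_var <= 0)) stopf("total_var must be positive")
  for (r in c(r_a, r_c, r_e))
    if (abs(r) > 1) stopf("aetiological correlations must lie in [-1, 1]")
  structure(list(traits = traits, means = as.numeric(means),
                 total_var = as.numeric(total_var),
                 A = as.numeric(A), C = as.numeric(C), E = as.numeric(E),
                 r_a = r_a, r_c = r_c, r_e = r_e,
                 k = if (n_t == 2) 11L else 4L),
            class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat("ACE parameters (", length(x$traits), " trait",
      if (length(x$traits) > 1) "s", ")\n", sep = "")
  m <- rbind(mean = x$means, total_var = x$total_var,
             A = x$A, C = x$C, E = x$E)
  colnames(m) <- x$traits
  print(round(m, 4))
  if (length(x$traits) == 2)
    cat(sprintf("rA = %.3f, rC = %.3f, rE = %.3f\n", x$r_a, x$r_c, x$r_e))
  invisible(x)
}

## T x T component covariance matrix for X in {A, C, E}:
## diagonal X_i * sigma_i^2, off-diagonal r_X * sqrt(X_i X_j) sigma_i sigma_j
component_sigma <- function(props, sigmas, r) {
  d <- sqrt(props) * sigmas
  m <- (d %o% d) * r
  diag(m) <- props * sigmas^2
  m
}

#' Model-implied per-pair covariance matrix
#'
#' Builds the `2T x 2T` covariance matrix of a twin pair's trait vector
#' (ordered twin1 trait1, twin1 trait2, twin2 trait1, twin2 trait2) under
#' the ACE model.  The within-person block is
#' \eqn{\Sigma_A + \Sigma_C + \Sigma_E}; the cross-twin block is
#' \eqn{\Sigma_A + \Sigma_C} for MZ pairs and
#' \eqn{\tfrac12\Sigma_A + \Sigma_C} for DZ pairs, reflecting that MZ twins
#' share all and DZ twins on average half of segregating additive genetic
#' variation, while the shared environment is fully shared in both.
#'
#' @param params an [ace_params] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return symmetric positive semi-definite numeric matrix with row/column
#'   names `<trait>_t1`, `<trait>_t2`.
#' @examples
#' p <- ace_params("motor", A = 0.21, C = 0.67, E = 0.12)
#' build_pair_covariance(p, "MZ")["motor_t1", "motor_t2"]  # 0.88
#' @export
build_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  stopifnot(inherits(params, "ace_params"))
  sig <- sqrt(params$total_var)
  S_A <- component_sigma(params$A, sig, params$r_a)
  S_C <- component_sigma(params$C, sig, params$r_c)
  S_E <- component_sigma(params$E, sig, params$r_e)
  for (nm in c("S_A", "S_C", "S_E")) {
    ev <- eigen(get(nm), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stopf("component matrix %s is not positive semi-definite (min eigenvalue %.3g)",
            sub("S_", "Sigma_", nm), min(ev))
  }
  within <- S_A + S_C + S_E
  cross <- if (zygosity == "MZ") S_A + S_C else 0.5 * S_A + S_C
  out <- rbind(cbind(within, cross), cbind(t(cross), within))
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stopf("implied %s pair covariance is not positive semi-definite", zygosity)
  nm <- c(t1col(params$traits), t2col(params$traits))
  dimnames(out) <- list(nm, nm)
  out
}

#' Covariate specification for the twin-pair generator
#'
#' @param name column base name.
#' @param dist `"normal"`, `"binary"` or `"ordinal"` (rounded, clamped
#'   normal on integer levels).
#' @param mean,sd distribution parameters (normal / ordinal).
#' @param p success probability (binary).
#' @param levels integer range `c(min, max)` for ordinal.
#' @param effects named per-trait standardized slopes: the trait shifts by
#'   `effect * sqrt(total_var)` per SD of the covariate.
#' @param level `"pair"` (both twins share one draw, e.g. family income) or
#'   `"twin"` (independent per twin).
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(name, dist = c("normal", "binary", "ordinal"),
                           mean = 0, sd = 1, p = 0.5, levels = c(1L, 11L),
                           effects = numeric(), level = c("pair", "twin")) {
  structure(list(name = name, dist = match.arg(dist), mean = mean, sd = sd,
                 p = p, levels = levels, effects = effects,
                 level = match.arg(level)),
            class = "covariate_spec")
}

#' Simulation specification for a classical twin sample
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param params an [ace_params] object giving the generating biometric
#'   structure.
#' @param missing_rate probability that any one twin-trait value is missing
#'   (independent per twin and trait); pairs losing every value are dropped.
#' @param covariates list of [covariate_spec] objects.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(n_mz, n_dz, params, missing_rate = 0.01,
                     covariates = list(), seed = 1L) {
  if (n_mz + n_dz < 1) stopf("at least one pair must be requested")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must lie in [0, 1)")
  stopifnot(inherits(params, "ace_params"))
  for (z in c("MZ", "DZ")) build_pair_covariance(params, z)  # validates PSD
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 params = params, missing_rate = missing_rate,
                 covariates = covariates, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generating parameters and design of the infant adaptive-behaviour study
#'
#' Convenience constructors for the study conditions the package emulates:
#' 164 MZ + 131 DZ complete pairs, a motor trait (mean 10.27, SD 1.05) and a
#' combined social-communication trait (mean 34.22, SD 1.65), bivariate ACE
#' structure A/C/E = 0.21/0.67/0.12 and 0.12/0.78/0.10 with rA = -0.39,
#' rC = 0.45, rE = 0.32, and demographic covariates (age, term age, sex,
#' parental age/education, household income) with the reported significant
#' standardized effects on both traits (age, term age, income; the
#' non-significant covariates carry null generating effects).
#'
#' @param unit_scale if `TRUE`, traits are generated with mean 0 and unit
#'   total variance (convenient for recovery studies).
#' @return `batss_ace_params()`: an [ace_params]; `batss_covariates()`:
#'   a list of [covariate_spec]; `batss_sim_spec()`: a complete [sim_spec].
#' @export
batss_ace_params <- function(unit_scale = FALSE) {
  ace_params(c("motor", "soccom"),
             means = if (unit_scale) c(0, 0) else c(10.27, 34.22),
             total_var = if (unit_scale) c(1, 1) else c(1.05^2, 1.65^2),
             A = c(0.21, 0.12), C = c(0.67, 0.78), E = c(0.12, 0.10),
             r_a = -0.39, r_c = 0.45, r_e = 0.32)
}

#' @rdname batss_ace_params
#' @export
batss_covariates <- function() {
  list(
    covariate_spec("age", "normal", mean = 167.29, sd = 8.88,
                   effects = c(motor = 0.28, soccom = 0.15), level = "pair"),
    covariate_spec("term_age", "normal", mean = 259.21, sd = 7.84,
                   effects = c(motor = 0.17, soccom = 0.11), level = "pair"),
    covariate_spec("sex", "binary", p = 0.4765,
                   effects = c(motor = 0, soccom = 0), level = "pair"),
    covariate_spec("parental_age", "normal", mean = 35.30, sd = 4.81,
                   effects = c(motor = 0, soccom = 0), level = "pair"),
    covariate_spec("parental_education", "ordinal", mean = 4.28, sd = 0.75,
                   levels = c(1L, 5L),
                   effects = c(motor = 0, soccom = 0), level = "pair"),
    covariate_spec("income", "ordinal", mean = 7.51, sd = 2.43,
                   levels = c(1L, 11L),
                   effects = c(motor = -0.19, soccom = -0.11), level = "pair")
  )
}

#' @rdname batss_ace_params
#' @param n_mz,n_dz,missing_rate,seed overrides of the study design.
#' @export
batss_sim_spec <- function(n_mz = 164, n_dz = 131, missing_rate = 0.01,
                           seed = 1L, unit_scale = FALSE) {
  sim_spec(n_mz, n_dz, batss_ace_params(unit_scale = unit_scale),
           missing_rate = missing_rate,
           covariates = batss_covariates(), seed = seed)
}

rmvnorm_chol <- function(n, mean, sigma) {
  p <- length(mean)
  ## PSD but possibly singular: use eigen-based square root
  e <- eigen(sigma, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% rt, 2, mean, "+")
}

draw_covariate <- function(cv, n) {
  x <- switch(cv$dist,
    normal = rnorm(n, cv$mean, cv$sd),
    binary = rbinom(n, 1L, cv$p),
    ordinal = pmin(pmax(round(rnorm(n, cv$mean, cv$sd)), cv$levels[1]),
                   cv$levels[2]))
  as.numeric(x)
}

#' Simulate a classical twin-pair dataset
#'
#' Draws per-pair trait vectors from the multivariate normal distribution
#' implied by [build_pair_covariance] for each zygosity, adds linear
#' covariate effects on the trait means, applies independent per-twin-trait
#' missingness, and drops pairs left with no observed trait value.
#'
#' @param spec a [sim_spec].
#' @return a wide data frame (one row per pair) with columns `pair_id`,
#'   `zygosity`, `<trait>_t1`, `<trait>_t2` and `<covariate>_t1/_t2`;
#'   attribute `"traits"` records the trait names and `"sim_spec"` the
#'   generating spec.
#' @examples
#' d <- simulate_twin_data(batss_sim_spec(seed = 7))
#' table(d$zygosity)
#' @export
simulate_twin_data <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  params <- spec$params
  traits <- params$traits
  n_t <- length(traits)
  with_seed(spec$seed, {
    blocks <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
      n <- if (z == "MZ") spec$n_mz else spec$n_dz
      if (n == 0) return(NULL)
      mu <- rep(params$means, 2)
      y <- rmvnorm_chol(n, mu, build_pair_covariance(params, z))
      colnames(y) <- c(t1col(traits), t2col(traits))
      df <- data.frame(zygosity = rep(z, n), y, stringsAsFactors = FALSE)
      df
    })
    out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
    n_pairs <- nrow(out)
    out <- cbind(pair_id = sprintf("pair_%04d", seq_len(n_pairs)), out)

    ## covariates (pair- or twin-level) and their linear effects on traits
    for (cv in spec$covariates) {
      if (cv$level == "pair") {
        x1 <- x2 <- draw_covariate(cv, n_pairs)
      } else {
        x1 <- draw_covariate(cv, n_pairs)
        x2 <- draw_covariate(cv, n_pairs)
      }
      out[[t1col(cv$name)]] <- x1
      out[[t2col(cv$name)]] <- x2
      cv_sd <- switch(cv$dist, normal = cv$sd,
                      binary = sqrt(cv$p * (1 - cv$p)), ordinal = cv$sd)
      cv_mean <- switch(cv$dist, normal = cv$mean, binary = cv$p,
                        ordinal = cv$mean)
      for (tr in names(cv$effects)) {
        b <- cv$effects[[tr]]
        if (b == 0 || !tr %in% traits) next
        shift <- b * sqrt(params$total_var[match(tr, traits)])
        out[[t1col(tr)]] <- out[[t1col(tr)]] + shift * (x1 - cv_mean) / cv_sd
        out[[t2col(tr)]] <- out[[t2col(tr)]] + shift * (x2 - cv_mean) / cv_sd
      }
    }

    ## independent per twin-trait missingness
    if (spec$missing_rate > 0) {
      for (cl in c(t1col(traits), t2col(traits))) {
        hit <- runif(n_pairs) < spec$missing_rate
        out[[cl]][hit] <- NA_real_
      }
      trait_cols <- c(t1col(traits), t2col(traits))
      keep <- rowSums(!is.na(out[, trait_cols, drop = FALSE])) > 0
      out <- out[keep, , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "traits") <- traits
    attr(out, "sim_spec") <- spec
    out
  })
}

#' Append simulated polygenic scores and ancestry principal components
#'
#' Adds per-twin standardized polygenic score (PGS) columns and 10 ancestry
#' principal-component columns.  Co-twin scores reflect genetic sharing:
#' MZ twins receive identical scores, DZ co-twin scores correlate 0.5.
#' PCs are independent standard normals.  Trait columns are shifted by the
#' stated standardized effect of each score.
#'
#' @param data twin-pair data frame.
#' @param score_names names for the scores (columns `pgs_<name>_t1/_t2`).
#' @param effect_sizes named (or recycled) standardized slope per score,
#'   applied to every trait in `traits`.
#' @param traits trait base names to perturb; defaults to the `"traits"`
#'   attribute.
#' @param seed integer RNG seed.
#' @return the data frame with score and `pc1..pc10` columns appended.
#' @export
simulate_pgs_columns <- function(data, score_names, effect_sizes = 0,
                                 traits = attr(data, "traits"), seed = 1L) {
  assert_pairs_df(data)
  if (nrow(data) == 0) stopf("dataset is empty")
  if (length(score_names) < 1) stopf("at least one score is required")
  effect_sizes <- rep_len(effect_sizes, length(score_names))
  names(effect_sizes) <- score_names
  n <- nrow(data)
  mz <- data$zygosity == "MZ"
  with_seed(seed, {
    for (sc in score_names) {
      g_shared <- rnorm(n)
      g1 <- g2 <- g_shared
      ## DZ: share half the additive genetic variance of the score
      g1[!mz] <- sqrt(0.5) * g_shared[!mz] + sqrt(0.5) * rnorm(sum(!mz))
      g2[!mz] <- sqrt(0.5) * g_shared[!mz] + sqrt(0.5) * rnorm(sum(!mz))
      data[[t1col(paste0("pgs_", sc))]] <- g1
      data[[t2col(paste0("pgs_", sc))]] <- g2
      b <- effect_sizes[[sc]]
      if (b != 0) for (tr in traits) {
        s <- sd(c(data[[t1col(tr)]], data[[t2col(tr)]]), na.rm = TRUE)
        data[[t1col(tr)]] <- data[[t1col(tr)]] + b * s * g1
        data[[t2col(tr)]] <- data[[t2col(tr)]] + b * s * g2
      }
    }
    for (j in 1:10) {
      data[[t1col(paste0("pc", j))]] <- rnorm(n)
      data[[t2col(paste0("pc", j))]] <- rnorm(n)
    }
    data
  })
}

#' Write / read a twin-pair dataset as CSV with a sidecar provenance file
#'
#' Missing values are written as empty fields.  `write_pairs()` also writes
#' `<path>.json` recording the generating [sim_spec] (including the seed)
#' when the dataset carries one.
#'
#' @param data twin-pair data frame.
#' @param path CSV path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` returns
#'   the data frame with the `"traits"` attribute restored when a sidecar
#'   file is present.
#' @export
write_pairs <- function(data, path) {
  assert_pairs_df(data)
  write.csv(data, path, row.names = FALSE, na = "")
  spec <- attr(data, "sim_spec")
  meta <- list(traits = attr(data, "traits"))
  if (!is.null(spec)) {
    meta$sim_spec <- list(
      n_mz = spec$n_mz, n_dz = spec$n_dz, seed = spec$seed,
      missing_rate = spec$missing_rate,
      params = unclass(spec$params),
      covariates = lapply(spec$covariates, function(cv) {
        cv <- unclass(cv); cv$effects <- as.list(cv$effects); cv
      }))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  assert_pairs_df(out)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "traits") <- meta$traits
  }
  out
}
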