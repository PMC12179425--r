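## Twin model ladder: saturated (free means and covariances per zygosity),
## assumption-constrained saturated submodels, univariate ACE and bivariate
## correlated-factors ACE, all fitted by FIML.

## observed moments used for starting values
obs_moments <- function(data, traits) {
  cols <- c(t1col(traits), t2col(traits))
  out <- list()
  for (z in c("MZ", "DZ")) {
    d <- data[data$zygosity == z, cols, drop = FALSE]
    if (!nrow(d)) next
    m <- vapply(d, mean, numeric(1), na.rm = TRUE)
    s <- vapply(d, sd, numeric(1), na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    m[!is.finite(m)] <- 0
    R <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    out[[z]] <- list(mean = m, sd = s, cor = R)
  }
  out
}

## Falconer-style starting proportions from double-entered twin correlations
falconer_start <- function(data, trait) {
  r <- function(z) tryCatch(
    twin_twin_correlation(data, trait, z)$estimate,
    error = function(e) if (z == "MZ") 0.6 else 0.45)
  rmz <- r("MZ"); rdz <- r("DZ")
  A <- min(max(2 * (rmz - rdz), 0.05), 0.85)
  C <- min(max(2 * rdz - rmz, 0.05), 0.85)
  if (A + C > 0.93) { f <- 0.93 / (A + C); A <- A * f; C <- C * f }
  c(A = A, C = C)
}

## ---- saturated model ------------------------------------------------------

## constraints: cumulative equality flags among
## means_twins, means_zyg, vars_twins, vars_zyg
saturated_builder <- function(mom, traits) {
  n_t <- length(traits)
  p <- 2 * n_t
  vars <- c(paste0(traits, ".t1"), paste0(traits, ".t2"))
  function(fixed = list(), constraints = character()) {
    mean_name <- function(z, twin, tr) {
      z2 <- if ("means_zyg" %in% constraints) NULL else z
      tw <- if ("means_twins" %in% constraints) NULL else twin
      paste(c("mean", z2, tw, tr), collapse = ".")
    }
    sd_name <- function(z, twin, tr) {
      z2 <- if ("vars_zyg" %in% constraints) NULL else z
      tw <- if ("vars_twins" %in% constraints) NULL else twin
      paste(c("log_sd", z2, tw, tr), collapse = ".")
    }
    grid <- expand.grid(z = c("MZ", "DZ"), twin = c("t1", "t2"),
                        tr = traits, stringsAsFactors = FALSE)
    mean_names <- unique(mapply(mean_name, grid$z, grid$twin, grid$tr))
    sd_names <- unique(mapply(sd_name, grid$z, grid$twin, grid$tr))
    cor_names <- character()
    for (z in c("MZ", "DZ"))
      for (i in seq_len(p - 1)) for (j in (i + 1):p)
        cor_names <- c(cor_names, paste("r", z, vars[i], vars[j], sep = "."))
    names_all <- c(mean_names, sd_names, cor_names)

    start <- setNames(numeric(length(names_all)), names_all)
    var_of <- function(twin, tr) paste0(tr, "_", twin)
    for (g in seq_len(nrow(grid))) {
      z <- grid$z[g]; tw <- grid$twin[g]; tr <- grid$tr[g]
      mz <- mom[[z]] %||% mom[[setdiff(c("MZ", "DZ"), z)]]
      v <- var_of(tw, tr)
      start[mean_name(z, tw, tr)] <- mz$mean[[v]]
      start[sd_name(z, tw, tr)] <- log(mz$sd[[v]])
    }
    for (z in c("MZ", "DZ")) {
      mz <- mom[[z]] %||% mom[[setdiff(c("MZ", "DZ"), z)]]
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        vi <- var_of(substr(vars[i], nchar(vars[i]) - 1, nchar(vars[i])),
                     sub("\\.t[12]$", "", vars[i]))
        vj <- var_of(substr(vars[j], nchar(vars[j]) - 1, nchar(vars[j])),
                     sub("\\.t[12]$", "", vars[j]))
        start[paste("r", z, vars[i], vars[j], sep = ".")] <-
          min(max(mz$cor[vi, vj], -0.95), 0.95)
      }
    }
    free <- setdiff(names_all, names(fixed))
    lower <- setNames(rep(-Inf, length(free)), free)
    upper <- setNames(rep(Inf, length(free)), free)
    lower[grepl("^r\\.", free)] <- -0.999
    upper[grepl("^r\\.", free)] <- 0.999
    lower[grepl("^log_sd", free)] <- -23
    upper[grepl("^log_sd", free)] <- 23

    build <- function(th) {
      val <- function(nm) if (nm %in% names(th)) th[[nm]] else fixed[[nm]]
      mean_fn <- function(z) {
        vapply(seq_len(p), function(i) {
          tw <- sub("^.*\\.(t[12])$", "\\1", vars[i])
          tr <- sub("\\.t[12]$", "", vars[i])
          val(mean_name(z, tw, tr))
        }, numeric(1))
      }
      cov_fn <- function(z) {
        sds <- vapply(seq_len(p), function(i) {
          tw <- sub("^.*\\.(t[12])$", "\\1", vars[i])
          tr <- sub("\\.t[12]$", "", vars[i])
          exp(val(sd_name(z, tw, tr)))
        }, numeric(1))
        R <- diag(p)
        for (i in seq_len(p - 1)) for (j in (i + 1):p)
          R[i, j] <- R[j, i] <- val(paste("r", z, vars[i], vars[j], sep = "."))
        (sds %o% sds) * R
      }
      list(mean_fn = mean_fn, cov_fn = cov_fn)
    }
    list(names = free, start = start[free], lower = lower, upper = upper,
         map = build,
         extract = function(th) {
           mapped <- build(th)
           lapply(c(MZ = "MZ", DZ = "DZ"), function(z)
             list(mean = setNames(mapped$mean_fn(z), vars),
                  cov = structure(mapped$cov_fn(z),
                                  dimnames = list(vars, vars))))
         })
  }
}

#' Fit the saturated twin model by FIML
#'
#' Estimates, per zygosity, free means for every twin-order/trait cell and
#' a free symmetric within-pair covariance matrix: the benchmark model the
#' biometric models are tested against.  Equality constraints on means or
#' variances (across twin order and/or zygosity) give the assumption
#' submodels.
#'
#' @param data twin-pair data frame.
#' @param traits trait base names (1 or 2); default from the `"traits"`
#'   attribute.
#' @param constraints character subset of `"means_twins"`, `"means_zyg"`,
#'   `"vars_twins"`, `"vars_zyg"`.
#' @param n_restarts maximum number of seeded random restarts used when the
#'   moment-based start fails to converge.
#' @param seed RNG seed for restarts.
#' @return a `twin_fit`; `params` holds per-zygosity mean vectors and
#'   covariance matrices, and for two traits `k = 28` in the unconstrained
#'   model.
#' @export
fit_saturated <- function(data, traits = attr(data, "traits"),
                          constraints = character(), n_restarts = 10,
                          seed = 1L) {
  if (is.null(traits)) stopf("specify `traits`")
  bad <- setdiff(constraints,
                 c("means_twins", "means_zyg", "vars_twins", "vars_zyg"))
  if (length(bad)) stopf("unknown constraint(s): %s", paste(bad, collapse = ", "))
  stats <- fiml_stats(data, traits)
  mom <- obs_moments(data, traits)
  b0 <- saturated_builder(mom, traits)
  builder <- function(fixed) b0(fixed, constraints = constraints)
  mspec <- builder(list())
  if (stats$n_obs <= length(mspec$names))
    stopf("too few observed data points (%d) for %d parameters",
          stats$n_obs, length(mspec$names))
  fitted <- fit_fiml_spec(stats, mspec, n_restarts = n_restarts, seed = seed)
  model <- if (length(constraints))
    paste0("saturated+", paste(constraints, collapse = "+")) else "saturated"
  twin_fit_result(model, fitted, mspec, stats, traits, builder = builder,
                  seed = seed, n_restarts = n_restarts)
}

#' Twin-modelling assumption tests
#'
#' Fits the cumulative ladder of assumption submodels of the saturated
#' model for one trait and compares each to the saturated fit by
#' likelihood-ratio test: equal means across twins within a pair (model 1),
#' additionally across zygosity (model 2), equal variances across twins
#' (model 3) and additionally across zygosity (model 4).  A warning (not an
#' error) is raised when any comparison rejects at `alpha`, since the ACE
#' model presumes these equalities.
#'
#' @inheritParams fit_saturated
#' @param trait trait base name.
#' @param alpha warning threshold for the LRT p-values.
#' @return list with the saturated `fit`, the four submodel fits, and
#'   `comparisons` (a data frame of `delta_LL`, `delta_df`, `p`).
#' @export
assumption_tests <- function(data, trait, alpha = 0.05, n_restarts = 10,
                             seed = 1L) {
  sat <- fit_saturated(data, trait, n_restarts = n_restarts, seed = seed)
  ladder <- list(
    model1 = "means_twins",
    model2 = c("means_twins", "means_zyg"),
    model3 = c("means_twins", "means_zyg", "vars_twins"),
    model4 = c("means_twins", "means_zyg", "vars_twins", "vars_zyg"))
  fits <- lapply(ladder, function(cs)
    fit_saturated(data, trait, constraints = cs, n_restarts = n_restarts,
                  seed = seed))
  cmp <- lapply(fits, function(f) compare_models(sat, f))
  tab <- do.call(rbind, lapply(names(cmp), function(nm) {
    x <- cmp[[nm]]
    data.frame(model = nm, k = x$k_nested, delta_LL = x$delta_LL,
               delta_df = x$delta_df, p = x$p_value)
  }))
  rownames(tab) <- NULL
  if (any(tab$p < alpha))
    warning(sprintf("assumption test(s) rejected at alpha = %g for '%s': %s",
                    alpha, trait,
                    paste(tab$model[tab$p < alpha], collapse = ", ")),
            call. = FALSE)
  list(saturated = sat, fits = fits, comparisons = tab)
}

## ---- univariate ACE -------------------------------------------------------

uni_ace_builder <- function(mom, trait, mean0, sd0, AC0) {
  function(fixed = list()) {
    e_fixed <- "E" %in% names(fixed)
    names_all <- c("mean", "log_sd", "A", if (!e_fixed) "C")
    free <- setdiff(names_all, names(fixed))
    start <- c(mean = mean0, log_sd = log(sd0), A = unname(AC0["A"]),
               C = unname(AC0["C"]))
    if (e_fixed) {
      eF <- fixed$E
      start["A"] <- min(start["A"], max(1 - eF - 1e-6, 0))
    }
    lower <- setNames(rep(-Inf, length(free)), free)
    upper <- setNames(rep(Inf, length(free)), free)
    for (nm in intersect(free, c("A", "C"))) { lower[nm] <- 0; upper[nm] <- 1 }
    if (e_fixed && "A" %in% free) upper["A"] <- max(1 - fixed$E, 0)
    lower[free == "log_sd"] <- -23; upper[free == "log_sd"] <- 23
    get_ace <- function(th) {
      val <- function(nm) if (nm %in% names(th)) th[[nm]] else fixed[[nm]]
      A <- val("A")
      C <- if (e_fixed) 1 - fixed$E - A else val("C")
      E <- 1 - A - C
      if (A < -1e-12 || C < -1e-12 || E < 1e-8) return(NULL)
      list(A = max(A, 0), C = max(C, 0), E = E,
           mean = val("mean"), sig = exp(val("log_sd")))
    }
    list(names = free, start = start[free], lower = lower, upper = upper,
         map = function(th) {
           a <- get_ace(th)
           if (is.null(a)) return(NULL)
           list(mean_fn = function(z) rep(a$mean, 2),
                cov_fn = function(z) ace_cov(a$A, a$C, a$E, a$sig,
                                             0, 0, 0, z))
         },
         extract = function(th) {
           a <- get_ace(th)
           ace_params(trait, means = a$mean, total_var = a$sig^2,
                      A = a$A, C = a$C, E = max(a$E, 1e-8))
         })
  }
}

#' Fit a univariate ACE model by FIML
#'
#' Four-parameter biometric model for one trait: a common mean (equated
#' across twin order and zygosity), a total phenotypic variance, and the
#' standardized proportions A and C (with E = 1 - A - C) that structure the
#' MZ and DZ cross-twin covariances as A + C and A/2 + C on the
#' standardized scale.  Boundary solutions (A = 0 or C = 0) are permitted
#' and reported as-is.
#'
#' @inheritParams assumption_tests
#' @param fixed named list of parameters to hold fixed (any of `mean`,
#'   `log_sd`, `A`, `C`, `E`), e.g. `list(C = 0)` for the nested no-C
#'   model.
#' @param ci optional character vector of parameters to compute 95%
#'   profile likelihood CIs for (see [profile_ci]).
#' @return a `twin_fit` with `params` an [ace_params] (k = 4 when nothing
#'   is fixed).
#' @export
fit_univariate_ace <- function(data, trait, fixed = list(), ci = NULL,
                               n_restarts = 10, seed = 1L) {
  stats <- fiml_stats(data, trait)
  have <- names(stats$n_zyg)[stats$n_zyg > 0]
  if (!all(c("MZ", "DZ") %in% have) &&
      !any(c("A", "C", "E") %in% names(fixed)))
    stopf("A and C are not jointly identified without both MZ and DZ pairs")
  mom <- obs_moments(data, trait)
  pooled <- c(data[[t1col(trait)]], data[[t2col(trait)]])
  builder <- uni_ace_builder(mom, trait, mean(pooled, na.rm = TRUE),
                             sd(pooled, na.rm = TRUE),
                             falconer_start(data, trait))
  mspec <- builder(fixed)
  fitted <- fit_fiml_spec(stats, mspec, n_restarts = n_restarts, seed = seed)
  out <- twin_fit_result("univariate_ace", fitted, mspec, stats, trait,
                         builder = builder, fixed = fixed, seed = seed,
                         n_restarts = n_restarts)
  if (!is.null(ci)) out <- add_profile_cis(out, ci)
  out
}

## ---- bivariate correlated-factors ACE ------------------------------------

biv_ace_builder <- function(traits, mean0, sd0, AC0, r0) {
  function(fixed = list()) {
    names_all <- character(); start <- numeric()
    e_fixed <- paste0("E.", traits) %in% names(fixed)
    for (i in seq_along(traits)) {
      tr <- traits[i]
      nm <- c(paste0("mean.", tr), paste0("log_sd.", tr), paste0("A.", tr),
              if (!e_fixed[i]) paste0("C.", tr))
      names_all <- c(names_all, nm)
      st <- c(mean0[i], log(sd0[i]), AC0[[i]]["A"], AC0[[i]]["C"])
      names(st) <- c(paste0("mean.", tr), paste0("log_sd.", tr),
                     paste0("A.", tr), paste0("C.", tr))
      if (e_fixed[i])
        st[paste0("A.", tr)] <- min(st[paste0("A.", tr)],
                                    max(1 - fixed[[paste0("E.", tr)]] - 1e-6, 0))
      start <- c(start, st)
    }
    names_all <- c(names_all, "rA", "rC", "rE")
    start <- c(start, rA = unname(r0["rA"]), rC = unname(r0["rC"]),
               rE = unname(r0["rE"]))
    free <- setdiff(names_all, names(fixed))
    lower <- setNames(rep(-Inf, length(free)), free)
    upper <- setNames(rep(Inf, length(free)), free)
    lower[grepl("^[AC]\\.", free)] <- 0
    upper[grepl("^[AC]\\.", free)] <- 1
    for (i in seq_along(traits)) {
      anm <- paste0("A.", traits[i])
      if (e_fixed[i] && anm %in% free)
        upper[anm] <- max(1 - fixed[[paste0("E.", traits[i])]], 0)
    }
    lower[free %in% c("rA", "rC")] <- -1
    upper[free %in% c("rA", "rC")] <- 1
    ## rE = +/-1 would make the unique-environment block singular and the
    ## implied pair covariance non-PD, so its box stops just short
    lower[free == "rE"] <- -0.999
    upper[free == "rE"] <- 0.999
    lower[grepl("^log_sd", free)] <- -23
    upper[grepl("^log_sd", free)] <- 23

    get_pars <- function(th) {
      val <- function(nm) if (nm %in% names(th)) th[[nm]] else fixed[[nm]]
      A <- C <- E <- sig <- mu <- numeric(length(traits))
      for (i in seq_along(traits)) {
        tr <- traits[i]
        A[i] <- val(paste0("A.", tr))
        C[i] <- if (e_fixed[i]) 1 - fixed[[paste0("E.", tr)]] - A[i]
                else val(paste0("C.", tr))
        E[i] <- 1 - A[i] - C[i]
        if (A[i] < -1e-12 || C[i] < -1e-12 || E[i] < 1e-8) return(NULL)
        A[i] <- max(A[i], 0); C[i] <- max(C[i], 0)
        sig[i] <- exp(val(paste0("log_sd.", tr)))
        mu[i] <- val(paste0("mean.", tr))
      }
      list(A = A, C = C, E = E, sig = sig, mu = mu,
           r_a = val("rA"), r_c = val("rC"), r_e = val("rE"))
    }
    list(names = free, start = start[free], lower = lower, upper = upper,
         map = function(th) {
           p <- get_pars(th)
           if (is.null(p)) return(NULL)
           list(mean_fn = function(z) rep(p$mu, 2),
                cov_fn = function(z) ace_cov(p$A, p$C, p$E, p$sig,
                                             p$r_a, p$r_c, p$r_e, z))
         },
         extract = function(th) {
           p <- get_pars(th)
           ace_params(traits, means = p$mu, total_var = p$sig^2,
                      A = p$A, C = p$C, E = pmax(p$E, 1e-8),
                      r_a = p$r_a, r_c = p$r_c, r_e = p$r_e)
         })
  }
}

#' Fit the bivariate correlated-factors ACE model by FIML
#'
#' Eleven-parameter bivariate twin model: each trait has its own mean,
#' total variance and standardized A/C/E decomposition, and like-type
#' latent factors across traits are allowed to correlate via the
#' aetiological correlations rA, rC and rE.  The implied per-pair
#' covariance is exactly [build_pair_covariance].
#'
#' @inheritParams fit_univariate_ace
#' @param traits the two trait base names.
#' @return a `twin_fit` with `params` an [ace_params] (k = 11 when nothing
#'   is fixed).
#' @export
fit_bivariate_correlated_factors <- function(data,
                                             traits = attr(data, "traits"),
                                             fixed = list(), ci = NULL,
                                             n_restarts = 10, seed = 1L) {
  if (length(traits) != 2) stopf("exactly two traits are required")
  stats <- fiml_stats(data, traits)
  if (!all(stats$n_zyg > 0))
    stopf("both MZ and DZ pairs are required")
  mean0 <- sd0 <- numeric(2); AC0 <- vector("list", 2)
  for (i in 1:2) {
    pooled <- c(data[[t1col(traits[i])]], data[[t2col(traits[i])]])
    mean0[i] <- mean(pooled, na.rm = TRUE)
    sd0[i] <- sd(pooled, na.rm = TRUE)
    AC0[[i]] <- falconer_start(data, traits[i])
  }
  rph <- tryCatch(
    cor(c(data[[t1col(traits[1])]], data[[t2col(traits[1])]]),
        c(data[[t1col(traits[2])]], data[[t2col(traits[2])]]),
        use = "complete.obs"),
    error = function(e) 0)
  if (!is.finite(rph)) rph <- 0
  r0 <- c(rA = 0, rC = min(max(rph, -0.8), 0.8),
          rE = min(max(rph, -0.8), 0.8))
  builder <- biv_ace_builder(traits, mean0, sd0, AC0, r0)
  mspec <- builder(fixed)
  fitted <- fit_fiml_spec(stats, mspec, n_restarts = n_restarts, seed = seed)
  out <- twin_fit_result("bivariate_correlated_factors", fitted, mspec,
                         stats, traits, builder = builder, fixed = fixed,
                         seed = seed, n_restarts = n_restarts)
  if (!is.null(ci)) out <- add_profile_cis(out, ci)
  out
}

## ---- model comparison -----------------------------------------------------

#' Likelihood-ratio and information-criterion comparison of nested fits
#'
#' @param fit_parent the less constrained model (more parameters).
#' @param fit_nested the constrained submodel fitted to the same data.
#' @return a `model_comparison`: `delta_LL` (difference in -2LL),
#'   `delta_df`, chi-square `p_value`, `delta_aic`, `delta_bic`, and
#'   `preferred` — the model the (more conservative) BIC selects.
#' @export
compare_models <- function(fit_parent, fit_nested) {
  stopifnot(inherits(fit_parent, "twin_fit"), inherits(fit_nested, "twin_fit"))
  if (fit_nested$k >= fit_parent$k)
    stopf("models are not nested: submodel has %d >= %d parameters",
          fit_nested$k, fit_parent$k)
  if (fit_nested$n_obs != fit_parent$n_obs)
    stopf("models were fitted to different data (%d vs %d data points)",
          fit_nested$n_obs, fit_parent$n_obs)
  delta <- fit_nested$minus2LL - fit_parent$minus2LL
  if (delta < -1e-6)
    warning("nested model fits better than its parent; parent fit is suspect",
            call. = FALSE)
  delta <- max(delta, 0)
  ddf <- fit_parent$k - fit_nested$k
  structure(list(
    parent = fit_parent$model, nested = fit_nested$model,
    k_parent = fit_parent$k, k_nested = fit_nested$k,
    delta_LL = delta, delta_df = ddf,
    p_value = pchisq(delta, ddf, lower.tail = FALSE),
    delta_aic = fit_nested$aic - fit_parent$aic,
    delta_bic = fit_nested$bic - fit_parent$bic,
    preferred = if (fit_nested$bic <= fit_parent$bic) fit_nested$model
                else fit_parent$model),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: delta(-2LL) = %.3f, delta(df) = %d, p = %.3f\n",
              x$nested, x$parent, x$delta_LL, x$delta_df, x$p_value))
  cat(sprintf("  delta(AIC) = %.3f, delta(BIC) = %.3f; BIC prefers: %s\n",
              x$delta_aic, x$delta_bic, x$preferred))
  invisible(x)
}

## comparison table mirroring the usual fit-statistics layout
#' Tabulate fits and their comparison to a reference model
#'
#' @param fits named list of `twin_fit`s; the first is the reference.
#' @return data frame with columns model, k, minus2LL, df, AIC, BIC,
#'   delta_LL, delta_df, p.
#' @export
fit_table <- function(fits) {
  ref <- fits[[1]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (i == 1) {
      data.frame(model = names(fits)[i] %||% f$model, k = f$k,
                 minus2LL = f$minus2LL, df = f$df, AIC = f$aic, BIC = f$bic,
                 delta_LL = NA_real_, delta_df = NA_integer_, p = NA_real_)
    } else {
      cmp <- compare_models(ref, f)
      data.frame(model = names(fits)[i] %||% f$model, k = f$k,
                 minus2LL = f$minus2LL, df = f$df, AIC = f$aic, BIC = f$bic,
                 delta_LL = cmp$delta_LL, delta_df = cmp$delta_df,
                 p = cmp$p_value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- profile likelihood confidence intervals ------------------------------

## full named parameter values including the derived E proportions
param_values <- function(fit) {
  vals <- fit$theta
  for (nm in names(fit$fixed)) vals[nm] <- fit$fixed[[nm]]
  p <- fit$params
  if (inherits(p, "ace_params")) {
    if (length(p$traits) == 1) {
      vals["A"] <- p$A; vals["C"] <- p$C; vals["E"] <- p$E
    } else {
      for (i in seq_along(p$traits)) {
        tr <- p$traits[i]
        vals[paste0("A.", tr)] <- p$A[i]
        vals[paste0("C.", tr)] <- p$C[i]
        vals[paste0("E.", tr)] <- p$E[i]
      }
      vals["rA"] <- p$r_a; vals["rC"] <- p$r_c; vals["rE"] <- p$r_e
    }
  }
  vals
}

param_domain <- function(parameter) {
  if (grepl("^(A|C|E)(\\.|$)", parameter)) c(0, 1)
  else if (parameter %in% c("rA", "rC")) c(-1, 1)
  else if (parameter == "rE") c(-0.999, 0.999)
  else if (grepl("^log_sd", parameter)) c(-23, 23)
  else c(-Inf, Inf)
}

#' Profile likelihood confidence interval for a fitted parameter
#'
#' Finds the bounds at which the profile -2 log-likelihood (all other
#' parameters refitted) rises by the chi-square(1) quantile (3.841 for 95%)
#' above its minimum, by root bisection.  When the likelihood does not
#' reach the threshold before the parameter's domain edge (e.g. a genetic
#' correlation hitting -1), the domain edge is returned and flagged.
#'
#' @param fit a converged `twin_fit` from an ACE model.
#' @param parameter parameter name: `"A"`, `"C"`, `"E"`, `"mean"`,
#'   `"log_sd"` for univariate fits; `"A.<trait>"` etc., `"rA"`, `"rC"`,
#'   `"rE"` for bivariate fits.
#' @param level confidence level.
#' @return numeric `c(low, high)` with logical attributes `pinned_low` /
#'   `pinned_high` marking domain-edge bounds.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  if (!fit$converged) stopf("profile CI requires a converged fit")
  vals <- param_values(fit)
  if (!parameter %in% names(vals))
    stopf("unknown parameter '%s'; available: %s", parameter,
          paste(names(vals), collapse = ", "))
  est <- unname(vals[parameter])
  crit <- fit$minus2LL + qchisq(level, 1)
  f <- function(v) refit_fixed(fit, setNames(list(v), parameter))$minus2LL - crit
  dom <- param_domain(parameter)
  tol <- 1e-4 * max(1, abs(est))

  one_side <- function(dir) {  # dir = -1 lower, +1 upper
    edge <- if (dir < 0) dom[1] else dom[2]
    if (is.finite(edge)) {
      if (abs(edge - est) < 1e-12) return(list(bound = edge, pinned = TRUE))
      fe <- f(edge)
      if (fe <= 0) return(list(bound = edge, pinned = TRUE))
      lo <- min(edge, est); hi <- max(edge, est)
      r <- uniroot(f, lower = lo, upper = hi, f.lower = if (dir < 0) fe else -qchisq(level, 1),
                   f.upper = if (dir < 0) -qchisq(level, 1) else fe, tol = tol)
      return(list(bound = r$root, pinned = FALSE))
    }
    step <- max(0.25 * abs(est), 0.25)
    v <- est + dir * step
    for (i in 1:60) {
      if (f(v) > 0) break
      step <- step * 2
      v <- est + dir * step
      if (i == 60) stopf("failed to bracket the %s profile bound",
                         if (dir < 0) "lower" else "upper")
    }
    r <- uniroot(f, lower = min(v, est), upper = max(v, est), tol = tol)
    list(bound = r$root, pinned = FALSE)
  }
  lo <- one_side(-1); hi <- one_side(1)
  structure(c(lo$bound, hi$bound),
            pinned_low = lo$pinned, pinned_high = hi$pinned,
            names = c("low", "high"))
}

#' @rdname profile_ci
#' @param parameters character vector of parameters; results are attached
#'   to the fit as a `ci` matrix.
#' @export
add_profile_cis <- function(fit, parameters, level = 0.95) {
  ci <- t(vapply(parameters, function(p) as.numeric(profile_ci(fit, p, level)),
                 numeric(2)))
  dimnames(ci) <- list(parameters, c("low", "high"))
  fit$ci <- ci
  fit
}
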