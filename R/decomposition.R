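## Derived quantities of a fitted (bivariate) ACE model: standardized
## components, model-implied twin correlations, and the decomposition of
## the phenotypic correlation into genetic and environmental parts.

#' Standardize raw variance components to proportions
#'
#' @param a2,c2,e2 per-trait raw component variances.
#' @return matrix with rows A, C, E of proportions summing to 1 per trait.
#' @export
standardize_components <- function(a2, c2, e2) {
  tot <- a2 + c2 + e2
  if (any(tot <= 0)) stopf("zero total variance")
  rbind(A = a2 / tot, C = c2 / tot, E = e2 / tot)
}

## normalize fit / params input to an ace_params
as_ace_params <- function(x) {
  if (inherits(x, "ace_params")) return(x)
  if (inherits(x, "twin_fit") && inherits(x$params, "ace_params"))
    return(x$params)
  stopf("expected an ace_params or an ACE twin_fit")
}

#' Model-implied twin and cross-trait correlations
#'
#' Computes, from standardized ACE parameters, the correlations the model
#' implies on the phenotypic scale:
#' \deqn{r_{MZ,i} = A_i + C_i, \qquad r_{DZ,i} = A_i/2 + C_i,}
#' and for two traits the cross-twin cross-trait correlations
#' \deqn{r_{ctct}^{MZ} = r_A\sqrt{A_1 A_2} + r_C\sqrt{C_1 C_2}, \qquad
#'       r_{ctct}^{DZ} = \tfrac12 r_A\sqrt{A_1 A_2} + r_C\sqrt{C_1 C_2},}
#' and the phenotypic correlation
#' \deqn{r_{ph} = r_A\sqrt{A_1 A_2} + r_C\sqrt{C_1 C_2} + r_E\sqrt{E_1 E_2}.}
#' These agree entrywise with [build_pair_covariance] on the unit-variance
#' scale.
#'
#' @param params an [ace_params] or an ACE `twin_fit`.
#' @return list with `rMZ`, `rDZ` (named per trait) and, for two traits,
#'   `ctct_MZ`, `ctct_DZ`, `r_ph`.
#' @examples
#' implied_twin_correlations(batss_ace_params())
#' @export
implied_twin_correlations <- function(params) {
  p <- as_ace_params(params)
  out <- list(rMZ = setNames(p$A + p$C, p$traits),
              rDZ = setNames(0.5 * p$A + p$C, p$traits))
  if (length(p$traits) == 2) {
    gA <- p$r_a * sqrt(p$A[1] * p$A[2])
    gC <- p$r_c * sqrt(p$C[1] * p$C[2])
    gE <- p$r_e * sqrt(p$E[1] * p$E[2])
    out$ctct_MZ <- gA + gC
    out$ctct_DZ <- 0.5 * gA + gC
    out$r_ph <- gA + gC + gE
  }
  out
}

#' Bivariate decomposition of the phenotypic correlation
#'
#' Splits the model-implied phenotypic correlation between two traits into
#' the contributions of correlated additive genetic, shared environmental
#' and unique environmental influences:
#' \eqn{biv\_X = r_X \sqrt{X_1 X_2}} for X in A, C, E, with
#' \eqn{biv\_A + biv\_C + biv\_E = r_{ph}} exactly.  Proportions
#' `biv_X / r_ph` may exceed 1 or be negative when contributions have
#' opposite signs; they still sum to 1.
#'
#' @inheritParams implied_twin_correlations
#' @return list with `biv_a`, `biv_c`, `biv_e` (correlation units),
#'   `r_ph`, and proportions `biv_a_prop`, `biv_c_prop`, `biv_e_prop`
#'   (`NA` when `r_ph` is 0).
#' @examples
#' bivariate_decomposition(batss_ace_params())
#' @export
bivariate_decomposition <- function(params) {
  p <- as_ace_params(params)
  if (length(p$traits) != 2) stopf("a bivariate parameter set is required")
  biv_a <- p$r_a * sqrt(p$A[1] * p$A[2])
  biv_c <- p$r_c * sqrt(p$C[1] * p$C[2])
  biv_e <- p$r_e * sqrt(p$E[1] * p$E[2])
  r_ph <- biv_a + biv_c + biv_e
  props <- if (r_ph == 0) rep(NA_real_, 3) else c(biv_a, biv_c, biv_e) / r_ph
  list(biv_a = biv_a, biv_c = biv_c, biv_e = biv_e, r_ph = r_ph,
       biv_a_prop = props[1], biv_c_prop = props[2], biv_e_prop = props[3])
}

#' Full decomposition report for a bivariate ACE fit
#'
#' Gathers standardized components, aetiological correlations, implied twin
#' correlations and the bivariate decomposition into one report.
#' Optionally attaches 95% CIs for the derived quantities by parametric
#' bootstrap: datasets are simulated from the fitted parameters at the
#' fitted design size, refitted, and the derived quantities recomputed.
#'
#' @param fit an ACE `twin_fit` (bivariate) or an [ace_params].
#' @param ci compute parametric-bootstrap CIs.
#' @param n_boot bootstrap draws.
#' @param seed RNG seed for the bootstrap.
#' @return a `decomposition_report` list: `standardized` (A/C/E by trait),
#'   `r_a`, `r_c`, `r_e`, `implied` (from [implied_twin_correlations]),
#'   `bivariate` (from [bivariate_decomposition]), optional `ci`.
#' @export
decompose_ace <- function(fit, ci = FALSE, n_boot = 2000, seed = 1L) {
  p <- as_ace_params(fit)
  out <- list(standardized = rbind(A = p$A, C = p$C, E = p$E),
              r_a = p$r_a, r_c = p$r_c, r_e = p$r_e,
              implied = implied_twin_correlations(p),
              bivariate = if (length(p$traits) == 2)
                bivariate_decomposition(p))
  colnames(out$standardized) <- p$traits
  if (ci) {
    if (!inherits(fit, "twin_fit"))
      stopf("bootstrap CIs require a twin_fit (design sizes are needed)")
    n_mz <- as.integer(fit$stats$n_zyg[["MZ"]])
    n_dz <- as.integer(fit$stats$n_zyg[["DZ"]])
    seeds <- derive_seeds(seed, n_boot)
    draws <- vapply(seq_len(n_boot), function(b) {
      d <- simulate_twin_data(sim_spec(n_mz, n_dz, p, missing_rate = 0,
                                       seed = seeds[b]))
      f <- tryCatch(
        fit_bivariate_correlated_factors(d, p$traits, n_restarts = 2,
                                         seed = seeds[b]),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) return(rep(NA_real_, 9))
      q <- f$params
      bd <- bivariate_decomposition(q)
      c(q$A, q$C, q$E, bd$biv_a, bd$biv_c, bd$biv_e)[c(1, 3, 5, 2, 4, 6, 7, 8, 9)]
    }, numeric(9))
    qs <- apply(draws, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    nm <- c(paste0(c("A.", "C.", "E."), p$traits[1]),
            paste0(c("A.", "C.", "E."), p$traits[2]),
            "biv_a", "biv_c", "biv_e")
    out$ci <- t(qs); rownames(out$ci) <- nm
    out$ci_meta <- list(method = "parametric bootstrap", n_boot = n_boot,
                        n_failed = sum(is.na(draws[1, ])), seed = seed)
  }
  structure(out, class = "decomposition_report")
}

#' @export
print.decomposition_report <- function(x, ...) {
  cat("Standardized variance components:\n")
  print(round(x$standardized, 3))
  if (!is.null(x$bivariate)) {
    cat(sprintf("rA = %.3f, rC = %.3f, rE = %.3f\n", x$r_a, x$r_c, x$r_e))
    b <- x$bivariate
    cat(sprintf("phenotypic r = %.3f = biv_A %.3f + biv_C %.3f + biv_E %.3f\n",
                b$r_ph, b$biv_a, b$biv_c, b$biv_e))
    cat(sprintf("proportions: %.2f / %.2f / %.2f\n",
                b$biv_a_prop, b$biv_c_prop, b$biv_e_prop))
  }
  invisible(x)
}
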