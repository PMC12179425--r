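## Simulation-based post-hoc power analysis: at given generating parameter
## values and design size, the probability that a likelihood-ratio test
## detects each variance component / aetiological correlation.

#' Post-hoc power by simulation
#'
#' For each replicate, simulates a twin dataset from `params` at the given
#' design size, fits the full ACE model (univariate or bivariate
#' correlated-factors, matching the number of traits) and, for each target
#' parameter, the nested model with that parameter fixed to zero; detection
#' is a likelihood-ratio p-value below `alpha` on 1 df.  Power is the
#' rejection fraction over successful replicates.
#'
#' Variance components lie on the boundary of their space under the null,
#' so the nominal chi-square(1) reference is conservative for them; with
#' `boundary_mixture = TRUE` a 50:50 mixture of chi-square(0) and
#' chi-square(1) is used for the A and C tests instead.
#'
#' @param params generating [ace_params].
#' @param n_mz,n_dz design size (pairs per zygosity).
#' @param parameters which parameters to test; defaults to every testable
#'   one (`A`, `C` per trait and, bivariate, `rA`, `rC`, `rE`).
#' @param n_replicates simulation replicates.
#' @param alpha test level.
#' @param seed RNG seed; replicates use derived per-replicate seeds.
#' @param boundary_mixture use the mixture reference for variance
#'   components.
#' @param n_restarts optimizer restart budget per fit.
#' @return a `power_report` data frame with per-parameter `power` and
#'   Monte-Carlo standard error `mc_se = sqrt(p(1-p)/n)`; attributes record
#'   `alpha`, `n_replicates`, the failure count, and the generating
#'   parameters.  More than 10% failed replicates flags the result.
#' @export
posthoc_power <- function(params, n_mz, n_dz, parameters = NULL,
                          n_replicates = 500, alpha = 0.05, seed = 1L,
                          boundary_mixture = FALSE, n_restarts = 3) {
  stopifnot(inherits(params, "ace_params"))
  if (n_replicates < 100) stopf("at least 100 replicates are required")
  bivar <- length(params$traits) == 2
  if (is.null(parameters)) {
    parameters <- if (bivar)
      c(paste0("A.", params$traits), paste0("C.", params$traits),
        "rA", "rC", "rE")
    else c("A", "C")
  }
  is_vc <- grepl("^[AC]\\.", parameters) | parameters %in% c("A", "C")
  seeds <- derive_seeds(seed, n_replicates)
  rej <- matrix(NA, n_replicates, length(parameters),
                dimnames = list(NULL, parameters))
  failures <- 0L
  for (b in seq_len(n_replicates)) {
    d <- simulate_twin_data(sim_spec(n_mz, n_dz, params, missing_rate = 0,
                                     seed = seeds[b]))
    full <- tryCatch({
      if (bivar) fit_bivariate_correlated_factors(
        d, params$traits, n_restarts = n_restarts, seed = seeds[b])
      else fit_univariate_ace(d, params$traits, n_restarts = n_restarts,
                              seed = seeds[b])
    }, error = function(e) NULL)
    if (is.null(full) || !full$converged) { failures <- failures + 1L; next }
    for (j in seq_along(parameters)) {
      pm <- parameters[j]
      nested <- tryCatch(
        refit_fixed(full, setNames(list(0), pm)),
        error = function(e) NULL)
      if (is.null(nested)) next
      delta <- max(nested$minus2LL - full$minus2LL, 0)
      pval <- pchisq(delta, 1, lower.tail = FALSE)
      if (boundary_mixture && is_vc[j])
        pval <- if (delta == 0) 1 else 0.5 * pval
      rej[b, j] <- pval < alpha
    }
  }
  n_eff <- colSums(!is.na(rej))
  power <- colMeans(rej, na.rm = TRUE)
  out <- data.frame(parameter = parameters, power = unname(power),
                    mc_se = sqrt(unname(power) * (1 - unname(power)) / n_eff),
                    n_effective = unname(n_eff))
  attr(out, "alpha") <- alpha
  attr(out, "n_replicates") <- n_replicates
  attr(out, "n_failed") <- failures
  attr(out, "flagged") <- failures > 0.1 * n_replicates
  attr(out, "params") <- params
  attr(out, "boundary_mixture") <- boundary_mixture
  class(out) <- c("power_report", "data.frame")
  out
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("Post-hoc power (%d replicates, alpha = %g%s)\n",
              attr(x, "n_replicates"), attr(x, "alpha"),
              if (attr(x, "flagged")) "; FLAGGED: >10% fit failures" else ""))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
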