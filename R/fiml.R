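## Full-information maximum likelihood (FIML) machinery for twin-pair
## multivariate-normal data.  Each pair contributes the MVN density of
## exactly its observed trait values (rows/columns for missing entries
## deleted), so incomplete pairs enter the likelihood without imputation.
##
## Pairs are grouped by (zygosity, missingness pattern); within a group the
## -2LL reduces to n*(p*log(2pi) + log|S|) + tr(S^-1 W) with W the SSCP of
## deviations from the model mean, so each objective evaluation costs a few
## small matrix operations regardless of sample size.

## Per-(zygosity, pattern) sufficient statistics
fiml_stats <- function(data, traits) {
  assert_pairs_df(data)
  cols <- c(t1col(traits), t2col(traits))
  miss <- setdiff(cols, names(data))
  if (length(miss)) stopf("missing trait column(s): %s", paste(miss, collapse = ", "))
  Y <- as.matrix(data[, cols, drop = FALSE])
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  zyg <- as.character(data$zygosity)[keep]
  groups <- list()
  for (z in unique(zyg)) {
    zi <- which(zyg == z)
    pat <- apply(obs[zi, , drop = FALSE], 1, paste, collapse = "")
    for (pt in unique(pat)) {
      ri <- zi[pat == pt]
      idx <- which(obs[ri[1], ])
      Yg <- Y[ri, idx, drop = FALSE]
      groups[[length(groups) + 1]] <- list(
        zygosity = z, idx = idx, n = length(ri),
        s = colSums(Yg), S = crossprod(Yg))
    }
  }
  structure(list(groups = groups, dim = ncol(Y),
                 n_pairs = nrow(Y), n_obs = sum(obs),
                 n_zyg = table(factor(zyg, levels = c("MZ", "DZ")))),
            class = "fiml_stats")
}

## -2 log-likelihood given mean_fn(zyg) -> length-2T vector and
## cov_fn(zyg) -> 2T x 2T matrix; +Inf if any implied covariance is not
## positive definite on an observed subspace (optimizer-safe)
m2ll_from_stats <- function(stats, mean_fn, cov_fn) {
  mu <- list(); Sig <- list()
  total <- 0
  for (g in stats$groups) {
    z <- g$zygosity
    if (is.null(mu[[z]])) { mu[[z]] <- mean_fn(z); Sig[[z]] <- cov_fn(z) }
    if (is.null(Sig[[z]])) return(Inf)
    mg <- mu[[z]][g$idx]
    Sg <- Sig[[z]][g$idx, g$idx, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    W <- g$S - tcrossprod(g$s, mg) - tcrossprod(mg, g$s) +
      g$n * tcrossprod(mg)
    total <- total + g$n * (length(g$idx) * log(2 * pi) + logdet) +
      sum(Sinv * W)
  }
  total
}

## internal ACE-implied covariance without constructor overhead
ace_cov <- function(A, C, E, sig, r_a, r_c, r_e, zygosity) {
  S_A <- component_sigma(A, sig, r_a)
  S_C <- component_sigma(C, sig, r_c)
  S_E <- component_sigma(E, sig, r_e)
  within <- S_A + S_C + S_E
  cross <- if (zygosity == "MZ") S_A + S_C else 0.5 * S_A + S_C
  rbind(cbind(within, cross), cbind(t(cross), within))
}

#' FIML -2 log-likelihood of a model for twin-pair data
#'
#' Evaluates the full-information maximum-likelihood objective: the sum
#' over pairs of \eqn{-2 \log} of the multivariate-normal density of each
#' pair's observed trait subvector under the model-implied per-zygosity
#' mean vector and covariance matrix.  Pairs with missing entries
#' contribute the marginal density of their observed entries only.
#'
#' @param data twin-pair data frame.
#' @param model either an [ace_params] object (means and covariance implied
#'   by the ACE structure) or a list with elements `mean` and `cov`, each a
#'   function of zygosity (`"MZ"`/`"DZ"`) returning the length-`2T` mean
#'   vector / `2T x 2T` covariance, or a fixed vector/matrix used for both
#'   zygosities.
#' @param traits trait base names; defaults to `model$traits` or the
#'   dataset's `"traits"` attribute.
#' @return the -2 log-likelihood (a single number; `Inf` if an implied
#'   covariance is not positive definite on some observed subspace).
#' @examples
#' p <- ace_params("y", A = 0.3, C = 0.4, E = 0.3)
#' d <- simulate_twin_data(sim_spec(20, 20, p, missing_rate = 0, seed = 1))
#' fiml_minus2ll(d, p)
#' @export
fiml_minus2ll <- function(data, model, traits = NULL) {
  if (inherits(model, "ace_params")) {
    traits <- traits %||% model$traits
    mean_fn <- function(z) rep(model$means, 2)
    cov_fn <- function(z) build_pair_covariance(model, z)
  } else if (is.list(model) && !is.null(model$mean) && !is.null(model$cov)) {
    traits <- traits %||% attr(data, "traits")
    mean_fn <- if (is.function(model$mean)) model$mean else function(z) model$mean
    cov_fn <- if (is.function(model$cov)) model$cov else function(z) model$cov
  } else stopf("`model` must be an ace_params or a list(mean=, cov=)")
  if (is.null(traits)) stopf("trait names could not be determined")
  m2ll_from_stats(fiml_stats(data, traits), mean_fn, cov_fn)
}

## ---- generic bounded quasi-Newton fitting with seeded restarts ----------

## mspec: list(names, start, lower, upper, map(theta) -> list(mean_fn,
## cov_fn) or NULL, extract(theta) -> params, k).  `names` are the FREE
## parameters only; fixed parameters are baked into `map` by the model
## builders.  A moment-based start is tried first; seeded random restarts
## run only if it fails to converge.
fit_fiml_spec <- function(stats, mspec, n_restarts = 10, seed = 1L,
                          m2ll_tol = 1e-8) {
  if (!length(mspec$names)) stopf("no free parameters left to fit")
  objective <- function(th) {
    if (any(!is.finite(th))) return(.Machine$double.xmax)
    mapped <- mspec$map(setNames(th, mspec$names))
    if (is.null(mapped)) return(.Machine$double.xmax)
    v <- m2ll_from_stats(stats, mapped$mean_fn, mapped$cov_fn)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  run <- function(start) {
    nlminb(start, objective, lower = mspec$lower, upper = mspec$upper,
           control = list(eval.max = 3000, iter.max = 1500,
                          rel.tol = 1e-12))
  }
  best <- run(mspec$start)
  n_used <- 0L
  ## nlminb flags flat-Hessian stops ("singular convergence") as code 1
  ## even at the optimum; only genuinely suspect stops trigger restarts
  ok <- function(res) res$objective < .Machine$double.xmax / 2 &&
    (res$convergence == 0 ||
     grepl("relative convergence|X-convergence|singular convergence",
           res$message))
  if (!ok(best) && n_restarts > 0) {
    seeds <- derive_seeds(seed, n_restarts)
    for (i in seq_len(n_restarts)) {
      st <- with_seed(seeds[i], {
        lo <- mspec$lower; hi <- mspec$upper; s <- mspec$start
        jitter <- s + rnorm(length(s), 0, pmax(abs(s) * 0.3, 0.3))
        box <- is.finite(lo) & is.finite(hi)
        jitter[box] <- runif(sum(box), lo[box], hi[box])
        jitter <- pmin(pmax(jitter, lo), hi)
        ## pull an infeasible jitter back toward the moment start
        for (h in 1:10) {
          if (objective(jitter) < .Machine$double.xmax / 2) break
          jitter <- (jitter + s) / 2
        }
        jitter
      })
      cand <- run(st)
      n_used <- i
      if (cand$objective < best$objective - m2ll_tol ||
          (ok(cand) && !ok(best))) best <- cand
      if (ok(best)) break
    }
  }
  list(theta = setNames(best$par, mspec$names), minus2LL = best$objective,
       converged = ok(best), n_restarts_used = n_used,
       k = length(mspec$names))
}

## assemble the exported fit-result object; `builder` is a closure
## function(fixed) -> mspec used by profile CIs for constrained refits
twin_fit_result <- function(model, fitted, mspec, stats, traits,
                            builder = NULL, fixed = list(), seed = 1L,
                            n_restarts = 10) {
  k <- fitted$k
  n_pairs <- stats$n_pairs
  structure(list(
    model = model,
    params = if (!is.null(mspec$extract)) mspec$extract(fitted$theta),
    theta = fitted$theta,
    minus2LL = fitted$minus2LL, k = k,
    n_obs = stats$n_obs, n_pairs = n_pairs,
    df = stats$n_obs - k,
    aic = fitted$minus2LL + 2 * k,
    bic = fitted$minus2LL + k * log(n_pairs),
    converged = fitted$converged,
    n_restarts_used = fitted$n_restarts_used,
    traits = traits, fixed = fixed,
    builder = builder, stats = stats,
    fit_seed = seed, n_restarts = n_restarts), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("Twin model fit: %s (%s)\n", x$model,
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  -2LL = %.3f   k = %d   df = %d   AIC = %.3f   BIC = %.3f\n",
              x$minus2LL, x$k, x$df, x$aic, x$bic))
  cat(sprintf("  converged: %s (%d restart(s) used)\n",
              x$converged, x$n_restarts_used))
  if (inherits(x$params, "ace_params")) print(x$params)
  if (!is.null(x$ci)) {
    cat("  95% profile CIs:\n")
    print(round(x$ci, 4))
  }
  invisible(x)
}

## refit the same model with extra fixed parameters, warm-started from the
## current optimum (used by profile CIs)
refit_fixed <- function(fit, fixed) {
  if (is.null(fit$builder)) stopf("this fit does not support constrained refits")
  all_fixed <- modifyList(as.list(fit$fixed), as.list(fixed))
  mspec <- fit$builder(all_fixed)
  shared <- intersect(mspec$names, names(fit$theta))
  mspec$start[match(shared, mspec$names)] <-
    pmin(pmax(fit$theta[shared], mspec$lower[match(shared, mspec$names)]),
         mspec$upper[match(shared, mspec$names)])
  fit_fiml_spec(fit$stats, mspec, n_restarts = fit$n_restarts,
                seed = fit$fit_seed)
}
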