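## Gaussian GEE (identity link) with cluster-robust sandwich variance for
## twin-pair data.  Twins are the units, pairs the clusters; the robust
## variance keeps Wald tests honest under within-pair correlation.

#' Fit a Gaussian GEE with robust (sandwich) standard errors
#'
#' Solves the generalized estimating equations
#' \eqn{\sum_i X_i' V_i^{-1} (y_i - X_i\beta) = 0} for twin-clustered data
#' with identity link and Gaussian variance, under an independence or
#' exchangeable working correlation.  The reported covariance is the
#' cluster-robust sandwich \eqn{B^{-1} M B^{-1}} with bread
#' \eqn{B = \sum_i X_i' V_i^{-1} X_i} and meat
#' \eqn{M = \sum_i X_i' V_i^{-1} e_i e_i' V_i^{-1} X_i}, with no
#' small-sample correction (large-sample z-based Wald convention).
#'
#' With `standardize = TRUE` (default) the response and every predictor are
#' z-scored before fitting, so slopes are in SD units and comparable across
#' covariates; binary and ordinal predictors are treated numerically.
#'
#' @param data twin-pair data frame (wide, `_t1`/`_t2` columns).
#' @param response trait base name.
#' @param predictors character vector of covariate base names.
#' @param working_correlation `"exchangeable"` (default; natural for twins)
#'   or `"independence"`.
#' @param standardize z-score response and predictors before fitting.
#' @return an object of class `gee_fit`: `coefficients`, `robust_se`,
#'   `ci_low`/`ci_high` (95% Wald), `p_values`, `vcov`, `alpha` (estimated
#'   exchangeable correlation), `n_individuals`, `n_clusters`, `converged`.
#' @export
fit_gee <- function(data, response, predictors,
                    working_correlation = c("exchangeable", "independence"),
                    standardize = TRUE) {
  working_correlation <- match.arg(working_correlation)
  long <- pairs_to_long(data, c(response, predictors))
  long <- long[complete.cases(long[, c(response, predictors), drop = FALSE]), ,
               drop = FALSE]
  n <- nrow(long)
  cl <- long$pair_id
  if (length(unique(cl)) < 2) stopf("need at least 2 clusters")
  y <- long[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(long[, predictors, drop = FALSE]))
  if (standardize) {
    zs <- function(v) {
      s <- sd(v)
      if (s == 0) return(v)  # caught by rank check below
      (v - mean(v)) / s
    }
    y <- zs(y)
    for (j in seq_along(predictors)) X[, j + 1] <- zs(X[, j + 1])
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }

  idx <- split(seq_len(n), cl)
  solve_beta <- function(alpha) {
    A <- matrix(0, p, p); b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      Ri_inv_X <- if (length(ii) == 1) Xi else {
        Ri <- matrix(alpha, length(ii), length(ii)); diag(Ri) <- 1
        solve(Ri, Xi)
      }
      A <- A + crossprod(Xi, Ri_inv_X)
      b <- b + crossprod(Ri_inv_X, y[ii])
    }
    drop(solve(A, b))
  }

  converged <- TRUE
  if (working_correlation == "independence") {
    alpha <- 0
    beta <- solve_beta(0)
  } else {
    alpha <- 0; beta <- solve_beta(0)
    for (it in 1:50) {
      e <- y - drop(X %*% beta)
      phi <- sum(e^2) / (n - p)
      num <- 0; npairs <- 0
      for (ii in idx) if (length(ii) > 1) {
        ee <- e[ii]
        cp <- (sum(ee)^2 - sum(ee^2)) / 2  # sum over j < k of e_j e_k
        num <- num + cp
        npairs <- npairs + choose(length(ii), 2)
      }
      alpha_new <- if (npairs > p) num / phi / (npairs - p) else 0
      alpha_new <- max(min(alpha_new, 0.999), -0.999)
      beta_new <- solve_beta(alpha_new)
      done <- max(abs(beta_new - beta), abs(alpha_new - alpha)) < 1e-10
      beta <- beta_new; alpha <- alpha_new
      if (done) break
      if (it == 50) converged <- FALSE
    }
  }

  ## sandwich: bread and meat at the working correlation
  e <- y - drop(X %*% beta)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    if (length(ii) == 1) {
      Ri_inv_X <- Xi
    } else {
      Ri <- matrix(alpha, length(ii), length(ii)); diag(Ri) <- 1
      Ri_inv_X <- solve(Ri, Xi)
    }
    B <- B + crossprod(Xi, Ri_inv_X)
    u <- crossprod(Ri_inv_X, e[ii])
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  V <- (V + t(V)) / 2
  se <- sqrt(diag(V))
  z <- beta / se
  crit <- qnorm(0.975)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 robust_se = setNames(se, colnames(X)),
                 ci_low = setNames(beta - crit * se, colnames(X)),
                 ci_high = setNames(beta + crit * se, colnames(X)),
                 p_values = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 vcov = V, alpha = alpha,
                 n_individuals = n, n_clusters = length(idx),
                 working_correlation = working_correlation,
                 standardized = standardize,
                 response = response, predictors = predictors,
                 converged = converged),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE (%s working correlation), %d twins in %d pairs\n",
              x$working_correlation, x$n_individuals, x$n_clusters))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.gee_fit <- function(x, ...) {
  data.frame(term = names(x$coefficients),
             beta = unname(x$coefficients),
             robust_se = unname(x$robust_se),
             ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
             p = unname(x$p_values), row.names = NULL)
}

#' Screen candidate covariates for association with the traits
#'
#' Fits, per trait, a GEE on all candidate covariates jointly (default,
#' one model per trait) or one covariate at a time, and retains every
#' covariate whose robust Wald p-value is at or below `alpha` for at least
#' one trait.
#'
#' @inheritParams fit_gee
#' @param traits trait base names.
#' @param candidates covariate base names to screen.
#' @param alpha retention threshold on the two-sided p-value.
#' @param joint screen all candidates in one joint model per trait
#'   (default) or in per-covariate marginal models.
#' @return list with `retained` (character vector), `table` (long data
#'   frame of per-trait coefficient rows) and `fits`.
#' @export
screen_covariates <- function(data, traits, candidates, alpha = 0.05,
                              joint = TRUE,
                              working_correlation = "exchangeable") {
  rows <- list(); fits <- list()
  for (tr in traits) {
    if (joint) {
      f <- fit_gee(data, tr, candidates, working_correlation)
      fits[[tr]] <- f
      tab <- as.data.frame(f)
      tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    } else {
      tab <- do.call(rbind, lapply(candidates, function(cv) {
        f <- fit_gee(data, tr, cv, working_correlation)
        d <- as.data.frame(f)
        d[d$term != "(Intercept)", , drop = FALSE]
      }))
      fits[[tr]] <- NULL
    }
    tab$trait <- tr
    rows[[tr]] <- tab
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  keep <- vapply(candidates, function(cv)
    any(tab$p[tab$term == cv] <= alpha), logical(1))
  list(retained = candidates[keep], table = tab, fits = fits, alpha = alpha)
}

#' Residualize trait scores on covariates
#'
#' Regresses a trait on covariates over the pooled sample (both twins, both
#' zygosities) and replaces the trait columns with residuals
#' `observed - fitted`, the scores modelled downstream by the twin models.
#' The fit uses an independence working correlation so residuals have
#' exactly zero mean and zero sample correlation with every regressor;
#' slopes would be identical in expectation under any working correlation.
#' A twin with an observed trait but a missing covariate gets a missing
#' residual (the count is recorded in the `"n_residual_dropped"` attribute).
#'
#' @inheritParams fit_gee
#' @param trait trait base name.
#' @param covariates covariate base names to residualize on.
#' @return the data frame with `<trait>_t1/_t2` replaced by residuals.
#' @export
residualize <- function(data, trait, covariates) {
  f <- fit_gee(data, trait, covariates,
               working_correlation = "independence", standardize = FALSE)
  beta <- f$coefficients
  dropped <- 0L
  for (suf in c("t1", "t2")) {
    obs <- data[[paste0(trait, "_", suf)]]
    Xw <- cbind(1, as.matrix(
      data[, paste0(covariates, "_", suf), drop = FALSE]))
    fitted <- drop(Xw %*% beta)
    res <- obs - fitted
    dropped <- dropped + sum(!is.na(obs) & is.na(res))
    data[[paste0(trait, "_", suf)]] <- res
  }
  attr(data, "n_residual_dropped") <-
    (attr(data, "n_residual_dropped") %||% 0L) + dropped
  attr(data, "residualized") <- union(attr(data, "residualized"), trait)
  data
}

#' Polygenic score association with a trait
#'
#' GEE association between one polygenic score and a trait, adjusting for
#' the first 10 ancestry principal components, with cluster-robust SEs.
#' One model per score; p-values are deliberately uncorrected for multiple
#' comparisons.
#'
#' @inheritParams fit_gee
#' @param trait trait base name.
#' @param score score column base name (e.g. `"pgs_adhd"`).
#' @param pc_columns ancestry PC base names.
#' @return a `gee_fit`; the `score_row` element is a one-row data frame
#'   with the score's beta, CI, SE and p.
#' @export
pgs_association <- function(data, trait, score,
                            pc_columns = paste0("pc", 1:10),
                            working_correlation = "exchangeable") {
  f <- fit_gee(data, trait, c(score, pc_columns), working_correlation)
  tab <- as.data.frame(f)
  f$score_row <- cbind(score = score, trait = trait,
                       tab[tab$term == score, -1, drop = FALSE])
  f
}
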