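## Descriptive twin statistics: twin-twin, cross-twin cross-trait and
## phenotypic correlations with 95% CIs, and distribution moments.

correlation_report <- function(estimate, ci, n_pairs, kind, zygosity,
                               traits, meta = NULL) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 n_pairs = n_pairs, kind = kind, zygosity = zygosity,
                 traits = traits, meta = meta),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s correlation [%s, %s]: %.3f (95%% CI %.3f, %.3f), n = %d pairs\n",
              x$kind, x$zygosity, paste(x$traits, collapse = " x "),
              x$estimate, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

check_cor_columns <- function(x, y, what) {
  if (length(x) < 3) stopf("fewer than 3 complete pairs for %s", what)
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined: zero variance in %s", what)
}

#' Twin-twin correlation
#'
#' Pearson correlation between co-twins' values on one trait within one
#' zygosity group.  Because the twin order within a pair is arbitrary, the
#' default estimate is computed on double-entered data — each pair
#' contributes both orderings `(t1, t2)` and `(t2, t1)` — which makes the
#' statistic invariant to relabelling twins.  The 95% CI uses the Fisher z
#' transform with the number of distinct pairs.
#'
#' @param data twin-pair data frame.
#' @param trait trait base name.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param double_entry use the symmetrized (label-invariant) estimator
#'   (default) or the raw single-order Pearson correlation.
#' @return a `correlation_report` with fields `estimate`, `ci_low`,
#'   `ci_high`, `n_pairs`.
#' @export
twin_twin_correlation <- function(data, trait, zygosity = c("MZ", "DZ"),
                                  double_entry = TRUE) {
  zygosity <- match.arg(zygosity)
  assert_pairs_df(data)
  d <- data[data$zygosity == zygosity, c(t1col(trait), t2col(trait))]
  d <- d[complete.cases(d), , drop = FALSE]
  x <- d[[1]]; y <- d[[2]]
  check_cor_columns(x, y, sprintf("%s (%s)", trait, zygosity))
  r <- if (double_entry) cor(c(x, y), c(y, x)) else cor(x, y)
  correlation_report(r, fisher_z_ci(r, nrow(d)), nrow(d),
                     "twin_twin", zygosity, trait)
}

#' Cross-twin cross-trait correlation
#'
#' Correlation between one twin's trait `trait_a` and the co-twin's trait
#' `trait_b`, pooled symmetrically over both orderings so the estimate does
#' not depend on twin labels.  An MZ/DZ difference in this statistic
#' signals genetic contributions to the covariation between the traits.
#'
#' @inheritParams twin_twin_correlation
#' @param trait_a,trait_b trait base names.
#' @return a `correlation_report`.
#' @export
cross_twin_cross_trait_correlation <- function(data, trait_a, trait_b,
                                               zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  assert_pairs_df(data)
  d <- data[data$zygosity == zygosity,
            c(t1col(trait_a), t2col(trait_a), t1col(trait_b), t2col(trait_b))]
  a1 <- d[[1]]; a2 <- d[[2]]; b1 <- d[[3]]; b2 <- d[[4]]
  ## both orderings: twin1's a with twin2's b, and twin2's a with twin1's b
  x <- c(a1, a2); y <- c(b2, b1)
  keep <- complete.cases(cbind(x, y))
  n_pairs <- sum(complete.cases(cbind(a1, b2)) | complete.cases(cbind(a2, b1)))
  if (n_pairs < 3)
    stopf("fewer than 3 pairs with the required cross-twin values")
  x <- x[keep]; y <- y[keep]
  check_cor_columns(x, y, sprintf("%s x %s (%s)", trait_a, trait_b, zygosity))
  r <- cor(x, y)
  correlation_report(r, fisher_z_ci(r, n_pairs), n_pairs,
                     "cross_twin_cross_trait", zygosity, c(trait_a, trait_b))
}

#' Phenotypic correlation between two traits
#'
#' Individual-level Pearson correlation between two traits across all
#' twins.  Because individuals are clustered in pairs, the 95% CI is
#' obtained by a cluster bootstrap that resamples whole pairs.
#'
#' @inheritParams cross_twin_cross_trait_correlation
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return a `correlation_report`; `meta$ci_method` records the bootstrap.
#' @export
phenotypic_correlation <- function(data, trait_a, trait_b, n_boot = 2000,
                                   seed = 1L) {
  assert_pairs_df(data)
  long <- pairs_to_long(data, c(trait_a, trait_b))
  keep <- complete.cases(long[, c(trait_a, trait_b)])
  long <- long[keep, , drop = FALSE]
  if (nrow(long) < 3) stopf("fewer than 3 individuals with both traits")
  check_cor_columns(long[[trait_a]], long[[trait_b]],
                    sprintf("%s x %s", trait_a, trait_b))
  r <- cor(long[[trait_a]], long[[trait_b]])
  ids <- unique(long$pair_id)
  by_pair <- split(seq_len(nrow(long)), long$pair_id)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(by_pair[take], use.names = FALSE)
      xa <- long[[trait_a]][idx]; xb <- long[[trait_b]][idx]
      if (sd(xa) == 0 || sd(xb) == 0) NA_real_ else cor(xa, xb)
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE, type = 7))
  correlation_report(r, ci, length(ids), "phenotypic", "pooled",
                     c(trait_a, trait_b),
                     meta = list(ci_method = "cluster bootstrap",
                                 n_boot = n_boot, seed = seed))
}

#' Distribution moments of a trait
#'
#' Sample mean, SD, skewness and excess kurtosis over all individuals.
#' Skewness and kurtosis use the adjusted Fisher-Pearson (sample-size
#' corrected) estimators.
#'
#' @inheritParams twin_twin_correlation
#' @return named list `mean`, `sd`, `skewness`, `kurtosis`, `n`.
#' @export
moment_descriptives <- function(data, trait) {
  assert_pairs_df(data)
  x <- c(data[[t1col(trait)]], data[[t2col(trait)]])
  x <- x[!is.na(x)]
  if (length(x) < 4) stopf("at least 4 non-missing values required")
  if (sd(x) == 0) stopf("moments undefined for a constant trait")
  list(mean = mean(x), sd = sd(x),
       skewness = e1071::skewness(x, type = 2),
       kurtosis = e1071::kurtosis(x, type = 2),
       n = length(x))
}

#' Full descriptive report for a twin-pair dataset
#'
#' Convenience wrapper computing, for each trait, the per-zygosity
#' twin-twin correlations and moments, and for a trait pair additionally
#' the phenotypic and per-zygosity cross-twin cross-trait correlations.
#'
#' @inheritParams twin_twin_correlation
#' @param traits trait base names (1 or 2); defaults to the `"traits"`
#'   attribute.
#' @param seed bootstrap seed passed to [phenotypic_correlation].
#' @return nested list of `correlation_report`s and moment lists.
#' @export
describe_twins <- function(data, traits = attr(data, "traits"), seed = 1L) {
  if (is.null(traits)) stopf("specify `traits`")
  out <- list(moments = lapply(setNames(traits, traits),
                               function(tr) moment_descriptives(data, tr)),
              twin_twin = list())
  for (tr in traits)
    out$twin_twin[[tr]] <- list(MZ = twin_twin_correlation(data, tr, "MZ"),
                                DZ = twin_twin_correlation(data, tr, "DZ"))
  if (length(traits) == 2) {
    out$phenotypic <- phenotypic_correlation(data, traits[1], traits[2],
                                             seed = seed)
    out$cross_twin_cross_trait <- list(
      MZ = cross_twin_cross_trait_correlation(data, traits[1], traits[2], "MZ"),
      DZ = cross_twin_cross_trait_correlation(data, traits[1], traits[2], "DZ"))
  }
  out
}
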