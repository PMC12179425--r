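## Config-driven end-to-end orchestration of the analysis ladder:
## combine domains -> descriptives -> GEE screening -> residualization ->
## twin correlations -> saturated + assumption models -> univariate ACE ->
## bivariate correlated factors -> model comparison -> decomposition ->
## optional power and PGS association.

#' Combine two raw-score domains into one trait
#'
#' Per-twin sum of two raw-score columns (missing if either input is
#' missing), used e.g. to merge socialization and communication scores
#' into one social-communication domain when item counts are low.
#' Distribution diagnostics (skewness, excess kurtosis) of the combined
#' column are attached for the decision audit.
#'
#' @param data twin-pair data frame.
#' @param domain_a,domain_b source column base names.
#' @param new_name base name for the combined trait.
#' @return the data frame with `<new_name>_t1/_t2` appended; attribute
#'   `"combine_diagnostics"` holds the moments.
#' @export
combine_domains <- function(data, domain_a, domain_b, new_name) {
  assert_pairs_df(data)
  if (any(c(t1col(new_name), t2col(new_name)) %in% names(data)))
    stopf("column '%s' already exists", new_name)
  for (suf in c("t1", "t2")) {
    a <- data[[paste0(domain_a, "_", suf)]]
    b <- data[[paste0(domain_b, "_", suf)]]
    if (is.null(a) || is.null(b))
      stopf("both '%s' and '%s' must have %s columns", domain_a, domain_b, suf)
    data[[paste0(new_name, "_", suf)]] <- a + b
  }
  diag <- tryCatch(moment_descriptives(data, new_name), error = function(e) NULL)
  attr(data, "combine_diagnostics") <-
    c(attr(data, "combine_diagnostics"), setNames(list(diag), new_name))
  data
}

#' Pipeline configuration
#'
#' Assembles (and validates the shape of) the configuration driving
#' [run_pipeline].  Every design-decision default of the package is
#' exposed as a flag here.
#'
#' @param input path to a pairs CSV (read with [read_pairs]) or a data
#'   frame.
#' @param traits named list mapping each analysed trait to its source
#'   column(s); a length-2 entry is summed via [combine_domains].
#' @param covariates candidate covariate base names for GEE screening.
#' @param alpha screening significance threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for JSON/CSV artifacts.
#' @param working_correlation GEE working correlation.
#' @param joint_screening screen covariates jointly (default) or marginally.
#' @param double_entry symmetrized twin correlations.
#' @param profile_cis compute 95% profile CIs on the ACE estimates.
#' @param n_boot bootstrap draws for the phenotypic-correlation CI.
#' @param run_power run post-hoc power at the fitted values.
#' @param power_replicates power replicates.
#' @param pgs_scores polygenic score column base names to associate
#'   (empty = skip).
#' @param n_restarts optimizer restart budget.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, traits, covariates = character(),
                            alpha = 0.05, seed = 1L, out_dir = NULL,
                            working_correlation = "exchangeable",
                            joint_screening = TRUE, double_entry = TRUE,
                            profile_cis = FALSE, n_boot = 2000,
                            run_power = FALSE, power_replicates = 500,
                            pgs_scores = character(), n_restarts = 10) {
  if (is.null(names(traits)) || any(names(traits) == ""))
    stopf("`traits` must be a named list")
  structure(list(input = input, traits = traits, covariates = covariates,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 working_correlation = working_correlation,
                 joint_screening = joint_screening,
                 double_entry = double_entry, profile_cis = profile_cis,
                 n_boot = n_boot, run_power = run_power,
                 power_replicates = power_replicates,
                 pgs_scores = pgs_scores, n_restarts = n_restarts),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of [pipeline_config].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$covariates <- as.character(y$covariates %||% character())
  y$pgs_scores <- as.character(y$pgs_scores %||% character())
  do.call(pipeline_config, y)
}

#' Run the full twin analysis pipeline
#'
#' Executes the analysis ladder on a conforming dataset: domain
#' combination, moment descriptives, GEE covariate screening,
#' residualization of traits on retained covariates, twin correlations,
#' saturated model and assumption tests, univariate ACE per trait, the
#' bivariate correlated-factors model with model comparison, the
#' decomposition report, and optionally post-hoc power and PGS
#' associations.  A stage failure aborts with the stage name; completed
#' stage outputs are kept in the returned bundle.  When `out_dir` is set,
#' JSON/CSV artifacts and a manifest (config, seeds, package version) are
#' written.
#'
#' @param config a [pipeline_config].
#' @return a named result bundle (list), invisibly also written to
#'   `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 8)
  bundle <- list(config = config)
  stage <- function(name, expr) {
    message(sprintf("[twinace] stage: %s", name))
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  data <- stage("load", {
    d <- if (is.character(config$input)) read_pairs(config$input)
         else config$input
    assert_pairs_df(d)
    d
  })
  trait_names <- names(config$traits)
  data <- stage("combine_domains", {
    for (tr in trait_names) {
      src <- config$traits[[tr]]
      if (length(src) == 2) data <- combine_domains(data, src[1], src[2], tr)
      else if (length(src) == 1 && src != tr) {
        data[[t1col(tr)]] <- data[[t1col(src)]]
        data[[t2col(tr)]] <- data[[t2col(src)]]
      }
      if (!t1col(tr) %in% names(data)) stopf("trait column '%s' not found", tr)
    }
    attr(data, "traits") <- trait_names
    data
  })
  bundle$moments <- stage("descriptives", lapply(
    setNames(trait_names, trait_names),
    function(tr) moment_descriptives(data, tr)))

  if (length(config$covariates)) {
    bundle$screening <- stage("gee_screening", screen_covariates(
      data, trait_names, config$covariates, alpha = config$alpha,
      joint = config$joint_screening,
      working_correlation = config$working_correlation))
    data <- stage("residualize", {
      for (tr in trait_names)
        if (length(bundle$screening$retained))
          data <- residualize(data, tr, bundle$screening$retained)
      data
    })
  }

  bundle$correlations <- stage("twin_correlations",
                               describe_twins(data, trait_names,
                                              seed = seeds[1]))
  bundle$assumptions <- stage("assumption_tests", lapply(
    setNames(trait_names, trait_names),
    function(tr) assumption_tests(data, tr, alpha = config$alpha,
                                  n_restarts = config$n_restarts,
                                  seed = seeds[2])))
  bundle$univariate <- stage("univariate_ace", lapply(
    setNames(trait_names, trait_names),
    function(tr) fit_univariate_ace(
      data, tr, ci = if (config$profile_cis) c("A", "C", "E"),
      n_restarts = config$n_restarts, seed = seeds[3])))

  if (length(trait_names) == 2) {
    bundle$saturated <- stage("saturated",
      fit_saturated(data, trait_names, n_restarts = config$n_restarts,
                    seed = seeds[4]))
    bundle$bivariate <- stage("bivariate_correlated_factors",
      fit_bivariate_correlated_factors(
        data, trait_names,
        ci = if (config$profile_cis) c("rA", "rC", "rE"),
        n_restarts = config$n_restarts, seed = seeds[5]))
    bundle$comparison <- stage("model_comparison", fit_table(
      list(saturated = bundle$saturated,
           correlated_factors = bundle$bivariate)))
    bundle$decomposition <- stage("decomposition",
                                  decompose_ace(bundle$bivariate))
    if (config$run_power)
      bundle$power <- stage("power", posthoc_power(
        bundle$bivariate$params,
        n_mz = as.integer(bundle$bivariate$stats$n_zyg[["MZ"]]),
        n_dz = as.integer(bundle$bivariate$stats$n_zyg[["DZ"]]),
        n_replicates = config$power_replicates, alpha = config$alpha,
        seed = seeds[6]))
  }

  if (length(config$pgs_scores))
    bundle$pgs <- stage("pgs_association", {
      rows <- list()
      for (tr in trait_names) for (sc in config$pgs_scores) {
        f <- pgs_association(data, tr, sc,
                             working_correlation = config$working_correlation)
        rows[[paste(tr, sc)]] <- f$score_row
      }
      tab <- do.call(rbind, rows); rownames(tab) <- NULL
      tab
    })

  bundle$manifest <- list(
    package = "twinace",
    version = as.character(utils::packageVersion("twinace")),
    seed = config$seed, stage_seeds = seeds,
    config = config[setdiff(names(config), "input")],
    input = if (is.character(config$input)) config$input else "<in-memory>",
    n_pairs = nrow(data))

  if (!is.null(config$out_dir)) stage("write_outputs", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wj <- function(x, f) jsonlite::write_json(
      x, file.path(config$out_dir, f), auto_unbox = TRUE, digits = NA,
      force = TRUE, null = "null", na = "null")
    wj(bundle$moments, "descriptives.json")
    if (!is.null(bundle$screening))
      write.csv(bundle$screening$table,
                file.path(config$out_dir, "gee_screening.csv"),
                row.names = FALSE)
    if (!is.null(bundle$comparison))
      write.csv(bundle$comparison,
                file.path(config$out_dir, "model_comparison.csv"),
                row.names = FALSE)
    if (!is.null(bundle$decomposition)) {
      dec <- bundle$decomposition
      wj(list(standardized = as.data.frame(dec$standardized),
              r_a = dec$r_a, r_c = dec$r_c, r_e = dec$r_e,
              implied = dec$implied, bivariate = dec$bivariate),
         "decomposition.json")
    }
    if (!is.null(bundle$pgs))
      write.csv(bundle$pgs, file.path(config$out_dir, "pgs.csv"),
                row.names = FALSE)
    if (!is.null(bundle$power))
      wj(as.data.frame(bundle$power), "power.json")
    wj(bundle$manifest, "manifest.json")
  })
  invisible(bundle)
}
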