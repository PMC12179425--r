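#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a stream of child seeds below 2^31 from one parent seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## pair-wide column names for a variable
t1col <- function(v) paste0(v, "_t1")
t2col <- function(v) paste0(v, "_t2")

assert_pairs_df <- function(data) {
  if (!is.data.frame(data)) stopf("`data` must be a data frame of twin pairs")
  miss <- setdiff(c("pair_id", "zygosity"), names(data))
  if (length(miss))
    stopf("twin-pair data lacks required column(s): %s",
          paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(data$zygosity)), c("MZ", "DZ"))
  if (length(bad))
    stopf("zygosity must be 'MZ' or 'DZ'; found: %s", paste(bad, collapse = ", "))
  invisible(data)
}

## stack a pair-wide data frame into one row per twin (long format),
## keeping pair_id/zygosity; vars are base names with _t1/_t2 columns
pairs_to_long <- function(data, vars) {
  assert_pairs_df(data)
  for (v in vars) {
    if (!all(c(t1col(v), t2col(v)) %in% names(data)))
      stopf("variable '%s' lacks %s/%s columns", v, t1col(v), t2col(v))
  }
  one <- function(suffix) {
    out <- data.frame(pair_id = data$pair_id,
                      zygosity = as.character(data$zygosity),
                      twin = suffix,
                      stringsAsFactors = FALSE)
    for (v in vars) out[[v]] <- data[[paste0(v, "_", suffix)]]
    out
  }
  rbind(one("t1"), one("t2"))
}

fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}
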