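# Internal helpers shared across modules.

METRIC_COLUMNS <- c("s_mean_diff", "s_median_diff", "s_mean_exp", "s_median_exp",
                    "corr_mean", "corr_median", "pc1")
SPREAD_METRICS <- METRIC_COLUMNS[1:4]
AGREEMENT_METRICS <- METRIC_COLUMNS[5:7]

#' Names of the seven consistency metrics
#'
#' Returns the metric column names used throughout the package, in canonical
#' order: the differential-expression spreads (`s_mean_diff`, `s_median_diff`),
#' the absolute-expression spreads (`s_mean_exp`, `s_median_exp`), the pairwise
#' Pearson summaries (`corr_mean`, `corr_median`) and the first-principal-
#' component variance fraction (`pc1`).
#'
#' @return Character vector of length 7.
#' @export
consistency_metrics <- function() METRIC_COLUMNS

#' Direction of each consistency metric
#'
#' Spread metrics are smaller-is-better (a consistent set has little spread);
#' correlation and PC1 metrics are larger-is-better.
#'
#' @param metric character vector of metric names.
#' @return Character vector, `"lower"` or `"higher"`, the better direction.
#' @export
metric_direction <- function(metric) {
  stopifnot(all(metric %in% METRIC_COLUMNS))
  ifelse(metric %in% SPREAD_METRICS, "lower", "higher")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("bin_max", "source", "y", "log_size"))

# Deterministic 31-bit seed derived from a master seed and a string key.
# Polynomial rolling hash mod (2^31 - 1); keeps per-set RNG streams stable
# when other sets are added or removed.
stable_seed <- function(seed, key) {
  bytes <- utf8ToInt(enc2utf8(as.character(key)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647)) %% 2147483647)
}

# Column sample SDs via explicit centering (two-pass; stable for near-constant
# columns). X is a numeric matrix; returns one SD per column, n-1 denominator.
col_sds <- function(X) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  sqrt(colSums(Xc * Xc) / (n - 1))
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
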