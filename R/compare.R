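# Cross-source comparison analyses over a table of consistency records:
# per-source means with direction-aware ranks, the 7x7 metric
# intercorrelation table, size-stratified profiles, nested linear models,
# and set-size variance decomposition.

#' Per-source metric means with direction-aware ranks
#'
#' Averages each requested metric over all sets (and organisms) within each
#' source, then ranks the sources per metric: rank 1 is the most consistent
#' source — the smallest mean for spread metrics, the largest for
#' correlation/PC1 metrics. Undefined metric values are excluded from means;
#' a source with no defined value for a metric gets `NA` mean and is excluded
#' from that metric's ranking. Exact mean ties are broken alphabetically by
#' source label for determinism.
#'
#' @param records consistency-record data frame (see
#'   [evaluate_collections()]).
#' @param metrics metric names to summarize (default all seven).
#' @return Data frame with columns `source`, `metric`, `mean`, `n_sets`,
#'   `rank`.
#' @export
summarize_by_source <- function(records, metrics = consistency_metrics()) {
  records <- validate_records(records)
  stopifnot(all(metrics %in% METRIC_COLUMNS))
  sources <- sort(unique(records$source))
  out <- do.call(rbind, lapply(metrics, function(m) {
    v <- records[[m]]
    means <- vapply(sources, function(s) {
      vs <- v[records$source == s & !is.na(v)]
      if (length(vs)) mean(vs) else NA_real_
    }, numeric(1L))
    ns <- vapply(sources, function(s)
      sum(records$source == s & !is.na(v)), integer(1L))
    ranked <- !is.na(means)
    key <- if (metric_direction(m) == "lower") means else -means
    rk <- rep(NA_integer_, length(sources))
    ord <- order(key[ranked], sources[ranked])
    rk[ranked][ord] <- seq_len(sum(ranked))
    data.frame(source = sources, metric = m, mean = means, n_sets = ns,
               rank = rk, row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson intercorrelation of the seven metrics
#'
#' Correlates the seven metric columns with each other across all gene sets,
#' using complete cases only (a row with any undefined metric is dropped so
#' every entry shares one row basis). Mean- and median-based variants of the
#' same metric class are typically near-collinear; spread metrics correlate
#' negatively with correlation/PC1 metrics because their consistency
#' directions are opposite.
#'
#' @param records consistency-record data frame; needs at least 3 complete
#'   rows.
#' @return Symmetric 7x7 numeric matrix with unit diagonal.
#' @export
metric_correlations <- function(records) {
  records <- validate_records(records)
  M <- as.matrix(records[, METRIC_COLUMNS])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 3L)
    stop("need at least 3 records with all seven metrics defined", call. = FALSE)
  stats::cor(M)
}

# Default size binning: exact sizes up to 20, then widening intervals.
default_size_bins <- function() c(2:20, 30, 50, 100, Inf)

size_bin_label <- function(n_genes, breaks = default_size_bins()) {
  breaks <- sort(unique(breaks))
  idx <- findInterval(n_genes, breaks + 1e-9) + 1L  # first break >= n
  idx <- pmin(idx, length(breaks))
  lab <- ifelse(idx == 1L | breaks[idx] == breaks[pmax(idx - 1L, 1L)] + 1L,
                as.character(breaks[idx]),
                sprintf("(%g,%g]", breaks[pmax(idx - 1L, 1L)], breaks[idx]))
  lab
}

#' Mean metric value by source and set-size bin
#'
#' Group-by average of one metric over (source, size-bin) cells, suppressing
#' cells with fewer than `min_sets` sets so sparse strata do not produce
#' noisy means. Default binning uses exact sizes 2-20 and then the intervals
#' (20,30], (30,50], (50,100], (100,Inf).
#'
#' @param records consistency-record data frame.
#' @param metric one metric name.
#' @param min_sets minimum sets per reported cell (default 20).
#' @param breaks increasing numeric vector of bin upper edges; consecutive
#'   integers give exact-size bins.
#' @return Data frame `source`, `size_bin`, `bin_max`, `n_sets`, `mean`.
#' @export
size_stratified_profile <- function(records, metric, min_sets = 20L,
                                    breaks = default_size_bins()) {
  records <- validate_records(records)
  stopifnot(length(metric) == 1L, metric %in% METRIC_COLUMNS)
  min_sets <- assert_scalar_count(min_sets, "min_sets", min = 1L)
  keep <- !is.na(records[[metric]])
  records <- records[keep, , drop = FALSE]
  breaks <- sort(unique(breaks))
  idx <- pmin(findInterval(records$n_genes, breaks + 1e-9) + 1L, length(breaks))
  lab <- size_bin_label(records$n_genes, breaks)
  agg <- stats::aggregate(records[[metric]],
                          by = list(source = records$source,
                                    bin_max = breaks[idx], size_bin = lab),
                          FUN = mean)
  n <- stats::aggregate(records[[metric]],
                        by = list(source = records$source,
                                  bin_max = breaks[idx], size_bin = lab),
                        FUN = length)
  out <- data.frame(source = agg$source, size_bin = agg$size_bin,
                    bin_max = agg$bin_max, n_sets = n$x, mean = agg$x,
                    stringsAsFactors = FALSE)
  out <- out[out$n_sets >= min_sets, , drop = FALSE]
  out <- out[order(out$source, out$bin_max), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal OLS wrapper returning a tidy model_fit. r2 defined as
# 1 - SSE/SST with the convention r2 = 0 for a constant response.
fit_ols <- function(formula, data, model_id, terms_label) {
  fit <- stats::lm(formula, data = data)
  y <- stats::model.response(stats::model.frame(fit))
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= 0) 0 else 1 - sse / sst
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    # a noiseless response is a legitimate input here (r2 = 1 by design)
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  effects <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                        std_error = cf[, 2L], t_value = cf[, 3L],
                        p_value = cf[, 4L], row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(model_id = model_id, terms = terms_label,
                 formula = formula, r2 = r2, n = length(y),
                 effects = effects, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s> %s | n=%d, r2=%.4f\n", x$model_id,
              paste(x$terms, collapse = " + "), x$n, x$r2))
  invisible(x)
}

#' Nested linear models for a consistency metric
#'
#' Fits four ordinary-least-squares models of increasing complexity for one
#' metric: (1) source only, (2) source + log10 set size, (3) source + log10
#' set size + organism, (4) all three plus every interaction term. Source and
#' organism are treatment-coded factors. r-squared is non-decreasing across
#' the nest; the model-4 gain over model 3 measures how much
#' combination-specific structure exists beyond the main effects. Records
#' with an undefined metric are dropped. With a single organism the organism
#' terms are dropped with a warning.
#'
#' @param records consistency-record data frame covering at least 2 sources.
#' @param metric one metric name.
#' @return List of four `model_fit` objects (ids `"1"`-`"4"`), each with
#'   `r2` and a per-coefficient `effects` table (estimates, standard errors,
#'   t and raw p-values).
#' @export
fit_nested_models <- function(records, metric) {
  records <- validate_records(records)
  stopifnot(length(metric) == 1L, metric %in% METRIC_COLUMNS)
  d <- data.frame(y = records[[metric]],
                  source = factor(records$source),
                  organism = factor(records$organism),
                  log_size = log10(records$n_genes))
  d <- d[!is.na(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$source)) < 2L)
    stop("nested models need records from at least 2 sources", call. = FALSE)
  d$source <- droplevels(d$source)
  d$organism <- droplevels(d$organism)
  has_org <- nlevels(d$organism) >= 2L
  if (!has_org)
    warning("single organism: organism terms dropped from models 3 and 4",
            call. = FALSE)
  f3 <- if (has_org) y ~ source + log_size + organism else y ~ source + log_size
  f4 <- if (has_org) y ~ source * log_size * organism else y ~ source * log_size
  list(
    fit_ols(y ~ source, d, "1", "source"),
    fit_ols(y ~ source + log_size, d, "2", c("source", "log_size")),
    fit_ols(f3, d, "3",
            c("source", "log_size", if (has_org) "organism")),
    fit_ols(f4, d, "4",
            c("source", "log_size", if (has_org) "organism", "interactions")))
}

#' How much of set-size variation is explained by organism vs source
#'
#' Two separate one-way OLS regressions of log10 set size: on organism alone
#' and on source alone. The r-squared values quantify which grouping drives
#' set-size differences (in compendium-scale data, source dominates).
#'
#' @param records consistency-record data frame.
#' @return Named list of two `model_fit` objects, `organism` and `source`.
#' @export
size_variance_decomposition <- function(records) {
  records <- validate_records(records)
  d <- data.frame(log_size = log10(records$n_genes),
                  source = factor(records$source),
                  organism = factor(records$organism))
  fit_one <- function(var) {
    if (nlevels(droplevels(d[[var]])) < 2L) {
      # single level: the grouping explains nothing
      return(fit_ols(stats::as.formula("log_size ~ 1"), d, var, var))
    }
    fit_ols(stats::as.formula(paste("log_size ~", var)), d, var, var)
  }
  list(organism = fit_one("organism"), source = fit_one("source"))
}

#' Correlation of organism gene counts with total gene-set counts
#'
#' Pearson correlation between the number of measured genes per organism and
#' the total number of gene sets available for it, across organisms. Larger
#' genomes support more annotated sets, so this is strongly positive in
#' compendium data.
#'
#' @param counts data frame with numeric columns `gene_count` and
#'   `set_count`, one row per organism (at least 3 rows).
#' @return Pearson r (numeric scalar).
#' @export
organism_level_correlation <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("gene_count", "set_count") %in% names(counts)))
  if (nrow(counts) < 3L) stop("need at least 3 organisms", call. = FALSE)
  stats::cor(as.numeric(counts$gene_count), as.numeric(counts$set_count))
}

#' Bundled per-organism gene and gene-set counts
#'
#' A reference table for 17 bacterial expression compendia: organism name,
#' number of measured genes, number of arrays, per-source gene-set counts
#' (GO BP/CC/MF, KEGG, predicted operons, SEED subsystems/scenarios/paths)
#' and the total set count.
#'
#' @return Data frame with 17 rows.
#' @export
organism_set_counts <- function() {
  path <- system.file("extdata", "organism_set_counts.tsv",
                      package = "gsconsistency", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
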