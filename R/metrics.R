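# The seven gene-set consistency metrics.
#
# For a set N of n genes measured on P arrays (log2 expression e_{k,i} for
# array k, gene i):
#
#   * diff spread:  for an array pair (k,l), d_i = e_{k,i} - e_{l,i}; the
#     sample SD of {d_i} over the set is s_{N,(k,l)}; s_mean_diff and
#     s_median_diff are the mean / median of s_{N,(k,l)} over pairs.
#     Pairs are subsampled (default 100 per organism) when P(P-1)/2 is large.
#   * abs spread:   s_{N,k} = sample SD of the n genes' values on array k;
#     s_mean_exp / s_median_exp are the mean / median over all P arrays.
#   * correlation:  corr_mean / corr_median summarize pairwise Pearson r over
#     the n(n-1)/2 gene pairs (a seeded 50-gene subsample for larger sets).
#   * pc1:          first eigenvalue of the n x n sample covariance matrix of
#     the set's genes divided by its trace — the fraction of variance captured
#     by the first principal component.
#
# Smaller spread = more consistent; larger corr/pc1 = more consistent.
# Sample SDs and covariances use the n-1 denominator throughout.

#' Sample array pairs for the differential-expression metrics
#'
#' Draws `n_pairs` distinct unordered array pairs uniformly without
#' replacement; if the total number of pairs `P(P-1)/2` does not exceed
#' `n_pairs`, all pairs are returned and the sample is flagged exhaustive.
#'
#' @param n_arrays number of arrays P (>= 2).
#' @param n_pairs number of pairs to draw (default 100, the per-organism
#'   sampling depth used for large compendia).
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return Object of class `pair_sample`: list with `pairs` (two-column
#'   integer matrix, k < l per row), `exhaustive` and `seed`.
#' @export
sample_array_pairs <- function(n_arrays, n_pairs = 100L, seed = 1L) {
  n_arrays <- assert_scalar_count(n_arrays, "n_arrays", min = 2L)
  n_pairs <- assert_scalar_count(n_pairs, "n_pairs", min = 1L)
  total <- n_arrays * (n_arrays - 1) / 2
  if (total <= n_pairs) {
    idx <- seq_len(total)
    exhaustive <- TRUE
  } else {
    idx <- withr::with_seed(as.integer(seed),
                            sample.int(total, n_pairs, replace = FALSE))
    exhaustive <- FALSE
  }
  # decode linear index m in 1..P(P-1)/2 to the m-th pair (k,l), k < l,
  # enumerated as (1,2),(1,3),...,(1,P),(2,3),...
  m <- as.numeric(sort(idx))
  k <- ceiling(n_arrays - 0.5 -
                 sqrt((n_arrays - 0.5)^2 - 2 * m))
  offset <- (k - 1) * n_arrays - (k - 1) * k / 2
  l <- m - offset + k
  pairs <- cbind(k = as.integer(k), l = as.integer(l))
  stopifnot(all(pairs[, 1L] < pairs[, 2L]), all(pairs[, 2L] <= n_arrays),
            !anyDuplicated(pairs))
  structure(list(pairs = pairs, exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "pair_sample")
}

#' @export
print.pair_sample <- function(x, ...) {
  cat(sprintf("<pair_sample> %d array pairs%s (seed %d)\n", nrow(x$pairs),
              if (x$exhaustive) ", exhaustive" else "", x$seed))
  invisible(x)
}

#' Spread of differential expression for a gene set
#'
#' For each array pair (k, l) in `pairs`, computes the per-gene differential
#' values d_i = e_{k,i} - e_{l,i} (log2 ratios) and their sample standard
#' deviation across the set, then averages (`s_mean_diff`) and takes the
#' median (`s_median_diff`) over pairs. Small values mean the set's genes
#' move together between conditions.
#'
#' @param gene_ids character vector of member genes, all present in `x`,
#'   length >= 2.
#' @param x an `expr_matrix`.
#' @param pairs a `pair_sample` over `ncol(x)` arrays.
#' @return Named numeric vector `c(s_mean_diff, s_median_diff)`.
#' @export
diff_spread <- function(gene_ids, x, pairs) {
  stopifnot(inherits(pairs, "pair_sample"))
  if (!nrow(pairs$pairs)) stop("empty pair sample", call. = FALSE)
  X <- set_submatrix(gene_ids, x)
  if (max(pairs$pairs) > ncol(X))
    stop("pair sample refers to arrays beyond the matrix", call. = FALSE)
  D <- X[, pairs$pairs[, 1L], drop = FALSE] - X[, pairs$pairs[, 2L], drop = FALSE]
  s <- col_sds(D)
  c(s_mean_diff = mean(s), s_median_diff = stats::median(s))
}

#' Spread of absolute expression for a gene set
#'
#' For each array, the sample standard deviation of the set's n gene values;
#' summarized as the mean (`s_mean_exp`) and median (`s_median_exp`) over all
#' P arrays. No subsampling: every array contributes. Small values mean the
#' set's genes sit at similar expression levels.
#'
#' @inheritParams diff_spread
#' @return Named numeric vector `c(s_mean_exp, s_median_exp)`.
#' @export
abs_spread <- function(gene_ids, x) {
  X <- set_submatrix(gene_ids, x)
  s <- col_sds(X)
  c(s_mean_exp = mean(s), s_median_exp = stats::median(s))
}

#' Pairwise Pearson correlation summary for a gene set
#'
#' Computes Pearson r over all arrays for each unordered gene pair in the set
#' and summarizes by mean (`corr_mean`) and median (`corr_median`). Sets
#' larger than `max_genes` are first reduced to a seeded uniform subsample of
#' `max_genes` genes (the same subsample feeds both summaries). Pairs
#' involving a zero-variance gene have no defined correlation and are
#' excluded; if no pair survives, both summaries are `NA`.
#'
#' @inheritParams diff_spread
#' @param max_genes subsampling cap (default 50).
#' @param seed integer seed for the gene subsample; only consumed when
#'   `length(gene_ids) > max_genes`.
#' @return Named numeric vector `c(corr_mean, corr_median)`; `NA` when
#'   undefined.
#' @export
corr_summary <- function(gene_ids, x, max_genes = 50L, seed = 1L) {
  max_genes <- assert_scalar_count(max_genes, "max_genes", min = 2L)
  X <- set_submatrix(gene_ids, x)
  if (nrow(X) > max_genes) {
    pick <- withr::with_seed(as.integer(seed),
                             sample.int(nrow(X), max_genes, replace = FALSE))
    X <- X[pick, , drop = FALSE]
  }
  R <- suppressWarnings(stats::cor(t(X)))
  r <- R[upper.tri(R)]
  r <- r[!is.na(r)]
  if (!length(r))
    return(c(corr_mean = NA_real_, corr_median = NA_real_))
  c(corr_mean = mean(r), corr_median = stats::median(r))
}

#' Fraction of variance explained by the first principal component
#'
#' Treats the set's genes as variables and the arrays as observations, forms
#' the n x n sample covariance matrix (genes centered, not scaled), and
#' returns the first eigenvalue divided by the trace. A value near 1 means a
#' single latent profile drives the whole set. Computed on the full set —
#' no gene subsampling by default (`max_genes = Inf`); a cap is available for
#' sets so large that the eigendecomposition is impractical.
#'
#' @inheritParams corr_summary
#' @param max_genes optional cap on the number of genes (default `Inf`, off).
#' @return Named numeric `c(pc1 = ...)` in `(0, 1]`, with `pc1 >= 1/n`;
#'   `NA` when the set has zero total variance.
#' @export
pc1_fraction <- function(gene_ids, x, max_genes = Inf, seed = 1L) {
  X <- set_submatrix(gene_ids, x)
  if (is.finite(max_genes) && nrow(X) > max_genes) {
    max_genes <- assert_scalar_count(max_genes, "max_genes", min = 2L)
    pick <- withr::with_seed(as.integer(seed),
                             sample.int(nrow(X), max_genes, replace = FALSE))
    X <- X[pick, , drop = FALSE]
  }
  n <- nrow(X); P <- ncol(X)
  Xc <- X - rowMeans(X)
  trace <- sum(Xc * Xc) / (P - 1)
  if (trace <= 0) return(c(pc1 = NA_real_))
  # eigenvalues of cov(t(X)) equal those of the P x P Gram matrix of the
  # centered data; use whichever side is smaller
  S <- if (n <= P) tcrossprod(Xc) / (P - 1) else crossprod(Xc) / (P - 1)
  lambda1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1L]
  c(pc1 = lambda1 / trace)
}

#' Evaluate every set of one or more collections against a matrix
#'
#' Computes all seven consistency metrics for each gene set. One array-pair
#' sample is shared across the whole matrix (pairs are sampled once per
#' organism); the 50-gene correlation subsample is seeded per set from the
#' master seed and a stable hash of `source:set_id`, so adding or removing a
#' set never changes another set's subsample. Undefined metrics propagate as
#' `NA` without aborting the batch.
#'
#' @param collections a `gene_set_collection` or a list of them, already
#'   filtered to the matrix (see [filter_to_matrix()]).
#' @param x an `expr_matrix`.
#' @param n_pairs array pairs to sample for the differential metrics
#'   (default 100).
#' @param max_genes gene-subsampling cap for the correlation summaries
#'   (default 50).
#' @param seed master integer seed.
#' @return Data frame with one row per set: `organism`, `source`, `set_id`,
#'   `n_genes` and the seven metric columns.
#' @export
evaluate_collections <- function(collections, x, n_pairs = 100L,
                                 max_genes = 50L, seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  stopifnot(all(vapply(collections, inherits, logical(1L),
                       "gene_set_collection")))
  pairs <- sample_array_pairs(ncol(x$values), n_pairs = n_pairs,
                              seed = stable_seed(seed, "array_pairs"))
  rows <- lapply(collections, function(coll) {
    ids <- names(coll$sets)
    res <- lapply(ids, function(id) {
      g <- coll$sets[[id]]
      set_seed <- stable_seed(seed, paste0(coll$source, ":", id))
      c(diff_spread(g, x, pairs),
        abs_spread(g, x),
        corr_summary(g, x, max_genes = max_genes, seed = set_seed),
        pc1_fraction(g, x))
    })
    cbind(data.frame(organism = x$organism, source = coll$source,
                     set_id = ids, n_genes = lengths(coll$sets)[ids],
                     stringsAsFactors = FALSE),
          as.data.frame(do.call(rbind, res)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_records(out)
}
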