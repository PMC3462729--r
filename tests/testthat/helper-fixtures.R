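# Shared fixtures and independent brute-force oracles. The oracles use
# explicit loops, stats::sd / stats::cor on vectors, and full
# eigendecompositions, deliberately avoiding the package's vectorized paths.

random_em <- function(n_genes, n_arrays, seed, organism = "fixture") {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_arrays, mean = 7, sd = 2),
                n_genes, n_arrays,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("a%03d", seq_len(n_arrays))))
    expression_matrix(m, organism = organism)
  })
}

random_collection <- function(n_sets, gene_pool, seed, source = "SRC",
                              size_min = 2L, size_max = 6L) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(gene_pool, sample(size_min:size_max, 1L)))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    gene_set_collection(sets, source = source)
  })
}

all_pairs <- function(P) t(utils::combn(P, 2L))

# --- brute-force metric oracles -------------------------------------------

bf_diff_spread <- function(gene_ids, em, pairs) {
  X <- em$values[gene_ids, , drop = FALSE]
  s <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- X[, pairs[p, 1L]] - X[, pairs[p, 2L]]
    s[p] <- stats::sd(d)
  }
  c(mean(s), stats::median(s))
}

bf_abs_spread <- function(gene_ids, em) {
  X <- em$values[gene_ids, , drop = FALSE]
  s <- numeric(ncol(X))
  for (k in seq_len(ncol(X))) s[k] <- stats::sd(X[, k])
  c(mean(s), stats::median(s))
}

bf_corr_summary <- function(gene_ids, em) {
  X <- em$values[gene_ids, , drop = FALSE]
  n <- nrow(X)
  r <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::sd(X[i, ]) == 0 || stats::sd(X[j, ]) == 0) next
    r <- c(r, stats::cor(X[i, ], X[j, ]))
  }
  if (!length(r)) return(c(NA_real_, NA_real_))
  c(mean(r), stats::median(r))
}

bf_pc1 <- function(gene_ids, em) {
  X <- em$values[gene_ids, , drop = FALSE]
  S <- stats::cov(t(X))
  tr <- sum(diag(S))
  if (tr <= 0) return(NA_real_)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev[1L] / sum(ev)
}

# realized mean pairwise Pearson correlation over a collection's sets
mean_realized_corr <- function(collection, em) {
  mean(vapply(collection$sets, function(g)
    mean(stats::cor(t(em$values[g, , drop = FALSE]))[upper.tri(diag(length(g)))]),
    numeric(1L)))
}

stable_seed_for_test <- function(seed, key) gsconsistency:::stable_seed(seed, key)

# synthetic records table with known structure for the compare module
fake_records <- function(n_per_source, source_means, seed = 1L,
                         organisms = "orgA", slope = 0, noise_sd = 0.05) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(names(source_means), function(s) {
      n <- n_per_source
      sz <- sample(2:200, n, replace = TRUE)
      data.frame(organism = sample(organisms, n, replace = TRUE),
                 source = s, set_id = paste0(s, "_", seq_len(n)),
                 n_genes = sz,
                 stringsAsFactors = FALSE)
    }))
    base <- source_means[rows$source] + slope * log10(rows$n_genes) +
      stats::rnorm(nrow(rows), sd = noise_sd)
    for (m in consistency_metrics())
      rows[[m]] <- base + stats::rnorm(nrow(rows), sd = noise_sd)
    rows$corr_mean <- pmin(pmax(rows$corr_mean, -1), 1)
    rows$corr_median <- pmin(pmax(rows$corr_median, -1), 1)
    rows$pc1 <- pmin(pmax(rows$pc1, 1e-3), 1)
    rows
  })
}
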