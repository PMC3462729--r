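# Synthetic expression compendia with known ground-truth set structure.
#
# Each gene set follows a single-factor Gaussian block model:
#
#   g_i(a) = mu_i + lambda * f_s(a) + eps_i(a),   f_s ~ N(0,1), eps ~ (0, sd^2)
#
# with the loading lambda chosen so the expected pairwise Pearson correlation
# between two members equals the target rho: lambda^2 / (lambda^2 + sd^2) =
# rho, i.e. lambda = sd * sqrt(rho / (1 - rho)). The closed form makes rho an
# analytic oracle for the correlation metrics. Per-gene means mu_i carry the
# heterogeneous baseline levels of log2 array data; offset_spread adds extra
# within-set level dispersion (high-correlation / high-abs-spread sets).
# Background genes are independent noise around their own baselines.

#' Configuration for the synthetic compendium generator
#'
#' Defaults emulate an RMA-style bacterial compendium: log2 baselines around
#' 7 with SD 2 across genes, residual per-gene SD 0.5 across arrays, and
#' three sources ordered by target within-set correlation the way predicted
#' operons, SEED paths/scenarios and GO/KEGG sets order in real compendia.
#'
#' @param n_arrays number of arrays (>= 3).
#' @param n_background_genes genes assigned to no set.
#' @param sources list of source descriptors, each a list with `label`,
#'   `n_sets`, `size_min`, `size_max`, `rho` (target within-set Pearson
#'   correlation in `[0, 1)`), and optional per-source `baseline_sd`,
#'   `offset_spread`, `noise_df` overriding the global values.
#' @param baseline_mean grand mean log2 level.
#' @param baseline_mean_spread SD of per-gene baseline means (log2 units).
#' @param baseline_sd residual SD of a gene across arrays (log2 units).
#' @param offset_spread SD of additional per-gene level offsets within a set;
#'   inflates absolute-expression spread without touching correlations.
#' @param noise_df degrees of freedom for t-distributed residuals, rescaled
#'   to unit variance so the rho closed form still holds; `Inf` (default)
#'   gives Gaussian residuals. Small values create heavy tails that separate
#'   mean- from median-based metrics.
#' @param condition_effect optional numeric vector of per-array mean shifts
#'   (length `n_arrays`, recycled from length 2 as two array groups), applied
#'   to every gene.
#' @param seed integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_arrays = 40L,
                             n_background_genes = 200L,
                             sources = list(
                               list(label = "OPERON_LIKE", n_sets = 50L,
                                    size_min = 2L, size_max = 10L, rho = 0.9),
                               list(label = "PATH_LIKE", n_sets = 50L,
                                    size_min = 2L, size_max = 15L, rho = 0.5),
                               list(label = "GO_LIKE", n_sets = 50L,
                                    size_min = 3L, size_max = 40L, rho = 0.1)),
                             baseline_mean = 7,
                             baseline_mean_spread = 2,
                             baseline_sd = 0.5,
                             offset_spread = 0,
                             noise_df = Inf,
                             condition_effect = NULL,
                             seed = 1L) {
  n_arrays <- assert_scalar_count(n_arrays, "n_arrays", min = 3L)
  n_background_genes <- assert_scalar_count(n_background_genes,
                                            "n_background_genes", min = 0L)
  stopifnot(is.list(sources), length(sources) >= 1L)
  labels <- vapply(sources, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("duplicate source labels", call. = FALSE)
  for (s in sources) {
    rho <- s$rho
    if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
      stop(sprintf("source '%s': rho must be in [0, 1)", s$label), call. = FALSE)
    assert_scalar_count(s$n_sets, "n_sets", min = 1L)
    assert_scalar_count(s$size_min, "size_min", min = 2L)
    assert_scalar_count(s$size_max, "size_max", min = s$size_min)
    if (!is.null(s$noise_df) && s$noise_df <= 2)
      stop("noise_df must exceed 2 (finite variance)", call. = FALSE)
  }
  stopifnot(baseline_mean_spread >= 0, baseline_sd > 0, offset_spread >= 0)
  if (is.finite(noise_df) && noise_df <= 2)
    stop("noise_df must exceed 2 (finite variance)", call. = FALSE)
  if (!is.null(condition_effect)) {
    condition_effect <- as.numeric(condition_effect)
    if (length(condition_effect) == 2L)
      condition_effect <- rep(condition_effect, length.out = n_arrays)
    if (length(condition_effect) != n_arrays)
      stop("condition_effect must have length n_arrays (or 2 for two groups)",
           call. = FALSE)
  }
  structure(list(n_arrays = n_arrays,
                 n_background_genes = n_background_genes,
                 sources = sources,
                 baseline_mean = baseline_mean,
                 baseline_mean_spread = baseline_mean_spread,
                 baseline_sd = baseline_sd,
                 offset_spread = offset_spread,
                 noise_df = noise_df,
                 condition_effect = condition_effect,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Unit-variance residual draw: Gaussian or variance-rescaled t.
rnoise <- function(n, df) {
  if (is.infinite(df)) stats::rnorm(n)
  else stats::rt(n, df = df) * sqrt((df - 2) / df)
}

#' Generate a synthetic expression compendium with known set structure
#'
#' Draws an expression matrix, one gene-set collection per configured source,
#' and a ground-truth table, deterministically under the config seed. Set
#' members load on a shared latent factor so their expected pairwise Pearson
#' correlation equals the source's target rho; background genes are
#' independent.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `expression` (an `expr_matrix`), `collections`
#'   (named list of `gene_set_collection`), and `truth` (list with data
#'   frames `sets` — set_id, source, rho, size — and `genes` — gene_id,
#'   set_id, mu, lambda).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    P <- config$n_arrays
    array_ids <- sprintf("A%03d", seq_len(P))
    blocks <- list(); truth_sets <- list(); truth_genes <- list()
    collections <- list()
    for (src in config$sources) {
      sd_e <- src$baseline_sd %||% config$baseline_sd
      off <- src$offset_spread %||% config$offset_spread
      df <- src$noise_df %||% config$noise_df
      lambda <- sd_e * sqrt(src$rho / (1 - src$rho))
      sizes <- if (src$size_min == src$size_max) rep(src$size_min, src$n_sets)
      else sample(seq(src$size_min, src$size_max), src$n_sets, replace = TRUE)
      sets <- vector("list", src$n_sets)
      names(sets) <- sprintf("%s_set%04d", src$label, seq_len(src$n_sets))
      for (j in seq_len(src$n_sets)) {
        n <- sizes[j]
        ids <- sprintf("%s_g%02d", names(sets)[j], seq_len(n))
        mu <- config$baseline_mean +
          stats::rnorm(n, sd = config$baseline_mean_spread) +
          stats::rnorm(n, sd = off)
        f <- stats::rnorm(P)
        E <- matrix(rnoise(n * P, df) * sd_e, n, P)
        X <- mu + lambda * matrix(f, n, P, byrow = TRUE) + E
        dimnames(X) <- list(ids, array_ids)
        blocks[[length(blocks) + 1L]] <- X
        sets[[j]] <- ids
        truth_genes[[length(truth_genes) + 1L]] <-
          data.frame(gene_id = ids, set_id = names(sets)[j], mu = mu,
                     lambda = lambda, stringsAsFactors = FALSE)
      }
      truth_sets[[length(truth_sets) + 1L]] <-
        data.frame(set_id = names(sets), source = src$label, rho = src$rho,
                   size = sizes, stringsAsFactors = FALSE)
      collections[[src$label]] <-
        gene_set_collection(sets, source = src$label, organism = "synthetic")
    }
    if (config$n_background_genes > 0L) {
      n <- config$n_background_genes
      ids <- sprintf("BG_g%04d", seq_len(n))
      mu <- config$baseline_mean +
        stats::rnorm(n, sd = config$baseline_mean_spread)
      X <- mu + matrix(rnoise(n * P, config$noise_df) * config$baseline_sd,
                       n, P)
      dimnames(X) <- list(ids, array_ids)
      blocks[[length(blocks) + 1L]] <- X
      truth_genes[[length(truth_genes) + 1L]] <-
        data.frame(gene_id = ids, set_id = NA_character_, mu = mu,
                   lambda = 0, stringsAsFactors = FALSE)
    }
    values <- do.call(rbind, blocks)
    if (!is.null(config$condition_effect))
      values <- values + rep(config$condition_effect, each = nrow(values))
    list(expression = expression_matrix(values, organism = "synthetic"),
         collections = collections,
         truth = list(sets = do.call(rbind, truth_sets),
                      genes = do.call(rbind, truth_genes)))
  })
}

#' Rewire a collection so a target fraction of its genes is shared
#'
#' Adds genes to additional sets until roughly `overlap_fraction` of the
#' genes appearing in any set appear in two or more sets. The gene universe
#' (genes in at least one set) is unchanged, so the realized multi-set
#' percentage of [overlap_report()] approaches `100 * overlap_fraction`.
#'
#' @param base a `gene_set_collection` with at least 2 sets.
#' @param overlap_fraction target fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return A new `gene_set_collection`.
#' @export
make_overlapping_collection <- function(base, overlap_fraction, seed = 1L) {
  stopifnot(inherits(base, "gene_set_collection"),
            is.numeric(overlap_fraction), length(overlap_fraction) == 1L,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (overlap_fraction == 0) return(base)
  if (length(base) < 2L)
    stop("need at least 2 sets to create overlap", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    sets <- base$sets
    counts <- table(unlist(sets, use.names = FALSE))
    universe <- names(counts)
    target <- round(overlap_fraction * length(universe))
    singles <- sample(names(counts)[counts == 1L])
    need <- target - sum(counts >= 2L)
    if (need > length(singles))
      stop("not enough single-set genes to reach the requested overlap",
           call. = FALSE)
    if (need > 0L) {
      home <- vapply(singles[seq_len(need)], function(g)
        which(vapply(sets, function(s) g %in% s, logical(1L)))[1L], integer(1L))
      for (i in seq_len(need)) {
        cand <- setdiff(seq_along(sets), home[i])
        dest <- if (length(cand) == 1L) cand else sample(cand, 1L)
        sets[[dest]] <- c(sets[[dest]], singles[i])
      }
    }
    gene_set_collection(sets, source = base$source, organism = base$organism)
  })
}
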