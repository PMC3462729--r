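# End-to-end pipeline: simulate (or read) -> filter -> evaluate -> compare,
# with a provenance file sufficient to re-run bit-identically.

#' Run the full consistency-evaluation pipeline
#'
#' Stages: (1) obtain an expression matrix and gene-set collections, either
#' from `expression`/`gene_sets` paths or from the synthetic generator;
#' (2) filter every collection to the measured genes; (3) evaluate all seven
#' consistency metrics per set; (4) compare sources (per-source summary,
#' metric intercorrelations, size-stratified profiles, nested models,
#' size-variance decomposition). All outputs are TSV files in `out_dir`, plus
#' a `provenance.yaml` echoing the configuration, seed, package and R
#' versions and input checksums.
#'
#' @param config either a path to a YAML file or a list, with elements:
#'   `seed` (integer, default 1); `expression` (path to an expression TSV)
#'   and `gene_sets` (list of `{path, source}` entries), or `synthetic`
#'   (arguments for [synthetic_config()]) when no expression path is given;
#'   `n_pairs` (default 100), `max_genes` (default 50), `min_genes`
#'   (default 2), `min_sets` (default 20), `profile_metrics` (default the
#'   four headline metrics).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the records data frame, the comparison
#'   tables and the output file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  n_pairs <- as.integer(config$n_pairs %||% 100L)
  max_genes <- as.integer(config$max_genes %||% 50L)
  min_genes <- as.integer(config$min_genes %||% 2L)
  min_sets <- as.integer(config$min_sets %||% 20L)
  profile_metrics <- config$profile_metrics %||%
    c("s_mean_diff", "s_mean_exp", "corr_mean", "pc1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  checksums <- list()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  inputs <- stage("input", {
    if (!is.null(config$expression)) {
      for (p in c(config$expression,
                  vapply(config$gene_sets, `[[`, "", "path")))
        if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
      checksums[[config$expression]] <- unname(tools::md5sum(config$expression))
      em <- read_expression_matrix(config$expression)
      colls <- lapply(config$gene_sets, function(gs) {
        checksums[[gs$path]] <<- unname(tools::md5sum(gs$path))
        read_gmt(gs$path, source = gs$source, organism = em$organism)
      })
      list(expression = em, collections = colls)
    } else {
      sim_cfg <- do.call(synthetic_config,
                         c(config$synthetic %||% list(), list(seed = seed)))
      sim <- generate_synthetic(sim_cfg)
      paths$matrix <- file.path(out_dir, "matrix.tsv")
      write_expression_matrix(sim$expression, paths$matrix)
      for (coll in sim$collections) {
        p <- file.path(out_dir, sprintf("sets_%s.gmt", coll$source))
        write_gmt(coll, p)
        paths[[paste0("gmt_", coll$source)]] <- p
      }
      list(expression = sim$expression, collections = sim$collections)
    }
  })

  filtered <- stage("filter", {
    out <- lapply(inputs$collections, filter_to_matrix, x = inputs$expression,
                  min_genes = min_genes)
    message(sprintf("[filter] %d/%d sets retained",
                    sum(vapply(out, length, integer(1L))),
                    sum(vapply(inputs$collections, length, integer(1L)))))
    out
  })

  records <- stage("evaluate", {
    rec <- evaluate_collections(filtered, inputs$expression,
                                n_pairs = n_pairs, max_genes = max_genes,
                                seed = seed)
    n_undef <- sum(!stats::complete.cases(rec[, METRIC_COLUMNS]))
    message(sprintf("[evaluate] %d records, %d with undefined metric(s)",
                    nrow(rec), n_undef))
    paths$records <- file.path(out_dir, "records.tsv")
    write_records(rec, paths$records)
    rec
  })

  comparison <- stage("compare", {
    summary <- summarize_by_source(records)
    paths$source_summary <- file.path(out_dir, "source_summary.tsv")
    write_tsv(summary, paths$source_summary)

    cors <- tryCatch(metric_correlations(records), error = function(e) NULL)
    if (!is.null(cors)) {
      paths$metric_correlations <- file.path(out_dir, "metric_correlations.tsv")
      write_tsv(data.frame(metric = rownames(cors), cors,
                           check.names = FALSE), paths$metric_correlations)
    }

    profiles <- do.call(rbind, lapply(profile_metrics, function(m) {
      p <- size_stratified_profile(records, m, min_sets = min_sets)
      if (nrow(p)) cbind(metric = m, p) else NULL
    }))
    paths$size_profiles <- file.path(out_dir, "size_profiles.tsv")
    write_tsv(profiles %||% data.frame(), paths$size_profiles)

    fits <- if (length(unique(records$source)) >= 2L) {
      lapply(stats::setNames(profile_metrics, profile_metrics), function(m)
        fit_nested_models(records, m))
    } else NULL
    if (!is.null(fits)) {
      r2 <- do.call(rbind, lapply(names(fits), function(m)
        data.frame(metric = m, model_id = vapply(fits[[m]], `[[`, "", "model_id"),
                   r2 = vapply(fits[[m]], `[[`, 0, "r2"),
                   n = vapply(fits[[m]], `[[`, 0L, "n"))))
      paths$model_r2 <- file.path(out_dir, "model_r2.tsv")
      write_tsv(r2, paths$model_r2)
      eff <- do.call(rbind, lapply(names(fits), function(m)
        do.call(rbind, lapply(fits[[m]], function(f)
          cbind(metric = m, model_id = f$model_id, f$effects)))))
      paths$model_effects <- file.path(out_dir, "model_effects.tsv")
      write_tsv(eff, paths$model_effects)
    }

    sv <- size_variance_decomposition(records)
    paths$size_variance <- file.path(out_dir, "size_variance.tsv")
    write_tsv(data.frame(grouping = names(sv),
                         r2 = vapply(sv, `[[`, 0, "r2")), paths$size_variance)
    list(source_summary = summary, metric_correlations = cors,
         size_profiles = profiles, model_fits = fits,
         size_variance = sv)
  })

  prov <- list(
    package = "gsconsistency",
    package_version = as.character(utils::packageVersion("gsconsistency")),
    r_version = R.version.string,
    seed = seed,
    n_pairs = n_pairs, max_genes = max_genes, min_genes = min_genes,
    min_sets = min_sets,
    config = config,
    input_md5 = checksums)
  paths$provenance <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(prov, paths$provenance)

  invisible(c(list(records = records, paths = paths), comparison))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Plot size-stratified consistency profiles
#'
#' One line per source of the mean metric value across set-size bins — the
#' standard visual check that source differences persist across sizes.
#' Requires ggplot2.
#'
#' @param profile output of [size_stratified_profile()] (optionally with a
#'   `metric` column, faceted if present).
#' @return A ggplot object.
#' @export
plot_size_profiles <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = bin_max, y = mean, colour = source)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "set size (bin upper edge)", y = "mean metric value")
  if ("metric" %in% names(profile))
    p <- p + ggplot2::facet_wrap(~metric, scales = "free_y")
  p
}
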