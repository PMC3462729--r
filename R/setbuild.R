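# Gene-set construction and filtering.
#
# Ontology-style sources define a hierarchy of terms (three separate DAGs in
# the Gene Ontology's case); a term's gene set is its direct annotations plus
# the annotations of all of its descendant terms.

#' Build gene sets from term annotations and a term hierarchy
#'
#' Each term's set is the union of its directly annotated genes and the genes
#' of every descendant term (transitive closure over the child-to-parent
#' hierarchy). Terms whose propagated set is empty are omitted. Parent sets
#' are therefore always supersets of their children's sets. No deduplication
#' is performed when a parent and child end up with identical sets.
#'
#' @param annotations either a named list (term id -> character vector of
#'   directly annotated gene ids) or a two-column data frame
#'   `(term_id, gene_id)`.
#' @param hierarchy two-column data frame of `(child, parent)` term-id edges.
#'   Must be acyclic with no self-edges; terms carrying no direct annotation
#'   may appear. Pass a zero-row data frame for a flat vocabulary.
#' @param source source label for the resulting collection.
#' @param organism organism label.
#' @return A [gene_set_collection()] with one set per term that has at least
#'   one propagated gene, in sorted term order.
#' @examples
#' ann <- list(a = character(), b = "g2", c = "g1")
#' h <- data.frame(child = c("c", "b"), parent = c("b", "a"))
#' propagate_hierarchy(ann, h, source = "GO_BP")
#' @export
propagate_hierarchy <- function(annotations, hierarchy, source,
                                organism = "unspecified") {
  ann <- normalize_annotations(annotations)
  hierarchy <- as.data.frame(hierarchy)
  if (ncol(hierarchy) < 2L && nrow(hierarchy))
    stop("`hierarchy` must have two columns: child, parent", call. = FALSE)
  if (nrow(hierarchy)) {
    child <- as.character(hierarchy[[1L]])
    parent <- as.character(hierarchy[[2L]])
    if (any(child == parent))
      stop("hierarchy contains self-edge(s): ",
           paste(unique(child[child == parent]), collapse = ", "), call. = FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = child, to = parent, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = sort(unique(c(child, parent, names(ann)))))
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership ==
                                      which(comp$csize > 1L)[1L]]
      stop("hierarchy contains a cycle through terms: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
  } else {
    g <- NULL
  }
  terms <- sort(unique(c(names(ann),
                         if (!is.null(g)) igraph::V(g)$name else character())))
  direct <- function(t) ann[[t]] %||% character()
  sets <- lapply(terms, function(t) {
    below <- if (!is.null(g) && t %in% igraph::V(g)$name) {
      # descendants = vertices that can reach t along child->parent edges
      igraph::subcomponent(g, t, mode = "in")$name
    } else t
    sort(unique(unlist(lapply(below, direct), use.names = FALSE)))
  })
  names(sets) <- terms
  sets <- sets[lengths(sets) > 0L]
  gene_set_collection(sets, source = source, organism = organism)
}

normalize_annotations <- function(annotations) {
  if (is.data.frame(annotations)) {
    if (ncol(annotations) < 2L)
      stop("annotation data frame needs columns term_id, gene_id", call. = FALSE)
    annotations <- split(as.character(annotations[[2L]]),
                         as.character(annotations[[1L]]))
  }
  if (!is.list(annotations) || (length(annotations) && is.null(names(annotations))))
    stop("`annotations` must be a named list or a (term_id, gene_id) data frame",
         call. = FALSE)
  lapply(annotations, function(g) unique(as.character(g)))
}

#' Restrict a collection to genes measured by an expression matrix
#'
#' Each set is intersected with the matrix's gene identifiers; sets left with
#' fewer than `min_genes` measured genes are dropped. This is the standard
#' pre-analysis filter: a consistency metric is only defined for sets with at
#' least two genes that have expression data.
#'
#' @param collection a `gene_set_collection`.
#' @param x an `expr_matrix`.
#' @param min_genes minimum surviving set size (>= 2).
#' @return A new filtered `gene_set_collection`; the input is not modified.
#' @export
filter_to_matrix <- function(collection, x, min_genes = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(x, "expr_matrix"))
  min_genes <- assert_scalar_count(min_genes, "min_genes", min = 2L)
  measured <- genes(x)
  sets <- lapply(collection$sets, function(g) g[g %in% measured])
  sets <- sets[lengths(sets) >= min_genes]
  gene_set_collection(sets, source = collection$source,
                      organism = collection$organism)
}

#' Restrict a collection to a gene universe
#'
#' In the default membership mode, keeps only the sets having at least one
#' gene in `universe`, without altering any surviving set's contents — the
#' restriction narrows which sets are analyzed, not what they contain. With
#' `trim = TRUE` the surviving sets are additionally intersected with the
#' universe.
#'
#' @param collection a `gene_set_collection`.
#' @param universe non-empty character vector of gene identifiers.
#' @param trim if `TRUE`, intersect surviving sets with the universe.
#' @return A new `gene_set_collection`.
#' @export
restrict_to_universe <- function(collection, universe, trim = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be non-empty", call. = FALSE)
  hits <- vapply(collection$sets, function(g) any(g %in% universe), logical(1L))
  sets <- collection$sets[hits]
  if (trim) sets <- lapply(sets, function(g) g[g %in% universe])
  gene_set_collection(sets, source = collection$source,
                      organism = collection$organism)
}

#' Gene overlap and genome coverage of a collection
#'
#' Reports the percentage of genes (among genes appearing in at least one set)
#' that appear in two or more sets, and the percentage of the organism's
#' measured genes covered by at least one set. High multi-set overlap means a
#' source's apparent consistency could be driven by shared genes rather than
#' independent sets.
#'
#' @param collection a non-empty `gene_set_collection`.
#' @param organism_genes character vector: the organism's measured gene
#'   universe (typically `genes(x)` of the expression matrix).
#' @return A list of class `overlap_report` with fields `source`,
#'   `pct_multi_set` and `pct_genome_covered`, both in `[0, 100]`.
#' @export
overlap_report <- function(collection, organism_genes) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection)) stop("collection is empty", call. = FALSE)
  organism_genes <- unique(as.character(organism_genes))
  if (!length(organism_genes))
    stop("`organism_genes` must be non-empty", call. = FALSE)
  counts <- table(unlist(collection$sets, use.names = FALSE))
  if (!length(counts)) stop("no gene appears in any set", call. = FALSE)
  in_any <- names(counts)
  structure(list(
    source = collection$source,
    pct_multi_set = 100 * sum(counts >= 2L) / length(in_any),
    pct_genome_covered = 100 * sum(in_any %in% organism_genes) /
      length(organism_genes)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %s: %.1f%% of covered genes in >1 set; %.1f%% of genome covered\n",
              x$source, x$pct_multi_set, x$pct_genome_covered))
  invisible(x)
}
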