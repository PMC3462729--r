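#' Construct a gene-set collection
#'
#' A named list of gene sets sharing a source label (e.g. `GO_BP`, `KEGG`,
#' `OPERON`, `SEED_PATH`, or any user-defined label) and an organism.
#'
#' @param sets named list of character vectors; names are set identifiers,
#'   elements are the member gene identifiers. Genes must be unique within a
#'   set; duplicates raise an error (use [read_gmt()] for tolerant parsing).
#' @param source non-empty source label for every set in the collection.
#' @param organism organism label.
#' @return Object of class `gene_set_collection`.
#' @examples
#' gsc <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = c("g2", "g3")),
#'                            source = "OPERON")
#' length(gsc)
#' @export
gene_set_collection <- function(sets, source, organism = "unspecified") {
  if (!is.list(sets))
    stop("`sets` must be a list of character vectors", call. = FALSE)
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets)))))
    stop("every set must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set identifier(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  if (!is.character(source) || length(source) != 1L || !nzchar(source))
    stop("`source` must be a single non-empty label", call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (anyDuplicated(g))
      stop("duplicated gene within a set", call. = FALSE)
    g
  })
  structure(list(organism = organism, source = source, sets = sets),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<gene_set_collection> source=%s organism=%s: %d sets",
              x$source, x$organism, length(sizes)))
  if (length(sizes))
    cat(sprintf(" (sizes %d-%d, median %g)", min(sizes), max(sizes),
                stats::median(sizes)))
  cat("\n")
  invisible(x)
}

#' Set sizes of a collection
#' @param collection a `gene_set_collection`.
#' @return Named integer vector of set sizes.
#' @export
set_sizes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lengths(collection$sets)
}
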