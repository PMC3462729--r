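#' Construct an expression matrix
#'
#' Container for a genes-by-arrays table of normalized, log2-scale expression
#' values (the convention of RMA-summarized array data; values are never
#' re-logged by this package). Rows are gene identifiers, columns are array
#' identifiers.
#'
#' @param values numeric matrix, genes in rows, arrays in columns, with unique
#'   non-empty `rownames` and `colnames`. All values must be finite. At least
#'   2 genes and 2 arrays.
#' @param organism organism label attached to the matrix.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the numeric matrix) and `organism`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
#' em <- expression_matrix(m, organism = "E_coli")
#' dim(em)
#' @export
expression_matrix <- function(values, organism = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and array colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate array identifier(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (nrow(values) < 2L)
    stop("expression matrix needs at least 2 genes", call. = FALSE)
  if (ncol(values) < 2L)
    stop("expression matrix needs at least 2 arrays", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (!is.character(organism) || length(organism) != 1L || !nzchar(organism))
    stop("`organism` must be a single non-empty string", call. = FALSE)
  structure(list(values = values, organism = organism), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and array identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of identifiers, in matrix order.
#' @export
genes <- function(x) UseMethod("genes")

#' @rdname genes
#' @export
genes.expr_matrix <- function(x) rownames(x$values)

#' @rdname genes
#' @export
arrays <- function(x) UseMethod("arrays")

#' @rdname genes
#' @export
arrays.expr_matrix <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d genes x %d arrays (log2 scale)\n",
              x$organism, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Extract the submatrix for a gene set, with validation shared by the metric
# functions. Returns genes-in-rows numeric matrix.
set_submatrix <- function(gene_ids, x, min_genes = 2L) {
  stopifnot(inherits(x, "expr_matrix"))
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("gene set contains duplicated identifiers", call. = FALSE)
  missing <- setdiff(gene_ids, genes(x))
  if (length(missing))
    stop("gene(s) absent from the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         "; filter the collection to the matrix first", call. = FALSE)
  if (length(gene_ids) < min_genes)
    stop(sprintf("gene set must have at least %d measured genes", min_genes),
         call. = FALSE)
  x$values[gene_ids, , drop = FALSE]
}
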