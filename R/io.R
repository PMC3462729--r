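# File formats. One fixed TSV dialect throughout: UTF-8, tab-separated,
# '#'-prefixed comment lines ignored, "NA" as the missing-value token.

#' Read an expression matrix from TSV
#'
#' Expects a header row of array identifiers, a first column of gene
#' identifiers, and numeric cells (log2-scale expression). An optional
#' `# organism: <label>` comment line (as written by
#' [write_expression_matrix()]) sets the organism.
#'
#' @param path path to a TSV file.
#' @param organism organism label; overrides any `# organism:` comment.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, organism = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L)
    stop("expression TSV needs a header plus at least one gene row", call. = FALSE)
  if (is.null(organism)) {
    org_line <- grep("^#\\s*organism:", comments, value = TRUE)
    organism <- if (length(org_line))
      sub("^#\\s*organism:\\s*", "", org_line[1L]) else "unspecified"
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1L]]
  array_ids <- header[-1L]
  if (length(array_ids) < 2L)
    stop("expression matrix needs at least 2 array columns", call. = FALSE)
  n_col <- length(header)
  rows <- fields[-1L]
  bad_len <- which(lengths(rows) != n_col)
  if (length(bad_len))
    stop(sprintf("row %d has %d fields, expected %d", bad_len[1L],
                 lengths(rows)[bad_len[1L]], n_col), call. = FALSE)
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  cells <- t(vapply(rows, function(r) r[-1L], character(length(array_ids))))
  if (length(array_ids) == 1L) cells <- matrix(cells, ncol = 1L)
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = length(gene_ids)))
  bad <- which(is.na(values) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', array '%s': '%s'",
                 gene_ids[bad[1L, 1L]], array_ids[bad[1L, 2L]],
                 cells[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; all cells must be finite",
         call. = FALSE)
  dimnames(values) <- list(gene_ids, array_ids)
  em <- expression_matrix(values, organism = organism)
  stopifnot(nrow(em$values) == length(rows))  # no silently dropped rows
  em
}

#' Write an expression matrix to TSV
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# organism: %s", x$organism), con)
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' ignored. Genes duplicated within a line are deduplicated with a warning.
#'
#' @param path path to a GMT file.
#' @param source source label to attach to the collection.
#' @param organism organism label.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source, organism = "unspecified") {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene",
                 line_no[short[1L]], lengths(fields)[short[1L]]), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (anyDuplicated(g)) {
      warning(sprintf("set '%s': duplicated gene(s) removed", f[1L]),
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  names(sets) <- ids
  out <- gene_set_collection(sets, source = source, organism = organism)
  stopifnot(length(out) == length(body))  # every input line became a set
  out
}

#' Write a gene-set collection to a GMT file
#'
#' The description field is written as `"."`.
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id)
    paste(c(id, ".", collection$sets[[id]]), collapse = "\t"), character(1L))
  writeLines(lines, con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}

#' Write consistency records to TSV
#'
#' One row per gene set: organism, source, set_id, n_genes, then the seven
#' metric columns. Undefined metrics are written as `NA`.
#'
#' @param records data frame of consistency records, as returned by
#'   [evaluate_collections()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  if (!nrow(records)) stop("no records to write", call. = FALSE)
  utils::write.table(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read consistency records from TSV
#'
#' @param path path written by [write_records()].
#' @return Data frame of consistency records.
#' @export
read_records <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          na.strings = "NA", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  validate_records(df)
}

# Shared schema check for the records table.
validate_records <- function(records) {
  need <- c("organism", "source", "set_id", "n_genes", METRIC_COLUMNS)
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  records$n_genes <- as.integer(records$n_genes)
  for (m in METRIC_COLUMNS) records[[m]] <- as.numeric(records[[m]])
  records[need]
}
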