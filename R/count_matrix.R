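#' Construct a validated count matrix
#'
#' The basic container used by every modality: a genes x columns matrix of
#' non-negative integer counts with unique gene and column identifiers, plus
#' optional per-column metadata (condition, donor, cell type).
#'
#' @param values Numeric matrix of non-negative integral counts.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param column_ids Character vector of unique column (sample or cell)
#'   identifiers (defaults to `colnames(values)`).
#' @param column_meta Optional `data.frame` with one row per column; typical
#'   columns are `condition`, `donor`, `cell_type`.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (integer matrix with dimnames) and `column_meta`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         column_ids = colnames(values), column_meta = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  # R drops dimnames of zero-extent subsets to NULL
  if (is.null(gene_ids) && nrow(values) == 0) gene_ids <- character()
  if (is.null(column_ids) && ncol(values) == 0) column_ids <- character()
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (is.null(column_ids)) stop("column identifiers are required")
  gene_ids <- as.character(gene_ids)
  column_ids <- as.character(column_ids)
  if (length(gene_ids) != nrow(values) || length(column_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_c <- unique(column_ids[duplicated(column_ids)])
  if (length(dup_c))
    stop("duplicate column identifiers: ", paste(dup_c, collapse = ", "))
  if (length(values) && (anyNA(values) || any(values < 0)))
    stop("negative or missing counts at ",
         paste(utils::head(which(is.na(values) | values < 0), 3), collapse = ", "))
  if (length(values) && any(values != round(values)))
    stop("fractional counts at ",
         paste(utils::head(which(values != round(values)), 3), collapse = ", "))
  storage.mode(values) <- "double"  # counts can exceed .Machine$integer.max in total
  dimnames(values) <- list(gene_ids, column_ids)
  if (!is.null(column_meta)) {
    column_meta <- as.data.frame(column_meta)
    if (nrow(column_meta) != ncol(values))
      stop("column_meta must have one row per column")
  }
  structure(list(values = values, column_meta = column_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d columns\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$column_meta))
    cat("column_meta:", paste(names(x$column_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Gene identifiers of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of gene ids.
#' @export
genes <- function(m) rownames(m$values)

#' Column identifiers of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of column ids.
#' @export
columns <- function(m) colnames(m$values)

#' Subset a count matrix by genes and/or columns
#'
#' @param m A `count_matrix`.
#' @param genes,cols Character or integer indices; `NULL` keeps all.
#' @return A `count_matrix` with metadata subset accordingly.
#' @export
subset_counts <- function(m, genes = NULL, cols = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    meta <- if (is.null(m$column_meta)) NULL else {
      idx <- if (is.character(cols)) match(cols, colnames(m$values)) else cols
      m$column_meta[idx, , drop = FALSE]
    }
  } else meta <- m$column_meta
  count_matrix(v, column_meta = meta)
}

lib_sizes <- function(m) colSums(m$values)
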