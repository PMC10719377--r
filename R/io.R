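# Readers and writers for the plain-text formats the pipeline touches.
# All readers validate rather than coerce; all writers emit files their own
# reader accepts.

mtx_sidecars <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = paste0(stem, "_genes.tsv"), samples = paste0(stem, "_samples.tsv"))
}

#' Read a count matrix from MatrixMarket or dense TSV
#'
#' MTX files use the MatrixMarket coordinate format with 1-based indices and
#' sidecar identifier files `<stem>_genes.tsv` / `<stem>_samples.tsv` (one id
#' per line). Dense TSV files carry gene ids in the first column and column
#' ids in the header.
#'
#' @param path Path to a `.mtx` or `.tsv` file.
#' @param format One of `"auto"` (by extension), `"mtx"`, `"tsv"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    side <- mtx_sidecars(path)
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(side$genes)
    col_ids <- readLines(side$samples)
    if (length(gene_ids) != nrow(m))
      stop("gene sidecar has ", length(gene_ids), " ids for ", nrow(m), " rows")
    if (length(col_ids) != ncol(m))
      stop("sample sidecar has ", length(col_ids), " ids for ", ncol(m), " columns")
    neg <- which(m < 0)
    if (length(neg))
      stop("negative count at matrix entry ", neg[1], " (gene ",
           gene_ids[(neg[1] - 1) %% nrow(m) + 1], ")")
    count_matrix(m, gene_ids, col_ids)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    gene_ids <- tab[[1]]
    dup <- unique(gene_ids[duplicated(gene_ids)])
    if (length(dup))
      stop("duplicate gene identifiers in ", path, ": ", paste(dup, collapse = ", "))
    v <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(v) <- "double")
    if (anyNA(v)) stop("non-numeric count in ", path)
    count_matrix(v, gene_ids, colnames(tab)[-1])
  }
}

#' Write a count matrix to MatrixMarket or dense TSV
#'
#' @param m A [count_matrix()].
#' @param path Output path (`.mtx` writes identifier sidecars alongside).
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(m, path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    side <- mtx_sidecars(path)
    Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix"), path)
    writeLines(genes(m), side$genes)
    writeLines(columns(m), side$samples)
    invisible(c(path, side$genes, side$samples))
  } else {
    tab <- data.frame(gene = genes(m), m$values, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  }
}

#' Read a spatial transcript table
#'
#' Expects a CSV whose header is exactly `x,y,gene`; coordinates are 0-based
#' pixels (x rightward, y downward).
#'
#' @param path CSV path.
#' @param pixel_size_um Physical pixel size, stored as an attribute; all
#'   computation is in pixels.
#' @return A `data.frame` with columns `x`, `y`, `gene`.
#' @export
read_spatial <- function(path, pixel_size_um = 0.138) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  if (!identical(header, c("x", "y", "gene")))
    stop("spatial CSV header must be exactly x,y,gene; got: ",
         paste(header, collapse = ","))
  tab <- utils::read.csv(path, colClasses = c("numeric", "numeric", "character"))
  validate_spatial(tab)
  attr(tab, "pixel_size_um") <- pixel_size_um
  tab
}

validate_spatial <- function(tab) {
  stopifnot(all(c("x", "y", "gene") %in% names(tab)))
  bad <- !is.finite(tab$x) | !is.finite(tab$y) | tab$x < 0 | tab$y < 0
  if (any(bad)) stop("non-finite or negative coordinate at row ", which(bad)[1])
  if (any(!nzchar(tab$gene))) stop("empty gene name at row ", which(!nzchar(tab$gene))[1])
  invisible(tab)
}

#' Write a spatial transcript table
#' @param tab `data.frame` with columns x, y, gene.
#' @param path Output CSV path.
#' @export
write_spatial <- function(tab, path) {
  validate_spatial(tab)
  utils::write.csv(tab[, c("x", "y", "gene")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an integer segmentation label mask from TIFF
#'
#' The mask is a single-plane unsigned-integer image; 0 is background and
#' label k > 0 marks the pixels of cell k.
#'
#' @param path TIFF path.
#' @return Integer matrix (rows = y, columns = x).
#' @export
read_mask <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(planes) != 1) stop("mask TIFF must be single-plane; got ", length(planes))
  grid <- planes[[1]]
  if (length(dim(grid)) == 3) {
    if (dim(grid)[3] != 1) stop("mask TIFF must have a single channel")
    grid <- grid[, , 1]
  }
  storage.mode(grid) <- "integer"
  if (any(grid < 0)) stop("mask contains negative labels")
  grid
}

#' Write an integer label mask to a 16-bit TIFF
#' @param grid Integer matrix of labels (max 65535).
#' @param path Output path.
#' @export
write_mask <- function(grid, path) {
  if (any(grid < 0) || any(grid != round(grid))) stop("labels must be non-negative integers")
  if (max(grid) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(grid / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a GMT-like gene set collection
#'
#' Tab-separated lines: set name, description, then member genes. Sets with
#' zero members are retained with a warning.
#'
#' @param path TSV path.
#' @return Named list of character vectors (the gene sets).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 2) stop("GMT line needs at least a name and description: ", f[1])
    members <- unique(f[-(1:2)])
    members[nzchar(members)]
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    warning("gene sets with zero members retained: ", paste(empty, collapse = ", "))
  sets
}

#' Write a GMT-like gene set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a consensus signature as JSON
#'
#' The JSON carries a list of entries `{gene, direction, support, sets}` plus
#' `alpha_used` and free-form provenance.
#'
#' @param path JSON path.
#' @return A `consensus_signature` object.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- do.call(rbind, lapply(obj$entries, function(e)
    data.frame(gene = e$gene, direction = as.integer(e$direction),
               stringsAsFactors = FALSE)))
  if (is.null(entries))
    entries <- data.frame(gene = character(), direction = integer())
  entries$support <- lapply(obj$entries, function(e) unlist(e$support))
  entries$sets <- lapply(obj$entries, function(e) unlist(e$sets))
  new_signature(entries, alpha_used = obj$alpha_used,
                conflicts = unlist(obj$conflicts) %||% character(),
                provenance = obj$provenance %||% list())
}

#' @rdname read_signature
#' @param sig A `consensus_signature`.
#' @export
write_signature <- function(sig, path) {
  entries <- lapply(seq_len(nrow(sig$entries)), function(i)
    list(gene = sig$entries$gene[i],
         direction = sig$entries$direction[i],
         support = as.list(sig$entries$support[[i]]),
         sets = as.list(sig$entries$sets[[i]])))
  obj <- list(entries = entries, alpha_used = sig$alpha_used,
              conflicts = as.list(sig$conflicts),
              provenance = sig$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a YAML simulation / pipeline configuration
#' @param path YAML path.
#' @return Named list of parameters.
#' @export
read_config <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
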