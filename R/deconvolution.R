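# Estimate cell-type composition of bulk profiles from a multi-donor
# single-cell reference: cross-donor-variance-weighted non-negative least
# squares on relative expression profiles.

#' Build a deconvolution reference from single-nucleus counts
#'
#' Per (donor, cell type), counts are pooled and scaled to relative
#' expression (sum 1 over genes). The reference holds the across-donor mean
#' profile per type, the cross-donor variance per (gene, type), and the mean
#' per-cell library size per type.
#'
#' @param sn A [count_matrix()] of single-nucleus counts.
#' @param meta Cell metadata with columns `donor` and `cell_type` (defaults
#'   to `sn$column_meta`).
#' @return An object of class `deconv_reference`.
#' @export
build_reference <- function(sn, meta = sn$column_meta) {
  stopifnot(!is.null(meta), all(c("donor", "cell_type") %in% names(meta)),
            nrow(meta) == ncol(sn$values))
  donors <- sort(unique(meta$donor))
  if (length(donors) < 2) stop("need at least 2 donors")
  types <- sort(unique(meta$cell_type))
  G <- nrow(sn$values)
  pooled <- matrix(NA_real_, G, length(types), dimnames = list(genes(sn), types))
  v_cross <- pooled
  lib_size <- stats::setNames(numeric(length(types)), types)
  for (t in types) {
    sel_t <- meta$cell_type == t
    prof <- sapply(donors, function(d) {
      cols <- sel_t & meta$donor == d
      if (!any(cols)) return(rep(NA_real_, G))
      tot <- rowSums(sn$values[, cols, drop = FALSE])
      tot / sum(tot)
    })
    n_d <- sum(colSums(!is.na(prof)) > 0)
    if (n_d < 2)
      warning("cell type '", t, "' present in a single donor: variance 0")
    pooled[, t] <- rowMeans(prof, na.rm = TRUE)
    v_cross[, t] <- if (n_d >= 2) apply(prof, 1, stats::var, na.rm = TRUE) else 0
    lib_size[t] <- mean(colSums(sn$values[, sel_t, drop = FALSE]))
  }
  v_cross[is.na(v_cross)] <- 0
  structure(list(genes = genes(sn), types = types, pooled = pooled,
                 var_cross = v_cross, lib_size = lib_size),
            class = "deconv_reference")
}

#' @export
print.deconv_reference <- function(x, ...) {
  cat(sprintf("deconv_reference: %d genes, types: %s\n", length(x$genes),
              paste(x$types, collapse = ", ")))
  invisible(x)
}

#' Deconvolve one bulk profile into cell-type proportions
#'
#' Solves the non-negative least squares problem
#' `min || W^(1/2) (b - M p') ||` where `b` is the bulk relative profile,
#' the columns of `M` are the pooled type profiles scaled by mean library
#' size, and `W = diag(1 / (cross-donor variance + eps))`; `p'` is then
#' normalized to proportions. Scale-invariant in the bulk column.
#'
#' @param bulk_column Named count vector, or a 1-column [count_matrix()].
#' @param ref A [build_reference()] object.
#' @param eps Variance floor for the weights.
#' @param exclude_genes Genes to drop (e.g. those removed by
#'   [high_abundance_filter()]).
#' @return List with `proportions` (named, non-negative, sum 1) and
#'   `residual_norm`.
#' @export
deconvolve <- function(bulk_column, ref, eps = 1e-8, exclude_genes = NULL) {
  if (inherits(bulk_column, "count_matrix")) {
    stopifnot(ncol(bulk_column$values) == 1)
    bulk_column <- stats::setNames(bulk_column$values[, 1], genes(bulk_column))
  }
  if (is.null(names(bulk_column))) stop("bulk column must be named by gene")
  if (sum(bulk_column) == 0) stop("all-zero bulk profile")
  shared <- setdiff(intersect(names(bulk_column), ref$genes), exclude_genes)
  if (length(shared) < 10) stop("fewer than 10 shared genes")
  b <- bulk_column[shared] / sum(bulk_column[shared])
  M <- sweep(ref$pooled[shared, , drop = FALSE], 2, ref$lib_size, "*")
  w <- 1 / (rowMeans(ref$var_cross[shared, , drop = FALSE]) + eps)
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(M * sw, b * sw)
  p_raw <- fit$x
  if (sum(p_raw) == 0) stop("NNLS returned the zero solution")
  list(proportions = stats::setNames(p_raw / sum(p_raw), ref$types),
       residual_norm = sqrt(max(fit$resid.norm, 0)))
}

#' Class-averaged cell-type proportions
#'
#' Arithmetic mean of per-sample proportions within each class, without
#' renormalization (the radar-chart reporting convention in which class
#' sums need not equal 100%).
#'
#' @param props Samples x types matrix (or data.frame) of proportions.
#' @param classes Class label per sample.
#' @return Classes x types matrix of mean proportions.
#' @export
class_average_proportions <- function(props, classes) {
  props <- as.matrix(props)
  stopifnot(nrow(props) == length(classes))
  cls <- sort(unique(classes))
  out <- t(vapply(cls, function(k)
    colMeans(props[classes == k, , drop = FALSE]), numeric(ncol(props))))
  rownames(out) <- cls
  out
}
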