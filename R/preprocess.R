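# Normalization and filtering shared by all modalities: low-expression
# filtering, TMM factors, log2-CPM, and the dominant-gene (GFAP-style)
# high-abundance filter.

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its CPM reaches `min_cpm` in at least
#' `ceiling(min_prop * smallest group size)` columns. Gene order is
#' preserved; an empty result is allowed (with a warning).
#'
#' @param m A [count_matrix()].
#' @param groups Character/factor vector mapping columns to groups (>= 2 groups).
#' @param min_cpm Minimum counts-per-million to call a gene expressed in a column.
#' @param min_prop Proportion of the smallest group that must reach `min_cpm`.
#' @return A filtered [count_matrix()].
#' @export
filter_low_expressed <- function(m, groups, min_cpm = 1, min_prop = 0.7) {
  stopifnot(length(groups) == ncol(m$values))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  lib <- lib_sizes(m)
  if (any(lib == 0)) stop("column with zero total count")
  cpm <- sweep(m$values, 2, lib / 1e6, "/")
  n_req <- ceiling(min_prop * min(table(groups)))
  keep <- rowSums(cpm >= min_cpm) >= n_req
  if (!any(keep)) warning("no genes survive the low-expression filter")
  subset_counts(m, genes = which(keep))
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-correcting per-column scale factors (Robinson--Oshlack TMM):
#' gene-wise log ratios against a reference column are doubly trimmed by M
#' (30% each tail) and A (5% each tail), and the factor is 2 to the
#' inverse-variance-weighted mean of the surviving M values. Factors are
#' rescaled to geometric mean 1. The reference defaults to the column whose
#' upper-quartile CPM is closest to the mean upper-quartile.
#'
#' @param m A [count_matrix()].
#' @param ref_column Optional reference column index.
#' @param logratio_trim,sum_trim,a_cutoff Trimming parameters.
#' @return Numeric vector of per-column factors (geometric mean 1).
#' @export
tmm_factors <- function(m, ref_column = NULL, logratio_trim = 0.30,
                        sum_trim = 0.05, a_cutoff = -1e10) {
  v <- m$values
  if (any(colSums(v) <= 0)) stop("every column must have positive total count")
  f <- edgeR::calcNormFactors(v, method = "TMM", refColumn = ref_column,
                              logratioTrim = logratio_trim, sumTrim = sum_trim,
                              doWeighting = TRUE, Acutoff = a_cutoff)
  stats::setNames(as.numeric(f), columns(m))
}

#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / ((library_size * factor + 2 * prior) / 1e6))`.
#'
#' @param m A [count_matrix()].
#' @param factors Per-column normalization factors (default all 1).
#' @param prior_count Positive prior added to counts (default 0.5).
#' @return Numeric matrix of log2-CPM values with the dimnames of `m`.
#' @export
log_cpm <- function(m, factors = NULL, prior_count = 0.5) {
  if (prior_count <= 0) stop("prior_count must be positive")
  if (is.null(factors)) factors <- rep(1, ncol(m$values))
  if (any(factors <= 0)) stop("normalization factors must be positive")
  eff <- lib_sizes(m) * factors + 2 * prior_count
  log2(sweep(m$values + prior_count, 2, eff / 1e6, "/"))
}

#' Remove genes dominating the transcript pool
#'
#' Removes every gene whose share of all counted transcripts exceeds
#' `max_fraction` (default 0.40, below the 49--89% range observed for GFAP
#' in the motivating tissue data). Works on a spatial transcript table
#' (one row per transcript) or a [count_matrix()].
#'
#' @param x A spatial transcript `data.frame` (column `gene`) or a
#'   [count_matrix()].
#' @param max_fraction Maximum tolerated share of total transcripts.
#' @return List with `data` (filtered input) and `removed`
#'   (`data.frame(gene, fraction)`).
#' @export
high_abundance_filter <- function(x, max_fraction = 0.40) {
  if (inherits(x, "count_matrix")) {
    tot <- rowSums(x$values)
    frac <- if (sum(tot) > 0) tot / sum(tot) else tot
    drop <- which(frac > max_fraction)
    report <- data.frame(gene = genes(x)[drop], fraction = unname(frac[drop]))
    list(data = subset_counts(x, genes = setdiff(seq_along(tot), drop)),
         removed = report)
  } else {
    counts <- table(x$gene)
    frac <- as.numeric(counts) / sum(counts)
    drop <- names(counts)[frac > max_fraction]
    report <- data.frame(gene = drop,
                         fraction = frac[match(drop, names(counts))])
    out <- x[!(x$gene %in% drop), , drop = FALSE]
    rownames(out) <- NULL
    list(data = out, removed = report)
  }
}
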