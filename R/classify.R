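# The consensus / non-consensus classifier and the class-level summaries:
# per-cell directional concordance against the consensus signature, class
# distribution percentages, presence-pattern categories, and pairwise
# Wilcoxon differential expression between classes.

#' Classify disease microglia by directional concordance with the signature
#'
#' For each cell and each evaluable signature gene g, the deviation is the
#' cell's log-normalized expression minus the healthy reference; the gene
#' agrees when the deviation's sign matches the signature direction and its
#' magnitude exceeds `epsilon`. The concordance C is the fraction of
#' evaluable genes that agree, and a cell is consensus iff `C >= tau`.
#' Cells with no evaluable gene are non-consensus (warned).
#'
#' @param cell_values Gene x cell matrix of log-normalized expression for
#'   the disease microglia to classify.
#' @param sig A `consensus_signature` (non-empty).
#' @param healthy_ref Named vector: per-gene mean log-normalized expression
#'   of control-donor microglia.
#' @param tau Concordance threshold (default 1: strict all-gene agreement).
#' @param epsilon Minimum absolute deviation to count as agreement.
#' @return `data.frame(cell, n_evaluable, concordance, class)`.
#' @export
classify_consensus <- function(cell_values, sig, healthy_ref, tau = 1.0,
                               epsilon = 0.0) {
  if (!nrow(sig$entries)) stop("classification undefined for an empty signature")
  eval_genes <- intersect(sig$entries$gene,
                          intersect(rownames(cell_values), names(healthy_ref)))
  cells <- colnames(cell_values) %||% as.character(seq_len(ncol(cell_values)))
  if (!length(eval_genes)) {
    warning("no evaluable signature genes: all cells non-consensus")
    return(data.frame(cell = cells, n_evaluable = 0L, concordance = 0,
                      class = "non-consensus"))
  }
  dirs <- sig$entries$direction[match(eval_genes, sig$entries$gene)]
  dev <- cell_values[eval_genes, , drop = FALSE] - healthy_ref[eval_genes]
  agree <- (sign(dev) == dirs) & (abs(dev) > epsilon)
  conc <- colMeans(agree)
  data.frame(cell = cells, n_evaluable = length(eval_genes),
             concordance = conc,
             class = ifelse(conc >= tau, "consensus", "non-consensus"),
             row.names = NULL)
}

#' Classify an annotated spatial cell table
#'
#' Control microglia are labeled `healthy` and serve as the reference (they
#' are never classified); disease microglia are classified by
#' [classify_consensus()]; non-microglia get `NA`.
#'
#' @param counts Gene x cell count matrix (columns align with `meta` rows).
#' @param meta `data.frame` with per-cell `condition`
#'   (`control`/`disease`) and `cell_type`.
#' @param sig A `consensus_signature`.
#' @param tau,epsilon Passed to [classify_consensus()].
#' @param ref_stat `"mean"` (default) or `"median"` healthy reference.
#' @return `meta` with added `class` and `concordance` columns.
#' @export
classify_spatial_cells <- function(counts, meta, sig, tau = 1.0, epsilon = 0.0,
                                   ref_stat = c("mean", "median")) {
  ref_stat <- match.arg(ref_stat)
  stopifnot(nrow(meta) == ncol(counts),
            all(c("condition", "cell_type") %in% names(meta)))
  ln <- lognorm_cells(counts)
  healthy <- meta$condition == "control" & meta$cell_type == "microglia"
  pd_mg <- meta$condition == "disease" & meta$cell_type == "microglia"
  if (!any(healthy)) stop("no control microglia to build the healthy reference")
  ref_fun <- if (ref_stat == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  healthy_ref <- ref_fun(ln[, healthy, drop = FALSE])
  meta$class <- ifelse(meta$cell_type == "microglia" & meta$condition == "control",
                       "healthy", NA_character_)
  meta$concordance <- NA_real_
  if (any(pd_mg)) {
    res <- classify_consensus(ln[, pd_mg, drop = FALSE], sig, healthy_ref,
                              tau = tau, epsilon = epsilon)
    meta$class[pd_mg] <- res$class
    meta$concordance[pd_mg] <- res$concordance
  }
  meta
}

#' Consensus percentage from class counts
#'
#' `100 * n_consensus / n_total`: the share of disease microglia classified
#' as consensus.
#'
#' @param n_consensus,n_total Non-negative counts, `n_total > 0`.
#' @return Percentage on the 0--100 scale.
#' @export
consensus_percentage <- function(n_consensus, n_total) {
  stopifnot(n_total > 0, n_consensus >= 0, n_consensus <= n_total)
  100 * n_consensus / n_total
}

#' Distribution percentages of class-average expression
#'
#' Per gene, each class's share (in percent) of the sum of the class
#' averages; rows whose class averages are all zero are undefined and
#' returned as `NA` (flagged).
#'
#' @param class_means Gene x class matrix of non-negative mean expression.
#' @return Matrix of percentages (rows sum to 100 where defined).
#' @export
distribution_percentage <- function(class_means) {
  class_means <- as.matrix(class_means)
  if (any(class_means < 0)) stop("class means must be non-negative")
  tot <- rowSums(class_means)
  out <- 100 * class_means / ifelse(tot == 0, NA, tot)
  out
}

#' Presence flags and presence-pattern categories per gene
#'
#' A gene is "expressed" in a class when it is detected (count > 0) in at
#' least `max(min_cells, ceiling(min_frac * class size))` cells of that
#' class. Categories from the pattern: `none` (nowhere), `class-specific:X`
#' (only in X), `class-absent:X` (everywhere but X), `all-classes`.
#'
#' @param counts Gene x cell count matrix.
#' @param classes Class label per cell (every class non-empty).
#' @param min_cells,min_frac Detection thresholds.
#' @return List with `presence` (gene x class logical matrix) and
#'   `category` (named character vector).
#' @export
class_specific_genes <- function(counts, classes, min_cells = 2,
                                 min_frac = 0.01) {
  cls <- if (is.factor(classes)) levels(classes) else sort(unique(classes))
  classes <- as.character(classes)
  if (any(table(factor(classes, levels = cls)) == 0)) stop("empty class")
  presence <- vapply(cls, function(k) {
    sel <- classes == k
    need <- max(min_cells, ceiling(min_frac * sum(sel)))
    rowSums(counts[, sel, drop = FALSE] > 0) >= need
  }, logical(nrow(counts)))
  rownames(presence) <- rownames(counts)
  n_in <- rowSums(presence)
  category <- rep("all-classes", nrow(counts))
  category[n_in == 0] <- "none"
  one <- n_in == 1
  category[one] <- paste0("class-specific:",
                          cls[apply(presence[one, , drop = FALSE], 1, which)])
  gap <- n_in == length(cls) - 1 & length(cls) > 1
  category[gap] <- paste0("class-absent:",
                          cls[apply(!presence[gap, , drop = FALSE], 1, which)])
  list(presence = presence,
       category = stats::setNames(category, rownames(counts)))
}

#' Pairwise Wilcoxon differential expression between classes
#'
#' For each class pair, a per-gene Wilcoxon rank sum test on log-normalized
#' values with BH FDR within the pair. `log2fc` is first class minus second.
#'
#' @param counts Gene x cell count matrix.
#' @param classes Class label per cell (>= 2 cells per class).
#' @return Named list of DE `data.frame`s
#'   (`gene, log2fc, p, q, direction, test`), one per pair `"A_vs_B"`.
#' @export
class_de <- function(counts, classes) {
  cls <- sort(unique(classes))
  sizes <- table(factor(classes, levels = cls))
  if (any(sizes < 2)) stop("need at least 2 cells per class")
  ln <- lognorm_cells(counts)
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- classes == pr[1]; b <- classes == pr[2]
    res <- lapply(seq_len(nrow(ln)), function(i)
      wilcoxon_rank_sum(ln[i, a], ln[i, b], mode = "approx"))
    lfc <- rowMeans(ln[, a, drop = FALSE]) - rowMeans(ln[, b, drop = FALSE])
    p <- vapply(res, `[[`, 0, "p")
    data.frame(gene = rownames(ln), log2fc = lfc, p = p, q = bh_fdr(p),
               direction = as.integer(sign(lfc)), test = "wilcoxon",
               row.names = NULL)
  })
  stats::setNames(out, vapply(pairs, paste, "", collapse = "_vs_"))
}

#' Class-level summary of microglial expression
#'
#' Combines distribution percentages (class means on the de-logged scale),
#' presence flags, pairwise Wilcoxon DE, and per-gene categories. On top of
#' the presence-pattern categories, genes expressed in all classes are
#' refined using the DE results: `consensus-enriched` (higher in consensus
#' than both other classes at `q < alpha`) and `non-consensus-depleted`
#' (lower in non-consensus than both other classes at `q < alpha`).
#'
#' @param counts Gene x cell count matrix (microglia only).
#' @param classes Class per cell, from
#'   `{healthy, consensus, non-consensus}`.
#' @param alpha Significance threshold for the DE refinement.
#' @param min_cells,min_frac Passed to [class_specific_genes()].
#' @return List with `summary` (`data.frame`: gene, pct_<class> columns,
#'   category) and `de` (the [class_de()] list).
#' @export
class_summary <- function(counts, classes, alpha = 0.05, min_cells = 2,
                          min_frac = 0.01) {
  cls <- sort(unique(classes))
  ln <- lognorm_cells(counts)
  expr <- 2^ln - 1
  class_means <- vapply(cls, function(k)
    rowMeans(expr[, classes == k, drop = FALSE]), numeric(nrow(expr)))
  pct <- distribution_percentage(class_means)
  spec <- class_specific_genes(counts, classes, min_cells, min_frac)
  de <- class_de(counts, classes)
  category <- spec$category
  refine <- function(gene, up_class) {
    others <- setdiff(cls, up_class)
    all(vapply(others, function(o) {
      nm <- paste(sort(c(up_class, o)), collapse = "_vs_")
      row <- de[[nm]][de[[nm]]$gene == gene, ]
      sign_needed <- if (startsWith(nm, up_class)) 1L else -1L
      nrow(row) == 1 && row$q < alpha && row$direction == sign_needed
    }, TRUE))
  }
  all_cls <- names(category)[category == "all-classes"]
  for (g in all_cls) {
    if ("consensus" %in% cls && refine(g, "consensus"))
      category[g] <- "consensus-enriched"
  }
  if ("non-consensus" %in% cls) {
    dep <- names(category)[category == "all-classes"]
    for (g in dep) {
      others <- setdiff(cls, "non-consensus")
      low <- all(vapply(others, function(o) {
        nm <- paste(sort(c("non-consensus", o)), collapse = "_vs_")
        row <- de[[nm]][de[[nm]]$gene == g, ]
        sign_needed <- if (startsWith(nm, "non-consensus")) -1L else 1L
        nrow(row) == 1 && row$q < alpha && row$direction == sign_needed
      }, TRUE))
      if (low) category[g] <- "non-consensus-depleted"
    }
  }
  colnames(pct) <- paste0("pct_", cls)
  list(summary = data.frame(gene = rownames(counts), pct,
                            category = unname(category), row.names = NULL),
       de = de)
}
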