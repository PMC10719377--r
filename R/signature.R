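# Marker-set scoring and construction of the cross-modality consensus
# disease-microglia signature: a directional gene list supported by both the
# bulk and single-nucleus modalities through shared significantly enriched
# gene sets.

new_signature <- function(entries, alpha_used, conflicts = character(),
                          provenance = list()) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries)) {
    stopifnot(all(entries$direction %in% c(-1L, 1L)),
              !anyDuplicated(entries$gene),
              all(lengths(entries$support) >= 1),
              all(lengths(entries$sets) >= 1))
  }
  structure(list(entries = entries, alpha_used = alpha_used,
                 conflicts = conflicts, provenance = provenance),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("consensus_signature: %d genes (alpha %.3g), %d direction conflicts\n",
              nrow(x$entries), x$alpha_used, length(x$conflicts)))
  invisible(x)
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum score of a marker set within one expression
#' profile. Genes are ranked by descending expression (ties broken by gene
#' id); the score is the sum over positions of the difference between the
#' weighted cumulative in-set fraction (weights `|rank value|^alpha_weight`,
#' rank value = N at the top) and the cumulative out-of-set fraction.
#'
#' @param expr Named numeric vector: one expression value per gene.
#' @param set Character vector of member gene ids.
#' @param alpha_weight Rank-weight exponent (default 0.25).
#' @return A single enrichment score.
#' @export
ssgsea_score <- function(expr, set, alpha_weight = 0.25) {
  universe <- names(expr)
  if (is.null(universe)) stop("expr must be a named vector")
  members <- intersect(set, universe)
  if (!length(members)) stop("set has empty intersection with the universe")
  if (length(members) == length(universe)) stop("set must not equal the universe")
  ord <- order(-expr, universe)
  n <- length(expr)
  in_set <- names(expr)[ord] %in% members
  w <- (n - seq_len(n) + 1)^alpha_weight
  p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (n - length(members))
  sum(p_in - p_out)
}

#' Hypergeometric over-representation analysis of a DE table
#'
#' The query is the set of genes significant at `q < alpha` in the DE table;
#' each gene set is tested for overlap with the query against the universe
#' (upper-tail hypergeometric), and BH FDR is applied across sets. Sets
#' disjoint from the universe are skipped with a warning.
#'
#' @param de A [de_table()] result.
#' @param sets Named list of gene sets.
#' @param universe Character vector of all testable gene ids (must contain
#'   the DE genes).
#' @param alpha Significance threshold defining the query.
#' @return `data.frame(set, K, k, p, q)` with a list column `overlap_genes`
#'   and a list column `overlap_directions`.
#' @export
ora <- function(de, sets, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  if (!all(de$gene %in% universe)) stop("universe must contain all DE genes")
  query <- de$gene[de$q < alpha]
  usable <- vapply(sets, function(s) length(intersect(s, universe)) > 0, TRUE)
  if (any(!usable))
    warning("sets disjoint from the universe skipped: ",
            paste(names(sets)[!usable], collapse = ", "))
  sets <- sets[usable]
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- intersect(s, query)
    data.frame(set = nm, K = length(s), k = length(ov),
               p = hypergeom_test(length(ov), length(s), length(query),
                                  length(universe)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), K = integer(), k = integer(),
                      p = numeric())
  out$q <- if (nrow(out)) bh_fdr(out$p) else numeric()
  out$overlap_genes <- lapply(out$set, function(nm)
    intersect(intersect(sets[[nm]], universe), query))
  out$overlap_directions <- lapply(out$overlap_genes, function(g)
    de$direction[match(g, de$gene)])
  rownames(out) <- NULL
  out
}

#' Build the cross-modality consensus signature
#'
#' 1. Run [ora()] on each modality; shared sets are those with `q < alpha`
#'    in both. 2. Drop any shared set lacking at least one significant DEG
#'    from each modality. 3. Signature genes are the union, over surviving
#'    sets, of their significant DEGs. 4. A gene significant in both
#'    modalities is kept only when the directions agree (conflicts are
#'    excluded and logged); a gene significant in one modality uses that
#'    sign. 5. Each entry records its modality support and contributing
#'    sets.
#'
#' @param de_bulk,de_sn [de_table()] results for the two modalities.
#' @param sets Named list of gene sets sharing the DE gene namespace.
#' @param alpha Significance threshold for both DEGs and set enrichment.
#' @param universe Optional explicit universe (default: union of the genes
#'   tested in either modality).
#' @return A `consensus_signature`; empty (with a warning) when no set is
#'   shared.
#' @export
build_consensus_signature <- function(de_bulk, de_sn, sets, alpha = 0.05,
                                      universe = NULL) {
  if (is.null(universe)) universe <- union(de_bulk$gene, de_sn$gene)
  ora_bulk <- ora(de_bulk, sets, universe, alpha)
  ora_sn <- suppressWarnings(ora(de_sn, sets, universe, alpha))
  shared <- intersect(ora_bulk$set[ora_bulk$q < alpha],
                      ora_sn$set[ora_sn$q < alpha])
  sig_bulk <- de_bulk$gene[de_bulk$q < alpha]
  sig_sn <- de_sn$gene[de_sn$q < alpha]
  surviving <- shared[vapply(shared, function(nm) {
    s <- sets[[nm]]
    length(intersect(s, sig_bulk)) >= 1 && length(intersect(s, sig_sn)) >= 1
  }, TRUE)]
  empty <- data.frame(gene = character(), direction = integer())
  empty$support <- list(); empty$sets <- list()
  if (!length(surviving)) {
    warning("no shared significant sets: empty consensus signature")
    return(new_signature(empty, alpha_used = alpha))
  }
  cand <- unique(unlist(lapply(surviving, function(nm)
    intersect(sets[[nm]], union(sig_bulk, sig_sn)))))
  conflicts <- character()
  rows <- lapply(cand, function(g) {
    in_b <- g %in% sig_bulk; in_s <- g %in% sig_sn
    d_b <- if (in_b) de_bulk$direction[match(g, de_bulk$gene)] else NA_integer_
    d_s <- if (in_s) de_sn$direction[match(g, de_sn$gene)] else NA_integer_
    if (in_b && in_s && d_b != d_s) {
      conflicts <<- c(conflicts, g)
      return(NULL)
    }
    dir <- if (in_b) d_b else d_s
    if (is.na(dir) || dir == 0L) return(NULL)  # zero-fold-change degenerate
    data.frame(gene = g, direction = as.integer(dir))
  })
  entries <- do.call(rbind, rows)
  if (is.null(entries)) entries <- empty
  if (nrow(entries)) {
    entries$support <- lapply(entries$gene, function(g)
      c("bulk", "sn")[c(g %in% sig_bulk, g %in% sig_sn)])
    entries$sets <- lapply(entries$gene, function(g)
      surviving[vapply(surviving, function(nm) g %in% sets[[nm]], TRUE)])
    entries <- entries[order(entries$gene), , drop = FALSE]
    rownames(entries) <- NULL
  }
  new_signature(entries, alpha_used = alpha, conflicts = sort(conflicts),
                provenance = list(shared_sets = sort(surviving)))
}
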