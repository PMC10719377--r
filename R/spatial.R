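# Turn transcript coordinates plus a segmentation label mask into an
# annotated cell x gene table: mask-lookup assignment with bounded
# nearest-label expansion, per-cell log normalization, variable-gene PCA
# k-means clustering, and marker-based cluster annotation.

#' Assign transcripts to segmented cells
#'
#' A transcript at 0-based coordinates (x, y) maps to pixel
#' (row floor(y)+1, col floor(x)+1). If that pixel carries a nonzero label
#' the transcript is counted for that cell; otherwise it goes to the label
#' of the nearest labeled pixel within Euclidean distance `expansion_px`
#' (ties broken by lowest label), else it is unassigned. Out-of-bounds
#' transcripts are unassigned with a warning. No cell is dropped by count:
#' every mask label appears in the output, zero counts included.
#'
#' @param transcripts `data.frame` with columns `x`, `y`, `gene`.
#' @param mask Integer label matrix (rows = y, columns = x; 0 background).
#' @param expansion_px Maximum expansion distance in pixels.
#' @return List with `counts` (gene x cell matrix, columns `cell_<label>`),
#'   `cells` (`data.frame(id, x, y, total)`, centroids from the mask),
#'   `assigned` (per-transcript label, 0 = unassigned) and `n_unassigned`.
#' @export
assign_transcripts <- function(transcripts, mask, expansion_px = 8) {
  validate_spatial(transcripts)
  if (!any(mask > 0)) stop("empty mask: no labeled pixels")
  H <- nrow(mask); W <- ncol(mask)
  n <- nrow(transcripts)
  px <- floor(transcripts$x); py <- floor(transcripts$y)
  in_bounds <- px >= 0 & px < W & py >= 0 & py < H
  if (any(!in_bounds))
    warning(sum(!in_bounds), " transcripts outside the mask bounds are unassigned")
  label <- integer(n)
  idx <- which(in_bounds)
  label[idx] <- mask[cbind(py[idx] + 1L, px[idx] + 1L)]
  if (expansion_px > 0) {
    todo <- which(in_bounds & label == 0L)
    if (length(todo)) {
      r <- ceiling(expansion_px)
      offs <- expand.grid(dy = -r:r, dx = -r:r)
      offs$d2 <- offs$dy^2 + offs$dx^2
      offs <- offs[offs$d2 <= expansion_px^2 & offs$d2 > 0, ]
      offs <- offs[order(offs$d2), ]
      for (d2 in unique(offs$d2)) {
        if (!length(todo)) break
        ring <- offs[offs$d2 == d2, ]
        best <- rep(NA_integer_, length(todo))
        for (k in seq_len(nrow(ring))) {
          rr <- py[todo] + ring$dy[k] + 1L
          cc <- px[todo] + ring$dx[k] + 1L
          ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
          lab <- rep(0L, length(todo))
          lab[ok] <- mask[cbind(rr[ok], cc[ok])]
          hit <- lab > 0L
          best[hit] <- pmin(best[hit], lab[hit], na.rm = TRUE)
        }
        found <- !is.na(best)
        label[todo[found]] <- best[found]
        todo <- todo[!found]
      }
    }
  }
  labels_all <- sort(unique(mask[mask > 0]))
  gene_ids <- sort(unique(transcripts$gene))
  counts <- matrix(0, length(gene_ids), length(labels_all),
                   dimnames = list(gene_ids, paste0("cell_", labels_all)))
  hit <- label > 0L
  if (any(hit)) {
    tab <- table(factor(transcripts$gene[hit], levels = gene_ids),
                 factor(label[hit], levels = labels_all))
    counts[] <- as.numeric(tab)
  }
  cent <- do.call(rbind, lapply(labels_all, function(l) {
    w <- which(mask == l, arr.ind = TRUE)
    c(x = mean(w[, 2] - 0.5), y = mean(w[, 1] - 0.5))
  }))
  cells <- data.frame(id = labels_all, x = cent[, "x"], y = cent[, "y"],
                      total = colSums(counts))
  list(counts = counts, cells = cells, assigned = label,
       n_unassigned = sum(label == 0L))
}

#' Per-cell log normalization of spatial counts
#'
#' `log2(1 + scale * count / total)`; cells with zero total stay all-zero.
#'
#' @param counts Gene x cell count matrix.
#' @param scale Normalization scale (default 1e4).
#' @return Matrix of log-normalized values.
#' @export
lognorm_cells <- function(counts, scale = 1e4) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log2(1 + sweep(counts, 2, scale / tot, "*"))
}

#' Cluster cells on the most variable genes
#'
#' Per-cell log normalization, variance ranking to the top `n_var_genes`
#' genes, PCA to `n_pcs` components, then k-means over `k_range` with k
#' chosen by maximal mean silhouette width. Deterministic given `seed`.
#'
#' @param counts Gene x cell count matrix.
#' @param n_var_genes Number of most-variable genes (all genes, with a
#'   warning, when fewer are available).
#' @param n_pcs Number of principal components.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed for the k-means initialization stream.
#' @return Integer cluster id per cell, with attribute `k`.
#' @export
cluster_cells <- function(counts, n_var_genes = 10, n_pcs = 5, k_range = 2:8,
                          seed = 1) {
  n_cells <- ncol(counts)
  if (n_cells < min(k_range)) stop("fewer cells than the smallest k")
  ln <- lognorm_cells(counts)
  if (nrow(ln) < n_var_genes) {
    warning("fewer genes than n_var_genes; using all ", nrow(ln), " genes")
    n_var_genes <- nrow(ln)
  }
  vars <- apply(ln, 1, stats::var)
  top <- rownames(ln)[order(-vars, rownames(ln))][seq_len(n_var_genes)]
  pca <- stats::prcomp(t(ln[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  emb <- pca$x[, seq_len(n_pcs), drop = FALSE]
  d <- stats::dist(emb)
  k_range <- k_range[k_range < n_cells]
  best <- NULL; best_sil <- -Inf
  for (k in k_range) {
    set.seed(seed + k)
    km <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
    sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    if (sil > best_sil + 1e-12) { best <- km$cluster; best_sil <- sil }
  }
  structure(as.integer(best), k = length(unique(best)), names = colnames(counts))
}

#' Annotate clusters with cell types from marker sets
#'
#' Expression is log-normalized and z-scored per gene across cells; each
#' cluster is assigned the type whose marker genes have the highest mean
#' z-score in that cluster. When the margin between the best and
#' second-best type does not exceed `min_margin`, the cluster is labeled
#' `"unknown"`. Marker sets disjoint from the panel are unavailable
#' (warned).
#'
#' @param counts Gene x cell count matrix.
#' @param clusters Integer cluster id per cell.
#' @param marker_sets Named list: one marker gene set per candidate type.
#' @param min_margin Minimum score margin for a confident call.
#' @return Named character vector: cell type per cluster id.
#' @export
annotate_clusters <- function(counts, clusters, marker_sets, min_margin = 0) {
  ln <- lognorm_cells(counts)
  usable <- vapply(marker_sets, function(s)
    length(intersect(s, rownames(ln))) > 0, TRUE)
  if (any(!usable))
    warning("marker sets disjoint from the panel: ",
            paste(names(marker_sets)[!usable], collapse = ", "))
  marker_sets <- marker_sets[usable]
  if (!length(marker_sets)) stop("no usable marker sets")
  mu <- rowMeans(ln); sdv <- apply(ln, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (ln - mu) / sdv
  cl_ids <- sort(unique(clusters))
  out <- vapply(cl_ids, function(cl) {
    zc <- rowMeans(z[, clusters == cl, drop = FALSE])
    scores <- vapply(marker_sets, function(s)
      mean(zc[intersect(s, rownames(z))]), 0)
    ord <- order(-scores)
    margin <- if (length(scores) > 1) scores[ord[1]] - scores[ord[2]] else Inf
    if (margin > min_margin) names(scores)[ord[1]] else "unknown"
  }, "")
  stats::setNames(out, cl_ids)
}
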