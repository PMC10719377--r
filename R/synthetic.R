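# Synthetic multi-modal data with planted ground truth: bulk NB counts for
# mutant vs isogenic microglia-like samples, multi-donor single-nucleus
# counts over five brain cell types, and a 100-gene spatial panel with
# segmented cells, a dominant ubiquitous gene, and a planted consensus
# subpopulation among disease microglia. Every generator is deterministic
# given the truth object and seed, so downstream stages can be verified by
# parameter recovery.

default_props <- c(microglia = 0.20, astrocyte = 0.25, neuron = 0.25,
                   oligodendrocyte = 0.20, endothelial = 0.10)

#' Create the planted simulation truth
#'
#' Draws the gene universe, baseline means, the planted disease signature
#' (genes and directions), per-type marker genes, the dominant ubiquitous
#' gene, and the spatial panel. All downstream generators consume this one
#' object, and recovery tests compare against it.
#'
#' @param n_genes Size of the gene universe.
#' @param n_signature Number of planted signature genes (0 allowed).
#' @param sig_log2fc Positive log2 effect magnitude of the planted signature.
#' @param cell_type_props Named proportions over cell types (sum to 1).
#' @param consensus_fraction Fraction of disease microglia planted as
#'   consensus cells in the spatial modality (default 0.054, the scale of
#'   the motivating tissue observation).
#' @param nb_dispersion NB dispersion phi shared by the generators.
#' @param dominant_fraction Fraction of all spatial transcripts contributed
#'   by the dominant gene (default 0.6).
#' @param panel_size Spatial panel size (default 100).
#' @param n_markers Marker genes per cell type.
#' @param marker_boost Fold-boost of marker genes in their own type.
#' @param donor_sd Log-scale SD of the per-donor random effect.
#' @param seed Integer seed; identical config + seed gives an identical truth.
#' @return An object of class `sim_truth`.
#' @export
make_truth <- function(n_genes = 2000, n_signature = 40, sig_log2fc = 2,
                       cell_type_props = default_props,
                       consensus_fraction = 0.054, nb_dispersion = 0.1,
                       dominant_fraction = 0.6, panel_size = 100,
                       n_markers = 20, marker_boost = 8, donor_sd = 0.3,
                       seed = 1) {
  if (abs(sum(cell_type_props) - 1) > 1e-9)
    stop("config error: cell_type_props must sum to 1")
  if (any(cell_type_props < 0)) stop("config error: negative proportion")
  if (is.null(names(cell_type_props))) stop("config error: proportions must be named")
  if (consensus_fraction < 0 || consensus_fraction > 1)
    stop("config error: consensus_fraction must lie in [0, 1]")
  if (nb_dispersion <= 0) stop("config error: nb_dispersion must be positive")
  if (n_signature > n_genes) stop("config error: signature larger than gene universe")
  if (panel_size > n_genes) stop("config error: panel larger than gene universe")
  if (n_signature < 0) stop("config error: negative signature size")
  if (n_genes < n_signature + 1 + n_markers * length(cell_type_props))
    stop("config error: gene universe too small for the signature, ",
         "dominant gene and markers")
  set.seed(seed)
  ids <- sprintf("G%04d", seq_len(n_genes))
  types <- names(cell_type_props)
  sig_idx <- if (n_signature > 0) sample(n_genes, n_signature) else integer()
  rest <- setdiff(seq_len(n_genes), sig_idx)
  dom_idx <- rest[sample(length(rest), 1)]
  rest <- setdiff(rest, dom_idx)
  marker_idx <- matrix(rest[sample(length(rest), n_markers * length(types))],
                       ncol = length(types))
  # cosmetic ids: the dominant gene and canonical microglia markers carry
  # their field names so annotation output reads naturally
  ids[dom_idx] <- "GFAP"
  if ("microglia" %in% types && n_markers >= 3)
    ids[marker_idx[1:3, match("microglia", types)]] <-
      c("TMEM119", "P2RY12", "MERTK")
  base_mean <- stats::setNames(stats::rlnorm(n_genes, meanlog = 1, sdlog = 1), ids)
  # a disease signature of a cell type consists of genes expressed in that
  # cell type: floor signature-gene baselines at the 80th percentile so the
  # planted effect is observable at single-cell depth
  if (length(sig_idx))
    base_mean[sig_idx] <- pmax(base_mean[sig_idx],
                               stats::quantile(base_mean, 0.8))
  # markers are likewise chosen for being well expressed in their own type;
  # the two lead markers per type emulate canonical high-abundance markers
  # so the most-variable-gene selection sees every type
  base_mean[as.vector(marker_idx)] <-
    pmax(base_mean[as.vector(marker_idx)], stats::quantile(base_mean, 0.7))
  lead_idx <- as.vector(marker_idx[1:2, , drop = FALSE])
  base_mean[lead_idx] <- pmax(base_mean[lead_idx],
                              stats::quantile(base_mean, 0.95))
  signature <- data.frame(
    gene = ids[sig_idx],
    direction = if (n_signature > 0)
      ifelse(stats::rbinom(n_signature, 1, 0.5) == 1, 1L, -1L) else integer())
  type_markers <- stats::setNames(
    lapply(seq_along(types), function(j) ids[marker_idx[, j]]), types)
  # spatial panels are curated: signature genes, the dominant gene, and a
  # block of markers per type, padded with filler genes
  fixed <- unique(c(ids[sig_idx], ids[dom_idx],
                    unlist(lapply(type_markers, utils::head, 10))))
  filler <- setdiff(ids, c(fixed, unlist(type_markers)))
  if (length(filler) < panel_size - length(fixed))
    stop("config error: gene universe too small to fill the panel")
  panel <- c(fixed, sample(filler, max(0, panel_size - length(fixed))))
  truth <- list(genes = ids, base_mean = base_mean, signature = signature,
                sig_log2fc = sig_log2fc, cell_type_props = cell_type_props,
                consensus_fraction = consensus_fraction,
                nb_dispersion = nb_dispersion,
                dominant_gene = list(gene = ids[dom_idx],
                                     fraction = dominant_fraction),
                type_markers = type_markers, marker_boost = marker_boost,
                donor_sd = donor_sd, panel = panel, seed = as.integer(seed))
  class(truth) <- "sim_truth"
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d genes, %d signature genes (log2fc %.2g), %d cell types, seed %d\n",
    length(x$genes), nrow(x$signature), x$sig_log2fc,
    length(x$cell_type_props), x$seed))
  invisible(x)
}

sig_multiplier <- function(truth, gene_ids) {
  mult <- rep(1, length(gene_ids))
  i <- match(truth$signature$gene, gene_ids)
  ok <- !is.na(i)
  mult[i[ok]] <- 2^(truth$signature$direction[ok] * truth$sig_log2fc)
  mult
}

#' Generate bulk RNA-seq counts for disease vs control samples
#'
#' Counts are negative binomial with log-normal baseline gene means and the
#' planted signature (fold change `2^(direction * sig_log2fc)`) applied to
#' the disease group. Column sums vary around `depth` (Poisson library
#' sizes).
#'
#' @param truth A [make_truth()] object.
#' @param n_per_group Samples per group (>= 2).
#' @param depth Expected library size (> 0).
#' @param seed Seed (defaults to `truth$seed + 1`).
#' @return A [count_matrix()] with `column_meta$condition` in
#'   `{control, disease}`.
#' @export
gen_bulk_counts <- function(truth, n_per_group = 6, depth = 1e6,
                            seed = truth$seed + 1) {
  stopifnot(n_per_group >= 2)
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  G <- length(truth$genes)
  rel_ctrl <- truth$base_mean / sum(truth$base_mean)
  rel_dis <- rel_ctrl * sig_multiplier(truth, truth$genes)
  rel_dis <- rel_dis / sum(rel_dis)
  n <- 2 * n_per_group
  cond <- rep(c("control", "disease"), each = n_per_group)
  libs <- stats::rpois(n, depth)
  v <- vapply(seq_len(n), function(j) {
    rel <- if (cond[j] == "control") rel_ctrl else rel_dis
    stats::rnbinom(G, size = 1 / truth$nb_dispersion, mu = rel * libs[j])
  }, numeric(G))
  count_matrix(v, truth$genes,
               paste0(cond, "_", rep(seq_len(n_per_group), 2)),
               column_meta = data.frame(condition = cond))
}

type_profile <- function(truth, type) {
  w <- truth$base_mean
  mk <- truth$type_markers[[type]]
  w[mk] <- w[mk] * truth$marker_boost
  # markers are specific: other types express them at a small residual level
  other <- setdiff(unlist(truth$type_markers), mk)
  w[other] <- w[other] * 0.05
  w / sum(w)
}

#' Generate multi-donor single-nucleus counts over brain cell types
#'
#' Each cell draws a type from `truth$cell_type_props` and a donor; means
#' combine a type-specific profile (marker genes boosted), a per-donor
#' log-normal random effect, and -- for disease-donor microglia only -- the
#' planted signature shift.
#'
#' @param truth A [make_truth()] object.
#' @param donors_per_group Donors per condition (>= 2).
#' @param cells_per_donor Cells per donor (0 allowed: empty matrix).
#' @param cell_depth Expected per-cell total count.
#' @param seed Seed (defaults to `truth$seed + 2`).
#' @return A [count_matrix()] with `column_meta` columns
#'   `cell_id, donor, condition, cell_type`.
#' @export
gen_sn_counts <- function(truth, donors_per_group = 5, cells_per_donor = 200,
                          cell_depth = 2000, seed = truth$seed + 2) {
  stopifnot(donors_per_group >= 2)
  if (length(truth$cell_type_props) < 2) stop("need at least 2 cell types")
  set.seed(seed)
  types <- names(truth$cell_type_props)
  donors <- c(paste0("ctrl_d", seq_len(donors_per_group)),
              paste0("pd_d", seq_len(donors_per_group)))
  donor_cond <- rep(c("control", "disease"), each = donors_per_group)
  G <- length(truth$genes)
  profiles <- vapply(types, function(t) type_profile(truth, t), numeric(G))
  donor_eff <- matrix(stats::rlnorm(G * length(donors), 0, truth$donor_sd),
                      G, length(donors))
  n_cells <- length(donors) * cells_per_donor
  meta <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(max(n_cells, 0))),
    donor = rep(donors, each = cells_per_donor),
    condition = rep(donor_cond, each = cells_per_donor),
    stringsAsFactors = FALSE)[seq_len(n_cells), , drop = FALSE]
  meta$cell_type <- if (n_cells > 0)
    sample(types, n_cells, replace = TRUE, prob = truth$cell_type_props)
  else character()
  v <- matrix(0, G, n_cells, dimnames = list(truth$genes, meta$cell_id))
  if (n_cells > 0) {
    sig_mult <- sig_multiplier(truth, truth$genes)
    depths <- stats::rpois(n_cells, cell_depth)
    for (j in seq_len(n_cells)) {
      w <- profiles[, meta$cell_type[j]] *
        donor_eff[, match(meta$donor[j], donors)]
      if (meta$condition[j] == "disease" && meta$cell_type[j] == "microglia")
        w <- w * sig_mult
      w <- w / sum(w)
      v[, j] <- stats::rnbinom(G, size = 1 / truth$nb_dispersion,
                               mu = w * depths[j])
    }
  }
  count_matrix(v, truth$genes, meta$cell_id, column_meta = meta)
}

place_discs <- function(n_cells, field, radius, max_tries) {
  H <- field[1]; W <- field[2]
  if (W - 2 * radius <= 0 || H - 2 * radius <= 0)
    stop("field too small for cell discs")
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0
  while (length(cx) < n_cells) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not pack ", n_cells, " non-overlapping cells into the field")
    x <- stats::runif(1, radius, W - radius)
    y <- stats::runif(1, radius, H - radius)
    if (!length(cx) || min((cx - x)^2 + (cy - y)^2) >= (2 * radius + 1)^2) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  data.frame(x = cx, y = cy)
}

discs_to_mask <- function(centers, field, radius) {
  H <- field[1]; W <- field[2]
  mask <- matrix(0L, H, W)
  for (k in seq_len(nrow(centers))) {
    x0 <- centers$x[k]; y0 <- centers$y[k]
    cols <- max(1, floor(x0 - radius)):min(W, ceiling(x0 + radius) + 1)
    rows <- max(1, floor(y0 - radius)):min(H, ceiling(y0 + radius) + 1)
    # pixel (row i, col j) covers [j-1, j) x [i-1, i) in 0-based coordinates;
    # label it when its center lies inside the disc
    px <- cols - 0.5; py <- rows - 0.5
    inside <- outer((py - y0)^2, (px - x0)^2, "+") <= radius^2
    sub <- mask[rows, cols, drop = FALSE]
    sub[inside] <- k
    mask[rows, cols] <- sub
  }
  mask
}

points_in_disc <- function(n, cx, cy, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a spatial transcriptomics dataset with a planted consensus class
#'
#' Cells are non-overlapping discs in a pixel field. Per cell, transcript
#' counts for the panel genes are drawn from its type profile; among disease
#' microglia a fraction `truth$consensus_fraction` is generated with all
#' signature-gene means shifted in the signature direction. The dominant
#' gene is emitted both inside cells and as uniform background so that its
#' share of all transcripts hits `truth$dominant_gene$fraction`. The label
#' mask encodes the discs as labels `1..n_cells` over background 0.
#'
#' @param truth A [make_truth()] object.
#' @param n_cells Number of cells (ignored when `cell_plan` is given).
#' @param field `c(H, W)` field size in pixels.
#' @param pd_fraction Probability a cell comes from a disease donor.
#' @param cell_plan Optional `data.frame(condition, cell_type, n)` fixing the
#'   exact composition (e.g. exactly 653 disease microglia).
#' @param depth Expected non-signature transcript count per cell.
#' @param sig_gene_mean Expected count of each signature gene in a healthy
#'   microglial cell (panels are designed so their target genes are reliably
#'   detectable).
#' @param radius Cell disc radius in pixels.
#' @param background_share Fraction of dominant-gene transcripts emitted as
#'   uniform background rather than inside cells.
#' @param dispersion NB dispersion of the per-cell molecule counts.
#'   Single-molecule counting is close to Poisson, so the spatial default
#'   (0.02) is far below the sequencing dispersion in `truth$nb_dispersion`.
#' @param seed Seed (defaults to `truth$seed + 3`).
#' @return List with `transcripts` (x, y, gene), `mask` (H x W integer
#'   matrix), `cells` (ground-truth table: id, x, y, condition, cell_type,
#'   class), and `panel`.
#' @export
gen_spatial <- function(truth, n_cells = 600, field = c(600, 600),
                        pd_fraction = 0.5, cell_plan = NULL, depth = 400,
                        sig_gene_mean = 20, radius = 8, background_share = 0.5,
                        dispersion = 0.02, seed = truth$seed + 3) {
  set.seed(seed)
  panel <- truth$panel
  dom <- truth$dominant_gene$gene
  dom_f <- truth$dominant_gene$fraction
  if (!is.null(cell_plan)) {
    stopifnot(all(c("condition", "cell_type", "n") %in% names(cell_plan)))
    cells <- data.frame(
      condition = rep(cell_plan$condition, cell_plan$n),
      cell_type = rep(cell_plan$cell_type, cell_plan$n))
    n_cells <- nrow(cells)
  } else {
    stopifnot(n_cells >= 1)
    cells <- data.frame(
      condition = ifelse(stats::rbinom(n_cells, 1, pd_fraction) == 1,
                         "disease", "control"),
      cell_type = sample(names(truth$cell_type_props), n_cells, replace = TRUE,
                         prob = truth$cell_type_props))
  }
  cells$id <- seq_len(n_cells)
  is_pd_mg <- cells$condition == "disease" & cells$cell_type == "microglia"
  consensus <- is_pd_mg & stats::rbinom(n_cells, 1, truth$consensus_fraction) == 1
  cells$class <- ifelse(cells$cell_type != "microglia", NA_character_,
                 ifelse(cells$condition == "control", "healthy",
                 ifelse(consensus, "consensus", "non-consensus")))

  centers <- place_discs(n_cells, field, radius, max_tries = 500 * n_cells)
  cells$x <- centers$x; cells$y <- centers$y
  mask <- discs_to_mask(centers, field, radius)

  # expected counts per (panel gene x cell); dominant gene handled separately
  core <- setdiff(panel, dom)
  sig_in_panel <- intersect(truth$signature$gene, core)
  prof <- vapply(names(truth$cell_type_props), function(t) {
    w <- type_profile(truth, t)[core]
    e <- depth * w / sum(w)
    if (t == "microglia" && length(sig_in_panel)) e[sig_in_panel] <- sig_gene_mean
    e
  }, numeric(length(core)))
  rownames(prof) <- core
  counts <- matrix(0, length(core), n_cells, dimnames = list(core, NULL))
  cons_mult <- sig_multiplier(truth, core)
  for (j in seq_len(n_cells)) {
    e <- prof[, cells$cell_type[j]]
    if (isTRUE(cells$class[j] == "consensus")) e <- e * cons_mult
    counts[, j] <- stats::rnbinom(length(core), size = 1 / dispersion, mu = e)
  }
  t_rest <- sum(counts)
  d_total <- round(dom_f / (1 - dom_f) * t_rest)
  d_bg <- round(d_total * background_share)
  d_cells <- as.integer(stats::rmultinom(1, d_total - d_bg, rep(1, n_cells)))

  per_cell <- colSums(counts) + d_cells
  tx <- vector("list", n_cells + 1L)
  for (j in seq_len(n_cells)) {
    gene_vec <- c(rep(core, counts[, j]), rep(dom, d_cells[j]))
    pts <- points_in_disc(length(gene_vec), cells$x[j], cells$y[j], radius)
    tx[[j]] <- data.frame(x = pts$x, y = pts$y, gene = gene_vec)
  }
  tx[[n_cells + 1L]] <- data.frame(
    x = stats::runif(d_bg, 0, field[2]), y = stats::runif(d_bg, 0, field[1]),
    gene = rep(dom, d_bg))
  transcripts <- do.call(rbind, tx)
  rownames(transcripts) <- NULL
  list(transcripts = transcripts, mask = mask,
       cells = cells[, c("id", "x", "y", "condition", "cell_type", "class")],
       panel = panel)
}

#' Generate a synthetic gene-set collection with planted signature sets
#'
#' Distributes the planted signature genes across `n_planted` sets (padded
#' with random non-signature genes) and fills the remaining sets with random
#' non-signature genes. Used to exercise signature construction end-to-end.
#'
#' @param truth A [make_truth()] object.
#' @param n_sets Total number of sets.
#' @param n_planted Number of sets carrying signature genes.
#' @param set_size Members per set.
#' @param seed Seed (defaults to `truth$seed + 4`).
#' @return Named list of gene sets; attribute `planted` names the seeded sets.
#' @export
gen_gene_sets <- function(truth, n_sets = 50, n_planted = 5, set_size = 20,
                          seed = truth$seed + 4) {
  stopifnot(n_planted <= n_sets)
  set.seed(seed)
  nonsig <- setdiff(truth$genes, c(truth$signature$gene, truth$dominant_gene$gene))
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  sig <- truth$signature$gene
  assign_to <- if (length(sig)) rep_len(seq_len(max(n_planted, 1)), length(sig))
  for (i in seq_len(n_sets)) {
    planted <- if (i <= n_planted && length(sig)) sig[assign_to == i] else character()
    pad <- sample(nonsig, max(0, set_size - length(planted)))
    sets[[i]] <- c(planted, pad)
  }
  attr(sets, "planted") <- names(sets)[seq_len(n_planted)]
  sets
}
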