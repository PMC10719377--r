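# End-to-end orchestration: simulate (or load) the three modalities, run
# differential expression, build the consensus signature, deconvolve the
# bulk samples, process the spatial data, classify microglia, and write a
# report directory.

pipeline_defaults <- function() {
  list(
    seed = 1,
    alpha = 0.05,
    tau = 1.0,
    epsilon = 0.0,
    sn_min_prop = 0.1,
    max_fraction = 0.40,
    expansion_px = 8,
    ref_stat = "mean",
    sim = list(n_genes = 2000, n_signature = 40, sig_log2fc = 2,
               consensus_fraction = 0.054, nb_dispersion = 0.1,
               dominant_fraction = 0.6,
               bulk_n_per_group = 6, bulk_depth = 1e6,
               sn_donors_per_group = 5, sn_cells_per_donor = 200,
               sn_cell_depth = 2000,
               spatial_n_cells = 600, spatial_field = c(600, 600),
               spatial_depth = 400, spatial_sig_gene_mean = 20,
               n_sets = 50, n_planted = 5, set_size = 20))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Run the full pipeline and write a report directory
#'
#' With `simulate = TRUE` the three modalities (bulk, single-nucleus,
#' spatial) plus a gene-set collection are generated from the planted truth
#' at `seed`; otherwise `config` must name the input files. The stages are:
#' bulk NB-LRT DE, single-nucleus microglia Wilcoxon DE, consensus-signature
#' construction, variance-weighted NNLS deconvolution of each bulk sample,
#' spatial high-abundance filtering, transcript assignment, clustering,
#' marker annotation, and consensus classification of disease microglia.
#'
#' Outputs in `out_dir`: `de_bulk.tsv`, `de_sn.tsv`, `signature.json`,
#' `props.csv`, `cells.csv`, `class_summary.tsv`, `report.json`, `run.log`.
#' `report.json` contains only run-deterministic content (wall-clock
#' timestamps go to the log), so two runs at the same seed are
#' byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param config Optional configuration list (or path to a YAML file) with
#'   any of the keys of the built-in defaults; in file mode also an
#'   `inputs` block naming `bulk_counts`, `bulk_groups`, `sn_counts`,
#'   `sn_meta`, `gene_sets`, `transcripts`, `mask`, `markers`,
#'   `cell_conditions` (CSV `label,condition`).
#' @param simulate Generate the inputs from the synthetic module.
#' @param seed Integer master seed (overrides the config seed).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(out_dir, config = NULL, simulate = FALSE, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(pipeline_defaults(), config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("pdmg run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
           " seed=", cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (simulate) {
    s <- cfg$sim
    truth <- stage("simulate", make_truth(
      n_genes = s$n_genes, n_signature = s$n_signature,
      sig_log2fc = s$sig_log2fc, consensus_fraction = s$consensus_fraction,
      nb_dispersion = s$nb_dispersion, dominant_fraction = s$dominant_fraction,
      seed = cfg$seed))
    bulk <- stage("simulate", gen_bulk_counts(truth, s$bulk_n_per_group,
                                              s$bulk_depth))
    sn <- stage("simulate", gen_sn_counts(truth, s$sn_donors_per_group,
                                          s$sn_cells_per_donor, s$sn_cell_depth))
    sp <- stage("simulate", gen_spatial(truth, n_cells = s$spatial_n_cells,
                                        field = s$spatial_field,
                                        depth = s$spatial_depth,
                                        sig_gene_mean = s$spatial_sig_gene_mean))
    sets <- stage("simulate", gen_gene_sets(truth, s$n_sets, s$n_planted,
                                            s$set_size))
    markers <- truth$type_markers
    transcripts <- sp$transcripts; mask <- sp$mask
    spatial_cond <- stats::setNames(sp$cells$condition, sp$cells$id)
    bulk_groups <- bulk$column_meta$condition
  } else {
    inp <- cfg$inputs
    if (is.null(inp)) stop("stage 'inputs' failed: config$inputs missing")
    bulk <- stage("inputs", read_count_matrix(inp$bulk_counts))
    grp <- stage("inputs", utils::read.csv(inp$bulk_groups))
    bulk_groups <- grp$condition[match(columns(bulk), grp$sample)]
    sn <- stage("inputs", read_count_matrix(inp$sn_counts))
    sn$column_meta <- stage("inputs", utils::read.csv(inp$sn_meta))
    sets <- stage("inputs", read_gene_sets(inp$gene_sets))
    markers <- stage("inputs", read_gene_sets(inp$markers))
    transcripts <- stage("inputs", read_spatial(inp$transcripts))
    mask <- stage("inputs", read_mask(inp$mask))
    cond_map <- stage("inputs", utils::read.csv(inp$cell_conditions))
    spatial_cond <- stats::setNames(cond_map$condition, cond_map$label)
    truth <- NULL
  }
  log_line("inputs: bulk ", nrow(bulk$values), "x", ncol(bulk$values),
           ", sn ", nrow(sn$values), "x", ncol(sn$values),
           ", transcripts ", nrow(transcripts))

  de_bulk <- stage("de_bulk", de_table(bulk, bulk_groups, method = "nb_lrt",
                                       alpha = cfg$alpha))
  mg <- sn$column_meta$cell_type == "microglia"
  sn_mg <- subset_counts(sn, cols = which(mg))
  # per-cell DE uses a detection-style filter (a gene needs CPM >= 1 in 10%
  # of the smaller group), the single-cell convention, not the bulk 70% rule
  de_sn <- stage("de_sn", de_table(sn_mg, sn_mg$column_meta$condition,
                                   method = "wilcoxon", alpha = cfg$alpha,
                                   min_prop = cfg$sn_min_prop,
                                   normalize = "libsize"))
  signature <- stage("signature", suppressWarnings(
    build_consensus_signature(de_bulk, de_sn, sets, alpha = cfg$alpha)))
  log_line("signature: ", nrow(signature$entries), " genes, ",
           length(signature$conflicts), " direction conflicts")

  bulk_flt <- high_abundance_filter(bulk, cfg$max_fraction)
  ref <- stage("deconvolution", build_reference(sn))
  props <- stage("deconvolution", t(vapply(columns(bulk), function(sm)
    deconvolve(stats::setNames(bulk$values[, sm], genes(bulk)), ref,
               exclude_genes = bulk_flt$removed$gene)$proportions,
    numeric(length(ref$types)))))
  class_props <- class_average_proportions(props, bulk_groups)

  sp_flt <- stage("spatial", high_abundance_filter(transcripts,
                                                   cfg$max_fraction))
  asn <- stage("spatial", assign_transcripts(sp_flt$data, mask,
                                             expansion_px = cfg$expansion_px))
  clusters <- stage("spatial", cluster_cells(asn$counts, seed = cfg$seed))
  ann <- stage("spatial", annotate_clusters(asn$counts, clusters, markers))
  cell_meta <- data.frame(
    id = asn$cells$id, x = asn$cells$x, y = asn$cells$y,
    total = asn$cells$total, cluster = clusters,
    cell_type = unname(ann[as.character(clusters)]),
    condition = unname(spatial_cond[as.character(asn$cells$id)]))
  # an empty recovered signature (or no annotated control microglia to
  # anchor the healthy reference) leaves classification undefined: disease
  # microglia keep class NA and the report flags it
  has_ref <- any(cell_meta$cell_type == "microglia" &
                   cell_meta$condition == "control")
  cells <- if (nrow(signature$entries) && has_ref) {
    stage("classify", classify_spatial_cells(
      asn$counts, cell_meta, signature, tau = cfg$tau, epsilon = cfg$epsilon,
      ref_stat = cfg$ref_stat))
  } else {
    log_line(if (has_ref) "signature empty: classification skipped"
             else "no annotated control microglia: classification skipped")
    cell_meta$class <- ifelse(
      cell_meta$cell_type == "microglia" & cell_meta$condition == "control",
      "healthy", NA_character_)
    cell_meta$concordance <- NA_real_
    cell_meta
  }

  mg_cells <- !is.na(cells$class)
  summ <- if (any(mg_cells) && length(unique(cells$class[mg_cells])) >= 2 &&
              all(table(cells$class[mg_cells]) >= 2)) {
    stage("class_summary", class_summary(
      asn$counts[, mg_cells, drop = FALSE], cells$class[mg_cells],
      alpha = cfg$alpha))
  } else NULL

  n_cons <- sum(cells$class == "consensus", na.rm = TRUE)
  n_pd_mg <- sum(cells$class %in% c("consensus", "non-consensus"), na.rm = TRUE)
  report <- list(
    seed = cfg$seed,
    n_cells = nrow(cells),
    n_unassigned_transcripts = asn$n_unassigned,
    removed_high_abundance = sp_flt$removed,
    cells_per_class = as.list(table(cells$class[mg_cells])),
    n_pd_microglia = n_pd_mg,
    n_consensus = n_cons,
    consensus_percentage = if (n_pd_mg > 0)
      consensus_percentage(n_cons, n_pd_mg) else NA,
    signature_size = nrow(signature$entries),
    shared_sets = signature$provenance$shared_sets %||% character(),
    direction_conflicts = signature$conflicts,
    class_proportions = as.data.frame(class_props))

  utils::write.table(de_bulk, file.path(out_dir, "de_bulk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de_sn, file.path(out_dir, "de_sn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_signature(signature, file.path(out_dir, "signature.json"))
  utils::write.csv(data.frame(sample = rownames(props),
                              condition = bulk_groups, props,
                              row.names = NULL),
                   file.path(out_dir, "props.csv"), row.names = FALSE)
  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  if (!is.null(summ))
    utils::write.table(summ$summary, file.path(out_dir, "class_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done: ", n_cons, "/", n_pd_mg, " disease microglia consensus")
  invisible(report)
}

#' Write a simulated dataset to disk in the pipeline's file formats
#'
#' Emits `counts.mtx` (+ id sidecars), `sn_counts.mtx`, `cells.csv`,
#' `transcripts.csv`, `mask.tiff`, `sets.gmt`, `markers.gmt`,
#' `bulk_groups.csv`, `cell_conditions.csv` and `truth.json`.
#'
#' @param truth A [make_truth()] object.
#' @param out_dir Output directory.
#' @param ... Passed on to the generators (sizes, depths).
#' @return Invisibly, the output directory.
#' @export
simulate_to_dir <- function(truth, out_dir, ...) {
  dots <- list(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bulk <- gen_bulk_counts(truth)
  sn <- gen_sn_counts(truth)
  sp <- do.call(gen_spatial, c(list(truth), dots))
  sets <- gen_gene_sets(truth)
  write_count_matrix(bulk, file.path(out_dir, "counts.mtx"))
  utils::write.csv(data.frame(sample = columns(bulk),
                              condition = bulk$column_meta$condition),
                   file.path(out_dir, "bulk_groups.csv"), row.names = FALSE)
  write_count_matrix(sn, file.path(out_dir, "sn_counts.mtx"))
  utils::write.csv(sn$column_meta, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  write_spatial(sp$transcripts, file.path(out_dir, "transcripts.csv"))
  write_mask(sp$mask, file.path(out_dir, "mask.tiff"))
  utils::write.csv(data.frame(label = sp$cells$id,
                              condition = sp$cells$condition),
                   file.path(out_dir, "cell_conditions.csv"), row.names = FALSE)
  write_gene_sets(sets, file.path(out_dir, "sets.gmt"))
  write_gene_sets(truth$type_markers, file.path(out_dir, "markers.gmt"))
  jsonlite::write_json(
    list(signature = truth$signature, sig_log2fc = truth$sig_log2fc,
         cell_type_props = as.list(truth$cell_type_props),
         consensus_fraction = truth$consensus_fraction,
         nb_dispersion = truth$nb_dispersion,
         dominant_gene = truth$dominant_gene, seed = truth$seed,
         spatial_classes = sp$cells),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
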