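test_that("make_truth validates its configuration and honors requests", {
  truth <- make_truth(n_genes = 200, n_signature = 10,
                      consensus_fraction = 0.054, seed = 4)
  expect_equal(truth$consensus_fraction, 0.054)
  expect_equal(nrow(truth$signature), 10)
  expect_true(all(truth$signature$direction %in% c(-1L, 1L)))
  expect_true(all(truth$signature$gene %in% truth$genes))
  expect_false(any(duplicated(truth$signature$gene)))
  expect_equal(sum(truth$cell_type_props), 1)
  expect_equal(length(truth$panel), 100)
  expect_true(all(truth$signature$gene %in% truth$panel))
  expect_true(truth$dominant_gene$gene %in% truth$panel)
  # degenerate and invalid configs
  empty_sig <- make_truth(n_genes = 200, n_signature = 0, seed = 4)
  expect_equal(nrow(empty_sig$signature), 0)
  expect_error(make_truth(cell_type_props = c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(make_truth(n_genes = 10, n_signature = 11, panel_size = 5),
               "config error")
  expect_error(make_truth(nb_dispersion = 0), "config error")
  expect_error(make_truth(consensus_fraction = 1.2), "config error")
})

test_that("generators are deterministic given truth and seed", {
  truth <- make_truth(n_genes = 300, n_signature = 8, seed = 9)
  expect_identical(make_truth(n_genes = 300, n_signature = 8, seed = 9), truth)
  expect_identical(gen_bulk_counts(truth, 3), gen_bulk_counts(truth, 3))
  expect_identical(gen_sn_counts(truth, 2, 30), gen_sn_counts(truth, 2, 30))
  s1 <- gen_spatial(truth, n_cells = 30, field = c(200, 200), depth = 80)
  s2 <- gen_spatial(truth, n_cells = 30, field = c(200, 200), depth = 80)
  expect_identical(s1, s2)
  expect_identical(gen_gene_sets(truth), gen_gene_sets(truth))
  # a different seed changes the draw
  expect_false(identical(gen_bulk_counts(truth, 3, seed = 99),
                         gen_bulk_counts(truth, 3)))
})

test_that("bulk counts carry the planted effect and the NB moment structure", {
  # null effect: log2 group-mean ratio centered on 0
  null_truth <- make_truth(n_genes = 400, n_signature = 20, sig_log2fc = 0,
                           seed = 14)
  b0 <- gen_bulk_counts(null_truth, n_per_group = 30)
  v <- b0$values
  grp <- b0$column_meta$condition
  ratio0 <- log2(rowMeans(v[null_truth$signature$gene, grp == "disease"]) /
                 rowMeans(v[null_truth$signature$gene, grp == "control"]))
  expect_lt(max(abs(ratio0)), 0.3)

  # planted log2fc = 1 recovered within +/- 0.2 at n_per_group = 50
  truth <- make_truth(n_genes = 400, n_signature = 20, sig_log2fc = 1,
                      seed = 15)
  reps <- lapply(1:20, function(i)
    gen_bulk_counts(truth, n_per_group = 50, seed = 1000 + i))
  ratios <- sapply(reps, function(b) {
    g <- b$column_meta$condition
    log2(rowMeans(b$values[truth$signature$gene, g == "disease"]) /
         rowMeans(b$values[truth$signature$gene, g == "control"]))
  })
  expect_true(all(abs(rowMeans(ratios) * truth$signature$direction - 1) < 0.2))
})

test_that("simulated counts reproduce the NB mean-variance relationship", {
  truth <- make_truth(n_genes = 300, n_signature = 0, nb_dispersion = 0.15,
                      seed = 16)
  b <- gen_bulk_counts(truth, n_per_group = 500, depth = 5e4)
  v <- b$values[, b$column_meta$condition == "control"]
  mu <- rowMeans(v)
  s2 <- apply(v, 1, var)
  hi <- mu > 20
  expect_true(any(hi))
  expect_lt(max(abs(s2[hi] / (mu[hi] + 0.15 * mu[hi]^2) - 1)), 0.35)
  # dispersion -> 0: variance/mean ratio -> 1 (Poisson limit)
  tp <- make_truth(n_genes = 300, n_signature = 0, nb_dispersion = 1e-6,
                   seed = 17)
  bp <- gen_bulk_counts(tp, n_per_group = 500, depth = 5e4)
  vp <- bp$values[, bp$column_meta$condition == "control"]
  mup <- rowMeans(vp); s2p <- apply(vp, 1, var)
  hip <- mup > 20
  expect_lt(max(abs(s2p[hip] / mup[hip] - 1)), 0.25)
})

test_that("single-nucleus generator shifts only disease microglia", {
  one_type <- make_truth(
    n_genes = 200, n_signature = 5, seed = 18,
    cell_type_props = c(microglia = 1, astrocyte = 0, neuron = 0,
                        oligodendrocyte = 0, endothelial = 0))
  sn1 <- gen_sn_counts(one_type, donors_per_group = 2, cells_per_donor = 10)
  expect_true(all(sn1$column_meta$cell_type == "microglia"))

  truth <- make_truth(n_genes = 300, n_signature = 10, seed = 19)
  sn <- gen_sn_counts(truth, donors_per_group = 4, cells_per_donor = 150)
  meta <- sn$column_meta
  sig <- truth$signature
  ratio_for <- function(type) {
    d <- rowMeans(sn$values[sig$gene, meta$cell_type == type &
                              meta$condition == "disease", drop = FALSE])
    c_ <- rowMeans(sn$values[sig$gene, meta$cell_type == type &
                               meta$condition == "control", drop = FALSE])
    log2((d + 0.1) / (c_ + 0.1)) * sig$direction
  }
  expect_gt(mean(ratio_for("microglia")), 1)        # shifted toward 2^2
  expect_lt(abs(mean(ratio_for("astrocyte"))), 0.5) # unshifted
  # degenerate: zero cells still yields a valid empty container
  empty <- gen_sn_counts(truth, donors_per_group = 2, cells_per_donor = 0)
  expect_equal(ncol(empty$values), 0)
  expect_equal(nrow(empty$values), 300)
  expect_equal(nrow(empty$column_meta), 0)
})

test_that("spatial generator hits the dominant fraction and plants the consensus class", {
  truth <- make_truth(n_genes = 300, n_signature = 8, dominant_fraction = 0.6,
                      seed = 20)
  sp <- gen_spatial(truth, n_cells = 80, field = c(300, 300), depth = 120)
  dom_share <- mean(sp$transcripts$gene == truth$dominant_gene$gene)
  expect_gte(dom_share, 0.55)
  expect_lte(dom_share, 0.65)
  # every transcript's gene belongs to the 100-gene panel
  expect_true(all(sp$transcripts$gene %in% sp$panel))
  # mask labels are exactly 1..n_cells and each cell occupies pixels
  expect_setequal(sort(unique(as.vector(sp$mask[sp$mask > 0]))), 1:80)
  # classes: control microglia healthy, non-microglia NA
  expect_true(all(is.na(sp$cells$class[sp$cells$cell_type != "microglia"])))
  expect_true(all(sp$cells$class[sp$cells$cell_type == "microglia" &
                                   sp$cells$condition == "control"] == "healthy"))
  # consensus_fraction 0 plants no consensus cells
  t0 <- make_truth(n_genes = 300, n_signature = 8, consensus_fraction = 0,
                   seed = 20)
  sp0 <- gen_spatial(t0, n_cells = 60, field = c(300, 300), depth = 60)
  expect_equal(sum(sp0$cells$class == "consensus", na.rm = TRUE), 0)
  # an unpackable field errors out
  expect_error(gen_spatial(truth, n_cells = 500, field = c(100, 100)),
               "pack")
})

test_that("expected planted consensus count follows the binomial arithmetic", {
  expect_equal(0.054 * 653, 35.262, tolerance = 1e-9)
  plan <- data.frame(condition = "disease", cell_type = "microglia", n = 653)
  truth <- make_truth(n_genes = 300, n_signature = 8, seed = 22)
  sp <- gen_spatial(truth, cell_plan = plan, field = c(900, 900), depth = 60)
  n_cons <- sum(sp$cells$class == "consensus", na.rm = TRUE)
  expect_gte(n_cons, qbinom(0.005, 653, 0.054))
  expect_lte(n_cons, qbinom(0.995, 653, 0.054))
})

test_that("gene-set generator seeds the signature into the planted sets only", {
  truth <- make_truth(n_genes = 500, n_signature = 12, seed = 24)
  sets <- gen_gene_sets(truth, n_sets = 20, n_planted = 4, set_size = 15)
  planted <- attr(sets, "planted")
  expect_length(planted, 4)
  in_planted <- unique(unlist(sets[planted]))
  expect_true(all(truth$signature$gene %in% in_planted))
  other <- unique(unlist(sets[setdiff(names(sets), planted)]))
  expect_false(any(truth$signature$gene %in% other))
  expect_true(all(lengths(sets) == 15))
})
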