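test_that("ssGSEA score matches hand evaluation and extremal placement", {
  # universe of 4, single member at the top rank, unweighted (alpha 0):
  # running sum contributes 1 + 2/3 + 1/3 + 0 = 2
  expr <- c(a = 4, b = 3, c = 2, d = 1)
  expect_equal(ssgsea_score(expr, "a", alpha_weight = 0), 2)
  expect_error(ssgsea_score(expr, c("a", "b", "c", "d")), "universe")
  expect_error(ssgsea_score(expr, "zz"), "intersection")

  # members occupying the top |set| ranks maximize the score
  set.seed(5)
  universe <- paste0("g", 1:50)
  expr2 <- setNames(sort(runif(50), decreasing = TRUE), universe)
  top_score <- ssgsea_score(expr2, universe[1:5])
  rand <- replicate(200, ssgsea_score(expr2, sample(universe, 5)))
  expect_true(all(rand <= top_score + 1e-9))
})

test_that("unweighted ssGSEA null scores center on zero", {
  # the unweighted running sum has exact null mean 0; the rank-weighted
  # variant (alpha > 0) is known to carry a positive offset, so centering
  # is asserted for alpha = 0
  set.seed(6)
  universe <- paste0("g", 1:500)
  expr <- setNames(rnorm(500), universe)
  scores <- replicate(1000, ssgsea_score(expr, sample(universe, 10),
                                         alpha_weight = 0))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 2 * se + 0.05 * sd(scores))
})

test_that("ORA handles empty queries, disjoint sets and embeds the hypergeometric", {
  de <- data.frame(gene = paste0("g", 1:10), log2fc = 1, p = 1, q = 1,
                   direction = 1L, test = "wilcoxon")
  sets <- list(A = paste0("g", 1:3))
  res <- ora(de, sets, universe = de$gene)
  expect_equal(res$p, 1)
  expect_equal(res$q, 1)
  expect_warning(ora(de, list(A = "zz", B = "g1"), universe = de$gene),
                 "disjoint")
  # the k=K=n=5, N=10 enumeration case embedded in a one-set run
  de2 <- de
  de2$q <- c(rep(0.01, 5), rep(1, 5))
  res2 <- ora(de2, list(S = paste0("g", 1:5)), universe = de$gene)
  expect_equal(res2$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_setequal(res2$overlap_genes[[1]], paste0("g", 1:5))
})

test_that("consensus construction enforces the shared-set and direction rules", {
  mk_de <- function(sig_genes, dirs, universe) {
    data.frame(gene = universe, log2fc = ifelse(universe %in% sig_genes,
                                                dirs[match(universe, sig_genes)], 0.01),
               p = ifelse(universe %in% sig_genes, 1e-6, 0.9),
               q = ifelse(universe %in% sig_genes, 1e-5, 0.95),
               direction = as.integer(sign(ifelse(universe %in% sig_genes,
                                                  dirs[match(universe, sig_genes)], 1))),
               test = "wilcoxon")
  }
  universe <- paste0("g", 1:40)
  sets <- list(S1 = paste0("g", 1:8), S2 = paste0("g", 9:16),
               S3 = paste0("g", 33:40))
  # S1 significant in both modalities; S2 only in bulk; S3 in neither
  de_b <- mk_de(paste0("g", c(1:5, 9:12)), rep(1, 9), universe)
  de_s <- mk_de(paste0("g", 1:6), rep(1, 6), universe)
  sig <- build_consensus_signature(de_b, de_s, sets, alpha = 0.05)
  expect_setequal(sig$entries$gene, paste0("g", 1:6))
  expect_equal(sig$provenance$shared_sets, "S1")
  expect_true(all(vapply(sig$entries$sets, function(s) "S1" %in% s, TRUE)))
  # support reflects which modalities called each gene
  sup <- sig$entries$support[match(paste0("g", c(1, 6)), sig$entries$gene)]
  expect_setequal(sup[[1]], c("bulk", "sn"))
  expect_equal(sup[[2]], "sn")

  # conflicting directions exclude the gene and log it
  de_s2 <- mk_de(paste0("g", 1:6), c(1, 1, -1, 1, 1, 1), universe)
  sig2 <- build_consensus_signature(de_b, de_s2, sets, alpha = 0.05)
  expect_false("g3" %in% sig2$entries$gene)
  expect_equal(sig2$conflicts, "g3")

  # no shared set: empty signature with a warning, not an error
  de_s3 <- mk_de("g35", 1, universe)
  expect_warning(sig3 <- build_consensus_signature(de_b, de_s3, sets),
                 "no shared")
  expect_equal(nrow(sig3$entries), 0)
})

test_that("signature is invariant to set order and renaming; alpha tightening shrinks it", {
  truth <- make_truth(seed = 42)
  bulk <- gen_bulk_counts(truth)
  de_b <- de_table(bulk, bulk$column_meta$condition, method = "nb_lrt")
  sn <- gen_sn_counts(truth)
  mg <- subset_counts(sn, cols = which(sn$column_meta$cell_type == "microglia"))
  de_s <- de_table(mg, mg$column_meta$condition, method = "wilcoxon",
                   min_prop = 0.1, normalize = "libsize")
  sets <- gen_gene_sets(truth)
  s1 <- build_consensus_signature(de_b, de_s, sets)
  perm <- sets[rev(seq_along(sets))]
  s2 <- build_consensus_signature(de_b, de_s, perm)
  expect_equal(s1$entries$gene, s2$entries$gene)
  expect_equal(s1$entries$direction, s2$entries$direction)
  renamed <- sets
  names(renamed) <- paste0("X_", names(sets))
  s3 <- build_consensus_signature(de_b, de_s, renamed)
  expect_equal(s1$entries$gene, s3$entries$gene)
  # anti-monotonicity across an alpha grid
  prev <- s1$entries$gene
  for (a in c(0.02, 0.01, 0.005)) {
    cur <- suppressWarnings(
      build_consensus_signature(de_b, de_s, sets, alpha = a))$entries$gene
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})
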