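sig2 <- function() {
  entries <- data.frame(gene = c("up1", "dn1"), direction = c(1L, -1L))
  entries$support <- list("bulk", "bulk")
  entries$sets <- list("S", "S")
  pdmg:::new_signature(entries, alpha_used = 0.05)
}

test_that("concordance classification follows the sign-agreement rule", {
  sig <- sig2()
  ref <- c(up1 = 2, dn1 = 2, other = 1)
  vals <- cbind(
    at_ref = c(2, 2, 1),          # zero deviations -> C = 0
    perfect = c(3, 1, 1),         # +1 on up, -1 on down -> C = 1
    half = c(3, 3, 1))            # up agrees, down disagrees -> C = 0.5
  rownames(vals) <- names(ref)
  res <- classify_consensus(vals, sig, ref, tau = 1)
  expect_equal(res$class, c("non-consensus", "consensus", "non-consensus"))
  expect_equal(res$concordance, c(0, 1, 0.5))
  expect_equal(res$n_evaluable, rep(2L, 3))
  # boundary behavior in tau: C >= 0 holds for every cell, and in
  # particular every cell with at least one agreement is consensus
  res0 <- classify_consensus(vals, sig, ref, tau = 0)
  expect_true(all(res0$class[res0$concordance > 0] == "consensus"))
  expect_true(all(res0$class == "consensus"))  # literal C >= tau rule
  res_hi <- classify_consensus(vals, sig, ref, tau = 1.01)
  expect_true(all(res_hi$class == "non-consensus"))
  # epsilon imposes a deviation magnitude threshold
  res_eps <- classify_consensus(vals, sig, ref, tau = 1, epsilon = 1.5)
  expect_true(all(res_eps$class == "non-consensus"))
  empty <- pdmg:::new_signature(
    {e <- data.frame(gene = character(), direction = integer())
     e$support <- list(); e$sets <- list(); e}, alpha_used = 0.05)
  expect_error(classify_consensus(vals, empty, ref), "empty signature")
})

test_that("spatial classification is invariant to per-cell depth rescaling", {
  truth <- make_truth(n_genes = 300, n_signature = 6, seed = 40)
  plan <- data.frame(condition = c("disease", "control"),
                     cell_type = c("microglia", "microglia"), n = c(40, 40))
  sp <- gen_spatial(truth, cell_plan = plan, field = c(400, 400), depth = 100)
  flt <- high_abundance_filter(sp$transcripts)
  asn <- assign_transcripts(flt$data, sp$mask)
  meta <- sp$cells[, c("condition", "cell_type")]
  sig <- truth_signature(truth)
  base <- classify_spatial_cells(asn$counts, meta, sig)
  scaled <- asn$counts
  scaled[, 3] <- scaled[, 3] * 4   # quadruple one cell's depth
  rescaled <- classify_spatial_cells(scaled, meta, sig)
  expect_equal(base$class, rescaled$class)
  expect_equal(base$concordance, rescaled$concordance)
  expect_error(classify_spatial_cells(
    asn$counts, transform(meta, condition = "disease"), sig), "control microglia")
})

test_that("consensus percentage and distribution percentages do their arithmetic", {
  expect_equal(consensus_percentage(35, 653), 100 * 35 / 653)
  expect_equal(round(consensus_percentage(35, 653), 1), 5.4)
  expect_error(consensus_percentage(5, 0))
  pct <- distribution_percentage(rbind(g1 = c(2, 1, 1), g2 = c(0, 0, 5),
                                       g3 = c(1, 1, 1), g4 = c(0, 0, 0)))
  expect_equal(unname(pct["g1", ]), c(50, 25, 25))
  expect_equal(unname(pct["g2", ]), c(0, 0, 100))
  expect_equal(sum(pct["g3", ]), 100, tolerance = 1e-6)
  expect_true(all(is.na(pct["g4", ])))
  expect_error(distribution_percentage(rbind(c(-1, 2, 3))), "non-negative")
})

test_that("presence flags and categories reflect the detection pattern", {
  classes <- rep(c("healthy", "consensus", "non-consensus"), each = 10)
  counts <- rbind(
    nowhere = rep(0, 30),
    healthy_only = c(rep(5, 10), rep(0, 20)),
    not_in_consensus = c(rep(5, 10), rep(0, 10), rep(5, 10)),
    everywhere = rep(3, 30))
  colnames(counts) <- paste0("c", 1:30)
  res <- class_specific_genes(counts, classes)
  expect_equal(unname(res$category["nowhere"]), "none")
  expect_equal(unname(res$category["healthy_only"]), "class-specific:healthy")
  expect_equal(unname(res$category["not_in_consensus"]), "class-absent:consensus")
  expect_equal(unname(res$category["everywhere"]), "all-classes")
  expect_error(class_specific_genes(
    counts[, 1:20], factor(rep(c("a", "b"), each = 10),
                           levels = c("a", "b", "c"))),
    "empty class")
})

test_that("planted class-restricted genes are categorized reliably", {
  set.seed(41)
  ok <- replicate(20, {
    classes <- rep(c("healthy", "consensus", "non-consensus"), c(40, 15, 40))
    n <- length(classes)
    counts <- rbind(
      base1 = rpois(n, 20), base2 = rpois(n, 10),
      nc_only = ifelse(classes == "non-consensus", rpois(n, 6), 0),
      no_cons = ifelse(classes == "consensus", 0, rpois(n, 6)))
    colnames(counts) <- paste0("c", 1:n)
    res <- class_specific_genes(counts, classes)
    res$category[["nc_only"]] == "class-specific:non-consensus" &&
      res$category[["no_cons"]] == "class-absent:consensus"
  })
  expect_gte(mean(ok), 0.95)
})

test_that("pairwise class DE is null on copied classes and flags planted shifts", {
  set.seed(43)
  half <- matrix(rpois(20 * 25, 15), 20, 25)
  counts <- cbind(half, half)   # two identical "classes"
  rownames(counts) <- paste0("g", 1:20)
  colnames(counts) <- paste0("c", 1:50)
  de <- class_de(counts, rep(c("healthy", "consensus"), each = 25))
  expect_length(de, 1)
  expect_equal(sum(de[[1]]$q < 0.05), 0)
  expect_true(all(de[[1]]$q >= de[[1]]$p - 1e-12))
  expect_equal(de[[1]]$direction, as.integer(sign(de[[1]]$log2fc)))
  expect_error(class_de(counts[, 1:26], rep(c("a", "b"), c(25, 1))),
               "2 cells")
  # a consensus-enriched gene reaches significance in most replicates
  hits <- replicate(20, {
    classes <- rep(c("healthy", "consensus"), c(30, 30))
    cnt <- rbind(flat = rpois(60, 10),
                 up = rpois(60, ifelse(classes == "consensus", 40, 10)))
    colnames(cnt) <- paste0("c", 1:60)
    d <- class_de(cnt, classes)[["consensus_vs_healthy"]]
    d$q[d$gene == "up"] < 0.05 && d$direction[d$gene == "up"] == 1L
  })
  expect_gte(mean(hits), 0.9)
})

test_that("class summary combines percentages, presence and DE categories", {
  set.seed(44)
  classes <- rep(c("healthy", "consensus", "non-consensus"), each = 30)
  n <- length(classes)
  counts <- rbind(
    flat = rpois(n, 20),
    cons_up = rpois(n, ifelse(classes == "consensus", 80, 10)),
    nc_down = rpois(n, ifelse(classes == "non-consensus", 2, 25)),
    h_only = ifelse(classes == "healthy", rpois(n, 8), 0))
  colnames(counts) <- paste0("c", 1:n)
  res <- class_summary(counts, classes)
  s <- res$summary
  expect_equal(s$category[s$gene == "cons_up"], "consensus-enriched")
  expect_equal(s$category[s$gene == "nc_down"], "non-consensus-depleted")
  expect_equal(s$category[s$gene == "h_only"], "class-specific:healthy")
  pct_cols <- grep("^pct_", names(s))
  sums <- rowSums(s[, pct_cols])
  expect_true(all(abs(sums - 100) < 1e-6))
})
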