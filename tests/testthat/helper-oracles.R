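# Independent oracles and small fixture builders shared across tests.
# Each oracle is written from the defining formula, independently of the
# package implementation it checks.

# Wilcoxon: U by direct pair counting and p by full enumeration over all
# assignments of the pooled values to the two groups.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- oracle_u(x, y)
  us <- apply(utils::combn(length(pooled), nx), 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Hypergeometric upper tail by brute-force pmf summation.
oracle_hyper_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Poisson likelihood ratio statistic for two groups (closed form).
oracle_poisson_lrt <- function(x, y) {
  sx <- sum(x); sy <- sum(y); s <- sx + sy
  m1 <- mean(x); m2 <- mean(y); m <- s / (length(x) + length(y))
  term <- function(s_, m_) if (s_ > 0) s_ * log(m_) else 0
  2 * (term(sx, m1) + term(sy, m2) - term(s, m))
}

# TMM factor for one column vs a reference, coded from the published
# trimmed weighted-mean formula (double trim on M and A, inverse
# asymptotic-variance weights).
oracle_tmm_one <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  nO <- sum(obs); nR <- sum(ref)
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  m <- log2((obs / nO) / (ref / nR))
  a <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

# Nearest-labeled-pixel assignment by exhaustive search over all labeled
# pixels (ties resolved to the lowest label).
oracle_assign <- function(transcripts, mask, expansion) {
  lab_px <- which(mask > 0, arr.ind = TRUE)
  labs <- mask[lab_px]
  vapply(seq_len(nrow(transcripts)), function(i) {
    r <- floor(transcripts$y[i]) + 1L
    c_ <- floor(transcripts$x[i]) + 1L
    if (r < 1 || r > nrow(mask) || c_ < 1 || c_ > ncol(mask)) return(0L)
    if (mask[r, c_] > 0) return(mask[r, c_])
    d <- sqrt((lab_px[, 1] - r)^2 + (lab_px[, 2] - c_)^2)
    ok <- d <= expansion
    if (!any(ok)) return(0L)
    dmin <- min(d[ok])
    as.integer(min(labs[ok & abs(d - dmin) < 1e-9]))
  }, 0L)
}

# Dirichlet draw via normalized gamma variates.
rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# Adjusted Rand index (pair-counting formula).
ari <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  n <- length(a)
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Fixtures ------------------------------------------------------------------

toy_counts <- function(values, genes = NULL, cols = NULL, meta = NULL) {
  values <- as.matrix(values)
  if (is.null(genes))
    genes <- rownames(values) %||% sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cols))
    cols <- colnames(values) %||% sprintf("s%d", seq_len(ncol(values)))
  count_matrix(values, genes, cols, column_meta = meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a planted truth's signature as a consensus_signature object, for
# tests that isolate classification from signature recovery.
truth_signature <- function(truth) {
  n <- nrow(truth$signature)
  entries <- data.frame(gene = truth$signature$gene,
                        direction = truth$signature$direction)
  entries$support <- replicate(n, list("bulk"))
  entries$sets <- replicate(n, list("planted"))
  pdmg:::new_signature(entries, alpha_used = 0.05)
}

# A small two-class spatial scene used by several spatial tests.
tiny_scene <- function() {
  mask <- matrix(0L, 6, 6)
  mask[2:3, 2:3] <- 1L
  mask[5:6, 5:6] <- 2L
  tx <- data.frame(
    x = c(1.5, 2.1, 4.7, 5.5, 0.2, 3.4, 2.5, 5.1, 1.1, 4.2, 3.9, 0.7),
    y = c(1.5, 2.6, 4.8, 5.2, 0.3, 3.1, 1.2, 4.6, 4.9, 0.8, 3.8, 5.8),
    gene = rep(c("CAT", "TNF", "GFAP"), 4))
  list(mask = mask, transcripts = tx)
}
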