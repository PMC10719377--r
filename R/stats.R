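# Statistical kernels: exact/approximate Wilcoxon rank sum, negative
# binomial likelihood ratio test, BH FDR, hypergeometric upper tail,
# Spearman correlation, and the per-gene DE driver.

mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon rank sum test with exact tie handling
#'
#' The statistic U is the number of pairs (x_i, y_j) with x_i > y_j plus half
#' the tied pairs. The exact path enumerates all assignments of the pooled
#' values to the two groups (correct under ties); the approximate path uses
#' the normal approximation with tie-corrected variance and continuity
#' correction. `mode = "auto"` uses the exact path when
#' `length(x) + length(y) <= 14` and there are no ties.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode One of `"auto"`, `"exact"`, `"approx"`.
#' @return List with `U` and two-sided `p` (in (0, 1]).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- mann_whitney_u(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto") mode <- if (n <= 14 && !ties) "exact" else "approx"
  if (mode == "exact") {
    pooled <- c(x, y)
    combs <- utils::combn(n, nx)
    us <- apply(combs, 2, function(idx)
      mann_whitney_u(pooled[idx], pooled[-idx]))
    # two-sided exact p: 2 * min(tail probabilities), clipped at 1
    tol <- 1e-9
    p_lo <- mean(us <= u + tol)
    p_hi <- mean(us >= u - tol)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, p = max(p, .Machine$double.xmin))
}

nb_loglik <- function(y, mu, dispersion) {
  if (dispersion < 1e-12)
    sum(stats::dpois(y, lambda = pmax(mu, 1e-300), log = TRUE))
  else
    sum(stats::dnbinom(y, size = 1 / dispersion, mu = pmax(mu, 1e-300), log = TRUE))
}

nb_fit_mean <- function(y, offsets, dispersion) {
  # maximise the NB log-likelihood over a single log-scale intercept
  # (log link, fixed offsets, fixed dispersion)
  if (sum(y) == 0) return(list(beta = -Inf, ll = 0))
  beta0 <- log(sum(y) / sum(exp(offsets)))
  opt <- stats::optimize(function(b) nb_loglik(y, exp(b + offsets), dispersion),
                         interval = c(beta0 - 15, beta0 + 15), maximum = TRUE,
                         tol = 1e-9)
  list(beta = opt$maximum, ll = opt$objective)
}

#' Negative binomial likelihood ratio test for two groups
#'
#' Compares an NB model with one mean per group against a common-mean model,
#' both with a log link, fixed per-column offsets (log library sizes) and a
#' shared dispersion. The statistic is referred to chi-squared with 1 df.
#'
#' @param counts_x,counts_y Integer count vectors for the two groups.
#' @param offsets Log-scale offsets, `c(offsets_x, offsets_y)`; default 0.
#' @param dispersion NB dispersion phi (> 0, variance mu + phi mu^2).
#' @return List with `lrt` and `p`; an all-zero gene gives `lrt = 0, p = 1`.
#' @export
nb_lrt_test <- function(counts_x, counts_y, offsets = NULL, dispersion) {
  y <- c(counts_x, counts_y)
  if (is.null(offsets)) offsets <- rep(0, length(y))
  stopifnot(length(offsets) == length(y), dispersion > 0)
  if (sum(y) == 0) return(list(lrt = 0, p = 1))
  grp <- rep(1:2, c(length(counts_x), length(counts_y)))
  ll0 <- nb_fit_mean(y, offsets, dispersion)$ll
  ll1 <- nb_fit_mean(counts_x, offsets[grp == 1], dispersion)$ll +
         nb_fit_mean(counts_y, offsets[grp == 2], dispersion)$ll
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  list(lrt = lrt, p = max(min(p, 1), .Machine$double.xmin))
}

#' Pooled method-of-moments NB dispersion
#'
#' Per gene, the within-group moments give phi = (var - mean) / mean^2 on
#' offset-adjusted counts; the pooled estimate is the median over genes with
#' a positive estimate, floored at `floor_value`.
#'
#' @param m A [count_matrix()].
#' @param groups Group labels per column.
#' @param offsets Log-scale offsets (default log library size, centered).
#' @param floor_value Lower bound for the pooled estimate.
#' @return A single dispersion value.
#' @export
estimate_dispersion <- function(m, groups, offsets = NULL, floor_value = 1e-4) {
  v <- m$values
  if (is.null(offsets)) {
    ls <- lib_sizes(m)
    offsets <- log(ls) - mean(log(ls))
  }
  adj <- sweep(v, 2, exp(offsets), "/")
  ests <- unlist(lapply(unique(groups), function(g) {
    a <- adj[, groups == g, drop = FALSE]
    if (ncol(a) < 2) return(numeric())
    mu <- rowMeans(a)
    s2 <- apply(a, 1, stats::var)
    ok <- mu > 0
    (s2[ok] - mu[ok]) / mu[ok]^2
  }))
  ests <- ests[is.finite(ests) & ests > 0]
  if (!length(ests)) return(floor_value)
  max(floor_value, stats::median(ests))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) p_(j) * m / j`, clipped at 1,
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric upper-tail test
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the chance of at least `k`
#' overlaps when drawing `n` query genes from a universe of `N` containing a
#' set of size `K`.
#'
#' @param k Observed overlap.
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank vectors (average ranks for ties).
#' Undefined for a constant vector: returns `NA` with a warning.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return rho in \[-1, 1\], or `NA` when undefined.
#' @export
spearman_corr <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) stop("need equal lengths >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("Spearman correlation undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Per-gene differential expression table
#'
#' Filters lowly expressed genes, normalizes internally (TMM log2-CPM for the
#' Wilcoxon path; TMM-scaled library offsets for the NB LRT path), tests each
#' gene, and applies BH FDR. `log2fc` is the difference of group mean
#' log2-CPM, second contrast level minus first (disease minus control).
#'
#' @param m A [count_matrix()].
#' @param groups Group labels per column (exactly 2 groups).
#' @param method `"wilcoxon"` or `"nb_lrt"`.
#' @param alpha Significance threshold recorded with the table.
#' @param contrast Character pair `c(control, disease)`; defaults to the
#'   sorted unique group labels.
#' @param dispersion Optional NB dispersion; pooled method-of-moments
#'   estimate when `NULL`.
#' @param min_cpm,min_prop Passed to [filter_low_expressed()].
#' @param normalize `"tmm"` (bulk convention) or `"libsize"` (per-column
#'   totals only — the single-cell convention, where TMM's reference-column
#'   choice across sparse cells is unstable).
#' @return `data.frame` with columns `gene, log2fc, p, q, direction, test`
#'   and attribute `alpha`.
#' @export
de_table <- function(m, groups, method = c("wilcoxon", "nb_lrt"), alpha = 0.05,
                     contrast = NULL, dispersion = NULL,
                     min_cpm = 1, min_prop = 0.7,
                     normalize = c("tmm", "libsize")) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  empty <- data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      q = numeric(), direction = integer(), test = character())
  attr(empty, "alpha") <- alpha
  if (!nrow(m$values) || !ncol(m$values)) return(empty)
  groups <- as.character(groups)
  if (is.null(contrast)) contrast <- sort(unique(groups))
  if (length(contrast) != 2 || !all(groups %in% contrast))
    stop("exactly two groups are required")
  ix <- groups == contrast[1]; iy <- groups == contrast[2]
  if (method == "nb_lrt" && (sum(ix) < 2 || sum(iy) < 2))
    stop("nb_lrt needs at least 2 columns per group")
  mf <- filter_low_expressed(m, groups, min_cpm = min_cpm, min_prop = min_prop)
  if (!nrow(mf$values)) return(empty)
  factors <- if (normalize == "tmm") tmm_factors(mf)
             else rep(1, ncol(mf$values))
  lc <- log_cpm(mf, factors)
  log2fc <- rowMeans(lc[, iy, drop = FALSE]) - rowMeans(lc[, ix, drop = FALSE])
  if (method == "wilcoxon") {
    p <- vapply(seq_len(nrow(lc)), function(i)
      wilcoxon_rank_sum(lc[i, ix], lc[i, iy])$p, 0)
  } else {
    if (is.null(dispersion)) dispersion <- estimate_dispersion(mf, groups)
    offs <- log(lib_sizes(mf) * factors)
    v <- mf$values
    p <- vapply(seq_len(nrow(v)), function(i)
      nb_lrt_test(v[i, ix], v[i, iy], offsets = c(offs[ix], offs[iy]),
                  dispersion = dispersion)$p, 0)
  }
  out <- data.frame(gene = genes(mf), log2fc = log2fc, p = p, q = bh_fdr(p),
                    direction = as.integer(sign(log2fc)), test = method,
                    row.names = NULL)
  attr(out, "alpha") <- alpha
  out
}
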