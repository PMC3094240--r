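# Statistics layer. The headline statistic is the posterior probability that
# a gene is at least k-fold upregulated in pool A relative to pool B. With
# uniform priors on the per-sequence abundances p_A and p_B, the posteriors
# given counts a of A and b of B are independent Beta(a+1, A-a+1) and
# Beta(b+1, B-b+1), and
#
#   P = Pr(p_A >= k * p_B)
#     = \int_0^1 f_B(x) [1 - F_A(min(1, k x))] dx
#     = \int_0^1 [1 - F_A(min(1, k Q_B(u)))] du        (u = F_B(x))
#
# where F/Q are the Beta CDF and quantile. The quantile substitution absorbs
# the sharply peaked posterior density into the integration variable, so a
# fixed 32-point Gauss-Legendre rule stays accurate even for pool totals in
# the thousands. The Monte-Carlo sampler prob_fold_mc_oracle() is the ground
# truth the quadrature is verified against. Because every statistic is
# computed on the full gene list before any display filtering, display
# cut-offs can never change a reported value.

.gl_cache <- new.env(parent = emptyenv())

# n-point Gauss-Legendre nodes and weights on [0, 1], cached per n.
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

check_fold_args <- function(a, A, b, B, k) {
  if (A < 1 || B < 1) stop("pool totals A and B must be >= 1", call. = FALSE)
  if (a < 0 || b < 0) stop("gene counts must be non-negative", call. = FALSE)
  if (a > A || b > B) stop("gene count exceeds pool total", call. = FALSE)
  if (k < 1) stop("fold threshold k must be >= 1", call. = FALSE)
}

#' Posterior probability of at least k-fold upregulation
#'
#' Probability that the pool-A per-sequence abundance of a gene is at least
#' `k` times its pool-B abundance, under independent Beta posteriors
#' `Beta(a+1, A-a+1)` and `Beta(b+1, B-b+1)` (uniform priors). The defining
#' integral is evaluated with an `n_points`-point Gauss-Legendre rule; the
#' result is clamped to `[0, 1]`. The value is a pure function of the four
#' counts and `k` — it does not depend on any display cut-off.
#'
#' Reported on a 0-to-1 scale: a gene with a 95% posterior probability of
#' `k`-fold upregulation gets `P = 0.95`; values closest to one are the most
#' significant.
#'
#' @param a,b Per-gene sequence counts in pools A and B.
#' @param A,B Pool total sequence counts (both >= 1).
#' @param k Fold threshold, >= 1; default 3 (threefold upregulation).
#' @param n_points Number of quadrature nodes; default 32.
#' @return Probability in `[0, 1]`.
#' @seealso [prob_fold_mc_oracle()] for the Monte-Carlo cross-check.
#' @export
#' @examples
#' prob_fold_upregulation(50, 1000, 50, 1000, k = 1)  # symmetric: 0.5
#' prob_fold_upregulation(90, 1000, 3, 1000, k = 3)
prob_fold_upregulation <- function(a, A, b, B, k = 3, n_points = 32L) {
  check_fold_args(a, A, b, B, k)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  gl <- gauss_legendre_01(n_points)
  qb <- stats::qbeta(gl$x, b + 1, B - b + 1)
  surv <- 1 - stats::pbeta(pmin(1, k * qb), a + 1, A - a + 1)
  min(1, max(0, sum(gl$w * surv)))
}

#' Monte-Carlo oracle for the fold-upregulation probability
#'
#' Draws `n_samples` independent pairs from the two Beta posteriors and
#' returns the fraction with `p_A >= k * p_B`. Deterministic for a fixed
#' `seed`; the caller's RNG state is left untouched. Standard error is
#' approximately `sqrt(P(1-P)/n_samples)`.
#'
#' @inheritParams prob_fold_upregulation
#' @param n_samples Number of posterior draws, >= 1.
#' @param seed Integer seed.
#' @export
prob_fold_mc_oracle <- function(a, A, b, B, k = 3, n_samples = 1e5, seed = 1L) {
  check_fold_args(a, A, b, B, k)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  with_seed(seed, {
    pa <- stats::rbeta(n_samples, a + 1, A - a + 1)
    pb <- stats::rbeta(n_samples, b + 1, B - b + 1)
    mean(pa >= k * pb)
  })
}

#' Fisher exact test for a pool-count 2x2 table
#'
#' Tests the table `[[a, A-a], [b, B-b]]`. The two-sided p-value follows the
#' minimum-likelihood convention: conditioning on the margins, it sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (with the customary `1 + 1e-7` relative tolerance on the
#' comparison). `alternative = "greater"` gives the one-sided upper tail in
#' `a`.
#'
#' @inheritParams prob_fold_upregulation
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact <- function(a, A, b, B, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b) < 0) || a > A || b > B) {
    stop("invalid 2x2 table: need 0 <= a <= A and 0 <= b <= B", call. = FALSE)
  }
  m <- a + b                 # first-column margin
  n2 <- (A - a) + (B - b)    # second-column margin
  support <- max(0L, A - n2):min(A, m)
  d <- stats::dhyper(support, m, n2, A)
  obs <- d[match(a, support)]
  p <- if (alternative == "greater") {
    sum(d[support >= a])
  } else {
    sum(d[d <= obs * (1 + 1e-7)])
  }
  min(1, p)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment, returned in input order. The pipeline
#' always passes the complete gene list through this function before any
#' display filtering, so q-values are independent of display cut-offs. `NA`
#' p-values (undefined statistics, e.g. an empty pool) propagate as `NA`;
#' non-`NA` values outside `(0, 1]` are an error.
#'
#' @param pvals Numeric p-values in `(0, 1]` (or `NA`).
#' @return q-values in `(0, 1]`, same length and order.
#' @export
bh_qvalues <- function(pvals) {
  ok <- is.na(pvals) | (pvals > 0 & pvals <= 1)
  if (!all(ok)) {
    stop("p-values must lie in (0, 1]: offending value ",
         pvals[!ok][1L], call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Statistics configuration
#'
#' @param fold_k Fold threshold for [prob_fold_upregulation()]; default 3.
#' @param quadrature_points Gauss-Legendre node count; default 32.
#' @param f_cutoff,p_cutoff,q_cutoff Display cut-offs (`NULL` = off): keep
#'   rows with `F >= f_cutoff`, `P >= p_cutoff`, `q <= q_cutoff`.
#' @param two_sided If `TRUE`, the F cut-off also keeps `F <= 1/f_cutoff`
#'   (downregulation).
#' @param pseudocount Pseudocount for [odds_ratio()]; default 0.
#' @param mc_samples,seed Monte-Carlo oracle settings.
#' @return A `stat_config` list.
#' @export
stat_config <- function(fold_k = 3, quadrature_points = 32L,
                        f_cutoff = NULL, p_cutoff = NULL, q_cutoff = NULL,
                        two_sided = FALSE, pseudocount = 0,
                        mc_samples = 1e5, seed = 1L) {
  if (fold_k < 1) stop("fold_k must be >= 1", call. = FALSE)
  if (quadrature_points < 2L) stop("quadrature_points must be >= 2", call. = FALSE)
  if (!is.null(f_cutoff) && f_cutoff < 0) stop("f_cutoff must be >= 0", call. = FALSE)
  for (cutoff in list(p_cutoff, q_cutoff)) {
    if (!is.null(cutoff) && (cutoff < 0 || cutoff > 1)) {
      stop("p/q cut-offs must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(fold_k = fold_k, quadrature_points = as.integer(quadrature_points),
                 f_cutoff = f_cutoff, p_cutoff = p_cutoff, q_cutoff = q_cutoff,
                 two_sided = two_sided, pseudocount = pseudocount,
                 mc_samples = mc_samples, seed = as.integer(seed)),
            class = "stat_config")
}

#' Compute all per-gene statistics on the full gene list
#'
#' Adds `F` (sequence odds ratio), `P` (posterior probability of `fold_k`-fold
#' upregulation), `p_fisher` and BH `q` columns. Statistics are computed for
#' every row before any display filtering. When either pool total is zero the
#' probability-based statistics are undefined and flagged `NA`.
#'
#' @param rows Tabulated gene rows ([tabulate_gene_counts()]).
#' @param config A [stat_config()].
#' @return `rows` with `F`, `P`, `p_fisher`, `q` columns added.
#' @export
compute_gene_stats <- function(rows, config = stat_config()) {
  n <- nrow(rows)
  if (n == 0L) {
    rows$F <- rows$P <- rows$p_fisher <- rows$q <- numeric(0)
    return(rows)
  }
  rows$F <- odds_ratio(rows$a, rows$A, rows$b, rows$B, config$pseudocount)
  defined <- rows$A >= 1L & rows$B >= 1L
  rows$P <- rows$p_fisher <- NA_real_
  rows$P[defined] <- vapply(which(defined), function(i) {
    prob_fold_upregulation(rows$a[i], rows$A[i], rows$b[i], rows$B[i],
                           k = config$fold_k, n_points = config$quadrature_points)
  }, numeric(1))
  rows$p_fisher[defined] <- vapply(which(defined), function(i) {
    fisher_exact(rows$a[i], rows$A[i], rows$b[i], rows$B[i])
  }, numeric(1))
  rows$q <- bh_qvalues(rows$p_fisher)
  rows
}

#' Apply display cut-offs to a statistics table
#'
#' A pure filter: rows survive when `F >= f_cutoff` (or `F <= 1/f_cutoff` too
#' in two-sided mode), `P >= p_cutoff` and `q <= q_cutoff`, for whichever
#' cut-offs are set. Statistics are never recomputed, so a gene's `P` and `q`
#' are bit-identical under every choice of display cut-off. `F = Inf` passes
#' any F cut-off; rows with undefined (`NaN`/`NA`) values fail a set cut-off.
#'
#' @param rows Gene rows carrying `F`, `P`, `p_fisher`, `q`.
#' @param config A [stat_config()].
#' @return The surviving subset of `rows`, untouched.
#' @export
apply_display_cutoffs <- function(rows, config = stat_config()) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(config$f_cutoff)) {
    f_ok <- !is.nan(rows$F) & rows$F >= config$f_cutoff
    if (isTRUE(config$two_sided) && config$f_cutoff > 0) {
      f_ok <- f_ok | (!is.nan(rows$F) & rows$F <= 1 / config$f_cutoff)
    }
    keep <- keep & f_ok
  }
  if (!is.null(config$p_cutoff)) {
    keep <- keep & !is.na(rows$P) & rows$P >= config$p_cutoff
  }
  if (!is.null(config$q_cutoff)) {
    keep <- keep & !is.na(rows$q) & rows$q <= config$q_cutoff
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
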