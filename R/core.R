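# Pool construction and per-gene tabulation across two library pools.
# Conventions throughout: lower-case a/b are per-gene sequence counts, upper
# case A/B are pool-total mapped sequence counts. The gene list is the union
# of all clusters present in at least one pool, and the per-pool column sums
# equal the pool totals by construction (the library-list / gene-list
# conservation property).

#' Build the two comparison pools
#'
#' @param selected_a,selected_b Disjoint `dged_libraries` selections with
#'   mapped counts computed ([compute_mapped_counts()]).
#' @return List with elements `A` and `B`, each a `library_pool`:
#'   `label`, `library_ids`, `total_sequences` (sum of member mapped counts).
#' @export
build_pools <- function(selected_a, selected_b) {
  overlap <- intersect(selected_a$library_id, selected_b$library_id)
  if (length(overlap)) {
    stop("pools overlap: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (anyNA(selected_a$mapped_sequences) || anyNA(selected_b$mapped_sequences)) {
    stop("mapped counts unset: run compute_mapped_counts() before build_pools()",
         call. = FALSE)
  }
  pool <- function(label, libs) {
    structure(list(label = label, library_ids = libs$library_id,
                   total_sequences = as.integer(sum(libs$mapped_sequences))),
              class = "library_pool")
  }
  list(A = pool("A", selected_a), B = pool("B", selected_b))
}

sum_counts_by_cluster <- function(expression, library_ids) {
  e <- expression[expression$library_id %in% library_ids, , drop = FALSE]
  if (!nrow(e)) return(integer(0))
  s <- tapply(e$count, e$cluster_id, sum)
  stats::setNames(as.integer(s), names(s))
}

#' Tabulate per-gene counts across two pools
#'
#' Produces one row per gene cluster present in at least one pool (union
#' semantics) with per-gene counts `a`, `b`, pool totals `A`, `B` and presence
#' flags. Rows are ordered by descending total abundance `a + b`, ties broken
#' by ascending `cluster_id`, so reports are reproducible.
#'
#' @param pools Pool pair from [build_pools()].
#' @param expression Full expression table.
#' @param genes Gene table; every cluster seen in the pool libraries must be
#'   present in it.
#' @return Data frame with columns `cluster_id`, `symbol`, `title`, `a`, `b`,
#'   `A`, `B`, `present_a`, `present_b`.
#' @export
tabulate_gene_counts <- function(pools, expression, genes) {
  ca <- sum_counts_by_cluster(expression, pools$A$library_ids)
  cb <- sum_counts_by_cluster(expression, pools$B$library_ids)
  clusters <- union(names(ca), names(cb))
  missing <- setdiff(clusters, genes$cluster_id)
  if (length(missing)) {
    stop("expression references cluster ids absent from the gene table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- ifelse(is.na(ca[clusters]), 0L, ca[clusters])
  b <- ifelse(is.na(cb[clusters]), 0L, cb[clusters])
  idx <- match(clusters, genes$cluster_id)
  rows <- data.frame(
    cluster_id = clusters,
    symbol = genes$symbol[idx],
    title = genes$title[idx],
    a = as.integer(a),
    b = as.integer(b),
    A = pools$A$total_sequences,
    B = pools$B$total_sequences,
    stringsAsFactors = FALSE
  )
  rows$present_a <- rows$a >= 1L
  rows$present_b <- rows$b >= 1L
  rows <- rows[order(-(rows$a + rows$b), rows$cluster_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Sequence odds ratio
#'
#' `F = (a/A) / (b/B)`, the ratio of a gene's relative abundance between the
#' two pools. Zero-count conventions (no pseudocount): `F = Inf` when the gene
#' is present only in pool A, `F = 0` when present only in pool B, and `NaN`
#' (undefined) when absent from both. With `pseudocount = c > 0` the ratio is
#' `((a+c)/(A+c)) / ((b+c)/(B+c))` and always finite.
#'
#' @param a,b Per-gene sequence counts in pools A and B.
#' @param A,B Pool total sequence counts.
#' @param pseudocount Non-negative constant added to every term; default 0.
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio <- function(a, A, b, B, pseudocount = 0) {
  if (any(c(a, A, b, B) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(a > A) || any(b > B)) stop("per-gene count exceeds pool total", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount > 0) {
    c0 <- pseudocount
    return(((a + c0) / (A + c0)) / ((b + c0) / (B + c0)))
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  A <- rep_len(A, n); B <- rep_len(B, n)
  f <- rep(NaN, n)
  both <- a >= 1L & b >= 1L
  f[both] <- (a[both] / A[both]) / (b[both] / B[both])
  f[a >= 1L & b == 0L] <- Inf
  f[a == 0L & b >= 1L] <- 0
  f
}

#' Pool-presence Venn partition
#'
#' @param rows Tabulated gene rows ([tabulate_gene_counts()]).
#' @return Named integer vector `c(both, only_a, only_b)`; the three cells
#'   partition the gene list.
#' @export
venn_counts <- function(rows) {
  c(both = sum(rows$present_a & rows$present_b),
    only_a = sum(rows$present_a & !rows$present_b),
    only_b = sum(!rows$present_a & rows$present_b))
}

#' Flag genes unique to the two pools
#'
#' A gene is unique when it has no expression entry in any library outside
#' pool A or pool B; otherwise non-unique.
#'
#' @param rows Tabulated gene rows.
#' @param expression Full expression table (including non-pool libraries).
#' @param pools Pool pair from [build_pools()].
#' @return `rows` with a logical `unique` column added.
#' @export
flag_unique <- function(rows, expression, pools) {
  pool_ids <- c(pools$A$library_ids, pools$B$library_ids)
  outside <- expression$library_id[!(expression$library_id %in% pool_ids)]
  outside_clusters <- unique(expression$cluster_id[!(expression$library_id %in% pool_ids)])
  rows$unique <- !(rows$cluster_id %in% outside_clusters)
  rows
}

#' Default anonymous-transcript title patterns
#'
#' Case-insensitive regular expressions marking gene titles that describe an
#' anonymous or uncharacterized transcript. A cluster whose title matches any
#' of them is classified unknown even when it carries a symbol (e.g. a
#' "CDNA FLJ..." clone title). The rule is a documented heuristic and is
#' configurable.
#' @return Character vector of regular expressions (applied to lower-cased titles).
#' @export
dged_unknown_patterns <- function() {
  c("\\btranscribed locus\\b", "\\bcdna clone\\b", "\\bcdna flj",
    "\\best\\b", "\\bhypothetical\\b", "\\bopen reading frame\\b")
}

#' Flag genes with a known name/function
#'
#' `known` is true iff the symbol is non-empty and the title does not match
#' any anonymous-transcript pattern.
#'
#' @param rows Tabulated gene rows (with `symbol` and `title` columns).
#' @param patterns Regular expressions, see [dged_unknown_patterns()].
#' @return `rows` with a logical `known` column added.
#' @export
flag_known <- function(rows, patterns = dged_unknown_patterns()) {
  title_cf <- tolower(rows$title)
  anon <- rep(FALSE, nrow(rows))
  for (p in patterns) anon <- anon | grepl(p, title_cf)
  rows$known <- nzchar(trimws(rows$symbol)) & !anon
  rows
}

#' xProfiler-style summary table
#'
#' A 2x2 table of gene counts (known/unknown x unique/non-unique) whose four
#' cells always sum to the gene-list length, so the summary can never disagree
#' with the list it summarizes.
#'
#' @param rows Gene rows carrying `known` and `unique` flags.
#' @return List with `counts` (2x2 integer matrix) and `total`.
#' @export
summarize_xprofiler <- function(rows) {
  stopifnot(all(c("known", "unique") %in% names(rows)))
  m <- matrix(c(sum(rows$known & rows$unique), sum(rows$known & !rows$unique),
                sum(!rows$known & rows$unique), sum(!rows$known & !rows$unique)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("known", "unknown"), c("unique", "non-unique")))
  list(counts = m, total = nrow(rows))
}

#' Boolean-presence gene set for two pools
#'
#' Independent Boolean route: the set of gene clusters with at least one
#' expression entry in any pool library, taken directly from the expression
#' table. By design it enumerates the same genes as the odds-ratio route
#' ([tabulate_gene_counts()]).
#'
#' @param pools Pool pair from [build_pools()].
#' @param expression Full expression table.
#' @return Sorted character vector of cluster ids.
#' @export
xprofiler_gene_set <- function(pools, expression) {
  ids <- c(pools$A$library_ids, pools$B$library_ids)
  sort(unique(expression$cluster_id[expression$library_id %in% ids]))
}
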