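make_pool_fixture <- function() {
  libs <- make_libs(
    lib_text("A1", unique_tissue = "bone"), lib_text("A2", unique_tissue = "bone"),
    lib_text("B1", unique_tissue = "bone"), lib_text("OUT", unique_tissue = "liver"))
  expr <- expr_df(
    c("A1", "A1", "A2", "B1", "B1", "OUT"),
    c("Hs.1", "Hs.2", "Hs.1", "Hs.2", "Hs.3", "Hs.3"),
    c(3, 7, 5, 2, 4, 6))
  genes <- data.frame(cluster_id = c("Hs.1", "Hs.2", "Hs.3", "Hs.4"),
                      symbol = c("G1", "G2", "", "TGFBI"),
                      title = c("Gene one", "Gene two", "Transcribed locus",
                                "CDNA FLJ53400 complete cds"),
                      stringsAsFactors = FALSE)
  libs <- compute_mapped_counts(libs, expr)
  list(libs = libs, expr = expr, genes = genes)
}

test_that("pools carry mapped totals and reject overlap", {
  f <- make_pool_fixture()
  a <- f$libs[f$libs$library_id %in% c("A1", "A2"), ]
  b <- f$libs[f$libs$library_id == "B1", ]
  pools <- build_pools(a, b)
  expect_equal(pools$A$total_sequences, 15L)
  expect_equal(pools$B$total_sequences, 6L)
  expect_error(build_pools(a, f$libs[f$libs$library_id %in% c("A2", "B1"), ]),
               "overlap: A2")
  raw <- make_libs(lib_text("X1"))
  expect_error(build_pools(raw, b[0, ]), "compute_mapped_counts")
  # empty pool B is permitted
  expect_equal(build_pools(a, b[0, ])$B$total_sequences, 0L)
})

test_that("tabulation uses union semantics, conserves counts and orders rows", {
  f <- make_pool_fixture()
  pools <- build_pools(f$libs[f$libs$library_id %in% c("A1", "A2"), ],
                       f$libs[f$libs$library_id == "B1", ])
  rows <- tabulate_gene_counts(pools, f$expr, f$genes)
  expect_setequal(rows$cluster_id, c("Hs.1", "Hs.2", "Hs.3"))  # union, not Hs.4
  r1 <- rows[rows$cluster_id == "Hs.1", ]
  expect_equal(r1$a, 8L); expect_equal(r1$b, 0L)
  expect_true(r1$present_a); expect_false(r1$present_b)
  # conservation: column sums equal pool totals
  expect_identical(sum(rows$a), pools$A$total_sequences)
  expect_identical(sum(rows$b), pools$B$total_sequences)
  # deterministic order: descending a+b, ties by cluster_id
  expect_equal(rows$cluster_id, c("Hs.2", "Hs.1", "Hs.3"))
  # unknown cluster is an error
  bad <- rbind(f$expr, expr_df("A1", "Hs.999", 1))
  expect_error(tabulate_gene_counts(pools, bad, f$genes), "Hs\\.999")
})

test_that("count conservation holds across random fixtures", {
  for (seed in 1:10) {
    fx <- generate_random_db(30, 20, seed = 400 + seed)
    libs <- compute_mapped_counts(fx$libraries, fx$expression)
    ids <- libs$library_id
    a_ids <- ids[seq(1, 15)]; b_ids <- ids[seq(16, 30)]
    pools <- build_pools(libs[ids %in% a_ids, ], libs[ids %in% b_ids, ])
    rows <- tabulate_gene_counts(pools, fx$expression, fx$genes)
    expect_identical(sum(rows$a), pools$A$total_sequences)
    expect_identical(sum(rows$b), pools$B$total_sequences)
    # Boolean and odds-ratio routes enumerate the same gene set
    expect_identical(sort(rows$cluster_id), xprofiler_gene_set(pools, fx$expression))
  }
})

test_that("odds ratio follows the zero-count conventions", {
  expect_equal(odds_ratio(10, 1000, 5, 1000), 2)
  expect_equal(odds_ratio(0, 500, 7, 300), 0)
  expect_identical(odds_ratio(3, 300, 0, 500), Inf)
  expect_true(is.nan(odds_ratio(0, 300, 0, 500)))
  expect_equal(odds_ratio(3, 300, 0, 500, pseudocount = 1),
               (4 / 301) / (1 / 501))
  expect_error(odds_ratio(-1, 10, 0, 10), "non-negative")
  expect_error(odds_ratio(11, 10, 0, 10), "exceeds pool total")
})

test_that("odds ratio is reciprocal under pool swap for positive counts", {
  set.seed(17)
  for (i in 1:50) {
    a <- sample(1:50, 1); b <- sample(1:50, 1)
    A <- a + sample(1:500, 1); B <- b + sample(1:500, 1)
    expect_equal(odds_ratio(a, A, b, B) * odds_ratio(b, B, a, A), 1)
  }
})

test_that("venn counts partition the gene list", {
  rows <- data.frame(present_a = c(TRUE, TRUE, FALSE),
                     present_b = c(TRUE, FALSE, TRUE))
  expect_equal(venn_counts(rows), c(both = 1L, only_a = 1L, only_b = 1L))
  all_both <- data.frame(present_a = rep(TRUE, 4), present_b = rep(TRUE, 4))
  expect_equal(venn_counts(all_both), c(both = 4L, only_a = 0L, only_b = 0L))
})

test_that("unique flags reflect expression outside the pools", {
  f <- make_pool_fixture()
  pools <- build_pools(f$libs[f$libs$library_id %in% c("A1", "A2"), ],
                       f$libs[f$libs$library_id == "B1", ])
  rows <- tabulate_gene_counts(pools, f$expr, f$genes)
  rows <- flag_unique(rows, f$expr, pools)
  got <- setNames(rows$unique, rows$cluster_id)
  expect_true(got[["Hs.1"]]); expect_true(got[["Hs.2"]])
  expect_false(got[["Hs.3"]])  # also in library OUT
})

test_that("known/unknown flags follow symbol and title heuristics", {
  rows <- data.frame(
    symbol = c("ACTN4", "", "TGFBI", "GN1"),
    title = c("Actinin, alpha 4", "Transcribed locus",
              "CDNA FLJ53400 complete cds", "Testis specific protein"),
    stringsAsFactors = FALSE)
  rows <- flag_known(rows)
  expect_equal(rows$known, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("xprofiler summary cells always total the gene-list length", {
  rows <- data.frame(known = c(TRUE, TRUE, FALSE),
                     unique = c(TRUE, FALSE, TRUE))
  s <- summarize_xprofiler(rows)
  expect_equal(as.vector(s$counts), c(1L, 1L, 1L, 0L))
  expect_equal(s$total, 3L)
  expect_equal(sum(s$counts), s$total)
  empty <- summarize_xprofiler(rows[0, ])
  expect_equal(sum(empty$counts), 0L)
  for (seed in 1:5) {
    fx <- generate_random_db(20, 25, seed = 500 + seed)
    libs <- compute_mapped_counts(fx$libraries, fx$expression)
    pools <- build_pools(libs[1:10, ], libs[11:20, ])
    rows <- flag_known(flag_unique(
      tabulate_gene_counts(pools, fx$expression, fx$genes), fx$expression, pools))
    s <- summarize_xprofiler(rows)
    expect_equal(sum(s$counts), nrow(rows))
  }
})
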