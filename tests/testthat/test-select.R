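test_that("corrected selector requires exact unique-tissue equality", {
  libs <- make_libs(
    lib_text("B1", unique_tissue = "bone", keywords = "bone"),
    lib_text("B2", unique_tissue = "bone marrow", keywords = "bone marrow"),
    lib_text("B3", unique_tissue = "Bone", keywords = "bone"),
    lib_text("P1", unique_tissue = "pooled tissue", keywords = "bone"))
  sel <- select_corrected(libs, tissue_query("bone"))
  expect_setequal(sel$library_id, c("B1", "B3"))  # case-folded equality
  expect_false("B2" %in% sel$library_id)          # longer phrase excluded
  expect_false("P1" %in% sel$library_id)          # pooled tissue excluded
  pooled <- select_corrected(libs, tissue_query("pooled tissue"))
  expect_equal(pooled$library_id, "P1")
})

test_that("corrected selector ignores keywords entirely", {
  libs <- make_libs(lib_text("T1", keywords = "heart disease",
                             unique_tissue = "brain"))
  sel <- select_corrected(libs, tissue_query("ear"))
  expect_equal(nrow(sel), 0L)
})

test_that("legacy selector accepts nested substrings in keywords and unique tissue", {
  libs <- make_libs(
    lib_text("H1", keywords = "heart", unique_tissue = "heart"),
    lib_text("K1", keywords = "clear cell renal carcinoma", unique_tissue = "kidney"),
    lib_text("P1", keywords = "pericardium", unique_tissue = "heart"),
    lib_text("U1", keywords = "peripheral blood mononuclear cell",
             unique_tissue = "uncharacterized tissue"),
    lib_text("N1", keywords = "brain", unique_tissue = "brain"))
  sel <- select_legacy(libs, tissue_query("ear", mode = "legacy"))
  expect_setequal(sel$library_id, c("H1", "K1", "P1", "U1"))
  via <- setNames(sel$matched_via, sel$library_id)
  expect_equal(via[["H1"]], "keyword:heart")
  expect_equal(via[["P1"]], "unique_tissue")  # "ear" only inside "heart" there
  expect_match(via[["K1"]], "^keyword:clear cell renal carcinoma$")
})

test_that("legacy selector agrees with a brute-force substring scan", {
  for (seed in 1:10) {
    fx <- generate_random_db(40, 20, seed = seed)
    for (tissue in c("ear", "bone", "ar", "lymph node")) {
      got <- select_legacy(fx$libraries, tissue_query(tissue, mode = "legacy"))
      expect_setequal(got$library_id, brute_force_legacy_ids(fx$libraries, tissue))
    }
  }
})

test_that("corrected selection is sound and nested in legacy selection", {
  n_queries <- 0L
  for (seed in 1:10) {
    fx <- generate_random_db(50, 20, seed = 100 + seed)
    for (tissue in unique(fx$bookkeeping$tissues)) {
      cor <- select_corrected(fx$libraries, tissue_query(tissue))
      expect_true(all(tolower(cor$unique_tissue) == tolower(tissue)))
      leg <- select_legacy(fx$libraries, tissue_query(tissue, mode = "legacy"))
      expect_true(all(cor$library_id %in% leg$library_id))
      n_queries <- n_queries + 1L
    }
  }
  expect_gt(n_queries, 100L)
})

test_that("histology classification follows the whole-word lexicon", {
  libs <- make_libs(
    lib_text("C1", histology = "Ewing's sarcoma"),
    lib_text("N1", histology = "normal"),
    lib_text("O1", histology = "", keywords = character()),
    lib_text("X1", histology = "neuroblastoma"),     # no whole-word lexicon hit
    lib_text("C2", keywords = c("clear cell ovarian tumor")))
  cls <- classify_histology(libs)
  expect_equal(cls, c("cancer", "normal", "other", "other", "cancer"))
})

test_that("size cut-off respects its basis and min=0 is the identity", {
  libs <- make_libs(lib_text("L1", sequences = 1000))
  expect_identical(nrow(apply_size_cutoff(libs, 0, "mapped")), 1L)
  expect_error(apply_size_cutoff(libs, 100, "mapped"), "compute_mapped_counts")
  libs <- compute_mapped_counts(libs, expr_df("L1", "Hs.100001", 50))
  expect_equal(nrow(apply_size_cutoff(libs, 100, "declared")), 1L)
  expect_equal(nrow(apply_size_cutoff(libs, 100, "mapped")), 0L)
})

test_that("mapped-basis cut-off never keeps more than declared-basis", {
  for (seed in 1:20) {
    fx <- generate_random_db(30, 15, declared_inflation = runif(1, 0, 0.5),
                             seed = 200 + seed)
    libs <- compute_mapped_counts(fx$libraries, fx$expression)
    cut <- sample(0:40, 1)
    expect_lte(nrow(apply_size_cutoff(libs, cut, "mapped")),
               nrow(apply_size_cutoff(libs, cut, "declared")))
  }
})

test_that("mapped counts sum expression entries and flag inflation", {
  libs <- make_libs(lib_text("L1", sequences = 10), lib_text("L2", sequences = 5))
  got <- compute_mapped_counts(libs, expr_df(c("L1", "L1"), c("Hs.1", "Hs.2"), c(3, 7)))
  expect_equal(got$mapped_sequences, c(10L, 0L))
  expect_error(compute_mapped_counts(libs, expr_df("NOPE", "Hs.1", 1)),
               "unknown libraries: NOPE")
  expect_warning(compute_mapped_counts(libs, expr_df("L2", "Hs.1", 99)),
                 "exceeds declared.*L2")
  # declared inflation planted by the generator: mapped < declared everywhere
  fx <- generate_random_db(25, 15, declared_inflation = 0.3, seed = 5L)
  libs <- compute_mapped_counts(fx$libraries, fx$expression)
  expect_true(all(libs$mapped_sequences < libs$declared_sequences))
  expect_identical(libs$mapped_sequences,
                   vapply(libs$library_id,
                          function(id) fx$bookkeeping$mapped_totals[[id]],
                          integer(1), USE.NAMES = FALSE))
})

test_that("protocol filters honour bulk and normalization flags", {
  libs <- make_libs(
    lib_text("L1", protocol = c("bulk", "non-normalized")),
    lib_text("L2", protocol = c("bulk", "normalized")),
    lib_text("L3", protocol = c("non-normalized")))
  q <- tissue_query("brain", require_bulk = TRUE, require_non_normalized = TRUE)
  expect_equal(select_corrected(libs, q)$library_id, "L1")
})

test_that("classification rates match exact-annotation scoring", {
  fx <- generate_scenario("ear-trap", seed = 42)
  libs <- compute_mapped_counts(fx$libraries, fx$expression)
  leg <- select_legacy(libs, tissue_query("ear", mode = "legacy"))
  cr <- classification_rate(leg, "ear")
  expect_equal(cr$n_selected, 106L)
  expect_equal(cr$pct_correct, 5.66)
  expect_equal(cr$pct_incorrect, 94.34)

  cor <- select_corrected(libs, tissue_query("ear"))
  cr2 <- classification_rate(cor, "ear")
  expect_equal(cr2$pct_correct, 100)
  expect_equal(cr2$pct_incorrect, 0)

  empty <- classification_rate(cor[0, ], "ear")
  expect_false(empty$available)
  expect_equal(empty$pct_correct + empty$pct_incorrect, 0)
})

test_that("classification percentages sum to 100 within rounding", {
  for (seed in 1:15) {
    fx <- generate_random_db(30, 10, seed = 300 + seed)
    tissue <- sample(fx$bookkeeping$tissues, 1)
    sel <- select_legacy(fx$libraries, tissue_query(tissue, mode = "legacy"))
    cr <- classification_rate(sel, tissue)
    if (cr$available) {
      expect_lte(abs(cr$pct_correct + cr$pct_incorrect - 100), 0.01)
    }
  }
})

test_that("keyword-scored tissues count keyword phrase matches as correct", {
  libs <- make_libs(
    lib_text("S1", keywords = c("stem cell", "bulk"), unique_tissue = "uncharacterized tissue"),
    lib_text("S2", keywords = c("stem cells"), unique_tissue = "uncharacterized tissue"))
  cr <- classification_rate(libs, "stem cell")
  expect_equal(cr$n_correct, 1L)   # whole-phrase match only
})

test_that("legacy descendant-phrase knob reproduces metastasis inclusions", {
  fx <- generate_scenario("brain-metastasis", seed = 1)
  libs <- compute_mapped_counts(fx$libraries, fx$expression)
  plain <- select_legacy(libs, tissue_query("brain", mode = "legacy"))
  expect_setequal(plain$library_id, fx$bookkeeping$brain_ids)
  with_desc <- select_legacy(libs, tissue_query(
    "brain", mode = "legacy",
    extra_phrases = fx$bookkeeping$descendant_phrases))
  expect_setequal(with_desc$library_id,
                  c(fx$bookkeeping$brain_ids, fx$bookkeeping$metastasis_ids))
  cor <- select_corrected(libs, tissue_query("brain"))
  expect_setequal(cor$library_id, fx$bookkeeping$brain_ids)
})
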