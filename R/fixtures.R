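# Deterministic synthetic fixture generator. Emits a library flat file, an
# expression table and a gene table (as in-memory objects plus writers),
# together with bookkeeping of every planted truth, so tests can compare the
# pipeline's output against ground truth the generator recorded while
# building the data. Generation is a pure function of (scenario, seed,
# parameters): the same call yields byte-identical files.

#' Tissue vocabulary used by the random generator
#' @return Character vector of tissue phrases.
#' @export
tissue_vocabulary <- function() {
  c("adipose", "adrenal cortex", "bone", "bone marrow", "brain", "cartilage",
    "cerebellum", "cerebrum", "cervix", "colon", "ear", "eye", "heart",
    "kidney", "liver", "lung", "lymph node", "muscle", "ovary", "pancreas",
    "placenta", "prostate", "retina", "skin", "spleen", "stomach", "testis",
    "thymus", "thyroid", "uterus", "vascular")
}

# Zero-truncated Poisson draws (counts are >= 1 by construction: a gene
# listed for a library is represented by at least one sequence).
rtpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  as.integer(stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda))
}

fixture_gene_table <- function(n_genes) {
  idx <- seq_len(n_genes)
  cluster_id <- sprintf("Hs.%d", 100000L + idx)
  symbol <- sprintf("GN%03d", idx)
  title <- sprintf("Gene %d protein", idx)
  # every 4th cluster is an anonymous transcript; every 8th keeps a symbol
  # but an anonymous clone title (a named cluster can still be "unknown")
  anon <- idx %% 4L == 0L
  symbol[anon] <- ""
  title[anon] <- "Transcribed locus"
  clone <- idx %% 8L == 3L
  title[clone] <- sprintf("CDNA FLJ%d complete cds", 50000L + idx[clone])
  data.frame(cluster_id = cluster_id, symbol = symbol, title = title,
             stringsAsFactors = FALSE)
}

# Draw expression entries for a set of libraries over a gene catalogue and
# return entries plus per-library mapped totals.
draw_expression <- function(library_ids, gene_ids, mean_genes = 5,
                            mean_counts = 5, gene_pool = NULL) {
  entries <- list()
  totals <- stats::setNames(integer(length(library_ids)), library_ids)
  for (lib in library_ids) {
    pool <- if (is.null(gene_pool)) gene_ids else gene_pool[[lib]]
    k <- max(1L, min(length(pool), 1L + stats::rpois(1, mean_genes - 1)))
    cl <- sample(pool, k)
    cnt <- rtpois(k, mean_counts)
    entries[[lib]] <- data.frame(library_id = lib, cluster_id = cl,
                                 count = cnt, stringsAsFactors = FALSE)
    totals[[lib]] <- sum(cnt)
  }
  list(entries = do.call(rbind, unname(entries)), totals = totals)
}

make_libraries <- function(ids, titles, keywords, tissue, histology,
                           unique_tissue, protocol) {
  n <- length(ids)
  new_library_table(
    library_id = ids, title = titles,
    tissue_supplied = rep_len(tissue, n), histology = rep_len(histology, n),
    unique_tissue = rep_len(unique_tissue, n), declared_sequences = rep(0L, n),
    keywords = keywords, protocol = rep(list(protocol), n),
    extra = rep(list(stats::setNames(character(0), character(0))), n))
}

set_declared <- function(libraries, totals, inflation = 0) {
  mapped <- as.integer(totals[libraries$library_id])
  # rounded up so any positive inflation strictly exceeds the mapped count
  libraries$declared_sequences <- as.integer(ceiling(mapped * (1 + inflation)))
  libraries
}

scenario_ear_trap <- function(trap_split) {
  stopifnot(all(trap_split >= 0))
  bulk <- c("bulk", "non-normalized")
  counter <- 0L
  id_seq <- function(n) {
    out <- sprintf("LIB%04d", counter + seq_len(n))
    counter <<- counter + n
    out
  }
  ear_ids <- id_seq(6L)
  ear <- make_libraries(ear_ids, sprintf("Human ear library %d", 1:6),
                        lapply(1:6, function(i) c("ear", "normal")),
                        "ear", "normal", "ear", bulk)
  traps <- list()
  add <- function(n, title, kw, tissue, histology, ut, protocol = bulk) {
    if (n == 0L) return()
    ids <- id_seq(n)
    traps[[length(traps) + 1L]] <<- make_libraries(
      ids, sprintf("%s %d", title, seq_len(n)),
      rep(list(kw), n), tissue, histology, ut, protocol)
  }
  # category 1: "heart" keyword ("ear" nested inside "heart")
  add(trap_split[["heart"]], "Human heart library", c("heart", "normal"),
      "heart", "normal", "heart")
  # category 2: "heart disease" keyword on non-heart tissues
  hd_tissues <- rep_len(c("brain", "cerebellum", "cerebrum", "thymus", "vascular"),
                        trap_split[["heart_disease"]])
  for (tis in hd_tissues) {
    add(1L, paste("Human", tis, "library"), c("heart disease", tis),
        tis, "", tis)
  }
  # category 3: "pericardium" keyword, matched only via unique_tissue "heart"
  add(trap_split[["pericardium"]], "Human pericardium library",
      c("pericardium"), "pericardium", "normal", "heart")
  # category 4: "clear cell renal carcinoma" (kidney)
  add(trap_split[["renal"]], "Human renal carcinoma library",
      c("clear cell renal carcinoma"), "kidney", "clear cell renal carcinoma",
      "kidney")
  # category 5: "clear cell ovarian tumor" (ovary)
  add(trap_split[["ovarian"]], "Human ovarian tumor library",
      c("clear cell ovarian tumor"), "ovary", "clear cell ovarian tumor",
      "ovary")
  # category 6: "peripheral blood mononuclear cell" (uncharacterized tissue)
  add(trap_split[["pbmc"]], "Human PBMC library",
      c("peripheral blood mononuclear cell"), "blood", "",
      "uncharacterized tissue")
  # category 7: mixed-sample libraries with a "heart" keyword
  add(trap_split[["pooled"]], "Human pooled tissue library",
      c("heart", "pooled sample"), "mixed", "", "pooled tissue",
      c("bulk", "non-normalized", "pooled sample"))
  trap_tab <- do.call(rbind, traps)
  libs <- rbind(ear, trap_tab)
  class(libs) <- c("dged_libraries", "data.frame")
  list(libraries = libs, correct_ids = ear_ids,
       trap_ids = setdiff(libs$library_id, ear_ids))
}

scenario_bone_vs_marrow <- function() {
  bulk <- c("bulk", "non-normalized")
  mk <- function(ids, tissue, histology) {
    make_libraries(ids, sprintf("Human %s library %s", tissue, ids),
                   rep(list(c(tissue, histology)), length(ids)),
                   tissue, histology, tissue, bulk)
  }
  bone_n <- mk(sprintf("BONE%02dN", 1:4), "bone", "normal")
  bone_c <- mk(sprintf("BONE%02dC", 1:4), "bone", "osteosarcoma tumor")
  marrow <- mk(sprintf("MARR%02d", 1:5), "bone marrow", "normal")
  libs <- rbind(bone_n, bone_c, marrow)
  class(libs) <- c("dged_libraries", "data.frame")
  list(libraries = libs,
       bone_normal_ids = bone_n$library_id, bone_cancer_ids = bone_c$library_id,
       marrow_ids = marrow$library_id)
}

scenario_brain_metastasis <- function() {
  bulk <- c("bulk", "non-normalized")
  brain <- make_libraries(sprintf("BRN%02d", 1:8),
                          sprintf("Human brain library %d", 1:8),
                          rep(list(c("brain", "normal")), 8L),
                          "brain", "normal", "brain", bulk)
  ewing <- make_libraries("EWS01", "Human Ewing's sarcoma bone library",
                          list(c("bone", "Ewing's sarcoma")),
                          "bone", "Ewing's sarcoma", "bone", bulk)
  neuro <- make_libraries(sprintf("NBM%02d", 1:5),
                          sprintf("Human neuroblastoma marrow library %d", 1:5),
                          rep(list(c("bone marrow", "neuroblastoma")), 5L),
                          "bone marrow", "metastatic neuroblastoma tumor",
                          "bone marrow", bulk)
  libs <- rbind(brain, ewing, neuro)
  class(libs) <- c("dged_libraries", "data.frame")
  list(libraries = libs, brain_ids = brain$library_id,
       metastasis_ids = c(ewing$library_id, neuro$library_id),
       descendant_phrases = c("neuroblastoma", "Ewing's sarcoma"))
}

scenario_adipose_pools <- function() {
  bulk <- c("bulk", "non-normalized")
  normal <- make_libraries(sprintf("ADN%02d", 1:5),
                           sprintf("Human normal adipose library %d", 1:5),
                           rep(list(c("adipose", "normal")), 5L),
                           "adipose", "normal", "adipose", bulk)
  cancer <- make_libraries(sprintf("ADC%02d", 1:5),
                           sprintf("Human adipose carcinoma library %d", 1:5),
                           rep(list(c("adipose", "carcinoma")), 5L),
                           "adipose", "carcinoma", "adipose", bulk)
  outside <- make_libraries(sprintf("LIV%02d", 1:2),
                            sprintf("Human liver library %d", 1:2),
                            rep(list(c("liver", "normal")), 2L),
                            "liver", "normal", "liver", bulk)
  libs <- rbind(normal, cancer, outside)
  class(libs) <- c("dged_libraries", "data.frame")
  list(libraries = libs, normal_ids = normal$library_id,
       cancer_ids = cancer$library_id, outside_ids = outside$library_id)
}

#' Generate a named pathology scenario
#'
#' Deterministic fixtures embedding documented library-database pathologies:
#'
#' * `"ear-trap"` — 6 libraries truly from ear tissue plus (by default) 100
#'   trap libraries that a substring matcher wrongly selects for "ear": the
#'   "heart" keyword family, "heart disease" on brain/cerebellum/cerebrum/
#'   thymus/vascular libraries, "pericardium" libraries whose unique tissue
#'   is "heart", "clear cell renal carcinoma" (kidney), "clear cell ovarian
#'   tumor" (ovary), "peripheral blood mononuclear cell" (uncharacterized
#'   tissue) and mixed-sample "pooled tissue" libraries with a "heart"
#'   keyword. Default category split 70/10/8/5/3/2/2 (configurable).
#' * `"bone-vs-marrow"` — "bone" and "bone marrow" unique tissues, normal and
#'   cancerous bone pools.
#' * `"brain-metastasis"` — brain libraries plus a bone "Ewing's sarcoma"
#'   library and five bone-marrow "neuroblastoma" libraries; the bookkeeping
#'   carries the descendant phrase list that makes the legacy matcher pull
#'   them in for a "brain" query.
#' * `"adipose-pools"` — normal and cancerous adipose pools with declared
#'   counts inflated above mapped counts, plus two outside (liver) libraries.
#'
#' Every library receives expression entries (mapped count >= 1). Bookkeeping
#' records the planted truth: per-library mapped totals, correct/trap library
#' sets, pool definitions, the union gene set, its Venn partition and the
#' unique-gene set where applicable.
#'
#' @param name One of `"ear-trap"`, `"bone-vs-marrow"`, `"brain-metastasis"`,
#'   `"adipose-pools"`.
#' @param seed Integer seed; identical `(name, seed)` yields byte-identical
#'   files.
#' @param trap_split Named integer vector of ear-trap category sizes
#'   (`heart`, `heart_disease`, `pericardium`, `renal`, `ovarian`, `pbmc`,
#'   `pooled`).
#' @param n_genes Size of the gene catalogue.
#' @return List with `libraries`, `expression`, `genes`, `bookkeeping`.
#' @export
generate_scenario <- function(name, seed = 42L,
                              trap_split = c(heart = 70L, heart_disease = 10L,
                                             pericardium = 8L, renal = 5L,
                                             ovarian = 3L, pbmc = 2L, pooled = 2L),
                              n_genes = 40L) {
  known <- c("ear-trap", "bone-vs-marrow", "brain-metastasis", "adipose-pools")
  if (!name %in% known) {
    stop("unknown scenario '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    genes <- fixture_gene_table(n_genes)
    sc <- switch(name,
      "ear-trap" = scenario_ear_trap(trap_split),
      "bone-vs-marrow" = scenario_bone_vs_marrow(),
      "brain-metastasis" = scenario_brain_metastasis(),
      "adipose-pools" = scenario_adipose_pools())
    libs <- sc$libraries
    inflation <- if (name == "adipose-pools") 0.25 else 0
    dr <- draw_expression(libs$library_id, genes$cluster_id)
    libs <- set_declared(libs, dr$totals, inflation)
    book <- c(list(scenario = name, seed = seed,
                   library_ids = libs$library_id,
                   mapped_totals = as.list(dr$totals),
                   n_expression_entries = nrow(dr$entries)),
              sc[setdiff(names(sc), "libraries")])
    if (name == "adipose-pools") {
      in_pools <- dr$entries$library_id %in% c(sc$normal_ids, sc$cancer_ids)
      in_a <- dr$entries$library_id %in% sc$normal_ids
      in_b <- dr$entries$library_id %in% sc$cancer_ids
      union_cl <- sort(unique(dr$entries$cluster_id[in_pools]))
      cl_a <- unique(dr$entries$cluster_id[in_a])
      cl_b <- unique(dr$entries$cluster_id[in_b])
      outside_cl <- unique(dr$entries$cluster_id[!in_pools])
      book$union_clusters <- union_cl
      book$venn <- c(both = length(intersect(cl_a, cl_b)),
                     only_a = length(setdiff(cl_a, cl_b)),
                     only_b = length(setdiff(cl_b, cl_a)))
      book$unique_clusters <- setdiff(union_cl, outside_cl)
      book$pool_totals <- c(A = sum(dr$totals[sc$normal_ids]),
                            B = sum(dr$totals[sc$cancer_ids]))
    }
    list(libraries = libs, expression = dr$entries, genes = genes,
         bookkeeping = book)
  })
}

#' Generate a random library database
#'
#' Random tissues from [tissue_vocabulary()]; each library's keywords contain
#' its unique-tissue phrase verbatim (so a corrected selection is always a
#' subset of the legacy selection) plus a histology word. The number of genes
#' per library is `1 + Poisson(mean_genes - 1)` (at least one), per-gene
#' counts are zero-truncated Poisson with mean `mean_counts`, and
#' `declared_sequences = ceiling(mapped * (1 + declared_inflation))`.
#'
#' @param n_libraries,n_genes Database dimensions.
#' @param mean_genes Mean number of gene clusters per library.
#' @param mean_counts Mean sequence count per (library, gene) entry.
#' @param declared_inflation Relative excess of declared over mapped counts;
#'   `0` makes them equal.
#' @param seed Integer seed.
#' @return List with `libraries`, `expression`, `genes`, `bookkeeping`
#'   (mapped totals, tissue assignments, histology assignments).
#' @export
generate_random_db <- function(n_libraries, n_genes, mean_genes = 5,
                               mean_counts = 5, declared_inflation = 0,
                               seed = 1L) {
  stopifnot(n_libraries >= 0, n_genes >= 0, mean_counts > 0,
            declared_inflation >= 0)
  with_seed(seed, {
    genes <- fixture_gene_table(n_genes)
    if (n_libraries == 0L) {
      libs <- new_library_table()
      return(list(libraries = libs,
                  expression = data.frame(library_id = character(),
                                          cluster_id = character(),
                                          count = integer(),
                                          stringsAsFactors = FALSE),
                  genes = genes,
                  bookkeeping = list(mapped_totals = list(),
                                     tissues = character(0),
                                     histology = character(0))))
    }
    ids <- sprintf("RND%04d", seq_len(n_libraries))
    tissues <- sample(tissue_vocabulary(), n_libraries, replace = TRUE)
    hist_word <- sample(c("normal", "carcinoma", ""), n_libraries,
                        replace = TRUE, prob = c(0.5, 0.3, 0.2))
    kws <- lapply(seq_len(n_libraries), function(j) {
      k <- c(tissues[j], hist_word[j])
      k[nzchar(k)]
    })
    libs <- new_library_table(
      library_id = ids,
      title = sprintf("Synthetic %s library %d", tissues, seq_len(n_libraries)),
      tissue_supplied = tissues, histology = hist_word,
      unique_tissue = tissues, declared_sequences = rep(0L, n_libraries),
      keywords = kws,
      protocol = rep(list(c("bulk", "non-normalized")), n_libraries),
      extra = rep(list(stats::setNames(character(0), character(0))), n_libraries))
    dr <- draw_expression(ids, genes$cluster_id, mean_genes, mean_counts)
    libs <- set_declared(libs, dr$totals, declared_inflation)
    list(libraries = libs, expression = dr$entries, genes = genes,
         bookkeeping = list(mapped_totals = as.list(dr$totals),
                            tissues = stats::setNames(tissues, ids),
                            histology = stats::setNames(hist_word, ids)))
  })
}

#' Write a fixture to disk
#'
#' Emits `libraries.txt`, `expression.tsv`, `genes.tsv` and
#' `bookkeeping.json` under `dir`.
#'
#' @param fixture A fixture from [generate_scenario()] or
#'   [generate_random_db()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_library_records(fixture$libraries, file.path(dir, "libraries.txt"))
  write_expression_table(fixture$expression, file.path(dir, "expression.tsv"))
  write_gene_table(fixture$genes, file.path(dir, "genes.tsv"))
  jsonlite::write_json(fixture$bookkeeping, file.path(dir, "bookkeeping.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
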