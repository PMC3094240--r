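# End-to-end orchestration: selection -> pooling -> tabulation -> statistics
# -> TSV reports. Reports are written atomically (no partial file on error)
# and serialized at fixed precision so identical runs are byte-identical.

#' Run a library selection and write the library report
#'
#' Parses the inputs, computes mapped counts when an expression table is
#' given, selects libraries for the tissue query and (optionally) writes a
#' tab-separated report with columns `library_id`, `title`, `unique_tissue`,
#' `histology_class`, `declared_sequences`, `mapped_sequences`, `matched_via`
#' and `correct` (0/1, exact unique-tissue match against the query).
#'
#' @param libraries_file Library flat file path.
#' @param expression_file Expression table path, or `NULL` to skip mapped
#'   counts (then only `basis = "declared"` size cut-offs are possible).
#' @param tissue,mode,histology,require_bulk,require_non_normalized,min_sequences,basis,extra_phrases
#'   Passed to [tissue_query()].
#' @param out_file Report path, or `NULL` to skip writing.
#' @return Invisibly, a list: `selected` (the selection), `report` (the
#'   report data frame), `classification` ([classification_rate()]).
#' @export
run_select <- function(libraries_file, expression_file = NULL, tissue,
                       mode = c("corrected", "legacy"),
                       histology = c("any", "normal", "cancer"),
                       require_bulk = FALSE, require_non_normalized = FALSE,
                       min_sequences = 0L, basis = NULL,
                       extra_phrases = character(), out_file = NULL) {
  libs <- parse_library_records(libraries_file)
  if (!is.null(expression_file)) {
    libs <- compute_mapped_counts(libs, parse_expression_table(expression_file))
  }
  query <- tissue_query(tissue, mode = match.arg(mode),
                        histology = match.arg(histology),
                        require_bulk = require_bulk,
                        require_non_normalized = require_non_normalized,
                        min_sequences = min_sequences, basis = basis,
                        extra_phrases = extra_phrases)
  selected <- select_libraries(libs, query)
  report <- data.frame(
    library_id = selected$library_id,
    title = selected$title,
    unique_tissue = selected$unique_tissue,
    histology_class = selected$histology_class,
    declared_sequences = selected$declared_sequences,
    mapped_sequences = selected$mapped_sequences,
    matched_via = selected$matched_via,
    correct = as.integer(is_correct_library(selected, tissue)),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_file)) {
    header <- paste(names(report), collapse = "\t")
    body <- if (nrow(report)) {
      do.call(paste, c(lapply(report, function(col) {
        if (is.integer(col)) ifelse(is.na(col), "NA", as.character(col)) else col
      }), sep = "\t"))
    } else character(0)
    write_lines_atomic(c(header, body), out_file)
  }
  invisible(list(selected = selected, report = report,
                 classification = classification_rate(selected, tissue)))
}

format_gene_report <- function(rows, pools, library_totals) {
  comments <- c(
    sprintf("# pool_A_libraries=%d\tpool_A_total_sequences=%d\tlibrary_list_total_A=%d",
            length(pools$A$library_ids), pools$A$total_sequences, library_totals[["A"]]),
    sprintf("# pool_B_libraries=%d\tpool_B_total_sequences=%d\tlibrary_list_total_B=%d",
            length(pools$B$library_ids), pools$B$total_sequences, library_totals[["B"]])
  )
  cols <- c("cluster_id", "symbol", "title", "a", "b", "A", "B",
            "present_a", "present_b", "F", "P", "p_fisher", "q",
            "unique", "known")
  header <- paste(cols, collapse = "\t")
  body <- if (nrow(rows)) {
    do.call(paste, c(lapply(cols, function(cn) {
      col <- rows[[cn]]
      if (is.logical(col)) as.character(as.integer(col))
      else if (is.integer(col)) as.character(col)
      else if (is.numeric(col)) format_num6(col)
      else col
    }), sep = "\t"))
  } else character(0)
  c(comments, header, body)
}

#' Run a two-pool gene comparison and write the gene report
#'
#' Selects the two pools (both with the same mode), computes mapped counts,
#' tabulates per-gene counts over the union gene list, flags unique/known
#' genes, computes all statistics on the full list, and only then applies the
#' display cut-offs in `config`. The report header records each pool's total
#' mapped sequences alongside the library-list total (equal by construction).
#'
#' @param libraries_file,expression_file,genes_file Input paths.
#' @param tissue_a,tissue_b Tissue queries for pools A and B.
#' @param histology_a,histology_b Histology filters per pool.
#' @param mode Selection mode for both pools.
#' @param require_bulk,require_non_normalized,min_sequences,basis Selection
#'   filters (shared by both pools).
#' @param pool_a_ids,pool_b_ids Optional explicit library id vectors that
#'   bypass tissue selection.
#' @param config A [stat_config()].
#' @param out_file Gene report path, or `NULL` to skip writing.
#' @return Invisibly, a list: `genes` (full statistics table), `filtered`
#'   (after display cut-offs), `pools`, `summary` (venn counts, xProfiler
#'   2x2 table, pool and library-list totals).
#' @export
run_compare <- function(libraries_file, expression_file, genes_file,
                        tissue_a = NULL, tissue_b = NULL,
                        histology_a = "any", histology_b = "any",
                        mode = c("corrected", "legacy"),
                        require_bulk = FALSE, require_non_normalized = FALSE,
                        min_sequences = 0L, basis = NULL,
                        pool_a_ids = NULL, pool_b_ids = NULL,
                        config = stat_config(), out_file = NULL) {
  mode <- match.arg(mode)
  libs <- parse_library_records(libraries_file)
  expr <- parse_expression_table(expression_file)
  genes <- parse_gene_table(genes_file)
  libs <- compute_mapped_counts(libs, expr)

  pick <- function(ids, tissue, histology) {
    if (!is.null(ids)) {
      missing <- setdiff(ids, libs$library_id)
      if (length(missing)) {
        stop("unknown pool library ids: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      sel <- libs[match(ids, libs$library_id), , drop = FALSE]
      sel$histology_class <- classify_histology(sel)
      sel$matched_via <- rep("explicit", nrow(sel))
      rownames(sel) <- NULL
      return(sel)
    }
    if (is.null(tissue)) {
      stop("each pool needs either a tissue query or explicit library ids",
           call. = FALSE)
    }
    select_libraries(libs, tissue_query(
      tissue, mode = mode, histology = histology,
      require_bulk = require_bulk,
      require_non_normalized = require_non_normalized,
      min_sequences = min_sequences, basis = basis))
  }
  sel_a <- pick(pool_a_ids, tissue_a, histology_a)
  sel_b <- pick(pool_b_ids, tissue_b, histology_b)
  if (nrow(sel_a) == 0L || nrow(sel_b) == 0L) {
    warning("a pool is empty after selection; the gene report will be empty",
            call. = FALSE)
  }
  pools <- build_pools(sel_a, sel_b)
  rows <- tabulate_gene_counts(pools, expr, genes)
  rows <- flag_unique(rows, expr, pools)
  rows <- flag_known(rows)
  rows <- compute_gene_stats(rows, config)
  filtered <- apply_display_cutoffs(rows, config)
  library_totals <- c(A = sum(sel_a$mapped_sequences),
                      B = sum(sel_b$mapped_sequences))
  summary <- list(venn = venn_counts(rows),
                  xprofiler = summarize_xprofiler(rows),
                  pool_totals = c(A = pools$A$total_sequences,
                                  B = pools$B$total_sequences),
                  library_list_totals = library_totals)
  if (!is.null(out_file)) {
    write_lines_atomic(format_gene_report(filtered, pools, library_totals),
                       out_file)
  }
  invisible(list(genes = rows, filtered = filtered, pools = pools,
                 summary = summary))
}
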