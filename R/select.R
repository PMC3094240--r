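# Tissue-based library selection. Two modes:
#   corrected — the required phrase must be the ONLY annotation in the
#     "unique tissue" field (exact, case-folded equality), so dependent
#     tissues ("bone marrow" for "bone") and mixed-sample ("pooled tissue")
#     libraries are never pulled in;
#   legacy — emulates the historical CGAP matcher, which accepted the query
#     as a raw substring of any keywords phrase or of the unique-tissue field
#     without respecting word boundaries ("ear" matching "heart", or "clear
#     cell renal carcinoma").

#' Construct a tissue selection query
#'
#' @param tissue Tissue phrase to search for (e.g. `"ear"`, `"bone"`).
#' @param mode `"corrected"` (exact unique-tissue matching) or `"legacy"`
#'   (substring keyword/unique-tissue matching).
#' @param histology Keep only libraries classified `"normal"` or `"cancer"`
#'   by [classify_histology()], or `"any"` for no histology filter.
#' @param require_bulk Keep only libraries whose protocol flags include
#'   `bulk` (libraries made from tissue rather than cell lines).
#' @param require_non_normalized Drop libraries whose protocol flags include
#'   `normalized` (normalization equalizes clone abundance and destroys the
#'   count signal).
#' @param min_sequences Library size display cut-off; `0` keeps everything.
#' @param basis Which sequence count the size cut-off uses: `"mapped"`
#'   (sequences that map onto gene clusters; default in corrected mode) or
#'   `"declared"` (the submitter's `SEQUENCES` annotation; default in legacy
#'   mode, faithful to the historical behaviour).
#' @param extra_phrases Optional extra keyword phrases the legacy matcher also
#'   accepts (substring match), emulating histology-hierarchy descendants such
#'   as "neuroblastoma" being retrieved for a "brain" query. Ignored in
#'   corrected mode.
#' @return A `tissue_query` object.
#' @export
tissue_query <- function(tissue, mode = c("corrected", "legacy"),
                         histology = c("any", "normal", "cancer"),
                         require_bulk = FALSE, require_non_normalized = FALSE,
                         min_sequences = 0L, basis = NULL,
                         extra_phrases = character()) {
  mode <- match.arg(mode)
  histology <- match.arg(histology)
  tissue <- trimws(tissue)
  if (!nzchar(tissue)) stop("tissue query must be non-empty", call. = FALSE)
  if (min_sequences < 0) stop("min_sequences must be >= 0", call. = FALSE)
  if (is.null(basis)) basis <- if (mode == "corrected") "mapped" else "declared"
  basis <- match.arg(basis, c("mapped", "declared"))
  structure(list(tissue = tissue, mode = mode, histology = histology,
                 require_bulk = require_bulk,
                 require_non_normalized = require_non_normalized,
                 min_sequences = as.integer(min_sequences), basis = basis,
                 extra_phrases = extra_phrases),
            class = "tissue_query")
}

#' Default cancer lexicon for histology classification
#' @return Character vector of whole-word cancer terms.
#' @export
dged_cancer_lexicon <- function() {
  c("cancer", "carcinoma", "tumor", "tumour", "sarcoma", "blastoma",
    "leukemia", "lymphoma", "melanoma", "adenoma")
}

#' Classify library histology as normal / cancer / other
#'
#' A library is `"cancer"` if its histology annotation or any keywords phrase
#' contains a cancer lexicon term as a whole word (case-folded); `"normal"` if
#' they contain the whole word "normal" and no cancer term; otherwise
#' `"other"`.
#'
#' @param libraries A `dged_libraries` data frame.
#' @param cancer_lexicon Whole-word cancer terms; see [dged_cancer_lexicon()].
#' @return Character vector, one of `"normal"`, `"cancer"`, `"other"` per row.
#' @export
classify_histology <- function(libraries, cancer_lexicon = dged_cancer_lexicon()) {
  blob <- vapply(seq_len(nrow(libraries)), function(j) {
    tolower(paste(c(libraries$histology[j], libraries$keywords[[j]]), collapse = " "))
  }, character(1))
  cancer_re <- paste0("\\b(", paste(tolower(cancer_lexicon), collapse = "|"), ")\\b")
  is_cancer <- grepl(cancer_re, blob)
  is_normal <- grepl("\\bnormal\\b", blob) & !is_cancer
  ifelse(is_cancer, "cancer", ifelse(is_normal, "normal", "other"))
}

filter_histology <- function(selected, histology) {
  if (histology == "any") return(selected)
  selected[selected$histology_class == histology, , drop = FALSE]
}

has_flag <- function(protocol_list, flag) {
  vapply(protocol_list, function(p) flag %in% case_fold(p), logical(1))
}

filter_protocol <- function(selected, query) {
  if (query$require_bulk) {
    selected <- selected[has_flag(selected$protocol, "bulk"), , drop = FALSE]
  }
  if (query$require_non_normalized) {
    selected <- selected[!has_flag(selected$protocol, "normalized"), , drop = FALSE]
  }
  selected
}

#' Apply the library size display cut-off
#'
#' Keeps libraries whose sequence count on the chosen basis is at least
#' `min_sequences`. With `basis = "mapped"` the count is the number of
#' sequences that actually map onto gene clusters (requires
#' [compute_mapped_counts()] to have run); with `basis = "declared"` it is the
#' submitter's annotation, which is typically inflated by sequences that map
#' to nothing. A cut-off of zero is the identity.
#'
#' @param selected A `dged_libraries` data frame.
#' @param min_sequences Non-negative cut-off.
#' @param basis `"mapped"` or `"declared"`.
#' @export
apply_size_cutoff <- function(selected, min_sequences, basis = c("mapped", "declared")) {
  basis <- match.arg(basis)
  if (min_sequences == 0) return(selected)
  vals <- if (basis == "mapped") selected$mapped_sequences else selected$declared_sequences
  if (basis == "mapped" && anyNA(vals)) {
    stop("size cut-off on mapped counts requires compute_mapped_counts() first",
         call. = FALSE)
  }
  selected[vals >= min_sequences, , drop = FALSE]
}

#' Compute mapped sequence counts per library
#'
#' Sets each library's `mapped_sequences` to the sum of its expression-table
#' counts (0 for libraries with no entries) — the number of sequences that map
#' onto the gene clusters reported for that library, as opposed to the
#' submitter-declared `SEQUENCES` annotation. A warning is issued when a
#' library's mapped count exceeds its declared count (real submissions can
#' disagree in either direction).
#'
#' @param libraries A `dged_libraries` data frame.
#' @param expression Expression table ([parse_expression_table()]); every
#'   `library_id` in it must exist among `libraries`.
#' @return `libraries` with `mapped_sequences` filled in.
#' @export
compute_mapped_counts <- function(libraries, expression) {
  unknown <- setdiff(unique(expression$library_id), libraries$library_id)
  if (length(unknown)) {
    stop("expression entries reference unknown libraries: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sums <- tapply(expression$count, expression$library_id, sum)
  mapped <- as.integer(sums[libraries$library_id])
  mapped[is.na(mapped)] <- 0L
  libraries$mapped_sequences <- mapped
  over <- libraries$library_id[mapped > libraries$declared_sequences]
  if (length(over)) {
    warning("mapped sequence count exceeds declared count for: ",
            paste(over, collapse = ", "), call. = FALSE)
  }
  libraries
}

apply_common_filters <- function(selected, query) {
  selected$histology_class <- classify_histology(selected)
  selected <- filter_histology(selected, query$histology)
  selected <- filter_protocol(selected, query)
  selected <- apply_size_cutoff(selected, query$min_sequences, query$basis)
  rownames(selected) <- NULL
  selected
}

#' Corrected library selector
#'
#' Returns exactly the libraries whose case-folded, trimmed `unique_tissue`
#' equals the query tissue. A library whose unique-tissue annotation merely
#' contains the phrase inside a longer one ("bone marrow" for "bone") is
#' excluded, as are "pooled tissue" libraries unless that is itself the query.
#' Histology, protocol and size filters are then applied (size cut-off on
#' mapped counts by default). Input order is preserved.
#'
#' @param libraries A `dged_libraries` data frame.
#' @param query A [tissue_query()] with `mode = "corrected"`.
#' @return The selected subset with `histology_class` and `matched_via`
#'   columns added.
#' @export
select_corrected <- function(libraries, query) {
  stopifnot(inherits(query, "tissue_query"))
  if (query$mode != "corrected") stop("query mode must be 'corrected'", call. = FALSE)
  hit <- case_fold(libraries$unique_tissue) == case_fold(query$tissue)
  selected <- libraries[hit, , drop = FALSE]
  selected$matched_via <- rep("unique_tissue", nrow(selected))
  apply_common_filters(selected, query)
}

legacy_match_via <- function(libraries, needle, extra_phrases) {
  extra <- case_fold(extra_phrases)
  vapply(seq_len(nrow(libraries)), function(j) {
    kw <- libraries$keywords[[j]]
    kw_cf <- case_fold(kw)
    i <- which(grepl(needle, kw_cf, fixed = TRUE))
    if (length(i)) return(paste0("keyword:", kw[i[1L]]))
    if (grepl(needle, case_fold(libraries$unique_tissue[j]), fixed = TRUE)) {
      return("unique_tissue")
    }
    for (ph in extra) {
      i <- which(grepl(ph, kw_cf, fixed = TRUE))
      if (length(i)) return(paste0("keyword:", kw[i[1L]]))
    }
    NA_character_
  }, character(1))
}

#' Legacy substring library selector
#'
#' Emulates the historical matcher: a library is selected when the case-folded
#' query occurs as a substring — with no respect for word boundaries — of any
#' `keywords` phrase or of the `unique_tissue` field. "ear" therefore matches
#' "heart", "heart disease", "clear cell renal carcinoma" and "peripheral
#' blood mononuclear cell". Mixed-sample ("pooled tissue") libraries are not
#' excluded, faithful to the documented bug. `query$extra_phrases` are
#' additionally accepted as keyword substrings (histology-hierarchy
#' descendants). The same histology/protocol filters as the corrected mode
#' apply; the size cut-off uses declared counts by default.
#'
#' @inheritParams select_corrected
#' @param query A [tissue_query()] with `mode = "legacy"`.
#' @export
select_legacy <- function(libraries, query) {
  stopifnot(inherits(query, "tissue_query"))
  if (query$mode != "legacy") stop("query mode must be 'legacy'", call. = FALSE)
  via <- legacy_match_via(libraries, case_fold(query$tissue), query$extra_phrases)
  selected <- libraries[!is.na(via), , drop = FALSE]
  selected$matched_via <- via[!is.na(via)]
  apply_common_filters(selected, query)
}

#' Select libraries for a tissue query
#'
#' Dispatches to [select_corrected()] or [select_legacy()] by `query$mode`.
#' @inheritParams select_corrected
#' @export
select_libraries <- function(libraries, query) {
  if (query$mode == "corrected") select_corrected(libraries, query)
  else select_legacy(libraries, query)
}

# Tissues that never occur in the unique-tissue field; a library counts as
# correctly reported for them when the phrase appears among its keywords.
KEYWORD_SCORED_TISSUES <- c("germ cell", "head and neck", "stem cell")

is_correct_library <- function(selected, tissue) {
  t_cf <- case_fold(tissue)
  if (t_cf %in% KEYWORD_SCORED_TISSUES) {
    vapply(selected$keywords, function(k) t_cf %in% case_fold(k), logical(1))
  } else {
    case_fold(selected$unique_tissue) == t_cf
  }
}

#' Score how many selected libraries are correctly reported
#'
#' A library is correctly reported when its `unique_tissue` annotation
#' precisely matches the selected tissue (case-folded). For the tissues
#' `"germ cell"`, `"head and neck"` and `"stem cell"`, which never occur as a
#' unique-tissue annotation, a whole-phrase keywords match counts instead.
#' Percentages are reported to two decimals, rounded half-up. An empty
#' selection reports zero percentages flagged as not available.
#'
#' @param selected Libraries returned by a selector.
#' @param tissue The queried tissue phrase.
#' @return A `dged_classification` list: `tissue`, `n_selected`, `n_correct`,
#'   `n_incorrect`, `pct_correct`, `pct_incorrect`, `available`.
#' @export
classification_rate <- function(selected, tissue) {
  correct <- is_correct_library(selected, tissue)
  n <- nrow(selected)
  nc <- sum(correct)
  ni <- n - nc
  if (n > 0L) {
    pc <- round_half_up(100 * nc / n, 2)
    pinc <- round_half_up(100 * ni / n, 2)
  } else {
    pc <- 0; pinc <- 0
  }
  structure(list(tissue = tissue, n_selected = n, n_correct = nc,
                 n_incorrect = ni, pct_correct = pc, pct_incorrect = pinc,
                 available = n > 0L),
            class = "dged_classification")
}

#' @export
print.dged_classification <- function(x, ...) {
  cat(sprintf("Tissue query: %s\n", x$tissue))
  if (!x$available) {
    cat("No libraries selected (percentages not available)\n")
  } else {
    cat(sprintf("Libraries selected: %d (correct %d, incorrect %d)\n",
                x$n_selected, x$n_correct, x$n_incorrect))
    cat(sprintf("Correctly reported: %.2f%%  Incorrectly reported: %.2f%%\n",
                x$pct_correct, x$pct_incorrect))
  }
  invisible(x)
}
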