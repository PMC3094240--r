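# Readers and writers for the library metadata flat file and the relational
# expression / gene tables. Parsing is lossless: unknown flat-file headings are
# carried through verbatim so parse -> write reproduces a generated file
# byte-for-byte.

LIB_HEADINGS <- c("LIBRARY_ID", "TITLE", "KEYWORDS", "TISSUE", "HISTOLOGY",
                  "UNIQUE_TISSUE", "SEQUENCES", "PROTOCOL")
EXPR_HEADER <- "library_id\tcluster_id\tcount"
GENE_HEADER <- "cluster_id\tsymbol\ttitle"

new_library_table <- function(library_id = character(), title = character(),
                              tissue_supplied = character(), histology = character(),
                              unique_tissue = character(), declared_sequences = integer(),
                              keywords = list(), protocol = list(), extra = list()) {
  out <- data.frame(
    library_id = library_id,
    title = title,
    tissue_supplied = tissue_supplied,
    histology = histology,
    unique_tissue = unique_tissue,
    declared_sequences = as.integer(declared_sequences),
    mapped_sequences = rep(NA_integer_, length(library_id)),
    stringsAsFactors = FALSE
  )
  out$keywords <- keywords
  out$protocol <- protocol
  out$extra <- extra
  class(out) <- c("dged_libraries", "data.frame")
  out
}

split_phrases <- function(value) {
  if (!nzchar(value)) return(character(0))
  parts <- trimws(strsplit(value, ";", fixed = TRUE)[[1L]])
  parts[nzchar(parts)]
}

#' Parse a library metadata flat file
#'
#' Reads CGAP-style cDNA library records: one `HEADING: value` field per line,
#' records separated by a single blank line. Required headings are
#' `LIBRARY_ID`, `UNIQUE_TISSUE` and `SEQUENCES`; `TITLE`, `TISSUE`,
#' `HISTOLOGY`, `KEYWORDS` and `PROTOCOL` default to empty. `KEYWORDS` and
#' `PROTOCOL` are semicolon-separated phrase lists. Any other heading is kept
#' verbatim (in order) in the `extra` column so that writing the records back
#' out reproduces the input exactly.
#'
#' @param file Path or connection to read from.
#' @param text A literal string to parse instead of a file.
#' @return A data frame of class `dged_libraries` with columns `library_id`,
#'   `title`, `tissue_supplied`, `histology`, `unique_tissue`,
#'   `declared_sequences` (integer), `mapped_sequences` (integer, `NA` until
#'   [compute_mapped_counts()] runs) and list columns `keywords`, `protocol`,
#'   `extra`. Field values are whitespace-trimmed; original case is preserved.
#' @seealso [write_library_records()], [compute_mapped_counts()]
#' @export
#' @examples
#' txt <- paste0("LIBRARY_ID: LIB1\nTITLE: test\nKEYWORDS: heart disease; bulk\n",
#'               "TISSUE: brain\nHISTOLOGY: normal\nUNIQUE_TISSUE: brain\n",
#'               "SEQUENCES: 10\nPROTOCOL: bulk; non-normalized\n")
#' libs <- parse_library_records(text = txt)
#' libs$keywords[[1]]
parse_library_records <- function(file = NULL, text = NULL) {
  lines <- read_input_lines(file, text)
  blocks <- list()
  cur_h <- character(0)
  cur_v <- character(0)
  cur_start <- NA_integer_
  flush <- function() {
    if (length(cur_h)) {
      blocks[[length(blocks) + 1L]] <<- list(h = cur_h, v = cur_v, line = cur_start)
    }
    cur_h <<- character(0); cur_v <<- character(0); cur_start <<- NA_integer_
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0L) {
      stop(sprintf("library flat file parse error at line %d: no ':' separator in \"%s\"",
                   i, ln), call. = FALSE)
    }
    if (is.na(cur_start)) cur_start <- i
    cur_h <- c(cur_h, trimws(substr(ln, 1L, pos - 1L)))
    cur_v <- c(cur_v, trimws(substr(ln, pos + 1L, nchar(ln))))
  }
  flush()

  n <- length(blocks)
  ids <- titles <- tissues <- hists <- utissues <- character(n)
  seqs <- integer(n)
  kws <- prots <- extras <- vector("list", n)
  for (j in seq_len(n)) {
    b <- blocks[[j]]
    rec_name <- function() {
      id <- b$v[match("LIBRARY_ID", b$h)]
      if (is.na(id) || !nzchar(id)) sprintf("record #%d (line %d)", j, b$line)
      else sprintf("record '%s'", id)
    }
    getf <- function(h) { k <- match(h, b$h); if (is.na(k)) NA_character_ else b$v[[k]] }
    id <- getf("LIBRARY_ID")
    if (is.na(id) || !nzchar(id)) {
      stop("library record validation error: missing LIBRARY_ID in ", rec_name(), call. = FALSE)
    }
    for (req in c("UNIQUE_TISSUE", "SEQUENCES")) {
      if (is.na(getf(req))) {
        stop(sprintf("library record validation error: missing %s field in %s",
                     req, rec_name()), call. = FALSE)
      }
    }
    sq <- getf("SEQUENCES")
    if (!grepl("^[0-9]+$", sq)) {
      stop(sprintf("library record validation error: SEQUENCES must be a non-negative integer in %s (got \"%s\")",
                   rec_name(), sq), call. = FALSE)
    }
    ut <- getf("UNIQUE_TISSUE")
    if (grepl(";", ut, fixed = TRUE)) {
      stop(sprintf("library record validation error: UNIQUE_TISSUE must be a single phrase in %s (got \"%s\")",
                   rec_name(), ut), call. = FALSE)
    }
    ids[j] <- id
    titles[j] <- if (is.na(getf("TITLE"))) "" else getf("TITLE")
    tissues[j] <- if (is.na(getf("TISSUE"))) "" else getf("TISSUE")
    hists[j] <- if (is.na(getf("HISTOLOGY"))) "" else getf("HISTOLOGY")
    utissues[j] <- ut
    seqs[j] <- as.integer(sq)
    kws[[j]] <- if (is.na(getf("KEYWORDS"))) character(0) else split_phrases(getf("KEYWORDS"))
    prots[[j]] <- if (is.na(getf("PROTOCOL"))) character(0) else split_phrases(getf("PROTOCOL"))
    unknown <- !(b$h %in% LIB_HEADINGS)
    extras[[j]] <- stats::setNames(b$v[unknown], b$h[unknown])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("library record validation error: duplicate LIBRARY_ID: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  new_library_table(ids, titles, tissues, hists, utissues, seqs, kws, prots, extras)
}

#' Serialize library records to flat-file lines
#'
#' Emits the canonical heading order (`LIBRARY_ID`, `TITLE`, `KEYWORDS`,
#' `TISSUE`, `HISTOLOGY`, `UNIQUE_TISSUE`, `SEQUENCES`, `PROTOCOL`), then any
#' pass-through headings, then a blank line terminating the record.
#'
#' @param records A `dged_libraries` data frame.
#' @return Character vector of lines (no trailing newline characters).
#' @export
format_library_records <- function(records) {
  stopifnot(is.data.frame(records))
  lines <- character(0)
  for (j in seq_len(nrow(records))) {
    id <- records$library_id[j]
    if (is.na(id) || !nzchar(id)) stop("cannot write record: unset library_id", call. = FALSE)
    if (is.na(records$unique_tissue[j]) || !nzchar(records$unique_tissue[j])) {
      stop("cannot write record '", id, "': unset unique_tissue", call. = FALSE)
    }
    if (is.na(records$declared_sequences[j]) || records$declared_sequences[j] < 0L) {
      stop("cannot write record '", id, "': unset declared_sequences", call. = FALSE)
    }
    rec <- c(
      paste0("LIBRARY_ID: ", id),
      paste0("TITLE: ", records$title[j]),
      paste0("KEYWORDS: ", paste(records$keywords[[j]], collapse = "; ")),
      paste0("TISSUE: ", records$tissue_supplied[j]),
      paste0("HISTOLOGY: ", records$histology[j]),
      paste0("UNIQUE_TISSUE: ", records$unique_tissue[j]),
      paste0("SEQUENCES: ", records$declared_sequences[j]),
      paste0("PROTOCOL: ", paste(records$protocol[[j]], collapse = "; "))
    )
    ex <- records$extra[[j]]
    if (length(ex)) rec <- c(rec, paste0(names(ex), ": ", ex))
    lines <- c(lines, rec, "")
  }
  lines
}

#' Write library records to a flat file
#'
#' Inverse of [parse_library_records()]: parsing the written file recovers the
#' records, and a parsed fixture file round-trips byte-identically.
#'
#' @inheritParams format_library_records
#' @param file Path to write.
#' @export
write_library_records <- function(records, file) {
  write_lines_atomic(format_library_records(records), file)
}

parse_three_column <- function(file, text, header, what) {
  lines <- read_input_lines(file, text)
  if (!length(lines)) {
    stop(what, " parse error: empty input (expected header line)", call. = FALSE)
  }
  if (!identical(lines[[1L]], header)) {
    stop(sprintf("%s parse error: bad header line (expected \"%s\")",
                 what, gsub("\t", "\\\\t", header)), call. = FALSE)
  }
  body <- lines[-1L]
  body_idx <- which(nzchar(body))
  if (!length(body_idx)) {
    return(list(m = matrix(character(0), ncol = 3L), lines = integer(0)))
  }
  parts <- strsplit(body[body_idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) > 3L)
  if (length(bad)) {
    stop(sprintf("%s parse error at line %d: more than 3 columns",
                 what, body_idx[bad[1L]] + 1L), call. = FALSE)
  }
  parts <- lapply(parts, function(p) c(p, character(3L - length(p))))
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 3L, byrow = TRUE)
  list(m = m, lines = body_idx + 1L)
}

#' Parse a relational expression table
#'
#' Tab-delimited table with header `library_id<TAB>cluster_id<TAB>count`
#' listing, for each library, the gene clusters it contains and the number of
#' sequences in that library representing each cluster.
#'
#' @inheritParams parse_library_records
#' @return Data frame with character columns `library_id`, `cluster_id` and
#'   integer `count` (all counts >= 1).
#' @export
parse_expression_table <- function(file = NULL, text = NULL) {
  p <- parse_three_column(file, text, EXPR_HEADER, "expression table")
  if (!nrow(p$m)) {
    return(data.frame(library_id = character(), cluster_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  cnt <- p$m[, 3L]
  bad <- which(!grepl("^[0-9]+$", cnt) | cnt == "0")
  if (length(bad)) {
    stop(sprintf("expression table parse error at line %d: count must be a positive integer (got \"%s\")",
                 p$lines[bad[1L]], cnt[bad[1L]]), call. = FALSE)
  }
  key <- paste(p$m[, 1L], p$m[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("expression table validation error: duplicate (library_id, cluster_id) pair: ",
         paste(p$m[dup, 1L], p$m[dup, 2L], sep = "/", collapse = ", "), call. = FALSE)
  }
  data.frame(library_id = p$m[, 1L], cluster_id = p$m[, 2L],
             count = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Write an expression table
#' @param entries Data frame as returned by [parse_expression_table()].
#' @param file Path to write.
#' @export
write_expression_table <- function(entries, file) {
  write_lines_atomic(
    c(EXPR_HEADER,
      if (nrow(entries)) paste(entries$library_id, entries$cluster_id, entries$count, sep = "\t")),
    file)
}

#' Parse a relational gene table
#'
#' Tab-delimited table with header `cluster_id<TAB>symbol<TAB>title` giving the
#' identity of each gene cluster. An empty symbol is permitted (anonymous
#' transcripts); duplicate cluster ids are a validation error.
#'
#' @inheritParams parse_library_records
#' @return Data frame with character columns `cluster_id`, `symbol`, `title`.
#' @export
parse_gene_table <- function(file = NULL, text = NULL) {
  p <- parse_three_column(file, text, GENE_HEADER, "gene table")
  if (!nrow(p$m)) {
    return(data.frame(cluster_id = character(), symbol = character(),
                      title = character(), stringsAsFactors = FALSE))
  }
  blank <- which(!nzchar(p$m[, 1L]))
  if (length(blank)) {
    stop(sprintf("gene table validation error at line %d: empty cluster_id",
                 p$lines[blank[1L]]), call. = FALSE)
  }
  dup <- duplicated(p$m[, 1L])
  if (any(dup)) {
    stop("gene table validation error: duplicate cluster_id: ",
         paste(unique(p$m[dup, 1L]), collapse = ", "), call. = FALSE)
  }
  data.frame(cluster_id = p$m[, 1L], symbol = p$m[, 2L], title = p$m[, 3L],
             stringsAsFactors = FALSE)
}

#' Write a gene table
#' @param genes Data frame as returned by [parse_gene_table()].
#' @param file Path to write.
#' @export
write_gene_table <- function(genes, file) {
  write_lines_atomic(
    c(GENE_HEADER,
      if (nrow(genes)) paste(genes$cluster_id, genes$symbol, genes$title, sep = "\t")),
    file)
}
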