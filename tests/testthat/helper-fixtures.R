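# Shared helpers for building small in-code fixtures.

lib_text <- function(id, title = "t", keywords = character(), tissue = "",
                     histology = "", unique_tissue = "brain", sequences = 10,
                     protocol = c("bulk", "non-normalized"), extra = character()) {
  lines <- c(
    paste0("LIBRARY_ID: ", id),
    paste0("TITLE: ", title),
    paste0("KEYWORDS: ", paste(keywords, collapse = "; ")),
    paste0("TISSUE: ", tissue),
    paste0("HISTOLOGY: ", histology),
    paste0("UNIQUE_TISSUE: ", unique_tissue),
    paste0("SEQUENCES: ", sequences),
    paste0("PROTOCOL: ", paste(protocol, collapse = "; "))
  )
  if (length(extra)) lines <- c(lines, paste0(names(extra), ": ", extra))
  paste0(paste(lines, collapse = "\n"), "\n\n")
}

# Small in-memory library table built through the parser (so tests exercise
# the same construction path users do).
make_libs <- function(...) {
  parse_library_records(text = paste0(...))
}

expr_df <- function(library_id, cluster_id, count) {
  data.frame(library_id = library_id, cluster_id = cluster_id,
             count = as.integer(count), stringsAsFactors = FALSE)
}

# Independent brute-force legacy matcher: naive substring scan over the
# concatenation of each keywords phrase and the unique-tissue field.
brute_force_legacy_ids <- function(libraries, tissue) {
  needle <- tolower(trimws(tissue))
  hit <- vapply(seq_len(nrow(libraries)), function(j) {
    fields <- tolower(trimws(c(libraries$keywords[[j]], libraries$unique_tissue[j])))
    any(vapply(fields, function(f) {
      nf <- nchar(f); nn <- nchar(needle)
      if (nn > nf) return(FALSE)
      any(vapply(seq_len(nf - nn + 1L),
                 function(s) substr(f, s, s + nn - 1L) == needle, logical(1)))
    }, logical(1)))
  }, logical(1))
  libraries$library_id[hit]
}

# Independent log-factorial enumeration of the two-sided Fisher exact
# p-value (minimum-likelihood convention) for table [[a, A-a], [b, B-b]].
enum_fisher_p <- function(a, A, b, B) {
  m <- a + b
  n2 <- (A - a) + (B - b)
  support <- max(0L, A - n2):min(A, m)
  lp <- lfactorial(m) - lfactorial(support) - lfactorial(m - support) +
    lfactorial(n2) - lfactorial(A - support) - lfactorial(n2 - A + support) +
    lfactorial(A) + lfactorial(m + n2 - A) - lfactorial(m + n2)
  p <- exp(lp)
  obs <- p[match(a, support)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}
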