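# Internal helpers shared across modules.

# Case-folded, whitespace-trimmed text for annotation comparison. Parsing
# preserves original case; all matching goes through this.
case_fold <- function(x) tolower(trimws(x))

# Round half away from zero ("half-up" for positive percentages), which is how
# the reported library classification percentages are presented.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards: no routine in this package leaks global random state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Read input either from a file/connection or from a literal string.
read_input_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    stopifnot(is.character(text), length(text) == 1L)
    if (identical(text, "")) return(character(0))
    return(strsplit(text, "\n", fixed = TRUE)[[1L]])
  }
  if (is.null(file)) stop("either `file` or `text` must be supplied", call. = FALSE)
  if (is.character(file) && !file.exists(file)) {
    stop("input file not found: ", file, call. = FALSE)
  }
  readLines(file)
}

# Write lines to `file` atomically: the destination appears only once the
# content is complete, so a failed run leaves no partial report behind.
write_lines_atomic <- function(lines, file) {
  tmp <- paste0(file, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, file)) stop("could not write output file: ", file, call. = FALSE)
  invisible(file)
}

# Fixed-precision serialization: counts as integers, reals at 6 significant
# digits, so identical statistics serialize to identical bytes.
format_num6 <- function(x) {
  out <- character(length(x))
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  inf <- is.infinite(x)
  out[inf] <- ifelse(x[inf] > 0, "Inf", "-Inf")
  fin <- is.finite(x)
  out[fin] <- trimws(formatC(signif(x[fin], 6), format = "g", digits = 6))
  out
}
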