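#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Parse reports ---------------------------------------------------------

new_parse_report <- function(n_records = 0L, n_skipped = 0L,
                             warnings = character()) {
  structure(
    list(n_records = as.integer(n_records),
         n_skipped = as.integer(n_skipped),
         warnings = as.character(warnings)),
    class = "parse_report"
  )
}

#' Retrieve the parse report attached to a read result
#'
#' Every reader in the package attaches a parse report recording how many
#' records were kept, how many were skipped, and any per-record warnings.
#'
#' @param x An object returned by one of the `read_*()` functions.
#' @return A list with elements `n_records`, `n_skipped` and `warnings`.
#' @export
parse_report <- function(x) {
  if (igraph::is_igraph(x)) {
    return(igraph::graph_attr(x, "parse_report"))
  }
  attr(x, "parse_report", exact = TRUE)
}

set_parse_report <- function(x, report) {
  if (igraph::is_igraph(x)) {
    igraph::graph_attr(x, "parse_report") <- report
    return(x)
  }
  attr(x, "parse_report") <- report
  x
}

#' @export
print.parse_report <- function(x, ...) {
  cat("<parse_report> records:", x$n_records,
      " skipped:", x$n_skipped, "\n")
  if (length(x$warnings)) {
    cat(paste0("  - ", utils::head(x$warnings, 10L)), sep = "\n")
    if (length(x$warnings) > 10L) {
      cat("  ...", length(x$warnings) - 10L, "more\n")
    }
  }
  invisible(x)
}

# Small shared helpers --------------------------------------------------

# read non-empty, non-comment lines of a text file
read_data_lines <- function(path, comment = "#") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!is.null(comment) && nzchar(comment)) {
    lines <- lines[!startsWith(trimws(lines), comment)]
  }
  lines
}

# deterministic sub-seed derived from a base seed and a label, < 2^31
fork_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}
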