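# Readers and writers for the external formats the pipeline touches.
# All genomic coordinates are held 0-based half-open internally: BED is
# consumed as-is, FIMO and GAF conventions are converted on read.

#' Read genomic intervals from a BED3+ file
#'
#' Reads hotspot or coldspot intervals. Coordinates are kept 0-based
#' half-open, as in BED. Malformed lines, intervals on chromosomes absent
#' from `chrom_lengths`, and intervals exceeding chromosome bounds are
#' skipped and counted in the attached [parse_report()].
#'
#' @param path Path to a BED3+ text file.
#' @param chrom_lengths Named numeric vector mapping chromosome name to
#'   length in bases.
#' @param label One of `"hotspot"`, `"coldspot"`, `"other"`; recorded on
#'   the returned set.
#' @return A tibble with columns `chrom`, `start`, `end` (class
#'   `spot_set`), with attributes `label` and `parse_report`.
#' @export
read_intervals <- function(path, chrom_lengths,
                           label = c("other", "hotspot", "coldspot")) {
  label <- match.arg(label)
  stopifnot(is.numeric(chrom_lengths), all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)))
  lines <- read_data_lines(path, comment = "#")
  lines <- lines[!grepl("^(track|browser)\\b", lines)]
  warns <- character()
  rows <- vector("list", length(lines))
  kept <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 3L) {
      warns <- c(warns, paste("malformed line:", ln))
      next
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      warns <- c(warns, paste("invalid coordinates:", ln))
      next
    }
    if (!f[1] %in% names(chrom_lengths)) {
      warns <- c(warns, paste("unknown chromosome:", f[1]))
      next
    }
    if (end > chrom_lengths[[f[1]]]) {
      warns <- c(warns, paste("interval exceeds chromosome bounds:", ln))
      next
    }
    kept <- kept + 1L
    rows[[kept]] <- tibble(chrom = f[1], start = start, end = end)
  }
  out <- if (kept) dplyr::bind_rows(rows[seq_len(kept)]) else
    tibble(chrom = character(), start = numeric(), end = numeric())
  out <- new_spot_set(out, label)
  set_parse_report(out, new_parse_report(kept, length(lines) - kept, warns))
}

#' Construct an interval set in memory
#'
#' @param chrom,start,end Vectors describing 0-based half-open intervals.
#' @param label Interval class label.
#' @return A `spot_set` tibble.
#' @export
spot_set <- function(chrom, start, end,
                     label = c("other", "hotspot", "coldspot")) {
  label <- match.arg(label)
  stopifnot(all(start >= 0), all(end > start))
  new_spot_set(tibble(chrom = chrom, start = start, end = end), label)
}

new_spot_set <- function(tbl, label) {
  out <- as_tibble(tbl)
  class(out) <- c("spot_set", class(out))
  attr(out, "label") <- label
  out
}

#' @rdname read_intervals
#' @param x A `spot_set` tibble.
#' @export
write_intervals <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interval-set label ("hotspot", "coldspot" or "other")
#' @param x A `spot_set`.
#' @export
spot_label <- function(x) attr(x, "label", exact = TRUE) %||% "other"

# Motif matrices --------------------------------------------------------

#' Construct a motif (position frequency) matrix
#'
#' @param motif_id Identifier string.
#' @param counts 4 x w nonnegative matrix, rows in A, C, G, T order.
#' @param background Length-4 probability vector over A, C, G, T.
#' @param pseudocount Nonnegative scalar, distributed over bases according
#'   to `background` when scoring.
#' @return An object of class `motif_matrix`.
#' @export
motif_matrix <- function(motif_id, counts,
                         background = rep(0.25, 4), pseudocount = 0.1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("malformed motif: expected 4 rows (A,C,G,T)")
  if (ncol(counts) < 1L) abort("malformed motif: zero width")
  if (any(counts < 0)) abort("malformed motif: negative entry")
  stopifnot(length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-6, pseudocount >= 0)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(
    list(motif_id = as.character(motif_id), counts = counts,
         background = as.numeric(background),
         pseudocount = as.numeric(pseudocount)),
    class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix>", x$motif_id, " width:", ncol(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Motif width in bases
#' @param m A `motif_matrix`.
#' @export
motif_width <- function(m) ncol(m$counts)

#' Read transcription-factor binding motifs
#'
#' Supports JASPAR PFM (`>` header, four `A/C/G/T [ ... ]` rows) and MEME
#' minimal (letter-probability matrices, one row per position). A motif
#' whose nucleotide matrix does not have exactly four rows, or that
#' contains a negative entry, is a hard error.
#'
#' @param path Path to the motif file.
#' @param dialect `"jaspar_pfm"` or `"meme_minimal"`.
#' @inheritParams motif_matrix
#' @return A list of [motif_matrix()] objects.
#' @export
read_motifs <- function(path, dialect = c("jaspar_pfm", "meme_minimal"),
                        background = rep(0.25, 4), pseudocount = 0.1) {
  dialect <- match.arg(dialect)
  if (dialect == "jaspar_pfm") {
    read_motifs_jaspar(path, background, pseudocount)
  } else {
    read_motifs_meme(path, background, pseudocount)
  }
}

read_motifs_jaspar <- function(path, background, pseudocount) {
  lines <- read_data_lines(path, comment = NULL)
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) abort("no JASPAR motif headers found")
  bounds <- c(starts, length(lines) + 1L)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "[ \t]+")[[1]][1]
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L) abort("malformed motif: expected 4 nucleotide rows")
    rows <- lapply(body, function(b) {
      b <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?", "", b)
      b <- gsub("\\]", "", b)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(b), "[ \t]+")[[1]]))
      if (anyNA(vals)) abort("malformed motif: non-numeric entry")
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort("malformed motif: ragged rows")
    }
    motifs[[i]] <- motif_matrix(id, do.call(rbind, rows),
                                background, pseudocount)
  }
  motifs
}

read_motifs_meme <- function(path, background, pseudocount) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) abort("no MEME MOTIF records found")
  bounds <- c(starts, length(lines) + 1L)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[i]]), "[ \t]+")[[1]][2]
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    hdr <- grep("letter-probability matrix", body)
    if (!length(hdr)) abort("malformed motif: missing letter-probability matrix")
    w <- suppressWarnings(
      as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", body[hdr[1]])))
    rows <- list()
    j <- hdr[1] + 1L
    while (j <= length(body) && length(rows) < (w %||% Inf)) {
      tl <- trimws(body[j])
      if (!nzchar(tl)) { j <- j + 1L; next }
      vals <- suppressWarnings(as.numeric(strsplit(tl, "[ \t]+")[[1]]))
      if (anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    if (!length(rows)) abort("malformed motif: empty probability matrix")
    if (length(unique(lengths(rows))) != 1L || lengths(rows)[1] != 4L) {
      abort("malformed motif: expected 4 columns per position (A,C,G,T)")
    }
    # MEME rows are positions; transpose to 4 x w
    motifs[[i]] <- motif_matrix(id, t(do.call(rbind, rows)),
                                background, pseudocount)
  }
  motifs
}

# FIMO-style hit tables -------------------------------------------------

#' Read precomputed motif hits (FIMO-style TSV)
#'
#' Expects a tab-separated file with a header naming at least the motif
#' id, sequence name, start, stop and p-value columns (modern FIMO TSV).
#' FIMO's 1-based inclusive `[start, stop]` is converted to 0-based
#' half-open `[start - 1, stop)`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `motif_id`, `chrom`, `start`, `end`,
#'   `strand`, `score`, `p_value`, carrying a [parse_report()].
#' @export
read_fimo_hits <- function(path) {
  lines <- read_data_lines(path, comment = "#")
  if (!length(lines)) abort("empty FIMO file: header required")
  header <- strsplit(lines[1], "\t")[[1]]
  need <- c(motif_id = "motif_id", chrom = "sequence_name",
            start = "start", end = "stop", p_value = "p-value")
  idx <- stats::setNames(match(need, header), names(need))
  if (anyNA(idx)) {
    abort(paste("missing required FIMO column(s):",
                paste(need[is.na(idx)], collapse = ", ")))
  }
  strand_i <- match("strand", header)
  score_i <- match("score", header)
  body <- lines[-1]
  warns <- character()
  kept <- 0L
  rows <- vector("list", length(body))
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    p <- suppressWarnings(as.numeric(f[idx[["p_value"]]]))
    s <- suppressWarnings(as.numeric(f[idx[["start"]]]))
    e <- suppressWarnings(as.numeric(f[idx[["end"]]]))
    if (is.na(p) || is.na(s) || is.na(e)) {
      warns <- c(warns, paste("skipping row with missing value:", ln))
      next
    }
    kept <- kept + 1L
    rows[[kept]] <- tibble(
      motif_id = f[idx[["motif_id"]]],
      chrom = f[idx[["chrom"]]],
      start = s - 1, end = e,
      strand = if (!is.na(strand_i)) f[strand_i] else "+",
      score = if (!is.na(score_i))
        suppressWarnings(as.numeric(f[score_i])) else NA_real_,
      p_value = p)
  }
  out <- if (kept) dplyr::bind_rows(rows[seq_len(kept)]) else
    tibble(motif_id = character(), chrom = character(), start = numeric(),
           end = numeric(), strand = character(), score = numeric(),
           p_value = numeric())
  set_parse_report(out, new_parse_report(kept, length(body) - kept, warns))
}

#' Write motif hits as FIMO-compatible TSV
#'
#' Inverse of [read_fimo_hits()]: internal 0-based half-open coordinates
#' are written back as FIMO's 1-based inclusive start/stop, so internally
#' scanned hits and external FIMO output are interchangeable.
#'
#' @param hits A hit tibble as produced by [scan_intervals()].
#' @param path Output path.
#' @export
write_fimo_hits <- function(hits, path) {
  df <- data.frame(
    motif_id = hits$motif_id, motif_alt_id = "",
    sequence_name = hits$chrom,
    start = format(hits$start + 1, scientific = FALSE, trim = TRUE),
    stop = format(hits$end, scientific = FALSE, trim = TRUE),
    strand = hits$strand, score = hits$score,
    `p-value` = hits$p_value, `q-value` = "", matched_sequence = "",
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# PPI networks ----------------------------------------------------------

#' Read a protein-protein interaction network
#'
#' Two identifier columns plus an optional numeric weight column,
#' whitespace- or tab-separated. The result is an undirected simple
#' igraph: duplicate edges are merged keeping the maximum weight,
#' self-loops are dropped with a warning, and missing weights default
#' to 1.
#'
#' @param path Path to the edge-list file.
#' @return An undirected `igraph` object with edge attribute `weight`,
#'   carrying a [parse_report()] as a graph attribute.
#' @export
read_network <- function(path) {
  lines <- read_data_lines(path, comment = "#")
  warns <- character()
  kept <- 0L
  a <- b <- character(length(lines)); w <- numeric(length(lines))
  nodes <- character()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 2L) {
      warns <- c(warns, paste("malformed edge line:", ln))
      next
    }
    wt <- 1
    if (length(f) >= 3L) {
      wt <- suppressWarnings(as.numeric(f[3]))
      if (is.na(wt)) abort(paste("non-numeric edge weight:", f[3]))
    }
    nodes <- c(nodes, f[1], f[2])
    if (f[1] == f[2]) {
      warns <- c(warns, paste("self-loop dropped:", f[1]))
      next
    }
    kept <- kept + 1L
    a[kept] <- f[1]; b[kept] <- f[2]; w[kept] <- wt
  }
  edges <- tibble(a = a[seq_len(kept)], b = b[seq_len(kept)],
                  weight = w[seq_len(kept)])
  if (nrow(edges)) {
    # canonical orientation, then merge duplicates keeping max weight
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    edges <- edges |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(unique(nodes))))
  set_parse_report(g, new_parse_report(kept, length(lines) - kept, warns))
}

# Ontology + annotations ------------------------------------------------

#' Read a GO ontology (OBO 1.2) and gene annotations (GAF 2.x)
#'
#' Obsolete terms are excluded; `is_a` and `part_of` relationships are
#' retained as child-to-parent edges; a cycle in the resulting graph is a
#' hard error. GAF annotations carrying a `NOT` qualifier or referring to
#' a term absent from the DAG are skipped with a warning.
#'
#' @param obo_path Path to an OBO 1.2 file.
#' @param gaf_path Path to a GAF 2.x file.
#' @return A list with elements `dag` (a `go_dag`: tibbles `terms` and
#'   `edges`) and `annotations` (named list, gene id to character vector
#'   of term ids), carrying a [parse_report()].
#' @export
read_ontology <- function(obo_path, gaf_path) {
  dag <- read_obo(obo_path)
  lines <- readLines(gaf_path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  warns <- character()
  kept <- 0L
  genes <- terms <- character(length(lines))
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 5L) {
      warns <- c(warns, paste("malformed GAF line:", ln))
      next
    }
    if (grepl("\\bNOT\\b", f[4])) {
      warns <- c(warns, paste("NOT qualifier, annotation skipped:", f[2]))
      next
    }
    if (!f[5] %in% dag$terms$id) {
      warns <- c(warns, paste("annotation to unknown term skipped:", f[5]))
      next
    }
    kept <- kept + 1L
    genes[kept] <- f[2]; terms[kept] <- f[5]
  }
  ann <- split(terms[seq_len(kept)], genes[seq_len(kept)])
  ann <- lapply(ann, unique)
  out <- list(dag = dag, annotations = ann)
  set_parse_report(out, new_parse_report(kept, length(lines) - kept, warns))
}

read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_at <- which(trimws(lines) == "[Term]")
  if (!length(stanza_at)) abort("no [Term] stanzas found")
  bounds <- c(stanza_at, length(lines) + 1L)
  ids <- names_ <- ns <- character()
  ec <- ep <- er <- character()
  for (i in seq_along(stanza_at)) {
    body <- lines[(stanza_at[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[!startsWith(trimws(body), "[")]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), body, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":\\s*"), "", hit[1]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names_ <- c(names_, get1("name") %||% "")
    ns <- c(ns, get1("namespace") %||% "biological_process")
    for (p in grep("^is_a:", body, value = TRUE)) {
      parent <- strsplit(trimws(sub("^is_a:\\s*", "", p)), "[ \t!]")[[1]][1]
      ec <- c(ec, id); ep <- c(ep, parent); er <- c(er, "is_a")
    }
    for (p in grep("^relationship:\\s*part_of", body, value = TRUE)) {
      parent <- strsplit(
        trimws(sub("^relationship:\\s*part_of\\s*", "", p)), "[ \t!]")[[1]][1]
      ec <- c(ec, id); ep <- c(ep, parent); er <- c(er, "part_of")
    }
  }
  ns[is.na(ns)] <- "biological_process"
  terms <- tibble(id = ids, name = names_, namespace = ns)
  edges <- tibble(child = ec, parent = ep, relation = er) |>
    dplyr::filter(.data$child %in% ids, .data$parent %in% ids) |>
    dplyr::distinct()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) abort("cycle detected in ontology")
  }
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag>", nrow(x$terms), "terms,", nrow(x$edges), "edges\n")
  invisible(x)
}

# Clusters and orthologs -------------------------------------------------

#' Read conserved gene clusters (one whitespace-separated cluster per line)
#'
#' Clusters of size below 2 are dropped with a warning.
#'
#' @param path Path to the cluster file.
#' @return A list of character vectors, carrying a [parse_report()].
#' @export
read_clusters <- function(path) {
  lines <- read_data_lines(path, comment = "#")
  warns <- character()
  if (!length(lines)) warns <- "empty cluster file"
  clusters <- lapply(lines, function(ln) {
    unique(strsplit(trimws(ln), "[ \t]+")[[1]])
  })
  small <- lengths(clusters) < 2L
  if (any(small)) {
    warns <- c(warns, paste("cluster of size < 2 dropped, line",
                            which(small)))
  }
  out <- clusters[!small]
  set_parse_report(out, new_parse_report(length(out), sum(small), warns))
}

#' Read an ortholog map (two-column TSV)
#'
#' Duplicate pairs are merged; many-to-many maps are allowed.
#'
#' @param path Path to the two-column file.
#' @return A tibble with columns `a` and `b`, carrying a [parse_report()].
#' @export
read_orthologs <- function(path) {
  lines <- read_data_lines(path, comment = "#")
  warns <- character()
  kept <- 0L
  a <- b <- character(length(lines))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 2L) {
      warns <- c(warns, paste("malformed ortholog line:", ln))
      next
    }
    kept <- kept + 1L
    a[kept] <- f[1]; b[kept] <- f[2]
  }
  out <- dplyr::distinct(tibble(a = a[seq_len(kept)], b = b[seq_len(kept)]))
  set_parse_report(out, new_parse_report(kept, length(lines) - kept, warns))
}
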