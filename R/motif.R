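# PWM scanning: log-odds scoring, an exact score distribution under the
# background model (for p-values), interval scanning on both strands, and
# tabulation of per-interval hits into hotspot/coldspot counts.

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Log-odds scoring matrix of a motif
#'
#' Converts counts to a log2 odds matrix against the background:
#' `lo(b, j) = log2(((counts(b,j) + pc * bg(b)) / (colsum_j + pc)) / bg(b))`
#' where `pc` is the pseudocount, distributed over bases by the
#' background. With a zero pseudocount, zero counts give `-Inf` (an
#' impossible emission).
#'
#' @param m A [motif_matrix()].
#' @return A 4 x w numeric matrix in bits, rows A, C, G, T.
#' @export
log_odds_matrix <- function(m) {
  stopifnot(inherits(m, "motif_matrix"))
  if (any(m$background <= 0)) abort("zero background entry")
  cs <- colSums(m$counts)
  if (any(cs + m$pseudocount <= 0)) {
    abort("zero column sum with zero pseudocount")
  }
  pc_per_base <- m$pseudocount * m$background
  freq <- sweep(m$counts + pc_per_base, 2, cs + m$pseudocount, "/")
  log2(sweep(freq, 1, m$background, "/"))
}

#' Exact null distribution of motif window scores
#'
#' Computes the distribution of the log-odds score of a random window
#' under the i.i.d. background model, by position-wise convolution on a
#' score grid of width `precision` bits. Windows containing a base with a
#' `-Inf` log-odds entry are accumulated as an "impossible" mass that can
#' never reach any finite threshold.
#'
#' @param m A [motif_matrix()].
#' @param precision Score bin width in bits (default `1e-3`).
#' @return A `score_distribution`: sorted finite scores (bits), their
#'   probabilities, the `-Inf` mass, and the grid precision.
#' @export
score_distribution <- function(m, precision = 1e-3) {
  if (!is.numeric(precision) || precision <= 0) abort("precision must be > 0")
  lo <- log_odds_matrix(m)
  q <- round(lo / precision)  # integer grid; -Inf preserved
  bg <- m$background
  scores <- 0
  probs <- 1
  inf_mass <- 0
  for (j in seq_len(ncol(q))) {
    add <- q[, j]
    finite <- is.finite(add)
    inf_mass <- inf_mass + sum(probs) * sum(bg[!finite])
    if (!any(finite)) {
      scores <- numeric(); probs <- numeric()
      break
    }
    new_scores <- rep(scores, times = sum(finite)) +
      rep(add[finite], each = length(scores))
    new_probs <- rep(probs, times = sum(finite)) *
      rep(bg[finite], each = length(probs))
    agg <- rowsum(new_probs, group = new_scores)
    scores <- as.numeric(rownames(agg))
    probs <- as.numeric(agg)
    o <- order(scores)
    scores <- scores[o]; probs <- probs[o]
  }
  structure(
    list(score = scores * precision, qscore = scores, prob = probs,
         neg_inf_mass = inf_mass, precision = precision,
         tail = rev(cumsum(rev(probs)))),
    class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution>", length(x$score), "support points, P(-Inf) =",
      format(x$neg_inf_mass), "\n")
  invisible(x)
}

#' P-value of a window score under the background distribution
#'
#' `P(S >= s)` for each score, on the same discretization grid used by
#' [score_distribution()]. Non-increasing in the score; `-Inf` scores get
#' p-value 1.
#'
#' @param dist A `score_distribution`.
#' @param scores Numeric scores in bits (may include `-Inf`).
#' @export
score_pvalue <- function(dist, scores) {
  qs <- round(scores / dist$precision)
  vapply(qs, function(s) {
    if (!is.finite(s)) return(1)
    i <- findInterval(s - 0.5, dist$qscore) + 1L
    if (i > length(dist$qscore)) 0 else dist$tail[i]
  }, numeric(1))
}

# smallest quantized score whose tail probability is <= p_threshold
score_cutoff <- function(dist, p_threshold) {
  ok <- dist$tail <= p_threshold
  if (!any(ok)) return(Inf)
  dist$qscore[which(ok)[1]]
}

#' Scan genomic intervals with a motif
#'
#' Scores every window of motif width inside each interval, on both
#' strands (the reverse strand scores the reverse-complemented window),
#' and reports windows whose score p-value under the background
#' distribution is at most `p_threshold`. Windows containing non-ACGT
#' characters are skipped. Intervals shorter than the motif yield no
#' hits.
#'
#' @param m A [motif_matrix()].
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param targets A `spot_set` of intervals (see [read_intervals()]).
#' @param p_threshold Hit threshold on the score p-value, in `(0, 1]`.
#'   The default mirrors common motif-scanner practice.
#' @param dist Optionally a precomputed [score_distribution()] for `m`.
#' @return A hit tibble (`motif_id`, `chrom`, `start`, `end`, `strand`,
#'   `score`, `p_value`) in 0-based half-open genome coordinates.
#' @export
scan_intervals <- function(m, genome, targets, p_threshold = 1e-4,
                           dist = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  dist <- dist %||% score_distribution(m)
  qcut <- score_cutoff(dist, p_threshold)
  lo <- log_odds_matrix(m)
  w <- ncol(lo)
  lo_rc <- lo[4:1, rev(seq_len(w)), drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(targets))) {
    chrom <- targets$chrom[r]
    istart <- targets$start[r]
    iend <- targets$end[r]
    if (is.na(match(chrom, names(genome)))) next
    if (iend - istart < w) next
    s <- substr(genome[[chrom]], istart + 1, iend)
    x <- seq_to_int(s)
    n_win <- length(x) - w + 1L
    if (n_win < 1L) next
    fwd <- scan_scores(x, lo, n_win)
    rev_ <- scan_scores(x, lo_rc, n_win)
    for (hit in list(list(sc = fwd, strand = "+", mat = lo),
                     list(sc = rev_, strand = "-", mat = lo_rc))) {
      qs <- round(hit$sc / dist$precision)
      keep <- which(!is.na(qs) & is.finite(qs) & qs >= qcut)
      if (length(keep)) {
        out[[length(out) + 1L]] <- tibble(
          motif_id = m$motif_id, chrom = chrom,
          start = istart + keep - 1, end = istart + keep - 1 + w,
          strand = hit$strand, score = hit$sc[keep],
          p_value = score_pvalue(dist, hit$sc[keep]))
      }
    }
  }
  if (length(out)) {
    dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start,
                   .data$strand)
  } else {
    tibble(motif_id = character(), chrom = character(), start = numeric(),
           end = numeric(), strand = character(), score = numeric(),
           p_value = numeric())
  }
}

# window scores of an integer-encoded sequence; NA where any base is
# non-ACGT
scan_scores <- function(x, lo, n_win) {
  sc <- numeric(n_win)
  for (j in seq_len(ncol(lo))) {
    sc <- sc + lo[cbind(x[j:(j + n_win - 1L)], j)]
  }
  sc
}

#' Tabulate motif hits into hotspot/coldspot counts per motif
#'
#' A hit is assigned to an interval only when fully contained in it.
#' `HM` (`CM`) is the number of distinct hotspot (coldspot) intervals
#' with at least one assigned hit; `HN = N_H - HM`, `CN = N_C - CM`.
#'
#' @param hits A hit tibble ([scan_intervals()] or [read_fimo_hits()]).
#' @param hot,cold `spot_set` interval tibbles on the same assembly.
#' @param motif_ids Optional character vector of motifs to report even
#'   when they have zero hits.
#' @return A tibble with columns `motif_id`, `HM`, `HN`, `CM`, `CN`,
#'   `N_H`, `N_C`.
#' @export
tabulate_hits <- function(hits, hot, cold, motif_ids = NULL) {
  motif_ids <- sort(unique(c(motif_ids, hits$motif_id)))
  n_h <- nrow(hot)
  n_c <- nrow(cold)
  count_bound <- function(spots) {
    if (!nrow(hits) || !nrow(spots)) {
      return(tibble(motif_id = motif_ids, n = 0L))
    }
    spots2 <- tibble(chrom = spots$chrom, ivl_start = spots$start,
                     ivl_end = spots$end, ivl_id = seq_len(nrow(spots)))
    dplyr::inner_join(hits, spots2, by = "chrom",
                      relationship = "many-to-many") |>
      dplyr::filter(.data$start >= .data$ivl_start,
                    .data$end <= .data$ivl_end) |>
      dplyr::distinct(.data$motif_id, .data$ivl_id) |>
      dplyr::count(.data$motif_id, name = "n") |>
      dplyr::right_join(tibble(motif_id = motif_ids), by = "motif_id") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  hm <- count_bound(hot)
  cm <- count_bound(cold)
  tibble(motif_id = motif_ids,
         HM = hm$n[match(motif_ids, hm$motif_id)],
         CM = cm$n[match(motif_ids, cm$motif_id)]) |>
    dplyr::mutate(HN = n_h - .data$HM, CN = n_c - .data$CM,
                  N_H = n_h, N_C = n_c) |>
    dplyr::select("motif_id", "HM", "HN", "CM", "CN", "N_H", "N_C")
}
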