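# Per-TF prioritization: odds-ratio scores from hotspot/coldspot motif
# hits, hotspot-binding (HB) profiles and their correlation network,
# relevance scores from conserved clusters, and consensus ranking by
# minimum-cost assignment under Spearman's footrule.

#' Odds-ratio scores for hotspot binding preference
#'
#' For each motif, the odds ratio `O_hc = (HM/HN) / (CM/CN)` with
#' `HN = N_H - HM` and `CN = N_C - CM`: the odds of a hotspot containing
#' at least one motif occurrence against the same odds in coldspots.
#' Degenerate cells follow the conventions: `HM = N_H` or (`CM = 0` with
#' `HM > 0`) give `+Inf`; `HM = 0` gives 0; `HM = 0` and `CM = 0`
#' together are flagged undefined (recorded as 0, with a warning).
#'
#' @param hits A hit-count tibble from [tabulate_hits()] (columns
#'   `motif_id`, `HM`, `CM`, `N_H`, `N_C`).
#' @param haldane If `TRUE`, add 0.5 to all four cells before forming the
#'   ratio (Haldane-Anscombe correction). Off by default.
#' @return The input tibble with columns `odds_ratio` and `undefined`
#'   appended.
#' @export
odds_ratio <- function(hits, haldane = FALSE) {
  stopifnot(all(c("motif_id", "HM", "CM", "N_H", "N_C") %in% names(hits)))
  if (any(hits$HM > hits$N_H) || any(hits$CM > hits$N_C)) {
    abort("bound-interval count exceeds interval count")
  }
  if (any(hits$N_H <= 0) || any(hits$N_C <= 0)) {
    abort("interval counts must be positive")
  }
  hm <- hits$HM; cm <- hits$CM
  hn <- hits$N_H - hm; cn <- hits$N_C - cm
  undefined <- hm == 0 & cm == 0
  if (haldane) {
    or <- ((hm + 0.5) / (hn + 0.5)) / ((cm + 0.5) / (cn + 0.5))
  } else {
    or <- dplyr::case_when(
      undefined ~ 0,
      hm == 0 ~ 0,
      hn == 0 ~ Inf,
      cm == 0 ~ Inf,
      TRUE ~ (hm / hn) / (cm / cn))
  }
  if (any(undefined)) {
    warn(paste("odds ratio undefined (no hits in hotspots or coldspots)",
               "for:", paste(hits$motif_id[undefined], collapse = ", ")))
  }
  out <- dplyr::mutate(hits, odds_ratio = or, undefined = undefined)
  class(out) <- unique(c("or_table", class(out)))
  out
}

# Rankings --------------------------------------------------------------

#' Construct a ranking
#'
#' A ranking is a tibble mapping gene ids bijectively onto positions
#' `1..n` (1 = top), with an optional per-gene score.
#'
#' @param gene_ids Character vector in rank order (first = top).
#' @param scores Optional numeric scores aligned with `gene_ids`.
#' @return A `ranking` tibble with columns `gene_id`, `rank`, `score`.
#' @export
ranking <- function(gene_ids, scores = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids in ranking")
  if (!length(gene_ids)) abort("empty ranking")
  out <- tibble(gene_id = gene_ids, rank = seq_along(gene_ids),
                score = scores %||% rep(NA_real_, length(gene_ids)))
  class(out) <- c("ranking", class(out))
  out
}

ranking_positions <- function(r) {
  stats::setNames(r$rank, r$gene_id)
}

#' Rank motifs by odds-ratio score
#'
#' Descending odds ratio; ties broken by descending `HM`, then
#' lexicographic motif id, so the ordering is deterministic.
#'
#' @param records Output of [odds_ratio()].
#' @return A [ranking()] tibble.
#' @export
rank_by_or <- function(records) {
  stopifnot(nrow(records) >= 1L)
  o <- order(-records$odds_ratio, -records$HM, records$motif_id)
  ranking(records$motif_id[o], records$odds_ratio[o])
}

#' Rank genes by relevance score
#'
#' Descending score; ties broken lexicographically by gene id.
#'
#' @param scores Tibble with columns `gene_id` and a numeric score column
#'   (the first non-id numeric column is used).
#' @param score_col Name of the score column (default `"R"`).
#' @return A [ranking()] tibble.
#' @export
rank_by_score <- function(scores, score_col = "R") {
  o <- order(-scores[[score_col]], scores$gene_id)
  ranking(scores$gene_id[o], scores[[score_col]][o])
}

# HB profiles and network ------------------------------------------------

#' Hotspot-binding (HB) profile of one TF
#'
#' The genome is divided into consecutive bins of `bin_length` bases,
#' laid out per chromosome (each chromosome gets `ceil(len /
#' bin_length)` bins) and concatenated in the order of `chrom_lengths`.
#' Entry `i` counts the bound hotspots whose midpoint falls in bin `i`.
#'
#' @param bound_hotspots Interval tibble (`chrom`, `start`, `end`) of the
#'   hotspots this TF binds (at least one contained motif hit).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param bin_length Bin width in bases (default 5 Mb).
#' @return Integer vector of per-bin counts, length
#'   `sum(ceiling(chrom_lengths / bin_length))`.
#' @export
build_hb_profile <- function(bound_hotspots, chrom_lengths,
                             bin_length = 5e6) {
  stopifnot(bin_length > 0)
  n_bins <- ceiling(chrom_lengths / bin_length)
  offsets <- stats::setNames(cumsum(c(0, n_bins[-length(n_bins)])),
                             names(chrom_lengths))
  b <- integer(sum(n_bins))
  if (nrow(bound_hotspots)) {
    mid <- floor((bound_hotspots$start + bound_hotspots$end) / 2)
    bin <- offsets[bound_hotspots$chrom] + floor(mid / bin_length) + 1L
    tab <- table(bin)
    b[as.integer(names(tab))] <- as.integer(tab)
  }
  b
}

#' Per-TF HB profiles from a hit table
#'
#' Convenience wrapper computing [build_hb_profile()] for every motif in
#' a hit tibble: a hotspot is "bound" by a TF when it fully contains at
#' least one of the TF's hits.
#'
#' @inheritParams tabulate_hits
#' @inheritParams build_hb_profile
#' @param hotspots `spot_set` of hotspot intervals.
#' @return A matrix, one row per motif id, `lambda` columns.
#' @export
hb_profiles <- function(hits, hotspots, chrom_lengths, bin_length = 5e6,
                        motif_ids = NULL) {
  motif_ids <- sort(unique(c(motif_ids, hits$motif_id)))
  spots2 <- tibble(chrom = hotspots$chrom, ivl_start = hotspots$start,
                   ivl_end = hotspots$end, ivl_id = seq_len(nrow(hotspots)))
  bound <- dplyr::inner_join(hits, spots2, by = "chrom",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$start >= .data$ivl_start,
                  .data$end <= .data$ivl_end) |>
    dplyr::distinct(.data$motif_id, .data$ivl_id)
  profs <- vapply(motif_ids, function(id) {
    ivls <- bound$ivl_id[bound$motif_id == id]
    build_hb_profile(hotspots[ivls, , drop = FALSE], chrom_lengths,
                     bin_length)
  }, numeric(sum(ceiling(chrom_lengths / bin_length))))
  t(profs)
}

#' Build the HB network from profiles
#'
#' Nodes are TFs; an edge joins two TFs when the Pearson correlation of
#' their HB profiles is strictly greater than `threshold`. A
#' zero-variance profile has correlation treated as 0 and so gains no
#' edges.
#'
#' @param profiles Matrix of HB profiles, one row per TF (rownames are
#'   TF ids), or a named list of equal-length numeric vectors.
#' @param threshold Correlation threshold in `(-1, 1)` (default 0.7).
#' @return An undirected `igraph`; each edge carries its correlation as
#'   `weight`.
#' @export
build_hb_network <- function(profiles, threshold = 0.7) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  stopifnot(threshold > -1, threshold < 1)
  if (ncol(profiles) < 2L) abort("need at least 2 bins for correlation")
  ids <- rownames(profiles) %||% paste0("tf", seq_len(nrow(profiles)))
  cc <- suppressWarnings(stats::cor(t(profiles)))
  cc[is.na(cc)] <- 0  # zero-variance profiles
  cc[upper.tri(cc, diag = TRUE)] <- NA
  idx <- which(cc > threshold, arr.ind = TRUE)
  edges <- tibble(a = ids[idx[, 2]], b = ids[idx[, 1]],
                  weight = cc[idx])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Relevance scores from conserved clusters
#'
#' A gene's relevance is its frequency across conserved clusters (number
#' of clusters containing it), normalized by the maximum frequency over
#' all genes. Genes in the universe absent from every cluster get 0.
#'
#' @param clusters List of character vectors (see [read_clusters()]).
#' @param universe Character vector of gene ids to score.
#' @return Tibble with columns `gene_id`, `R`.
#' @export
relevance_from_clusters <- function(clusters, universe) {
  if (!length(clusters) || !any(lengths(clusters) > 0)) {
    abort("no nonempty clusters")
  }
  freq <- table(unlist(lapply(clusters, unique)))
  mx <- max(freq)
  r <- as.numeric(freq[universe])
  r[is.na(r)] <- 0
  tibble(gene_id = universe, R = r / mx)
}

# Footrule and KM aggregation -------------------------------------------

#' Spearman's footrule distance between two rankings
#'
#' The sum over genes of the absolute difference of their positions.
#'
#' @param a,b [ranking()] tibbles over the same gene universe.
#' @return A nonnegative integer.
#' @export
footrule_distance <- function(a, b) {
  pa <- ranking_positions(a)
  pb <- ranking_positions(b)
  if (!setequal(names(pa), names(pb))) {
    abort("rankings are over different gene universes")
  }
  sum(abs(pa - pb[names(pa)]))
}

#' Consensus ranking by minimum-cost assignment (KM aggregation)
#'
#' Finds the ranking minimizing the summed footrule distance to two
#' input rankings. TFs on one side and positions `1..n` on the other
#' form a complete bipartite graph with assignment cost
#' `w(t, p) = |sigma_o(t) - p| + |sigma_h(t) - p|`; an exact minimum-cost
#' perfect matching (Kuhn-Munkres) yields the consensus. Ties among
#' optimal matchings are resolved deterministically by solving over
#' lexicographically ordered ids; any optimum is valid and the total
#' cost is the quantity of interest.
#'
#' @param sigma_o,sigma_h [ranking()] tibbles over the same universe
#'   (e.g., the odds-ratio and HB-relevance rankings).
#' @return A list with `ranking` (the consensus [ranking()], scored as
#'   `1 / position`) and `total_cost` (the minimized objective).
#' @export
km_aggregate <- function(sigma_o, sigma_h) {
  po <- ranking_positions(sigma_o)
  ph <- ranking_positions(sigma_h)
  if (!setequal(names(po), names(ph))) {
    abort("rankings are over different gene universes")
  }
  ids <- sort(names(po))
  n <- length(ids)
  pos <- seq_len(n)
  cost <- outer(po[ids], pos, function(a, p) abs(a - p)) +
    outer(ph[ids], pos, function(a, p) abs(a - p))
  assign_ <- solve_assignment_min(cost)
  total <- sum(cost[cbind(seq_len(n), assign_)])
  ord <- ids[order(assign_)]
  list(ranking = ranking(ord, 1 / seq_len(n)), total_cost = total)
}

# exact minimum-cost assignment via maximum-weight bipartite matching
solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  wmax <- max(cost)
  weightm <- wmax - cost + 1  # positive weights -> perfect matching
  el <- cbind(rep(seq_len(n), each = n), rep(seq_len(n) + n, times = n))
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), each = n),
                                    edges = as.vector(t(el)))
  wts <- weightm[cbind(el[, 1], el[, 2] - n)]
  m <- igraph::max_bipartite_match(g, weights = wts)
  as.integer(m$matching[seq_len(n)] - n)
}

#' Select seed genes from a ranking
#'
#' Takes the top `ceiling(fraction * n)` genes of a ranking as seeds,
#' carrying their prioritization score for later restart-vector
#' construction. Non-finite scores (an infinite odds ratio) are replaced
#' by the largest finite seed score with a warning; with
#' `scores = "uniform"` every seed gets weight 1.
#'
#' @param r A [ranking()] tibble.
#' @param fraction Fraction of genes to keep, in `(0, 1]` (default 0.10).
#' @param scores `"ranking"` (use the ranking's scores) or `"uniform"`.
#' @return A `seed_set` tibble with columns `gene_id`, `weight`.
#' @export
select_seeds <- function(r, fraction = 0.10,
                         scores = c("ranking", "uniform")) {
  scores <- match.arg(scores)
  if (!nrow(r)) abort("empty ranking")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(r))
  top <- dplyr::slice_min(r, .data$rank, n = k, with_ties = FALSE)
  wt <- if (scores == "uniform") rep(1, k) else top$score
  if (anyNA(wt)) wt <- rep(1, k)
  if (any(!is.finite(wt))) {
    finite <- wt[is.finite(wt)]
    repl <- if (length(finite)) max(finite) else 1
    warn("non-finite seed scores replaced by the maximum finite score")
    wt[!is.finite(wt)] <- repl
  }
  out <- tibble(gene_id = top$gene_id, weight = wt)
  class(out) <- c("seed_set", class(out))
  out
}
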