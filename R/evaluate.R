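# End-to-end evaluation of one strong-signal synthetic replicate:
# generate the bundle in memory, run every pipeline stage, and measure
# recovery of each planted signal against the recorded ground truth.

#' Run one strong-signal replicate and measure planted-signal recovery
#'
#' Generates a synthetic bundle under the given seed, runs motif
#' scanning, odds-ratio prioritization, seed selection, random walk
#' with restart, top-k subnetwork induction, complex detection in both
#' species, and conserved matching, then scores the results against the
#' generator's ground truth.
#'
#' @param seed Integer replicate seed.
#' @param cfg A [synthetic_config()]; defaults to the strong-signal
#'   preset under `seed`.
#' @param na_threshold Recovery threshold on the neighborhood affinity
#'   between a detected complex and a planted one (default 0.8).
#' @return A one-row tibble: `hot_tfs_in_seeds` (all hotspot-preferring
#'   TFs selected as odds-ratio seeds), `n_truth` (planted complexes
#'   per species), `recovered_a`, `recovered_b` (planted complexes
#'   matched at `na_threshold`), `n_matchable` (planted pairs whose
#'   realized ortholog conservation reaches the matching threshold),
#'   `pairs_correct` (matchable pairs the matching links according to
#'   the planted cross-species correspondence),
#'   `rwr_members_above_median` (planted-complex members whose
#'   steady-state relevance exceeds the background median).
#' @export
strong_signal_metrics <- function(seed, cfg = synthetic_config(seed),
                                  na_threshold = 0.8) {
  gen <- gen_genome_and_spots(cfg)
  roster <- make_tf_roster(cfg)
  planted <- plant_motifs(gen$genome, gen$hotspots, gen$coldspots,
                          roster, cfg$seed)
  motifs <- roster_motifs(roster)
  targets <- new_spot_set(dplyr::bind_rows(gen$hotspots, gen$coldspots),
                          "other")
  hits <- dplyr::bind_rows(lapply(motifs, scan_intervals,
                                  genome = planted$genome,
                                  targets = targets))
  tab <- tabulate_hits(hits, gen$hotspots, gen$coldspots,
                       motif_ids = roster$tf_id)
  seeds <- suppressWarnings(
    select_seeds(rank_by_or(suppressWarnings(odds_ratio(tab))), 0.10))
  hot_tfs <- roster$tf_id[roster$is_hot]
  ppi <- gen_ppi_with_complexes(cfg, roster)
  fit <- rwr(ppi$net_a, seeds)
  sub <- induce_top_subnetwork(ppi$net_a, fit,
                               min(cfg$top_k, igraph::vcount(ppi$net_a)))
  cxa <- detect_complexes(sub)
  cxb <- detect_complexes(ppi$net_b)
  best_match <- function(cxs, truth) {
    if (!length(cxs)) return(c(idx = NA_integer_, na = 0))
    nas <- vapply(cxs, function(c) na_score(c$members, truth), numeric(1))
    c(idx = which.max(nas), na = max(nas))
  }
  ba <- vapply(ppi$truth$complexes_a, best_match, numeric(2), cxs = cxa)
  bb <- vapply(ppi$truth$complexes_b, best_match, numeric(2), cxs = cxb)
  pairs <- match_conserved(cxa, cxb, ppi$orthologs)
  n_truth <- length(ppi$truth$complexes_a)
  # a planted pair whose realized conservation fell below the matching
  # threshold cannot be paired by the method; it is excluded from the
  # denominator rather than counted against the matcher
  matchable <- which(ppi$truth$pairs$na_truth >= 0.25)
  # a matchable pair is correctly conserved when the matching links some
  # detected complex covering its A side (NA >= threshold) to one
  # covering its B side
  pairs_correct <- sum(vapply(matchable, function(i) {
    any(vapply(seq_len(nrow(pairs)), function(r) {
      na_score(cxa[[pairs$complex_a[r]]]$members,
               ppi$truth$complexes_a[[i]]) >= na_threshold &&
        na_score(cxb[[pairs$complex_b[r]]]$members,
                 ppi$truth$complexes_b[[i]]) >= na_threshold
    }, logical(1)))
  }, logical(1)))
  members <- unlist(ppi$truth$complexes_a)
  background <- setdiff(names(fit$p), c(members, seeds$gene_id))
  rwr_above <- sum(fit$p[members] > stats::median(fit$p[background]))
  tibble(
    seed = seed,
    hot_tfs_in_seeds = all(hot_tfs %in% seeds$gene_id),
    n_truth = n_truth,
    recovered_a = sum(ba["na", ] >= na_threshold),
    recovered_b = sum(bb["na", ] >= na_threshold),
    n_matchable = length(matchable),
    pairs_correct = pairs_correct,
    n_members = length(members),
    rwr_members_above_median = rwr_above)
}
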