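# End-to-end orchestration: scan -> prioritize -> rwr -> induce ->
# detect -> conserve -> go-eval, with per-stage file outputs and a JSON
# run manifest recording the config hash, input checksums and per-stage
# record counts.

#' Default pipeline configuration
#'
#' Returns the full default parameter block; entries under `inputs`
#' must be filled with file paths before running. Any YAML file with
#' the same structure can be passed to [run_pipeline()]; values given
#' there override these defaults.
#'
#' @return A nested list.
#' @export
default_pipeline_config <- function() {
  list(
    inputs = list(genome = NULL, hotspots = NULL, coldspots = NULL,
                  motifs = NULL, motif_dialect = "meme_minimal",
                  fimo_hits = NULL, ppi_a = NULL, ppi_b = NULL,
                  orthologs = NULL, clusters = NULL,
                  obo = NULL, gaf = NULL),
    out_dir = "recombnet_out",
    method = "or",                 # or | hb | km
    p_threshold = 1e-4,
    pseudocount = 0.1,
    bin_length = 5e6,
    pearson_threshold = 0.7,
    seed_fraction = 0.10,
    p0_mode = "ranking",           # ranking | uniform
    gamma = 0.7,
    tol = 1e-10,
    max_iter = 10000,
    top_k = 200,
    density_threshold = 0.7,
    attach_ratio = 0.5,
    redundancy_na = 0.25,
    conserved_threshold = 0.25,
    relation_weights = list(is_a = 0.8, part_of = 0.6))
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  out <- utils::modifyList(defaults, config)
  stopifnot(out$method %in% c("or", "hb", "km"),
            out$gamma > 0, out$gamma <= 1,
            out$seed_fraction > 0, out$seed_fraction <= 1)
  out
}

#' Run the full pipeline
#'
#' Executes the stages in order: motif scanning over hotspots and
#' coldspots, prioritization by the configured method, random walk with
#' restart from the selected seeds, induction of the top-k subnetwork,
#' complex detection in both species, conserved-complex matching, and
#' GO gap/enrichment evaluation. Each stage writes its outputs to
#' `out_dir` before the next starts; a failure aborts with the manifest
#' marking the failed stage.
#'
#' @param config A config list or the path to a YAML file; see
#'   [default_pipeline_config()].
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- Filter(Negate(is.null), cfg$inputs)
  input_files <- unlist(inputs[vapply(inputs, function(x)
    is.character(x) && file.exists(x), logical(1))])
  manifest <- list(
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("recombnet")),
    input_checksums = as.list(tools::md5sum(input_files)),
    stages = list())
  results <- list()
  stage_names <- c("scan", "prioritize", "rwr", "induce", "detect",
                   "conserve", "go_eval")
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  for (stage in stage_names) {
    res <- tryCatch(
      run_stage(stage, cfg, results),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "stage_failure"))
    if (inherits(res, "stage_failure")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = res$message)
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   res$message))
    }
    results[[stage]] <- res$value
    manifest$stages[[stage]] <- list(status = "completed",
                                     n_records = res$n_records)
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(list(manifest = manifest), results))
}

run_stage <- function(stage, cfg, results) {
  switch(stage,
         scan = stage_scan(cfg),
         prioritize = stage_prioritize(cfg, results$scan),
         rwr = stage_rwr(cfg, results$prioritize),
         induce = stage_induce(cfg, results$rwr),
         detect = stage_detect(cfg, results$induce),
         conserve = stage_conserve(cfg, results$detect),
         go_eval = stage_go_eval(cfg, results))
}

stage_scan <- function(cfg) {
  ins <- cfg$inputs
  stopifnot(!is.null(ins$hotspots), !is.null(ins$coldspots))
  if (!is.null(ins$fimo_hits)) {
    hits <- read_fimo_hits(ins$fimo_hits)
    motif_ids <- sort(unique(hits$motif_id))
    genome <- NULL
  } else {
    stopifnot(!is.null(ins$genome), !is.null(ins$motifs))
    dna <- Biostrings::readDNAStringSet(ins$genome)
    names(dna) <- sub("\\s.*", "", names(dna))
    genome <- stats::setNames(as.character(dna), names(dna))
    motifs <- read_motifs(ins$motifs, ins$motif_dialect,
                          pseudocount = cfg$pseudocount)
    motif_ids <- vapply(motifs, `[[`, character(1), "motif_id")
    chrom_lengths <- stats::setNames(nchar(genome), names(genome))
    hot <- read_intervals(ins$hotspots, chrom_lengths, "hotspot")
    cold <- read_intervals(ins$coldspots, chrom_lengths, "coldspot")
    both <- new_spot_set(dplyr::bind_rows(hot, cold), "other")
    hits <- dplyr::bind_rows(lapply(motifs, scan_intervals,
                                    genome = genome, targets = both,
                                    p_threshold = cfg$p_threshold))
  }
  chrom_lengths <- if (!is.null(genome)) {
    stats::setNames(nchar(genome), names(genome))
  } else {
    # no genome supplied: bound chromosome lengths from observed
    # coordinates in the hit and interval files
    infer_chrom_lengths(c(ins$hotspots, ins$coldspots), hits)
  }
  hot <- read_intervals(cfg$inputs$hotspots, chrom_lengths, "hotspot")
  cold <- read_intervals(cfg$inputs$coldspots, chrom_lengths, "coldspot")
  tab <- tabulate_hits(hits, hot, cold, motif_ids = motif_ids)
  write_fimo_hits(hits, file.path(cfg$out_dir, "hits.tsv"))
  utils::write.table(tab, file.path(cfg$out_dir, "hit_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(value = list(hits = hits, table = tab, hot = hot, cold = cold,
                    chrom_lengths = chrom_lengths, motif_ids = motif_ids),
       n_records = nrow(hits))
}

infer_chrom_lengths <- function(bed_paths, hits) {
  ends <- tibble(chrom = hits$chrom, end = hits$end)
  for (p in bed_paths) {
    lines <- read_data_lines(p, comment = "#")
    f <- strsplit(trimws(lines), "[ \t]+")
    ok <- lengths(f) >= 3
    ends <- dplyr::bind_rows(ends, tibble(
      chrom = vapply(f[ok], `[`, character(1), 1),
      end = suppressWarnings(
        as.numeric(vapply(f[ok], `[`, character(1), 3)))))
  }
  ends <- ends[!is.na(ends$end), , drop = FALSE]
  tapply(ends$end, ends$chrom, max)
}

stage_prioritize <- function(cfg, scan) {
  or_rank <- rank_by_or(odds_ratio(scan$table))
  rank_used <- or_rank
  if (cfg$method %in% c("hb", "km")) {
    clusters <- if (!is.null(cfg$inputs$clusters)) {
      read_clusters(cfg$inputs$clusters)
    } else {
      hb <- build_hb_network(
        hb_profiles(scan$hits, scan$hot, scan$chrom_lengths,
                    cfg$bin_length, motif_ids = scan$motif_ids),
        cfg$pearson_threshold)
      comps <- igraph::components(hb)
      grp <- split(names(comps$membership), comps$membership)
      Filter(function(g) length(g) >= 2, grp)
    }
    rel <- relevance_from_clusters(clusters, scan$motif_ids)
    hb_rank <- rank_by_score(rel)
    rank_used <- if (cfg$method == "hb") hb_rank else
      km_aggregate(or_rank, hb_rank)$ranking
  }
  out <- dplyr::mutate(rank_used, method = cfg$method)
  utils::write.table(
    out[, c("gene_id", "method", "score", "rank")],
    file.path(cfg$out_dir, paste0("ranking_", cfg$method, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  seeds <- select_seeds(rank_used, cfg$seed_fraction,
                        scores = if (cfg$p0_mode == "uniform")
                          "uniform" else "ranking")
  utils::write.table(seeds, file.path(cfg$out_dir, "seeds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(value = list(ranking = rank_used, seeds = seeds),
       n_records = nrow(seeds))
}

stage_rwr <- function(cfg, prio) {
  stopifnot(!is.null(cfg$inputs$ppi_a))
  net <- read_network(cfg$inputs$ppi_a)
  fit <- rwr(net, prio$seeds, gamma = cfg$gamma, tol = cfg$tol,
             max_iter = cfg$max_iter)
  tab <- tidy(fit)
  utils::write.table(tab, file.path(cfg$out_dir, "rwr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(value = list(net = net, fit = fit), n_records = nrow(tab))
}

stage_induce <- function(cfg, walked) {
  sub <- induce_top_subnetwork(walked$net, walked$fit,
                               min(cfg$top_k, igraph::vcount(walked$net)))
  write_edge_list(sub, file.path(cfg$out_dir, "subnetwork.tsv"))
  list(value = list(subnet = sub), n_records = igraph::vcount(sub))
}

stage_detect <- function(cfg, induced) {
  cxa <- detect_complexes(induced$subnet, cfg$density_threshold,
                          cfg$attach_ratio, cfg$redundancy_na)
  write_complexes(cxa, file.path(cfg$out_dir, "complexes_speciesA.txt"))
  cxb <- NULL
  if (!is.null(cfg$inputs$ppi_b)) {
    net_b <- read_network(cfg$inputs$ppi_b)
    cxb <- detect_complexes(net_b, cfg$density_threshold,
                            cfg$attach_ratio, cfg$redundancy_na)
    write_complexes(cxb, file.path(cfg$out_dir, "complexes_speciesB.txt"))
  }
  list(value = list(complexes_a = cxa, complexes_b = cxb),
       n_records = length(cxa))
}

stage_conserve <- function(cfg, detected) {
  if (is.null(detected$complexes_b) || is.null(cfg$inputs$orthologs)) {
    return(list(value = list(pairs = NULL), n_records = 0L))
  }
  orth <- read_orthologs(cfg$inputs$orthologs)
  pairs <- match_conserved(detected$complexes_a, detected$complexes_b,
                           orth, cfg$conserved_threshold)
  utils::write.table(pairs, file.path(cfg$out_dir, "conserved_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(value = list(pairs = pairs), n_records = nrow(pairs))
}

stage_go_eval <- function(cfg, results) {
  if (is.null(cfg$inputs$obo) || is.null(cfg$inputs$gaf)) {
    return(list(value = list(gap = NULL, enrichment = NULL),
                n_records = 0L))
  }
  onto <- read_ontology(cfg$inputs$obo, cfg$inputs$gaf)
  weights <- unlist(cfg$relation_weights)
  hg <- results$prioritize$seeds$gene_id
  g <- results$scan$motif_ids
  gap <- rank_terms_by_gap(onto$dag$terms$id, hg, g, onto$annotations,
                           onto$dag, weights)
  gap$description <- onto$dag$terms$name[match(gap$term,
                                               onto$dag$terms$id)]
  utils::write.table(
    gap[, c("term", "description", "S_HG", "S_G", "gap", "rank")],
    file.path(cfg$out_dir, "go_gap.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- NULL
  if (length(results$detect$complexes_a)) {
    universe <- igraph::V(results$rwr$net)$name
    enr <- complex_enrichment(results$detect$complexes_a,
                              onto$annotations, universe, adjust = "BH")
    utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(value = list(gap = gap, enrichment = enr), n_records = nrow(gap))
}

#' Naive conserved clusters from two HB networks
#'
#' A deliberately simple stand-in for full cross-species HB-network
#' alignment: keep the edges of network A whose endpoint pair has an
#' orthologous edge in network B, and return the connected components
#' of size at least 2 of the surviving graph. Not equivalent to a true
#' alignment tool; adequate for wiring relevance scores when no
#' precomputed cluster file is available.
#'
#' @param hb_a,hb_b HB networks ([build_hb_network()]) of two species.
#' @param orthologs Ortholog tibble (`a`, `b`).
#' @return List of character vectors (clusters over `hb_a` ids).
#' @export
naive_conserved_clusters <- function(hb_a, hb_b, orthologs) {
  ea <- igraph::as_edgelist(hb_a)
  eb <- igraph::as_edgelist(hb_b)
  eb_keys <- c(paste(eb[, 1], eb[, 2]), paste(eb[, 2], eb[, 1]))
  keep <- logical(nrow(ea))
  for (i in seq_len(nrow(ea))) {
    b1 <- orthologs$b[orthologs$a == ea[i, 1]]
    b2 <- orthologs$b[orthologs$a == ea[i, 2]]
    if (length(b1) && length(b2)) {
      keys <- as.vector(outer(b1, b2, paste))
      keep[i] <- any(keys %in% eb_keys)
    }
  }
  if (!any(keep)) return(list())
  g <- igraph::graph_from_edgelist(ea[keep, , drop = FALSE],
                                   directed = FALSE)
  comps <- igraph::components(g)
  grp <- split(names(comps$membership), comps$membership)
  unname(Filter(function(x) length(x) >= 2, grp))
}
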