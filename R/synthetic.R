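# Seeded synthetic-data generators emulating every input the pipeline
# reads: a genome with planted motif occurrences enriched in hotspots,
# two PPI networks with planted dense complexes linked by orthologs, a
# small GO DAG with annotations, and conserved clusters. Ground truth is
# recorded for every planted signal. Each generator draws from its own
# deterministic sub-seed, so adding one generator never perturbs
# another's output.

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the strong-signal regime the pipeline is validated
#' under: motifs of "hot" TFs planted in 80% of hotspots against a 10%
#' coldspot rate, 200 hotspots and 200 length-matched coldspots, three
#' planted complexes of size 6, and an ortholog conservation rate of
#' 0.8.
#'
#' @param seed Integer RNG seed; every generator forks a labeled
#'   sub-seed from it.
#' @param chrom_lengths Named chromosome lengths (bases).
#' @param n_hotspots,n_coldspots Interval counts.
#' @param interval_length Two-element range of interval lengths.
#' @param n_tfs Total TF roster size.
#' @param n_hot_tfs Number of hotspot-preferring TFs.
#' @param motif_width Consensus motif width in bases.
#' @param hot_rate,cold_rate Planting probability per hotspot/coldspot
#'   for hot TFs.
#' @param background_rate Planting probability (both interval classes)
#'   for the remaining TFs.
#' @param ppi_nodes Nodes per species network.
#' @param n_complexes,complex_size Planted complexes per species.
#' @param intra_p Edge probability inside a planted complex.
#' @param background_p Erdos-Renyi background edge probability.
#' @param conservation Probability that a complex member has a 1:1
#'   ortholog preserving complex membership.
#' @param background_orthology Probability that paired non-complex
#'   nodes are orthologs.
#' @param go_depth,go_branching Shape of the balanced GO DAG.
#' @param bin_length HB-profile bin length suited to the synthetic
#'   genome scale.
#' @param top_k Induced-subnetwork size for the pipeline.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                             n_hotspots = 200L, n_coldspots = 200L,
                             interval_length = c(80L, 120L),
                             n_tfs = 30L, n_hot_tfs = 3L,
                             motif_width = 8L,
                             hot_rate = 0.8, cold_rate = 0.1,
                             background_rate = 0.1,
                             ppi_nodes = 120L,
                             n_complexes = 3L, complex_size = 6L,
                             intra_p = 0.9, background_p = 0.02,
                             conservation = 0.8,
                             background_orthology = 0.2,
                             go_depth = 3L, go_branching = 2L,
                             bin_length = 5e4, top_k = 60L) {
  probs <- c(hot_rate, cold_rate, background_rate, intra_p, background_p,
             conservation, background_orthology)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_hotspots >= 0, n_coldspots >= 0, complex_size >= 3,
            go_depth >= 2, motif_width >= 1,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

#' Generate a genome with non-overlapping hotspot and coldspot intervals
#'
#' The genome is i.i.d. uniform over ACGT. Hotspots and coldspots are
#' placed without overlap, and their length multisets are equal
#' (length-matching removes interval length as a scanning-rate
#' confounder).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (named character vector), `hotspots` and
#'   `coldspots` (`spot_set` tibbles).
#' @export
gen_genome_and_spots <- function(cfg) {
  set.seed(fork_seed(cfg$seed, "genome"))
  genome <- vapply(cfg$chrom_lengths, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
  names(genome) <- names(cfg$chrom_lengths)
  lens <- sample(seq(cfg$interval_length[1], cfg$interval_length[2]),
                 cfg$n_hotspots, replace = TRUE)
  cold_lens <- sample(lens, cfg$n_coldspots,
                      replace = cfg$n_coldspots > cfg$n_hotspots)
  all_lens <- c(lens, cold_lens)
  placed <- place_intervals(all_lens, cfg$chrom_lengths)
  hot <- placed[seq_len(cfg$n_hotspots), , drop = FALSE]
  cold <- placed[cfg$n_hotspots + seq_len(cfg$n_coldspots), , drop = FALSE]
  list(genome = genome,
       hotspots = new_spot_set(hot, "hotspot"),
       coldspots = new_spot_set(cold, "coldspot"))
}

place_intervals <- function(lens, chrom_lengths, max_tries = 10000L) {
  n <- length(lens)
  out <- tibble(chrom = character(n), start = numeric(n), end = numeric(n))
  occupied <- lapply(chrom_lengths, function(...) {
    matrix(numeric(0), ncol = 2)
  })
  chroms <- names(chrom_lengths)
  pchrom <- chrom_lengths / sum(chrom_lengths)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = pchrom)
      start <- sample.int(chrom_lengths[[ch]] - lens[i], 1) - 1
      end <- start + lens[i]
      occ <- occupied[[ch]]
      if (!nrow(occ) || all(end <= occ[, 1] | start >= occ[, 2])) {
        occupied[[ch]] <- rbind(occ, c(start, end))
        out$chrom[i] <- ch; out$start[i] <- start; out$end[i] <- end
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place requested intervals without overlap")
  }
  out
}

#' Build the synthetic TF roster
#'
#' `n_tfs` TFs with distinct random consensus motifs of `motif_width`
#' bases; the first `n_hot_tfs` are hotspot-preferring (planting at
#' `hot_rate` in hotspots vs `cold_rate` in coldspots), the rest plant
#' at `background_rate` in both classes.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble: `tf_id`, `consensus`, `hot_rate`, `cold_rate`,
#'   `is_hot`.
#' @export
make_tf_roster <- function(cfg) {
  set.seed(fork_seed(cfg$seed, "roster"))
  consensus <- character(0)
  while (length(consensus) < cfg$n_tfs) {
    cand <- paste(sample(DNA_BASES, cfg$motif_width, replace = TRUE),
                  collapse = "")
    rc <- revcomp_chr(cand)
    if (!cand %in% consensus && !rc %in% consensus) {
      consensus <- c(consensus, cand)
    }
  }
  is_hot <- seq_len(cfg$n_tfs) <= cfg$n_hot_tfs
  tibble(tf_id = sprintf("TF%02d", seq_len(cfg$n_tfs)),
         consensus = consensus,
         hot_rate = ifelse(is_hot, cfg$hot_rate, cfg$background_rate),
         cold_rate = ifelse(is_hot, cfg$cold_rate, cfg$background_rate),
         is_hot = is_hot)
}

#' Plant motif occurrences into intervals
#'
#' For each TF and each interval, with the TF's per-class rate a
#' consensus occurrence is written at a uniform position inside the
#' interval. Planted occurrences never overlap one another; an interval
#' too short (or too crowded) for another occurrence is skipped and
#' recorded.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param hotspots,coldspots `spot_set` tibbles.
#' @param roster Output of [make_tf_roster()].
#' @param seed Integer seed.
#' @return List with `genome` (edited) and `truth` (tibble `tf_id`,
#'   `chrom`, `start`, `end`, `label`; skipped plants carry NA
#'   coordinates).
#' @export
plant_motifs <- function(genome, hotspots, coldspots, roster, seed = 1L) {
  set.seed(fork_seed(seed, "plant"))
  occupied <- list()
  rows <- list()
  edits <- list()
  plant_in <- function(spots, label, rate_col) {
    for (ti in seq_len(nrow(roster))) {
      w <- nchar(roster$consensus[ti])
      rate <- roster[[rate_col]][ti]
      if (rate <= 0) next
      draws <- stats::runif(nrow(spots)) < rate
      for (r in which(draws)) {
        chrom <- spots$chrom[r]
        lo <- spots$start[r]; hi <- spots$end[r]
        if (hi - lo < w) {
          rows[[length(rows) + 1L]] <<- tibble(
            tf_id = roster$tf_id[ti], chrom = chrom, start = NA_real_,
            end = NA_real_, label = paste0(label, ":skipped"))
          next
        }
        key <- paste0(chrom, ":", lo)
        occ <- occupied[[key]] %||% matrix(numeric(0), ncol = 2)
        pos <- NA
        for (try in 1:25) {
          cand <- lo + sample.int(hi - lo - w + 1L, 1) - 1
          if (!nrow(occ) ||
              all(cand + w <= occ[, 1] | cand >= occ[, 2])) {
            pos <- cand
            break
          }
        }
        if (is.na(pos)) {
          rows[[length(rows) + 1L]] <<- tibble(
            tf_id = roster$tf_id[ti], chrom = chrom, start = NA_real_,
            end = NA_real_, label = paste0(label, ":skipped"))
          next
        }
        occupied[[key]] <<- rbind(occ, c(pos, pos + w))
        edits[[length(edits) + 1L]] <<- list(
          chrom = chrom, pos = pos, text = roster$consensus[ti])
        rows[[length(rows) + 1L]] <<- tibble(
          tf_id = roster$tf_id[ti], chrom = chrom, start = pos,
          end = pos + w, label = label)
      }
    }
  }
  plant_in(hotspots, "hotspot", "hot_rate")
  plant_in(coldspots, "coldspot", "cold_rate")
  # apply all edits per chromosome in one pass (in-place substring
  # replacement would copy the whole chromosome per plant)
  by_chrom <- split(edits, vapply(edits, `[[`, character(1), "chrom"))
  for (ch in names(by_chrom)) {
    s <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    for (e in by_chrom[[ch]]) {
      s[(e$pos + 1):(e$pos + nchar(e$text))] <-
        strsplit(e$text, "", fixed = TRUE)[[1]]
    }
    genome[[ch]] <- paste(s, collapse = "")
  }
  truth <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(tf_id = character(), chrom = character(), start = numeric(),
           end = numeric(), label = character())
  list(genome = genome, truth = truth)
}

#' Generate two PPI networks with planted complexes and an ortholog map
#'
#' Species A's nodes include the whole TF roster; each planted complex
#' contains one hot TF plus background partners, wired at `intra_p`
#' over an Erdos-Renyi background at `background_p`. Species B mirrors
#' the complexes on its own identifiers; a `conservation` fraction of
#' complex members get 1:1 orthologs preserving complex membership,
#' plus a thin layer of background orthology.
#'
#' @param cfg A [synthetic_config()].
#' @param roster Output of [make_tf_roster()] (for the node roster).
#' @return List with `net_a`, `net_b` (igraphs), `orthologs` (tibble),
#'   and `truth` (lists `complexes_a`, `complexes_b`, and tibble
#'   `pairs` with the expected NA of each conserved pair).
#' @export
gen_ppi_with_complexes <- function(cfg, roster = make_tf_roster(cfg)) {
  force(roster)
  set.seed(fork_seed(cfg$seed, "ppi"))
  n_extra <- cfg$ppi_nodes - nrow(roster)
  if (n_extra < cfg$n_complexes * (cfg$complex_size - 1)) {
    abort("node budget exceeded by planted complexes")
  }
  extras_a <- sprintf("A%03d", seq_len(n_extra))
  nodes_a <- c(roster$tf_id, extras_a)
  nodes_b <- sprintf("B%03d", seq_len(cfg$ppi_nodes))
  hot_tfs <- roster$tf_id[roster$is_hot]
  complexes_a <- lapply(seq_len(cfg$n_complexes), function(i) {
    partners <- extras_a[(i - 1) * (cfg$complex_size - 1) +
                           seq_len(cfg$complex_size - 1)]
    sort(c(hot_tfs[((i - 1) %% length(hot_tfs)) + 1], partners))
  })
  complexes_b <- lapply(seq_len(cfg$n_complexes), function(i) {
    nodes_b[(i - 1) * cfg$complex_size + seq_len(cfg$complex_size)]
  })
  net_a <- planted_graph(nodes_a, complexes_a, cfg$intra_p,
                         cfg$background_p)
  net_b <- planted_graph(nodes_b, complexes_b, cfg$intra_p,
                         cfg$background_p)
  # orthologs among complex members, preserving membership
  oa <- ob <- character()
  n_mapped <- integer(cfg$n_complexes)
  for (i in seq_len(cfg$n_complexes)) {
    keep <- stats::runif(cfg$complex_size) < cfg$conservation
    n_mapped[i] <- sum(keep)
    oa <- c(oa, complexes_a[[i]][keep])
    ob <- c(ob, complexes_b[[i]][keep])
  }
  free_a <- setdiff(nodes_a, unlist(complexes_a))
  free_b <- setdiff(nodes_b, unlist(complexes_b))
  n_bg <- min(length(free_a), length(free_b))
  keep_bg <- stats::runif(n_bg) < cfg$background_orthology
  orthologs <- dplyr::distinct(tibble(
    a = c(oa, free_a[seq_len(n_bg)][keep_bg]),
    b = c(ob, free_b[seq_len(n_bg)][keep_bg])))
  pairs <- tibble(complex_a = seq_len(cfg$n_complexes),
                  complex_b = seq_len(cfg$n_complexes),
                  na_truth = n_mapped^2 / cfg$complex_size^2)
  list(net_a = net_a, net_b = net_b, orthologs = orthologs,
       truth = list(complexes_a = complexes_a, complexes_b = complexes_b,
                    pairs = pairs))
}

planted_graph <- function(nodes, complexes, intra_p, background_p) {
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < background_p
  for (cx in complexes) {
    in_cx <- pairs[1, ] %in% cx & pairs[2, ] %in% cx
    keep[in_cx] <- stats::runif(sum(in_cx)) < intra_p
  }
  edges <- tibble(a = pairs[1, keep], b = pairs[2, keep], weight = 1)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Generate a small GO DAG with annotations
#'
#' A rooted balanced `is_a` tree of the configured depth and branching
#' (plus one `part_of` cross-edge for relation coverage). One leaf is
#' the "recombination-like" marker term annotating exactly the
#' designated genes, so gap-score recovery is testable; the remaining
#' genes are annotated to leaves of the opposite branch.
#'
#' @param cfg A [synthetic_config()].
#' @param designated Genes the marker term annotates (default: the hot
#'   TFs of the roster).
#' @param others Remaining genes to annotate elsewhere.
#' @return List with `dag` (a `go_dag`), `annotations` (named list),
#'   and `marker_term`.
#' @export
gen_go <- function(cfg,
                   designated = make_tf_roster(cfg)$tf_id[
                     seq_len(cfg$n_hot_tfs)],
                   others = setdiff(make_tf_roster(cfg)$tf_id,
                                    designated)) {
  force(designated)
  force(others)
  set.seed(fork_seed(cfg$seed, "go"))
  depth <- cfg$go_depth
  br <- cfg$go_branching
  n_terms <- sum(br^(0:depth))
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  ec <- ep <- er <- character()
  # node i (1-based, breadth-first) has parent floor((i - 2) / br) + 1
  for (i in 2:n_terms) {
    ec <- c(ec, ids[i]); ep <- c(ep, ids[floor((i - 2) / br) + 1])
    er <- c(er, "is_a")
  }
  # one part_of cross-edge between the first two depth-2 siblings' parents
  if (n_terms >= br + 2) {
    ec <- c(ec, ids[br + 2]); ep <- c(ep, ids[2]); er <- c(er, "part_of")
  }
  terms <- tibble(id = ids,
                  name = c("root", paste0("term_", ids[-1])),
                  namespace = "biological_process")
  dag <- structure(list(terms = terms,
                        edges = dplyr::distinct(
                          tibble(child = ec, parent = ep, relation = er))),
                   class = "go_dag")
  leaves <- setdiff(ids, ep)
  marker <- leaves[1]
  distant <- leaves[(length(leaves) %/% 2 + 1):length(leaves)]
  ann <- c(
    stats::setNames(lapply(designated, function(g) marker), designated),
    stats::setNames(lapply(others, function(g) {
      sample(distant, sample(1:2, 1))
    }), others))
  list(dag = dag, annotations = ann, marker_term = marker)
}

#' Generate and write the full synthetic bundle
#'
#' Runs every generator under the configured seed, writes all files in
#' the formats the package reads (FASTA, BED, MEME minimal, edge-list
#' TSVs, OBO, GAF, ortholog TSV, cluster lines), and a JSON manifest
#' listing paths, the seed, and all ground-truth tables.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory pieces (`genome`,
#'   `hotspots`, `coldspots`, `roster`, `motifs`, `net_a`, `net_b`,
#'   `orthologs`, `go`, `truth`, `paths`).
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- gen_genome_and_spots(cfg)
  roster <- make_tf_roster(cfg)
  planted <- plant_motifs(gen$genome, gen$hotspots, gen$coldspots,
                          roster, cfg$seed)
  ppi <- gen_ppi_with_complexes(cfg, roster)
  go <- gen_go(cfg)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    hotspots = file.path(dir, "hotspots.bed"),
    coldspots = file.path(dir, "coldspots.bed"),
    motifs = file.path(dir, "motifs.meme"),
    ppi_a = file.path(dir, "ppi_speciesA.tsv"),
    ppi_b = file.path(dir, "ppi_speciesB.tsv"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    orthologs = file.path(dir, "orthologs.tsv"),
    clusters = file.path(dir, "clusters.txt"),
    manifest = file.path(dir, "manifest.json"))
  dna <- Biostrings::DNAStringSet(planted$genome)
  Biostrings::writeXStringSet(dna, paths$genome, width = 70L)
  write_intervals(gen$hotspots, paths$hotspots)
  write_intervals(gen$coldspots, paths$coldspots)
  write_meme_minimal(roster, paths$motifs)
  write_edge_list(ppi$net_a, paths$ppi_a)
  write_edge_list(ppi$net_b, paths$ppi_b)
  write_obo(go$dag, paths$obo)
  write_gaf(go$annotations, paths$gaf)
  utils::write.table(ppi$orthologs, paths$orthologs, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(vapply(ppi$truth$complexes_a, paste, character(1),
                    collapse = " "), paths$clusters)
  truth <- list(
    planted_motifs = planted$truth,
    hot_tfs = roster$tf_id[roster$is_hot],
    complexes_a = ppi$truth$complexes_a,
    complexes_b = ppi$truth$complexes_b,
    conserved_pairs = ppi$truth$pairs,
    marker_term = go$marker_term,
    designated_genes = roster$tf_id[seq_len(cfg$n_hot_tfs)])
  manifest <- list(seed = cfg$seed,
                   config = unclass(cfg)[!vapply(cfg, is.function,
                                                 logical(1))],
                   paths = lapply(paths, identity),
                   truth = truth)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome = planted$genome, hotspots = gen$hotspots,
                 coldspots = gen$coldspots, roster = roster,
                 motifs = roster_motifs(roster),
                 net_a = ppi$net_a, net_b = ppi$net_b,
                 orthologs = ppi$orthologs, go = go, truth = truth,
                 paths = paths, config = cfg))
}

#' One-hot motif matrices for a synthetic roster
#' @param roster Output of [make_tf_roster()].
#' @param pseudocount Pseudocount carried by each matrix.
#' @export
roster_motifs <- function(roster, pseudocount = 0.1) {
  lapply(seq_len(nrow(roster)), function(i) {
    bases <- strsplit(roster$consensus[i], "")[[1]]
    counts <- vapply(bases, function(b) as.numeric(DNA_BASES == b),
                     numeric(4))
    motif_matrix(roster$tf_id[i], counts, pseudocount = pseudocount)
  })
}

write_meme_minimal <- function(roster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_len(nrow(roster))) {
    bases <- strsplit(roster$consensus[i], "")[[1]]
    writeLines(c(paste("MOTIF", roster$tf_id[i]),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         length(bases))), con)
    for (b in bases) {
      writeLines(paste(sprintf("%.6f", as.numeric(DNA_BASES == b)),
                       collapse = " "), con)
    }
    writeLines("", con)
  }
}

write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight %||% rep(1, nrow(el))
  utils::write.table(data.frame(el[, 1], el[, 2], w), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste("id:", id),
                 paste("name:", dag$terms$name[i]),
                 paste("namespace:", dag$terms$namespace[i])), con)
    up <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (k in seq_len(nrow(up))) {
      if (up$relation[k] == "is_a") {
        writeLines(paste("is_a:", up$parent[k]), con)
      } else {
        writeLines(paste("relationship: part_of", up$parent[k]), con)
      }
    }
    writeLines("", con)
  }
}

write_gaf <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (g in names(annotations)) {
    for (t in annotations[[g]]) {
      writeLines(paste("SYN", g, g, "", t, "SYN:0001", "IEA", "", "P",
                       "", "", "protein", "taxon:0001", "20200101",
                       "SYN", "", "", sep = "\t"), con)
    }
  }
}
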