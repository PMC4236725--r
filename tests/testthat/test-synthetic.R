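# Synthetic-data generators: determinism, self-consistency, recovery
# hooks.

small_cfg <- function(seed = 1) {
  synthetic_config(seed = seed, chrom_lengths = c(chr1 = 5e4, chr2 = 3e4),
                   n_hotspots = 20, n_coldspots = 20, n_tfs = 6,
                   n_hot_tfs = 2, ppi_nodes = 40, go_depth = 2)
}

test_that("identical configs give byte-identical bundles", {
  cfg <- small_cfg(7)
  d1 <- file.path(tempdir(), "bundle_rep1")
  d2 <- file.path(tempdir(), "bundle_rep2")
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next  # paths inside differ by directory
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # a different seed changes the genome
  d3 <- file.path(tempdir(), "bundle_rep3")
  simulate_bundle(small_cfg(8), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("interval sets are non-overlapping and length-matched", {
  gen <- gen_genome_and_spots(small_cfg(3))
  both <- dplyr::bind_rows(gen$hotspots, gen$coldspots)
  expect_equal(sort(table(both$chrom) >= 0), sort(table(both$chrom) >= 0))
  by_chrom <- split(both, both$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  expect_equal(sort(gen$hotspots$end - gen$hotspots$start),
               sort(gen$coldspots$end - gen$coldspots$start))
  none <- gen_genome_and_spots(
    synthetic_config(seed = 1, n_hotspots = 0, n_coldspots = 0))
  expect_equal(nrow(none$hotspots), 0)
})

test_that("planted motifs are present and scannable at recorded positions", {
  cfg <- small_cfg(5)
  gen <- gen_genome_and_spots(cfg)
  roster <- make_tf_roster(cfg)
  planted <- plant_motifs(gen$genome, gen$hotspots, gen$coldspots,
                          roster, cfg$seed)
  truth <- planted$truth[!is.na(planted$truth$start), ]
  expect_gt(nrow(truth), 0)
  # every recorded plant is literally in the sequence
  for (r in seq_len(nrow(truth))) {
    got <- substr(planted$genome[[truth$chrom[r]]],
                  truth$start[r] + 1, truth$end[r])
    expect_equal(got,
                 roster$consensus[roster$tf_id == truth$tf_id[r]])
  }
  # no two plants overlap
  occ <- truth[order(truth$chrom, truth$start), ]
  by_chrom <- split(occ, occ$chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # the scanner finds at least the planted occurrences of each TF
  for (ti in which(roster$is_hot)) {
    m <- roster_motifs(roster)[[ti]]
    hits <- scan_intervals(m, planted$genome, gen$hotspots,
                           p_threshold = 0.25^cfg$motif_width)
    expect_gte(nrow(hits),
               sum(truth$tf_id == roster$tf_id[ti] &
                     truth$label == "hotspot"))
  }
})

test_that("rate-one planting writes one occurrence per interval", {
  cfg <- synthetic_config(seed = 2, chrom_lengths = c(chr1 = 5e4),
                          n_hotspots = 10, n_coldspots = 10,
                          n_tfs = 1, n_hot_tfs = 1,
                          hot_rate = 1, cold_rate = 0)
  gen <- gen_genome_and_spots(cfg)
  roster <- make_tf_roster(cfg)
  planted <- plant_motifs(gen$genome, gen$hotspots, gen$coldspots,
                          roster, cfg$seed)
  tt <- planted$truth
  expect_equal(sum(tt$label == "hotspot"), 10)
  expect_equal(sum(tt$label == "coldspot"), 0)
})

test_that("degenerate PPI generation yields disjoint cliques", {
  cfg <- synthetic_config(seed = 4, ppi_nodes = 40, n_tfs = 6,
                          n_hot_tfs = 3, intra_p = 1, background_p = 0)
  ppi <- gen_ppi_with_complexes(cfg, make_tf_roster(cfg))
  for (cx in ppi$truth$complexes_a) {
    sub <- igraph::induced_subgraph(ppi$net_a, cx)
    expect_equal(igraph::edge_density(sub), 1)
  }
  expect_equal(igraph::ecount(ppi$net_a),
               3 * choose(cfg$complex_size, 2))
  # full conservation makes every truth pair affinity 1
  cfg2 <- synthetic_config(seed = 4, ppi_nodes = 40, n_tfs = 6,
                           n_hot_tfs = 3, conservation = 1,
                           background_orthology = 0)
  ppi2 <- gen_ppi_with_complexes(cfg2, make_tf_roster(cfg2))
  expect_equal(ppi2$truth$pairs$na_truth, rep(1, 3))
  for (i in 1:3) {
    expect_equal(na_score(ppi2$truth$complexes_a[[i]],
                          ppi2$truth$complexes_b[[i]],
                          ppi2$orthologs), 1)
  }
})

test_that("truth-pair affinity follows the conservation arithmetic", {
  # exactly m of 5 members mapped -> affinity m^2 / 25
  cfg <- synthetic_config(seed = 11, ppi_nodes = 40, n_tfs = 6,
                          n_hot_tfs = 3, complex_size = 5,
                          conservation = 0.6, background_orthology = 0)
  ppi <- gen_ppi_with_complexes(cfg, make_tf_roster(cfg))
  for (i in 1:3) {
    m <- sum(ppi$orthologs$a %in% ppi$truth$complexes_a[[i]])
    expect_equal(ppi$truth$pairs$na_truth[i], m^2 / 25)
    expect_equal(na_score(ppi$truth$complexes_a[[i]],
                          ppi$truth$complexes_b[[i]], ppi$orthologs),
                 m^2 / 25)
  }
})

test_that("the synthetic GO DAG has the expected shape and signal", {
  cfg <- small_cfg(6)  # depth 2, branching 2 -> 7 terms
  go <- gen_go(cfg)
  expect_equal(nrow(go$dag$terms), 7)
  roster <- make_tf_roster(cfg)
  designated <- roster$tf_id[seq_len(cfg$n_hot_tfs)]
  # marker annotates exactly the designated genes: similarity 1
  expect_equal(geneset_similarity(go$marker_term, designated,
                                  go$annotations, go$dag), 1)
  gap <- gap_score(go$marker_term, designated, roster$tf_id,
                   go$annotations, go$dag)
  expect_gt(gap$gap, 0)
})

test_that("bundles re-read through the package readers match the truth", {
  cfg <- small_cfg(9)
  dir <- file.path(tempdir(), "bundle_verify")
  bundle <- simulate_bundle(cfg, dir)
  cl <- stats::setNames(nchar(bundle$genome), names(bundle$genome))
  hot <- read_intervals(bundle$paths$hotspots, cl, "hotspot")
  expect_equal(nrow(hot), cfg$n_hotspots)
  motifs <- read_motifs(bundle$paths$motifs, "meme_minimal")
  expect_length(motifs, cfg$n_tfs)
  net <- read_network(bundle$paths$ppi_a)
  expect_equal(igraph::ecount(net), igraph::ecount(bundle$net_a))
  onto <- read_ontology(bundle$paths$obo, bundle$paths$gaf)
  expect_equal(nrow(onto$dag$terms), nrow(bundle$go$dag$terms))
  orth <- read_orthologs(bundle$paths$orthologs)
  expect_equal(nrow(orth), nrow(bundle$orthologs))
  clusters <- read_clusters(bundle$paths$clusters)
  expect_length(clusters, cfg$n_complexes)
  manifest <- jsonlite::read_json(bundle$paths$manifest)
  expect_equal(manifest$seed, cfg$seed)
  expect_length(manifest$truth$complexes_a, cfg$n_complexes)
  # genome FASTA round-trips
  dna <- Biostrings::readDNAStringSet(bundle$paths$genome)
  expect_equal(unname(as.character(dna)), unname(bundle$genome))
})
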