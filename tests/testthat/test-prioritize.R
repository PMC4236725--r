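# Odds ratios, HB profiles/network, relevance, footrule, KM
# aggregation, seed selection.

or_tbl <- function(hm, cm, n_h = 100, n_c = 100, id = "M1") {
  tibble::tibble(motif_id = id, HM = hm, CM = cm, N_H = n_h, N_C = n_c)
}

test_that("odds ratio follows (HM/HN)/(CM/CN) with degenerate conventions", {
  # direct arithmetic: (30/70)/(10/90) = 27/7
  r <- odds_ratio(or_tbl(30, 10))
  expect_equal(r$odds_ratio, 27 / 7)

  expect_equal(odds_ratio(or_tbl(40, 40))$odds_ratio, 1)
  expect_equal(odds_ratio(or_tbl(5, 0, 10, 10))$odds_ratio, Inf)
  expect_equal(odds_ratio(or_tbl(10, 3, 10, 10))$odds_ratio, Inf)
  expect_equal(odds_ratio(or_tbl(0, 5))$odds_ratio, 0)

  expect_warning(r0 <- odds_ratio(or_tbl(0, 0)), "undefined")
  expect_true(r0$undefined)
  expect_equal(r0$odds_ratio, 0)

  expect_error(odds_ratio(or_tbl(101, 0)), "exceeds")

  # Haldane correction keeps everything finite
  rh <- odds_ratio(or_tbl(10, 0, 10, 10), haldane = TRUE)
  expect_true(is.finite(rh$odds_ratio))
})

test_that("OR ranking is deterministic under ties and ranks Inf first", {
  tab <- dplyr::bind_rows(or_tbl(30, 10, id = "b"),
                          or_tbl(10, 10, id = "c"),
                          or_tbl(20, 10, id = "a"))
  r <- rank_by_or(odds_ratio(tab))
  expect_equal(r$gene_id, c("b", "a", "c"))

  ties <- dplyr::bind_rows(or_tbl(10, 10, id = "z"),
                           or_tbl(10, 10, id = "y"))
  expect_equal(rank_by_or(odds_ratio(ties))$gene_id, c("y", "z"))

  inf <- dplyr::bind_rows(or_tbl(5, 0, 10, 10, id = "inf"),
                          or_tbl(9, 1, 10, 10, id = "fin"))
  expect_equal(rank_by_or(odds_ratio(inf))$gene_id[1], "inf")
})

test_that("HB profiles bin bound hotspots by midpoint", {
  cl <- c(chr1 = 10e6)
  spots <- tibble::tibble(chrom = "chr1",
                          start = c(0.9e6, 6.9e6), end = c(1.1e6, 7.1e6))
  b <- build_hb_profile(spots, cl, bin_length = 5e6)
  expect_equal(b, c(1, 1))
  expect_equal(build_hb_profile(spots[0, ], cl, 5e6), c(0, 0))

  three <- tibble::tibble(chrom = "chr1", start = c(0, 10, 20),
                          end = c(8, 18, 28))
  expect_equal(build_hb_profile(three, cl, 5e6), c(3, 0))

  # bins concatenate across chromosomes in order
  cl2 <- c(chr1 = 7e6, chr2 = 5e6)
  b2 <- build_hb_profile(tibble::tibble(chrom = "chr2", start = 0,
                                        end = 100), cl2, 5e6)
  expect_equal(length(b2), 2 + 1)
  expect_equal(b2, c(0, 0, 1))
})

test_that("HB network connects profiles by Pearson correlation", {
  profs <- rbind(g = c(1, 2, 3), h = c(2, 4, 6), k = c(3, 2, 1),
                 z = c(2, 2, 2))
  net <- build_hb_network(profs, threshold = 0.7)
  expect_equal(igraph::ecount(net), 1)
  e <- igraph::as_edgelist(net)
  expect_setequal(as.vector(e), c("g", "h"))  # r = 1 (scale-invariant)
  # anti-correlated and zero-variance profiles gain no edges
  expect_equal(igraph::degree(net)[["k"]], 0)
  expect_equal(igraph::degree(net)[["z"]], 0)
  expect_error(build_hb_network(profs[, 1, drop = FALSE]), "bins")
})

test_that("relevance is cluster frequency normalized by the maximum", {
  clusters <- list(c("g1", "g2"), c("g1", "g3"))
  r <- relevance_from_clusters(clusters, c("g1", "g2", "g3", "g4"))
  expect_equal(r$R, c(1, 0.5, 0.5, 0))

  single <- relevance_from_clusters(list(c("g1", "g2")), c("g1", "g2"))
  expect_equal(single$R, c(1, 1))

  expect_error(relevance_from_clusters(list(), "g1"), "cluster")
})

test_that("footrule distance is a metric on rankings", {
  a <- ranking(c("x", "y", "z"))
  b <- ranking(c("z", "y", "x"))
  expect_equal(footrule_distance(a, a), 0)
  expect_equal(footrule_distance(a, b), 4)
  expect_equal(footrule_distance(ranking(c("p", "q")),
                                 ranking(c("q", "p"))), 2)
  expect_error(footrule_distance(a, ranking(c("x", "y"))), "universe")

  set.seed(5)
  ids <- letters[1:6]
  for (rep in 1:20) {
    r1 <- ranking(sample(ids)); r2 <- ranking(sample(ids))
    r3 <- ranking(sample(ids))
    expect_equal(footrule_distance(r1, r2), footrule_distance(r2, r1))
    expect_lte(footrule_distance(r1, r3),
               footrule_distance(r1, r2) + footrule_distance(r2, r3))
  }
})

test_that("KM aggregation attains the exhaustive-search optimum", {
  ids3 <- c("a", "b", "c")
  so <- ranking(ids3)                    # a:1 b:2 c:3
  sh <- ranking(c("b", "a", "c"))        # a:2 b:1 c:3
  res <- km_aggregate(so, sh)
  expect_equal(res$total_cost, 2)        # brute force over 6 permutations

  same <- km_aggregate(so, so)
  expect_equal(same$total_cost, 0)
  expect_equal(same$ranking$gene_id, so$gene_id)

  one <- km_aggregate(ranking("solo"), ranking("solo"))
  expect_equal(one$total_cost, 0)

  set.seed(9)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    ids <- paste0("g", seq_len(n))
    so <- ranking(sample(ids)); sh <- ranking(sample(ids))
    res <- km_aggregate(so, sh)
    po <- stats::setNames(so$rank, so$gene_id)[sort(ids)]
    ph <- stats::setNames(sh$rank, sh$gene_id)[sort(ids)]
    expect_equal(res$total_cost, brute_force_km_cost(po, ph))
    # the returned consensus achieves the reported cost
    ps <- stats::setNames(res$ranking$rank, res$ranking$gene_id)[sort(ids)]
    expect_equal(sum(abs(po - ps) + abs(ph - ps)), res$total_cost)
  }
})

test_that("seed selection takes the ceiling of the top fraction", {
  mk <- function(n) ranking(sprintf("g%04d", 1:n), score = n:1)
  expect_equal(nrow(select_seeds(mk(177))), 18)
  expect_equal(nrow(select_seeds(mk(158))), 16)
  expect_equal(nrow(select_seeds(mk(148))), 15)
  expect_equal(nrow(select_seeds(mk(10), fraction = 1)), 10)

  s <- select_seeds(mk(20))
  expect_equal(s$gene_id, sprintf("g%04d", 1:2))
  expect_equal(s$weight, c(20, 19))

  u <- select_seeds(mk(20), scores = "uniform")
  expect_equal(u$weight, c(1, 1))

  inf_rank <- ranking(c("a", "b", "c"), scores = c(Inf, 3, 1))
  expect_warning(si <- select_seeds(inf_rank, fraction = 0.6),
                 "non-finite")
  expect_equal(si$weight, c(3, 3))
})

test_that("planted hotspot-preferring TFs top the OR ranking", {
  # scaled-down planted-signal check: hot TFs plant at >= 5x the
  # coldspot rate; all must fall in the top 10% of the OR ranking
  hits_ok <- 0L
  n_rep <- 5L
  for (s in 1:n_rep) {
    cfg <- synthetic_config(
      seed = s, chrom_lengths = c(chr1 = 2e5),
      n_hotspots = 100, n_coldspots = 100, n_tfs = 20, n_hot_tfs = 2,
      hot_rate = 0.5, cold_rate = 0.1)
    gen <- gen_genome_and_spots(cfg)
    roster <- make_tf_roster(cfg)
    planted <- plant_motifs(gen$genome, gen$hotspots, gen$coldspots,
                            roster, cfg$seed)
    targets <- dplyr::bind_rows(gen$hotspots, gen$coldspots)
    hits <- dplyr::bind_rows(lapply(
      roster_motifs(roster), scan_intervals,
      genome = planted$genome, targets = targets))
    tab <- tabulate_hits(hits, gen$hotspots, gen$coldspots,
                         motif_ids = roster$tf_id)
    r <- rank_by_or(suppressWarnings(odds_ratio(tab)))
    seeds <- suppressWarnings(select_seeds(r, 0.10))
    if (all(roster$tf_id[roster$is_hot] %in% seeds$gene_id)) {
      hits_ok <- hits_ok + 1L
    }
  }
  expect_gte(hits_ok, n_rep - 1L)
})
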