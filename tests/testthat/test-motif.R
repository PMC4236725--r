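# PWM scoring, exact score distributions, scanning, hit tabulation.

test_that("log-odds entries follow the closed form", {
  # one-hot column, no pseudocount, uniform background: 2 bits / -Inf
  m <- motif_matrix("x", matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  lo <- log_odds_matrix(m)
  expect_equal(unname(lo["A", 1]), 2)
  expect_true(all(is.infinite(lo[c("C", "G", "T"), 1])))

  # uniform column scores 0 everywhere
  u <- motif_matrix("u", matrix(0.25, 4, 1), pseudocount = 0)
  expect_equal(unname(log_odds_matrix(u)[, 1]), rep(0, 4))

  # counts (9,1,0,0), pseudocount 1, uniform background, by direct
  # arithmetic: freq_A = (9 + 0.25) / 11, entry = log2(freq / 0.25)
  h <- motif_matrix("h", matrix(c(9, 1, 0, 0), 4, 1), pseudocount = 1)
  lo_h <- log_odds_matrix(h)
  expect_equal(unname(lo_h["A", 1]), log2((9.25 / 11) / 0.25))
  expect_equal(unname(lo_h["C", 1]), log2((1.25 / 11) / 0.25))
  expect_equal(unname(lo_h["G", 1]), log2((0.25 / 11) / 0.25))

  bad_bg <- motif_matrix("b", matrix(1, 4, 1),
                         background = c(0.5, 0.5, 0, 0))
  expect_error(log_odds_matrix(bad_bg), "background")
})

test_that("score distribution matches enumeration and normalizes", {
  # width 1, uniform background: four outcomes with mass 1/4
  m1 <- motif_matrix("w1", matrix(c(4, 3, 2, 1), 4, 1), pseudocount = 1)
  d1 <- score_distribution(m1)
  expect_equal(sum(d1$prob) + d1$neg_inf_mass, 1, tolerance = 1e-9)
  expect_equal(d1$prob, rep(0.25, 4))  # four distinct scores, mass 1/4

  # width 2: compare against brute-force enumeration of 16 dinucleotides
  counts <- matrix(c(5, 2, 2, 1,
                    1, 1, 4, 4), 4, 2)
  m2 <- motif_matrix("w2", counts, pseudocount = 0.5)
  d2 <- score_distribution(m2, precision = 1e-3)
  lo <- log_odds_matrix(m2)
  brute <- vector("numeric", 16)
  k <- 0
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1
    brute[k] <- round(lo[i, 1] / 1e-3) + round(lo[j, 2] / 1e-3)
  }
  btab <- table(brute) / 16
  expect_equal(d2$qscore, as.numeric(names(btab)))
  expect_equal(d2$prob, as.numeric(btab))

  # P(score >= minimum) = 1
  expect_equal(score_pvalue(d2, min(d2$score)), 1)
  expect_error(score_distribution(m2, precision = 0), "precision")
})

test_that("p-values are non-increasing in score", {
  set.seed(7)
  counts <- matrix(stats::rpois(4 * 5, 3), 4, 5)
  m <- motif_matrix("mono", counts, pseudocount = 0.5)
  d <- score_distribution(m)
  s <- sort(stats::runif(25, min(d$score) - 1, max(d$score) + 1))
  p <- score_pvalue(d, s)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("one-hot scanning equals exact substring matching", {
  m <- one_hot_motif("ACGG", "ACGG")
  # p-threshold admitting only the maximal score for width 4: the
  # perfect match has null probability 0.25^4 under uniform background
  thr <- 0.25^4
  genome <- c(chr1 = "TTACGGTT")
  spots <- spot_set("chr1", 0, 8, "hotspot")
  hits <- scan_intervals(m, genome, spots, p_threshold = thr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$end, 6)
  expect_equal(hits$strand, "+")

  none <- scan_intervals(m, c(chr1 = "TTTTTTTT"), spots,
                         p_threshold = thr)
  expect_equal(nrow(none), 0)

  # ACGT is its own reverse complement: one occurrence, two strands
  pal <- scan_intervals(one_hot_motif("ACGT", "ACGT"),
                        c(chr1 = "ACGTTTTT"), spots,
                        p_threshold = thr)
  expect_equal(nrow(pal), 2)
  expect_setequal(pal$strand, c("+", "-"))
  expect_equal(unique(pal$start), 0)
})

test_that("one-hot hit counts match the string-search oracle on random sequences", {
  set.seed(11)
  word <- "GATTAC"
  m <- one_hot_motif("w", word)
  thr <- 0.25^nchar(word)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    spots <- spot_set("chr1", 0, 300, "other")
    hits <- scan_intervals(m, c(chr1 = s), spots, p_threshold = thr)
    expect_equal(nrow(hits), count_occurrences_both_strands(s, word))
  }
})

test_that("scanning respects strand symmetry", {
  set.seed(3)
  counts <- matrix(stats::rpois(4 * 5, 2) + 0.5, 4, 5)
  m <- motif_matrix("s", counts)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  spots <- spot_set("chr1", 0, 200, "other")
  fwd <- scan_intervals(m, c(chr1 = s), spots, p_threshold = 0.01)
  rev_ <- scan_intervals(m, c(chr1 = rc), spots, p_threshold = 0.01)
  expect_equal(nrow(fwd), nrow(rev_))
  # reflect reverse-scan coordinates back and compare hit multisets
  reflected <- sort(200 - rev_$end)
  expect_equal(sort(fwd$start), reflected)
  expect_equal(sort(fwd$score), sort(rev_$score))
})

test_that("short intervals and non-ACGT windows yield no hits", {
  m <- one_hot_motif("m", "ACGTAC")
  spots <- spot_set("chr1", 0, 4, "other")
  expect_equal(nrow(scan_intervals(m, c(chr1 = "ACGTNNNN"), spots)), 0)
  spots2 <- spot_set("chr1", 0, 8, "other")
  hits <- scan_intervals(m, c(chr1 = "ACGTNCGT"), spots2,
                         p_threshold = 1)
  expect_equal(nrow(hits), 0)  # every window crosses the N
})

test_that("hits tabulate by full containment into distinct intervals", {
  hot <- spot_set("chr1", c(0, 100), c(50, 150), "hotspot")
  cold <- spot_set("chr1", 200, 250, "coldspot")
  hits <- tibble::tibble(
    motif_id = "M1", chrom = "chr1",
    start = c(5, 10, 20, 45), end = c(11, 16, 26, 51),
    strand = "+", score = 1, p_value = 0.01)
  # three contained hits in hotspot 1; the fourth straddles its end
  tab <- tabulate_hits(hits, hot, cold)
  expect_equal(tab$HM, 1)
  expect_equal(tab$CM, 0)
  expect_equal(tab$HN, 1)
  expect_equal(tab$N_H, 2)

  tab0 <- tabulate_hits(hits[0, ], hot, cold, motif_ids = "M1")
  expect_equal(tab0$HM, 0)
  expect_equal(tab0$CM, 0)
})
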