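# Shared fixtures and small independent oracles.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# one-hot motif for a consensus string
one_hot_motif <- function(id, consensus, pseudocount = 0.1) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- vapply(bases, function(b)
    as.numeric(c("A", "C", "G", "T") == b), numeric(4))
  motif_matrix(id, counts, pseudocount = pseudocount)
}

# exact substring occurrence count on both strands (string-search
# oracle, independent of the PWM scanner)
count_occurrences_both_strands <- function(seq, word) {
  cnt <- function(s, w) {
    n <- 0L
    start <- 1L
    repeat {
      i <- regexpr(w, substr(s, start, nchar(s)), fixed = TRUE)
      if (i == -1L) break
      n <- n + 1L
      start <- start + i
    }
    n
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(word)))
  n <- cnt(seq, word)
  if (rc == word) 2L * n else n + cnt(seq, rc)
}

# all permutations of 1..n (brute-force oracle support)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

# minimal footrule-aggregation cost by exhaustive search
brute_force_km_cost <- function(po, ph) {
  n <- length(po)
  pm <- all_perms(n)
  min(apply(pm, 1, function(sigma) {
    sum(abs(po - sigma) + abs(ph - sigma))
  }))
}

# brute-force maximum-weight bipartite matching over all matchings
brute_force_matching_weight <- function(w, threshold = 0) {
  w[w < threshold] <- 0
  best <- 0
  recurse <- function(i, used, total) {
    if (i > nrow(w)) {
      best <<- max(best, total)
      return()
    }
    recurse(i + 1, used, total)  # leave row i unmatched
    for (j in seq_len(ncol(w))) {
      if (!used[j] && w[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1, used, total + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(ncol(w)), 0)
  best
}

# hypergeometric upper-tail by exhaustive subset enumeration
brute_force_hyper_tail <- function(k, n_complex, n_term, universe_size) {
  sets <- utils::combn(universe_size, n_complex)
  hits <- colSums(sets <= n_term)  # first n_term elements are "in F"
  mean(hits >= k)
}

# tiny GO chain: root <- a <- b (is_a), one namespace
chain_dag <- function() {
  structure(list(
    terms = tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003"),
      name = c("root", "a", "b"),
      namespace = "biological_process"),
    edges = tibble::tibble(
      child = c("GO:0000002", "GO:0000003"),
      parent = c("GO:0000001", "GO:0000002"),
      relation = "is_a")), class = "go_dag")
}

# small deterministic test graph from an edge list
graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}
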