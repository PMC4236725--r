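# GO-based evaluation: relation-weighted ancestor-contribution semantic
# similarity between terms, term-to-gene and term-to-gene-set similarity,
# gap scores contrasting a prioritized subset against the full universe,
# and hypergeometric complex-enrichment p-values.

#' Evaluation GO terms for recombination biology
#'
#' Named constants for the two terms most directly tied to meiotic
#' recombination hotspots, used throughout the evaluation stage.
#' @export
go_recombination_terms <- c(dna_recombination = "GO:0006310",
                            meiosis = "GO:0007126")

# S-values of all ancestors of a term: S(t) = 1, and an ancestor a gets
# the maximum over parent edges (c -> a) on paths from t of
# weight(relation) * S(c). Computed by relaxation; the DAG guarantees
# termination.
term_svalues <- function(t, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  s <- stats::setNames(1, t)
  frontier <- t
  while (length(frontier)) {
    nxt <- character()
    for (child in frontier) {
      up <- dag$edges[dag$edges$child == child, , drop = FALSE]
      if (!nrow(up)) next
      cand <- unname(weights[up$relation]) * s[[child]]
      for (k in seq_len(nrow(up))) {
        parent <- up$parent[k]
        if (is.na(s[parent]) || cand[k] > s[[parent]]) {
          s[parent] <- cand[k]
          nxt <- c(nxt, parent)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Semantic similarity between two GO terms
#'
#' Graph-based similarity over the ancestor closures: each term's
#' ancestors (itself included) carry S-values propagated from the term
#' with per-relation weights (`is_a` 0.8, `part_of` 0.6), and
#' `sim(t, u)` is the summed S-value contribution of the common
#' ancestors relative to both terms' total semantic values. Terms from
#' different namespaces have similarity 0 (with a warning).
#'
#' @param t,u Term ids present in the DAG.
#' @param dag A `go_dag` from [read_ontology()].
#' @param weights Named relation weights.
#' @return A number in `[0, 1]`; 1 iff the terms coincide.
#' @export
term_similarity <- function(t, u, dag,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  it <- match(t, dag$terms$id)
  iu <- match(u, dag$terms$id)
  if (is.na(it) || is.na(iu)) abort("unknown term")
  if (dag$terms$namespace[it] != dag$terms$namespace[iu]) {
    warn("terms from different namespaces; similarity is 0")
    return(0)
  }
  st <- term_svalues(t, dag, weights)
  su <- term_svalues(u, dag, weights)
  common <- intersect(names(st), names(su))
  sum(st[common] + su[common]) / (sum(st) + sum(su))
}

#' Similarity between a term and a gene
#'
#' The maximum similarity between `t` and any term annotating the gene;
#' a gene with no annotations scores 0.
#'
#' @param t Term id.
#' @param g Gene id, present in the annotation map.
#' @param annotations Named list, gene id to character vector of terms.
#' @inheritParams term_similarity
#' @export
term_gene_similarity <- function(t, g, annotations, dag,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!g %in% names(annotations)) abort(paste("unknown gene:", g))
  tg <- annotations[[g]]
  if (!length(tg)) return(0)
  max(vapply(tg, function(tp) {
    suppressWarnings(term_similarity(t, tp, dag, weights))
  }, numeric(1)))
}

#' Similarity between a term and a gene set
#'
#' The mean over the set of [term_gene_similarity()]; genes missing
#' from the annotation map contribute 0 (no annotation means no
#' semantic signal).
#'
#' @param t Term id.
#' @param genes Nonempty character vector.
#' @inheritParams term_gene_similarity
#' @export
geneset_similarity <- function(t, genes, annotations, dag,
                               weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!length(genes)) abort("empty gene set")
  vals <- vapply(genes, function(g) {
    if (!g %in% names(annotations)) return(0)
    term_gene_similarity(t, g, annotations, dag, weights)
  }, numeric(1))
  mean(vals)
}

#' Gap score of a term between a prioritized subset and its universe
#'
#' `gap(t) = (S(t, HG) - S(t, G)) / S(t, G)`: the relative excess of the
#' term's similarity to the prioritized genes `HG` over the whole
#' universe `G`. A large gap marks a term enriched in `HG` but not in
#' `G` at large. When `S(t, G) = 0` the gap is undefined and flagged.
#'
#' @param t Term id.
#' @param hg Prioritized gene subset; must be contained in `g`.
#' @param g Universe gene set.
#' @inheritParams term_gene_similarity
#' @return Tibble row: `term`, `S_HG`, `S_G`, `gap`, `undefined`.
#' @export
gap_score <- function(t, hg, g, annotations, dag,
                      weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!all(hg %in% g)) abort("prioritized set is not a subset of the universe")
  s_hg <- geneset_similarity(t, hg, annotations, dag, weights)
  s_g <- geneset_similarity(t, g, annotations, dag, weights)
  undef <- s_g == 0
  tibble(term = t, S_HG = s_hg, S_G = s_g,
         gap = if (undef) NA_real_ else (s_hg - s_g) / s_g,
         undefined = undef)
}

#' Rank terms by gap score
#'
#' Descending gap; terms with undefined gaps are excluded; ties broken
#' by term id.
#'
#' @param terms Nonempty character vector of term ids.
#' @inheritParams gap_score
#' @return Tibble of [gap_score()] rows plus `rank`.
#' @export
rank_terms_by_gap <- function(terms, hg, g, annotations, dag,
                              weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(length(terms) >= 1L)
  res <- dplyr::bind_rows(lapply(terms, gap_score, hg = hg, g = g,
                                 annotations = annotations, dag = dag,
                                 weights = weights))
  res <- res[!res$undefined, , drop = FALSE]
  if (!nrow(res)) return(dplyr::mutate(res, rank = integer()))
  res <- res[order(-res$gap, res$term), , drop = FALSE]
  dplyr::mutate(res, rank = dplyr::row_number())
}

#' Hypergeometric enrichment p-value of a complex for a term
#'
#' The upper tail `P(X >= k)` of the hypergeometric distribution: the
#' probability that a random complex of the same size drawn from a
#' universe of `universe_size` proteins contains at least `k` of the
#' `n_term` proteins annotated with the term. `k = 0` gives 1.
#' Evaluated through the stable log-space hypergeometric tail.
#'
#' @param k Number of complex members annotated with the term.
#' @param n_complex Complex size.
#' @param n_term Number of universe proteins annotated with the term.
#' @param universe_size Total number of proteins in the genome.
#' @return A probability.
#' @export
hypergeom_pvalue <- function(k, n_complex, n_term, universe_size) {
  stopifnot(is_count(k), is_count(n_complex), is_count(n_term),
            is_count(universe_size),
            n_complex <= universe_size, n_term <= universe_size,
            k <= n_complex)
  if (k == 0) return(1)
  stats::phyper(k - 1, n_term, universe_size - n_term, n_complex,
                lower.tail = FALSE)
}

#' GO enrichment of every complex in a set
#'
#' Applies [hypergeom_pvalue()] per complex per term, with optional
#' multiple-testing adjustment across all complex-term pairs.
#'
#' @param complexes A `complex_set`.
#' @param annotations Named list, gene to terms.
#' @param universe Character vector of all proteins in the genome.
#' @param terms Terms to test (default: every annotated term).
#' @param adjust One of `"none"`, `"bonferroni"`, `"BH"`.
#' @return Tibble: `complex_id`, `term`, `k`, `n_term`, `p_value`,
#'   `adjusted_p`.
#' @export
complex_enrichment <- function(complexes, annotations, universe,
                               terms = NULL,
                               adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  terms <- terms %||% sort(unique(unlist(annotations)))
  term_genes <- lapply(terms, function(t) {
    names(annotations)[vapply(annotations, function(x) t %in% x,
                              logical(1))]
  })
  names(term_genes) <- terms
  rows <- list()
  for (i in seq_along(complexes)) {
    members <- complexes[[i]]$members
    for (t in terms) {
      f <- intersect(term_genes[[t]], universe)
      k <- length(intersect(members, f))
      rows[[length(rows) + 1L]] <- tibble(
        complex_id = i, term = t, k = k, n_term = length(f),
        p_value = hypergeom_pvalue(k, length(members), length(f),
                                   length(universe)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- if (adjust == "none") out$p_value else
    stats::p.adjust(out$p_value, method = adjust)
  dplyr::arrange(out, .data$p_value)
}
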