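# Core-attachment protein-complex mining, neighborhood-affinity scoring
# of complex pairs over an ortholog map, and conserved-pair extraction by
# exact maximum-weight bipartite matching.

#' Mine protein complexes by core-attachment
#'
#' For each vertex v, the neighborhood graph on `{v} union N(v)` is
#' pruned by repeatedly deleting a minimum-degree vertex (never v
#' itself; ties broken lexicographically) until the density
#' `2E / (V (V - 1))` reaches `density_threshold`; the surviving set is
#' a candidate core. Every outside protein adjacent to at least
#' `attach_ratio` of the core is then attached. Complexes of size < 3
#' are discarded, and redundant complexes (pairwise neighborhood
#' affinity at least `redundancy_na`) are filtered keeping the denser
#' one (ties: the larger, then the lexicographically first member).
#'
#' @param net An undirected `igraph`.
#' @param density_threshold Core density threshold in `(0, 1]`
#'   (default 0.7).
#' @param attach_ratio Attachment threshold in `(0, 1]` (default 0.5);
#'   the comparison is weak, so a ratio exactly at the threshold
#'   attaches.
#' @param redundancy_na Redundancy filter threshold in `(0, 1]`
#'   (default 0.25).
#' @return A `complex_set`: list of complexes, each a list with
#'   `members` (sorted character vector), `core`, and `density` (density
#'   of the full member set). See [tidy.complex_set()].
#' @export
detect_complexes <- function(net, density_threshold = 0.7,
                             attach_ratio = 0.5, redundancy_na = 0.25) {
  stopifnot(density_threshold > 0, density_threshold <= 1,
            attach_ratio > 0, attach_ratio <= 1,
            redundancy_na > 0, redundancy_na <= 1)
  nodes <- igraph::V(net)$name
  if (!length(nodes)) {
    return(structure(list(), class = "complex_set"))
  }
  adj <- lapply(igraph::adjacent_vertices(net, nodes), function(v) v$name)
  names(adj) <- nodes
  candidates <- list()
  for (v in nodes) {
    cand <- mine_core(v, adj, density_threshold)
    if (is.null(cand)) next
    core <- cand$set
    # attachment: outside proteins adjacent to >= attach_ratio of core
    outside <- setdiff(nodes, core)
    n_in <- vapply(outside, function(p) length(intersect(adj[[p]], core)),
                   integer(1))
    attached <- outside[n_in / length(core) >= attach_ratio]
    members <- sort(c(core, attached))
    if (length(members) < 3L) next
    candidates[[length(candidates) + 1L]] <- list(
      members = members, core = sort(core),
      density = set_density(members, adj))
  }
  structure(filter_redundant(candidates, redundancy_na),
            class = "complex_set")
}

# Restrict the neighborhood graph to its core vertices (degree at
# least the neighborhood average, v always kept), then iteratively
# delete min-degree vertices until dense. Without the core-vertex
# filter, pruning stops at the first density-passing set and routinely
# retains low-degree stragglers whose presence dilutes the complex;
# the surviving set also only counts when v itself reaches the core's
# average degree, or a straggler seed spawns a shifted near-duplicate
# core that shadows the true complex in the redundancy filter.
mine_core <- function(v, adj, density_threshold) {
  set <- sort(c(v, adj[[v]]))
  if (length(set) > 2L) {
    deg <- vapply(set, function(u) length(intersect(adj[[u]], set)),
                  integer(1))
    set <- sort(union(v, set[deg >= mean(deg)]))
  }
  repeat {
    dens <- set_density(set, adj)
    if (dens >= density_threshold) {
      # a core below 3 vertices is a bare edge, not a dense region
      if (length(set) < 3L) return(NULL)
      deg <- vapply(set, function(u) length(intersect(adj[[u]], set)),
                    integer(1))
      if (deg[[v]] < mean(deg)) return(NULL)
      return(list(set = set, density = dens))
    }
    if (length(set) <= 2L) return(NULL)
    deg <- vapply(set, function(u) length(intersect(adj[[u]], set)),
                  integer(1))
    removable <- setdiff(set, v)
    dmin <- min(deg[removable])
    victim <- sort(removable[deg[removable] == dmin])[1]
    set <- setdiff(set, victim)
  }
}

set_density <- function(set, adj) {
  n <- length(set)
  if (n < 2L) return(1)
  e <- sum(vapply(set, function(u) length(intersect(adj[[u]], set)),
                  integer(1))) / 2
  2 * e / (n * (n - 1))
}

filter_redundant <- function(candidates, redundancy_na) {
  if (length(candidates) <= 1L) return(unname(candidates))
  key <- vapply(candidates, function(cx) {
    paste(cx$members, collapse = " ")
  }, character(1))
  candidates <- candidates[!duplicated(key)]
  dens <- vapply(candidates, `[[`, numeric(1), "density")
  size <- vapply(candidates, function(cx) length(cx$members), integer(1))
  first <- vapply(candidates, function(cx) cx$members[1], character(1))
  # cohesiveness (density x size) decides which of two redundant
  # complexes survives: density alone lets a small near-clique shifted
  # off a larger dense region shadow the region itself
  o <- order(-(dens * size), -dens, -size, first)
  kept <- list()
  for (i in o) {
    redundant <- any(vapply(kept, function(kx) {
      na_score(kx$members, candidates[[i]]$members) >= redundancy_na
    }, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- candidates[[i]]
  }
  kept
}

#' @export
print.complex_set <- function(x, ...) {
  cat("<complex_set>", length(x), "complexes\n")
  invisible(x)
}

#' Tidy a complex set into a tibble
#'
#' @param x A `complex_set` from [detect_complexes()].
#' @param ... Unused.
#' @return Tibble with `complex_id`, `size`, `density`, and a `members`
#'   list-column.
#' @method tidy complex_set
#' @export
tidy.complex_set <- function(x, ...) {
  tibble(complex_id = seq_along(x),
         size = vapply(x, function(cx) length(cx$members), integer(1)),
         density = vapply(x, `[[`, numeric(1), "density"),
         members = lapply(x, `[[`, "members"))
}

#' Write complexes one per line (density-prefixed, space-separated)
#'
#' @param x A `complex_set`.
#' @param path Output path.
#' @export
write_complexes <- function(x, path) {
  lines <- vapply(x, function(cx) {
    paste(c(format(cx$density, digits = 6), cx$members), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Neighborhood affinity between two complexes
#'
#' `NA(A, B) = overlap^2 / (|A| |B|)`, where the overlap is `|A
#' intersect B|` for same-species comparisons (identity map) or the
#' number of ortholog pairs `(a, b)` with `a` in A and `b` in B. Under
#' many-to-many orthology the raw value can exceed 1; it is then clamped
#' to 1 with a warning.
#'
#' @param a,b Character vectors of complex members (or complex entries
#'   from a `complex_set`).
#' @param orthologs `NULL` for the identity map, or an ortholog tibble
#'   (`a`, `b`) from [read_orthologs()].
#' @return A number in `[0, 1]`.
#' @export
na_score <- function(a, b, orthologs = NULL) {
  if (is.list(a) && !is.null(a$members)) a <- a$members
  if (is.list(b) && !is.null(b$members)) b <- b$members
  stopifnot(length(a) > 0, length(b) > 0)
  if (is.null(orthologs)) {
    overlap <- length(intersect(a, b))
  } else {
    overlap <- sum(orthologs$a %in% a & orthologs$b %in% b)
  }
  val <- overlap^2 / (length(a) * length(b))
  if (val > 1) {
    warn("neighborhood affinity > 1 under many-to-many orthology; clamped")
    val <- 1
  }
  val
}

#' Match conserved complexes across two species
#'
#' Builds the bipartite graph of complex pairs weighted by
#' [na_score()] over the ortholog map, removes edges below `threshold`,
#' and extracts an exact maximum-total-weight matching, so each complex
#' joins at most one conserved pair.
#'
#' @param h,m `complex_set`s from two species.
#' @param orthologs Ortholog tibble (`a` ids from `h`'s species, `b`
#'   ids from `m`'s).
#' @param threshold Minimum affinity for a pair, in `(0, 1]` (default
#'   0.25).
#' @return Tibble with `complex_a`, `complex_b` (indices into `h` and
#'   `m`), `na_weight`, `members_a`, `members_b`; zero rows when no pair
#'   reaches the threshold.
#' @export
match_conserved <- function(h, m, orthologs, threshold = 0.25) {
  stopifnot(threshold > 0, threshold <= 1)
  empty <- tibble(complex_a = integer(), complex_b = integer(),
                  na_weight = numeric(), members_a = character(),
                  members_b = character())
  if (!length(h) || !length(m)) return(empty)
  wm <- matrix(0, length(h), length(m))
  for (i in seq_along(h)) {
    for (j in seq_along(m)) {
      wm[i, j] <- na_score(h[[i]], m[[j]], orthologs)
    }
  }
  el <- which(wm >= threshold, arr.ind = TRUE)
  if (!nrow(el)) return(empty)
  g <- igraph::make_bipartite_graph(
    rep(c(FALSE, TRUE), c(length(h), length(m))),
    edges = as.vector(t(cbind(el[, 1], el[, 2] + length(h)))))
  mt <- igraph::max_bipartite_match(g, weights = wm[el])
  pair_a <- which(!is.na(mt$matching[seq_along(h)]))
  if (!length(pair_a)) return(empty)
  pair_b <- as.integer(mt$matching[pair_a] - length(h))
  tibble(complex_a = pair_a, complex_b = pair_b,
         na_weight = wm[cbind(pair_a, pair_b)],
         members_a = vapply(h[pair_a], function(cx)
           paste(cx$members, collapse = " "), character(1)),
         members_b = vapply(m[pair_b], function(cx)
           paste(cx$members, collapse = " "), character(1))) |>
    dplyr::arrange(dplyr::desc(.data$na_weight))
}
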