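# Random walk with restart over a PPI network: column-stochastic
# normalization, iteration to the steady state, non-seed ranking, and
# induction of the top-k subnetwork.

#' Column-stochastic transition matrix of a PPI network
#'
#' `W[i, j] = A[i, j] / deg_w(j)`, where `deg_w(j)` is the weighted
#' degree of node `j`, so every column sums to 1 and a walker's
#' probability mass is conserved. Isolated nodes get a unit self-loop.
#'
#' @param net An undirected `igraph` with positive edge weights (a
#'   missing `weight` attribute means unit weights).
#' @return A sparse `Matrix` with node names as dimnames.
#' @export
normalize_adjacency <- function(net) {
  stopifnot(igraph::vcount(net) >= 1L)
  w <- igraph::E(net)$weight %||% rep(1, igraph::ecount(net))
  if (any(w < 0)) abort("negative edge weight")
  a <- igraph::as_adjacency_matrix(net, attr =
    if (!is.null(igraph::E(net)$weight)) "weight" else NULL, sparse = TRUE)
  a <- methods::as(a, "dMatrix")
  deg <- Matrix::colSums(a)
  isolated <- deg == 0
  if (any(isolated)) {
    d <- Matrix::Diagonal(n = nrow(a), x = as.numeric(isolated))
    a <- a + d
    deg[isolated] <- 1
  }
  W <- a %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- list(igraph::V(net)$name, igraph::V(net)$name)
  W
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - gamma) W p_t + gamma p_0` from the seed
#' restart vector `p_0` until the L1 difference between successive
#' vectors drops below `tol`. `p_0` places the seeds' weights
#' (normalized to sum 1) on the seed nodes and 0 elsewhere; at
#' `gamma = 1` the steady state is `p_0` itself.
#'
#' @param net An undirected `igraph`, or a precomputed transition matrix
#'   from [normalize_adjacency()] (with dimnames).
#' @param seeds A `seed_set` tibble (`gene_id`, `weight`) from
#'   [select_seeds()], or a character vector (uniform weights). Seeds
#'   absent from the network are dropped with a warning; at least one
#'   must remain.
#' @param gamma Restart probability in `(0, 1]` (default 0.7).
#' @param tol L1 convergence threshold (default `1e-10`).
#' @param max_iter Iteration cap (default 10000); reaching it returns
#'   the current vector flagged `converged = FALSE`.
#' @return An `rwr_fit` object; see [tidy.rwr_fit()] and
#'   [glance.rwr_fit()].
#' @export
rwr <- function(net, seeds, gamma = 0.7, tol = 1e-10, max_iter = 10000L) {
  stopifnot(gamma > 0, gamma <= 1, tol > 0, max_iter >= 1)
  W <- if (igraph::is_igraph(net)) normalize_adjacency(net) else net
  nodes <- rownames(W)
  if (is.character(seeds)) seeds <- tibble(gene_id = seeds, weight = 1)
  present <- seeds$gene_id %in% nodes
  if (!all(present)) {
    warn(paste("seeds absent from the network dropped:",
               paste(seeds$gene_id[!present], collapse = ", ")))
    seeds <- seeds[present, , drop = FALSE]
  }
  if (!nrow(seeds)) abort("no seed present in the network")
  if (any(seeds$weight < 0)) abort("seed weights must be nonnegative")
  sw <- seeds$weight
  if (sum(sw) == 0) sw <- rep(1, length(sw))
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds$gene_id] <- sw / sum(sw)
  p <- p0
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(max_iter)) {
    p_new <- as.numeric((1 - gamma) * (W %*% p)) + gamma * p0
    iterations <- t
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  names(p) <- nodes
  structure(
    list(p = p, p0 = p0, seeds = seeds$gene_id, gamma = gamma, tol = tol,
         iterations = iterations, converged = converged),
    class = "rwr_fit")
}

#' @export
print.rwr_fit <- function(x, ...) {
  cat("<rwr_fit> ", length(x$p), " nodes, ", length(x$seeds), " seeds, ",
      "gamma = ", x$gamma, ", ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Tidy a random-walk fit into a per-node tibble
#'
#' @param x An `rwr_fit`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `p` (steady-state relevance),
#'   `is_seed`, and `rank` (descending `p`, ties by gene id).
#' @method tidy rwr_fit
#' @export
tidy.rwr_fit <- function(x, ...) {
  out <- tibble(gene_id = names(x$p), p = as.numeric(x$p),
                is_seed = names(x$p) %in% x$seeds)
  out$rank <- rank_order(out$p, out$gene_id)
  dplyr::arrange(out, .data$rank)
}

#' One-row summary of a random-walk fit
#'
#' @inheritParams tidy.rwr_fit
#' @method glance rwr_fit
#' @export
glance.rwr_fit <- function(x, ...) {
  tibble(n_nodes = length(x$p), n_seeds = length(x$seeds),
         gamma = x$gamma, iterations = x$iterations,
         converged = x$converged, total_mass = sum(x$p))
}

# dense ranks for descending score with lexicographic tie-break
rank_order <- function(score, id) {
  match(seq_along(score), order(-score, id))
}

#' Rank non-seed genes by steady-state relevance
#'
#' @param fit An `rwr_fit`.
#' @return A [ranking()] over the non-seed nodes, descending `p`, ties
#'   broken by gene id. Empty non-seed sets give an empty tibble.
#' @export
rank_nonseeds <- function(fit) {
  ns <- setdiff(names(fit$p), fit$seeds)
  if (!length(ns)) {
    return(tibble(gene_id = character(), rank = integer(),
                  score = numeric()))
  }
  p <- fit$p[ns]
  o <- order(-p, ns)
  ranking(ns[o], as.numeric(p[o]))
}

#' Induce the subnetwork of the top-k genes
#'
#' Vertex-induced subgraph on the `k` nodes with highest steady-state
#' relevance (seeds compete by their own `p`; ties broken by gene id).
#'
#' @param net The `igraph` the walk ran on.
#' @param fit An `rwr_fit` on that network.
#' @param k Number of nodes to keep, `1 <= k <= n` (values above `n`
#'   are truncated).
#' @return An `igraph`.
#' @export
induce_top_subnetwork <- function(net, fit, k) {
  stopifnot(is_count(k), k >= 1)
  k <- min(k, length(fit$p))
  o <- order(-fit$p, names(fit$p))
  keep <- names(fit$p)[o[seq_len(k)]]
  igraph::induced_subgraph(net, keep)
}
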