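---
title: "Methods: prioritizing trans-regulators and complexes for recombination hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing trans-regulators and complexes for recombination hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombnet)
```

## The problem

Meiotic crossovers cluster in short genomic regions — recombination
hotspots. A handful of trans-acting regulators are known (PRDM9 above
all), but PRDM9 explains only part of hotspot variation, so the search
for additional regulators, and for the protein machineries they act in,
is open. `recombnet` implements a network pipeline for that search:

1. **Prioritize** DNA-binding proteins by how strongly their motifs
   prefer hotspots over matched coldspots (odds-ratio scores), by their
   relevance in cross-species hotspot-binding (HB) networks, and by a
   consensus of the two rankings.
2. **Propagate** the top-prioritized genes as seeds through a
   protein–protein interaction (PPI) network with a random walk with
   restart (RWR), scoring genes that lack binding data.
3. **Detect** dense protein complexes in the subnetwork induced by the
   top-ranked genes, and match complexes across species by
   ortholog-based neighborhood affinity.
4. **Evaluate** gene sets and complexes against the Gene Ontology with
   semantic-similarity gap scores and hypergeometric enrichment.

A seeded synthetic-data module generates every input class, so the full
pipeline runs and is tested without any external download.

## Prioritization

### Odds-ratio scores

For a TF with motif occurrences counted per interval, with `HM` of
`N_H` hotspots and `CM` of `N_C` coldspots containing at least one
occurrence, the odds ratio is

\[
O_{hc} = \frac{HM / HN}{CM / CN}, \qquad HN = N_H - HM,\; CN = N_C - CM .
\]

A hit belongs to an interval only when fully contained in it —
"occurrence in a hotspot" is read as containment, which is
deterministic and avoids double counting at boundaries. Degenerate
tables follow fixed conventions: `HM = N_H` or (`CM = 0`, `HM > 0`)
give \(+\infty\); `HM = 0` gives 0; a TF absent from both classes is
flagged undefined. An optional Haldane–Anscombe +0.5 correction on all
four cells is available but off by default, so reported scores are the
plain ratio. Ties in the ranking break by descending `HM`, then motif
id, making the ranking reproducible.

The motif occurrences themselves come either from an external
FIMO-style hit table or from the built-in scanner (below).

### Motif scanning

Motifs are position frequency matrices (JASPAR PFM or MEME minimal
dialects). Scoring uses the log2 odds of the pseudocount-smoothed
frequency against a 0-order background; the default pseudocount of 0.1,
distributed by background frequency, keeps scores finite. P-values come
from the *exact* distribution of window scores under the i.i.d.
background, computed by position-wise convolution on a score grid of
1e-3 bits — fine enough that discretization error sits far below any
decision boundary, at negligible cost for motif widths in practical
use. A window is a hit when \(P(S \ge s) \le\) `p_threshold`; the
default `1e-4` mirrors common scanner practice since no single
canonical threshold exists. Both strands are scanned (the reverse
strand scores the reverse-complemented window); windows containing
non-ACGT characters are skipped. With a one-hot matrix and a threshold
that admits only the maximal score, scanning reduces exactly to
substring search — the test suite exploits this equivalence against an
independent string-matching oracle. Note that a threshold below
\(0.25^w\) admits nothing, since the perfect match itself has null
probability \(0.25^w\) under the uniform background.

### HB profiles, HB networks and relevance

The genome is divided into fixed-length bins (default 5 Mb for real
genomes; the synthetic preset uses 50 kb to match its 1 Mb genome). A
TF's HB profile counts, per bin, the hotspots it binds; a hotspot is
assigned to the bin containing its midpoint, which gives every hotspot
exactly one bin even when it straddles a boundary. Two TFs are
connected in the HB network when the Pearson correlation of their
profiles strictly exceeds 0.7; zero-variance profiles are treated as
uncorrelated. Relevance `R(g)` is the number of conserved clusters
containing `g`, normalized by the maximum over genes. Conserved
clusters are read from a file when available; otherwise a deliberately
naive fallback intersects two species' HB networks over an ortholog map
and takes connected components of size ≥ 2 — adequate wiring, but not a
substitute for a real cross-species network aligner.

### Consensus ranking (KM aggregation)

Given the odds-ratio ranking \(\sigma_o\) and the HB ranking
\(\sigma_h\), the consensus \(\sigma^\*\) minimizes the summed
Spearman footrule displacement
\(\sum_i |\sigma_o(i)-\sigma(i)| + |\sigma_h(i)-\sigma(i)|\). Assigning
TFs to positions is a linear assignment problem on the complete
bipartite graph with cost \(w(t,p) = |\sigma_o(t)-p| +
|\sigma_h(t)-p|\); an exact Kuhn–Munkres solver (igraph's weighted
bipartite matching, converted from min-cost to max-weight) returns an
optimal assignment. Multiple optima can exist; the implementation is
deterministic (ids are sorted before solving) and the tests assert the
cost, which is unique.

### Seed selection

The top 10% of a ranking (ceiling of `0.10 * n`) becomes the seed set:
rosters of 177, 158 and 148 TFs yield 18, 16 and 15 seeds. Seeds carry
their prioritization score into the restart vector; because an infinite
odds ratio cannot be normalized, non-finite scores are replaced by the
largest finite seed score (with a warning), and a uniform mode is
available when score magnitudes should not matter.

## Random walk with restart

With column-stochastic transition matrix \(W\) (entry \(A_{ij} /
\deg_w(j)\)) and restart vector \(p_0\) (seed scores normalized to sum
1), the walk iterates

\[
p_{t+1} = (1-\gamma)\, W p_t + \gamma\, p_0
\]

until the L1 difference of successive iterates falls below `tol`.
Defaults: \(\gamma = 0.7\), `tol = 1e-10`, at most 10,000 iterations.
Column-stochastic normalization is the convention that conserves
probability mass for undirected graphs; isolated nodes receive a unit
self-loop so every column still sums to 1 and the total mass stays at 1
to within 1e-9 at every step. The steady state solves \(p = \gamma (I -
(1-\gamma) W)^{-1} p_0\); the test suite checks the iterative result
against this direct linear solve on dozens of random graphs, and the
\(\gamma = 1\) limit returns \(p_0\) exactly. The walk runs on the full
graph as read — no restriction to the largest connected component —
which means non-seed nodes unreachable from any seed simply keep
relevance 0.

The subnetwork induced by the top `top_k` nodes (default 200; the
synthetic preset uses 60 on its 120-node networks) feeds complex
detection. Ties at the boundary break by gene id.

## Complex detection and cross-species matching

Detection is core–attachment mining: for each vertex `v`, the
neighborhood graph on `{v} ∪ N(v)` is first restricted to its core
vertices — those whose degree within the neighborhood reaches the
neighborhood's average (`v` is always kept) — and then pruned by
repeatedly deleting a minimum-degree vertex (never `v`; ties
lexicographic) until the density \(2E/(V(V-1))\) reaches
`density_threshold` (default 0.7). The average-degree filter matters:
without it, pruning stops at the first density-passing set and
routinely retains low-degree stragglers whose presence dilutes the
complex and every affinity computed from it. The surviving set is a
candidate core when it has at least 3 vertices (a bare edge is not a
dense region) and `v` itself reaches at least the core's average
degree — without the latter condition, a low-degree straggler adjacent
to someone else's dense region spawns a shifted near-duplicate core
that can shadow the true complex downstream. Every outside protein
adjacent to at least `attach_ratio` (default 0.5, weak inequality) of
the core is attached; complexes below 3 members are dropped.

Redundant complexes — pairwise neighborhood affinity at or above
`redundancy_na` (default 0.25) — are filtered keeping the candidate
with the higher cohesiveness (density × size), with density, size and
first member as successive tie-breaks. Cohesiveness rather than raw
density decides survival because a small near-clique carved out of a
larger dense region is almost always the less informative duplicate,
yet often the denser one.

The neighborhood affinity between complexes \(A\) and \(B\) is

\[
NA(A, B) = \frac{|A \cap B|^2}{|A| \cdot |B|},
\]

where the overlap is set intersection within a species and the number
of ortholog pairs across species. Under many-to-many orthology the raw
value can exceed 1; it is clamped to 1 with a warning rather than
silently rescaled. Cross-species conserved pairs are extracted by exact
maximum-total-weight bipartite matching over the affinity graph after
removing edges below 0.25, so each complex joins at most one pair and
total conservation is maximized — a greedy pairing can strand complexes
that an optimal matching pairs.

## GO evaluation

Term–term similarity follows a relation-weighted
ancestor-contribution scheme: within a term's ancestor closure, the
term itself has S-value 1 and each ancestor the maximum over paths of
the product of per-edge weights (`is_a` 0.8, `part_of` 0.6); the
similarity of two terms is the summed S-value of their common ancestors
relative to both terms' total semantic value. It is symmetric, 1
exactly on identical terms, positive for any two terms sharing a root,
and 0 across namespaces. Term–gene similarity maximizes over the
gene's annotations (an unannotated gene scores 0); term–set similarity
averages over the evaluated set — the mean is taken over the set being
scored, which is the only normalization that makes the subset and
universe scores comparable in the gap

\[
gap(t) = \frac{S(t, HG) - S(t, G)}{S(t, G)} .
\]

Terms with \(S(t, G) = 0\) have no defined gap and are excluded from
ranking. Complex enrichment uses the hypergeometric upper tail
\(P(X \ge k)\) for `k` annotated members in a complex of its size drawn
from the annotated universe, computed through R's log-space-stable
distribution functions and verified in the tests against exhaustive
subset enumeration; raw p-values are reported, with Bonferroni and
Benjamini–Hochberg adjustments as options.

## The synthetic-data generators

The generators emulate every input: an i.i.d. uniform-ACGT genome with
non-overlapping, length-matched hotspot and coldspot sets (length
matching removes interval length as a scanning-rate confounder);
consensus motif occurrences planted per TF per interval at configured
rates, never overlapping one another, with every write recorded in a
truth table; two PPI networks as planted dense subgraphs over an
Erdős–Rényi background, cross-linked by 1:1 orthologs preserving
complex membership; a balanced `is_a` GO DAG (with one `part_of`
cross-edge) whose marker leaf annotates a designated gene set; and
conserved clusters mirroring the planted complexes. Each generator
draws from its own deterministic sub-seed forked from the master seed,
so adding a generator never perturbs another's stream, and one seed
yields byte-identical bundles.

The default configuration is the strong-signal regime the pipeline is
validated under: 3 of 30 TFs plant their 8-mer consensus in 80% of 200
hotspots against 10% of 200 coldspots (other TFs plant at 10% in both);
two 500 kb chromosomes; 3 planted complexes of size 6 per species
(each containing one hotspot-preferring TF) wired at edge probability
0.9 over a background of 0.02 on 120 nodes; ortholog conservation 0.8.
The intra-complex edge probability and background rate were chosen once
as a realistic dense-module-versus-noise contrast; with binomial edge
sampling a planted member occasionally keeps too few intra-complex
edges to belong to any dense region, and a planted pair's realized
conservation occasionally falls below the 0.25 matching threshold —
the end-to-end evaluation counts the former against recovery (hence
the ≥95%-of-replicates criterion rather than 100%) and excludes the
latter from the pairing denominator, since no matcher honoring the
threshold could pair it.

What the generators do **not** emulate: real base composition and
repeat structure, recombination-rate landscapes, linkage
disequilibrium, degree-heterogeneous (scale-free) PPI topology,
realistic GO depth or annotation sparsity, and many-to-many orthology.
Passing the planted-signal suites therefore demonstrates that the
machinery recovers strong signals it was pointed at — not that the
defaults are tuned for any particular real genome.

## Numerical and design choices

| Parameter | Default | Where | Why |
|---|---|---|---|
| `p_threshold` | 1e-4 | scanner | common scanner default; exposed as config |
| `pseudocount` | 0.1 (by background) | scanner | finite scores, standard practice |
| score grid | 1e-3 bits | scanner | exactness far below decision boundaries |
| `bin_length` | 5 Mb | HB profiles | genome-scale bins; 50 kb in the synthetic preset |
| `pearson_threshold` | 0.7 | HB network | strict "greater than" |
| `seed_fraction` | 0.10 | seeds | ceiling reproduces 18/16/15 on 177/158/148 |
| `gamma` | 0.7 | RWR | standard restart probability for PPI walks |
| `tol` | 1e-10 (L1) | RWR | convergence threshold; norm choice documented |
| `top_k` | 200 | induction | subnetwork size for complex mining |
| `density_threshold` | 0.7 | detection | dense-region cutoff |
| `attach_ratio` | 0.5 (weak) | detection | attachment at exactly half attaches |
| `redundancy_na` / matching threshold | 0.25 | detection / matching | duplicate and conserved-pair cutoff |
| relation weights | 0.8 / 0.6 | GO similarity | `is_a` stronger than `part_of`; config keys |

Degenerate inputs have defined behavior throughout: empty interval
files parse to empty sets, isolated network nodes get self-loops,
zero-variance HB profiles gain no edges, unannotated genes score 0,
`S(t,G) = 0` flags the gap undefined, and all-zero seed weights fall
back to uniform.

## Validation scale

The test suite validates solver components against independent oracles
at small sizes where exhaustive computation is feasible (assignments up
to n = 6 against all n! permutations, matchings up to 6×6 against all
matchings, hypergeometric tails up to a 12-protein universe against all
subsets, walks up to 50 nodes against the direct linear solve) and the
full pipeline on 20 strong-signal replicates at the preset scale above.
These sizes were chosen so the oracles remain exact and the whole suite
runs quickly; the components themselves have no size-specific code
paths.

## Known limitations

- The scanner supports only 0-order backgrounds and ungapped matrices.
- The naive conserved-cluster fallback is not a network aligner; real
  analyses should supply cluster files from a dedicated tool.
- Conserved matching is one-to-one; overlapping or multi-way complex
  correspondences are out of scope.
- GO similarity values depend on the relation-weight scheme; other
  similarity measures (e.g., information-content based) would give
  different absolute values, so cross-study comparison of similarity
  magnitudes is not meaningful.
- RWR relevance on the full graph leaves nodes disconnected from all
  seeds at exactly 0, which is intended but means rank ties among them
  are resolved purely lexicographically.
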