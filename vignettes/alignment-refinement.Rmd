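---
title: "Refining global PPI network alignments by local search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining global PPI network alignments by local search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapalign)
```

## The model

Two protein–protein interaction (PPI) networks are simple undirected graphs
$G_X = (X, E_X)$ and $G_Y = (Y, E_Y)$. A global alignment is a matching $M$
in the complete bipartite graph on $X \times Y$: an injective, possibly
partial, assignment of proteins of one species to proteins of the other.
Each cross-species pair carries a non-negative sequence-similarity score
$s(x, y)$ (BLAST bit scores in practice; the package treats scores as
non-negative reals since normalized scores are fractional). For a matched
pair $e = (x, y)$, its topology similarity under $M$ is

$$ t(e \mid M) \;=\; \bigl|\{ (x', y') \in M : (x, x') \in E_X,\ (y, y') \in E_Y \}\bigr|, $$

the number of interactions around $x$ that $M$ maps onto interactions
around $y$. The refiner maximizes the convex combination

$$ w(M) \;=\; \alpha \sum_{e \in M} t(e \mid M) \;+\; (1 - \alpha) \sum_{e \in M} s(e), \qquad \alpha \in [0, 1]. $$

Summing $t$ over matched pairs counts every conserved interaction exactly
twice, once from each endpoint, so $\sum_e t(e|M) = 2\,c(M)$ with $c(M)$
the conserved-edge count; this identity is asserted by a property test on a
thousand random instances. Maximizing $w$ exactly is NP-hard (it contains
subgraph isomorphism), which motivates local search.

Assumptions worth stating: the graphs are simple (self-loops in input files
are dropped, because $t$ and the edge-correctness metric are defined on
neighborhoods of distinct vertices, and the drop is counted); identifiers
are opaque case-sensitive strings, and no accession normalization is
attempted; partial mappings are legitimate throughout — unmatched endpoints
simply contribute nothing.

## The search procedure

Starting from any valid mapping $M_0$, the refiner repeatedly applies the
*first* strictly improving admissible move and stops when a full scan finds
none (a local optimum) or when an iteration cap is reached. Three move
kinds exist:

* **2-Opt**: pairs $(x, y), (x', y') \in M$ become $(x, y'), (x', y)$;
* **unmatched reassignment**: $(x, y)$ becomes $(x, y_{\text{new}})$ for an
  unmatched $y_{\text{new}}$;
* **3-Opt** (optional): three matched pairs have their $Y$-endpoints
  permuted; all five non-identity permutations are evaluated and the best
  taken.

A move is *admissible* only if an introduced partner lies in a candidate
list: $N_c(x)$ holds the $c$ highest-scoring partners of $x$ (ties broken
by identifier), and symmetrically $N_c(y)$. The candidate restriction is
what makes the scan affordable — the neighborhood size is $O(c\,|M|)$
rather than $O(|M|^2)$. For sequence-free settings (e.g. refining a
topology-only aligner with no score table), a `topology` candidate mode
ranks partners by degree agreement $-|\deg x - \deg y|$ (ties prefer the
higher $\min(\deg)$, then identifier). 3-Opt triples are enumerated as an
admissible 2-swap plus a third matched pair adjacent — in $G_X$, or in
$G_Y$ through the images — to one of the four touched vertices, with a cap
of $10\,|M|$ triples per scan; this neighborhood is the package's own
generalization of the pairwise move set, and the per-scan cap is part of
the neighborhood's definition.

Design choices that were genuinely open, and how they were settled:

* **First-improvement, not best-improvement.** The scan order is
  deterministic (matched pairs by identifier, candidates best-first), so
  results are exactly reproducible; first-improvement is the classic 2-Opt
  practice and avoids a full neighborhood evaluation per accepted move. A
  `seed` argument optionally shuffles the scan order for robustness
  studies — it affects nothing else.
* **Strictness tolerance.** A move must improve $w$ by more than
  `tol = 1e-9`. Ties are never accepted, which rules out floating-point
  livelock: $w$ increases by a bounded-away-from-zero amount per accepted
  move and is bounded above, so the loop provably terminates. The
  trajectory (`objective_trajectory`, one value per accepted move plus the
  start) is strictly increasing by construction and is checked as such.
* **Unmatched-target moves are on by default.** When one network has spare
  vertices, or the seed aligner leaves nodes unmapped, pure pair swaps
  cannot reach some improvements; the reassignment move fills that gap and
  can be disabled (`allow_unmatched = FALSE`).
* **Incremental deltas.** Move evaluation re-computes only the topology
  terms adjacent to the touched vertices; a dedicated test checks
  agreement with full recomputation to $10^{-12}$ over ten thousand random
  moves, and 3-Opt deltas are computed from a locally recounted
  conserved-edge total for the same reason.

## Seeding and the automatic α

The package's own seed is the maximum-weight bipartite matching on the
positive similarity scores, delegated to `igraph`'s matching backend.
Because several optimal matchings can exist, a deterministic tie-break
re-solves restricted problems to select the lexicographically smallest
optimal pair sequence; pairs with zero similarity are never matched by the
seeder (they add no weight, and unmatched nodes are acceptable).

Raw BLAST tables can be asymmetric, so scores are symmetrized by taking
the maximum of the two orientations; duplicate rows likewise keep the
maximum. Normalization divides by the global maximum, mapping scores onto
$(0, 1]$ — the simplest transform guaranteeing the unit range, and one
that provably preserves which matchings are optimal.

The topology weight defaults to an automatic rule: with $S_0$ the seed's
total sequence score and $T_0$ its total topology similarity,

$$ \alpha^\* = \frac{2 S_0}{2 S_0 + T_0}, $$

the unique value making the realized topology contribution
$\alpha^\* T_0$ exactly twice the realized sequence contribution
$(1-\alpha^\*) S_0$ — i.e. the refinement favors topology twice as much as
the seed did. The value is clamped to $[0.01, 0.99]$ so neither term is
ever switched off entirely by the automatic rule ($T_0 = 0$ would
otherwise give $\alpha^\* = 1$); when the seed carries no sequence score at
all, the sequence-free regime applies and $\alpha = 1$ is used outright.

## Quality metrics

**Edge correctness (EC)** is the conserved-edge count divided by
$\min(|E_X|, |E_Y|)$. Normalizing by the smaller edge set keeps the ratio
in $[0, 1]$ and comparable when network sizes differ by orders of
magnitude, which is the norm for public PPI data. It is 0 when either
network has no edges.

**Functional coherence (FC)** uses the Gene Ontology. A term's
*standardized set* is itself plus its transitive `is_a` ancestors at depth
1–5 from the namespace root (depth = shortest `is_a` hop distance; the
root itself is excluded; `part_of` and other relations are ignored, the
plain hierarchy being what the depth rule addresses). For an aligned pair,
every annotation pair $(g_x, g_y)$ with non-empty standardized sets
contributes the Jaccard overlap of those sets, and the pair's FC is the
*median* of these overlaps — the median has force exactly because the
cross product usually yields several values. The mapping's FC is the mean
over aligned pairs where it is defined; pairs lacking usable annotation
are excluded rather than scored zero, since in real data only roughly
60–70% of proteins carry GO annotations. Whether the depth window should
count the root as distance 0 or 1 is ambiguous in common usage; the
package fixes depth(root) = 0 and keeps depths 1–5.

## The synthetic generators

`geometric_random_graph(n, m, seed)` drops $n$ points uniformly in the
unit square (dimension configurable) and keeps the $m$ closest pairs —
equivalently, the disk graph at the smallest admitting radius, trimmed to
exactly $m$ edges by dropping the longest ties deterministically.
Geometric graphs are a standard, structurally realistic null model for PPI
topology, and the exact-count trimming makes the randomized network
size-matched to a real one, which EC comparisons require.

`planted_instance()` provides ground truth: network $Y$ is a relabeled
copy of an Erdős–Rényi (or geometric) network $X$ with a fraction
$\rho_e$ of edges rewired (equal numbers removed and added — false
negatives and false positives), and the score table gives each true pair a
score near $s_{\text{true}} = 1$ (±10%) except for a fraction $\rho_s$ of
proteins whose true score is deleted and replaced by three random decoys
up to $s_{\text{noise}} = 0.5$. The defaults used throughout the tests and
the acceptance script — $n = 100$, $p = 0.1$, $\rho_e = 0.2$,
$\rho_s = 0.3$, auto-tuned α, $c = 20$, 3-Opt, 20 seeds — emulate a
moderately noisy two-species comparison at desk scale: the edge-noise
level matches the often-quoted ~20% false-positive rate of two-hybrid
screens, and the score-scrambling fraction mirrors the share of proteins
whose homology signal is absent or misleading. What the generator does
*not* emulate: the heavy-tailed degree distributions, protein families and
paralogy structure, cross-database identifier mess, and the
million-edge scale of real PPI collections. Passing the recovery tests
therefore shows the machinery behaves as designed under controlled noise,
not that any particular biological alignment is correct.

The recovery property asserted in the tests is deliberately one-sided
where it must be: refined node correctness is required not to fall (and
refined EC to strictly rise) in at least 18 of 20 seeded runs. EC is *not*
asserted to increase as a theorem — the objective can trade conserved
edges against sequence score — so the tests assert what is provable
($w$ strictly increases) and record the metric deltas.

## Numerical and degenerate-input conventions

* Absent similarity pairs score 0; stored scores are strictly positive.
* An empty similarity store yields an empty seed matching; normalizing an
  empty store is an error (there is nothing to scale).
* `t` of a pair whose endpoints have no neighbors is 0, not undefined, so
  the objective's sum is total.
* Matching ties, candidate ties and move scans all break ties by
  identifier order; equal-objective moves are never accepted.
* Mappings referencing identifiers outside the networks are rejected;
  similarity rows referencing unknown identifiers are dropped with a
  warning (and counted), with orientation fixed by membership.
* The refiner's iteration cap (default 10000, far above the swap counts
  local optima need at these sizes) marks its result
  `terminated_by = "iteration_cap"` so a capped run is never mistaken for
  a certified local optimum; `is_local_optimum()` re-scans the full
  admissible neighborhood as an explicit post-hoc certificate.

## Problem sizes in the test suite

The oracle-backed tests run at sizes where exhaustive enumeration is
exact: instances with up to 6 proteins per side are compared against
brute-force optima over all matchings (200 instances), seed matchings
against a brute-force maximum-weight oracle (260 instances across suites),
and incremental deltas against full recomputation (10,000 moves). The
stochastic recovery protocol runs 20 seeds at $n = 100$. These sizes are
the package's chosen trade-off between coverage and a test suite that runs
in minutes; the refiner itself is routinely usable at tens of thousands of
candidate pairs since scan cost scales with $c\,|M|$ and vertex degrees,
though the dense similarity matrix used internally makes very large
$|X| \times |Y|$ products memory-hungry.

## Known limitations

* The 3-Opt neighborhood is a principled reconstruction (admissible
  2-swap × adjacent third pair, capped per scan); other 3-Opt
  formulations exist and may reach different local optima.
* Local search offers no approximation guarantee; the oracle tests report
  how often the global optimum is attained at toy sizes, but nothing
  follows for large instances.
* FC uses only `is_a` edges and unweighted Jaccard overlaps; semantic
  similarity measures (Resnik, Lin) are out of scope.
* No multi-network alignment, no $k$-Opt for $k \ge 4$, no restarts or
  annealing.

## A complete small run

```{r example}
net_x <- read_network(system.file("extdata", "toy-net-x.tsv", package = "swapalign"))
net_y <- read_network(system.file("extdata", "toy-net-y.tsv", package = "swapalign"))
sim <- read_similarity(system.file("extdata", "toy-sim.tsv", package = "swapalign"))
inst <- alignment_instance(net_x, net_y, sim)

m0 <- initial_matching(inst)
res <- refine_alignment(m0, inst, alpha = 0.5, c = 2)
summary(res)
c(initial = ec_ratio(m0, inst), refined = ec_ratio(res$mapping, inst))
plot(res)
```
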