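---
title: "Cosine-distance indices for link prediction: model, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosine-distance indices for link prediction: model, protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlink)
```

## The problem

Given an observed unweighted, undirected, simple network $G = (V, E)$ with
$n = |V|$ nodes and $m = |E|$ edges, link prediction asks which
currently-absent node pairs are most likely to be true (missing or future)
links. In a protein–protein interaction map this prioritizes candidate
interactions for experimental validation; in a power grid or a social
network it flags likely future connections. Similarity-based prediction
assigns every candidate pair $(v_i, v_j)$ a score $s_{ij}$ and ranks pairs
by it; the modelling question is what "similar" should mean.

Neighbor-counting scores (common neighbors and its normalizations) are
cheap but assign zero to every pair without shared neighbors — an
*underestimation* problem that is severe in sparse, low-clustering
networks. Pure distance scores collapse to few distinct values because
small-world distances concentrate on a handful of integers. The CD family
implemented here combines both sources of information.

## The CD model

**Distances and the threshold.** Let $d_{ij}$ be the shortest-path length
(hop count). For a positive integer threshold $k$, the $k$-distance matrix
$L$ keeps $l_{ij} = d_{ij}$ wherever $d_{ij} \le k$ and sets
$l_{ij} = \infty$ otherwise. With $k = d_{\max}$ (the diameter) $L$ is the
distance matrix itself; $k = d_{\max}$ is the default throughout.

**Coordinates.** The coordinate matrix $C$ inverts $L$ entrywise,

$$
c_{ij} = \begin{cases} 1/l_{ij}, & i \ne j\\ 1, & i = j, \end{cases}
$$

with $1/\infty := 0$. Row $C_i$ is read as the coordinate of $v_i$ in
$n$-dimensional space: nearby nodes contribute large entries, far nodes
small ones, unreachable nodes zero. The unit diagonal matters: it keeps
every row nonzero, and it keeps the $i$th and $j$th components of the two
vectors informative when comparing rows $i$ and $j$ (with a zero diagonal,
one of each pair of aligned entries is always zero and that information is
lost). For $k = 1$, $C = A + I$ exactly.

**CD.** The score of a pair is the cosine of the angle between their
coordinate vectors,

$$
s^{CD}_{ij} = \frac{C_i \cdot C_j}{\lVert C_i\rVert\,\lVert C_j\rVert}
  \in [0, 1].
$$

In a connected network every pair gets a strictly positive score, so CD
does not suffer the underestimation of neighbor counts; and two nodes get
*identical* scores against all third nodes only when they are structurally
equivalent (identical neighbor sets), so large ties are rare. Both
properties are enforced by tests (the structural-equivalence one at
absolute tolerance $10^{-12}$).

**LD, CD-LD, CD\*LD.** The local-community-density score generalizes the
idea of counting links among common neighbors: for a base index $s^*$,

$$
s^{LD}_{ij} = \sum_{\{p,q\} \subseteq \Gamma(i) \cap \Gamma(j)} s^*_{pq},
$$

summing the base similarity over unordered distinct pairs of common
neighbors. CD-LD instantiates $s^* = s^{CD}$, and CD\*LD is the
elementwise product $s^{CD}_{ij} \cdot s^{CD\text{-}LD}_{ij}$. Pairs with
fewer than two common neighbors score 0.

**CDI.** CD empirically favors assortative networks (high-degree nodes
linking to high-degree nodes), while preferential attachment (PA, the
degree product $k_i k_j$) favors disassortative ones. The degree-corrected
variant multiplies the two:

$$
s^{CDI}_{ij} = \frac{C_i \cdot C_j}{\lVert C_i\rVert\,\lVert C_j\rVert}
  \times (k_i \times k_j),
$$

with degrees taken from the training graph, the only graph available at
scoring time.

```{r}
g <- make_ba(60, 2, seed = 3)
similarity_scores(g, "CD-LD")
```

## The shortest-path routine

`shortest_path_matrix()` computes all-pairs distances by per-source
frontier expansion: initialize the source row from the adjacency
structure, and repeatedly (i) locate the nodes at distance $k$, (ii) take
the union of their neighbors, (iii) stamp those not yet assigned a
distance with $k + 1$, until the frontier is empty. This is breadth-first
search expressed on matrix rows; per source it costs $O(n + m)$, so
$O(n(n+m))$ overall. The union in step (ii) is essential — an intersection
of the frontier's neighbor sets would not visit the next shell — and the
implementation is pinned to an independent Floyd–Warshall oracle,
entrywise including the placement of $\infty$ on disconnected graphs, on
all fixtures with $n \le 40$.

## Evaluation protocol

`evaluate_index()` repeats, for a configurable number of iterations
(default 100, the size also used in the end-to-end suite):

1. **Split.** A uniform random 90/10 partition of $E$ into training set
   $E^T$ and probe set $E^P$, with $|E^P| = \mathrm{round}(0.1\,m)$
   (round-half-up, minimum 1). No re-sampling if the training graph
   disconnects: coordinates of separated pairs are simply 0, by the
   $1/\infty$ convention. All vertices are kept.
2. **Score.** The index is recomputed on the training graph alone. For
   CD-family indices at `k = "diameter"`, the diameter is re-resolved on
   each training graph, since probe removal can change it.
3. **Rank.** Candidates are all unordered non-training pairs (probe edges
   are among them by construction). Ties are broken uniformly at random
   under a per-iteration seed. This matters: CD-LD and the
   common-neighbor family put most pairs at exactly 0, and any fixed tie
   order (say, by node index) would bias precision either way.
4. **Precision.** With $L = |E^P|$ and $l$ probe edges among the top-$L$
   candidates, $\mathrm{Precision} = l / L$.

The random predictor (`"RANDOM"`, i.i.d. uniform scores) calibrates the
scale: its expected precision is $|E^P| / |\text{candidates}|$, and the
test suite verifies this within three standard errors over 2000 seeded
splits of a 30-node benchmark graph. Relative precision (a method's mean
precision divided by RANDOM's on the same network) is provided for
cross-network comparison, and `aggregate_by_group()` averages such values
over groups of networks, e.g. by assortativity sign.

AUC is deliberately not implemented: ranking quality at the top of the
candidate list is what matters for prioritizing experiments, and AUC can
look good while the top of the ranking is poor.

```{r}
ev <- evaluate_index(g, "CN", iterations = 20, seed = 42)
glance(ev)
```

## Baseline roster

Fourteen classical indices are included for comparison, computed from the
training adjacency matrix $A$, degrees $k_i$, and common-neighbor sets
$\Gamma(i) \cap \Gamma(j)$: CN, Salton, Sørensen, LHN, PA, RA, the local
path indices LP3 $= [A^2 + \varepsilon A^3]_{ij}$ and LP4
$= [A^2 + \varepsilon A^3 + \varepsilon^2 A^4]_{ij}$ with
$\varepsilon = 0.01$, the local random walk LRW with $t = 3$ steps, and
the local-community family CAR, CPA, CAA, CRA, CJC. Conventions the
sources leave open are fixed as follows and locked by brute-force oracle
tests on all fixtures with $n \le 12$:

* LRW starts from a point mass at the source, uses the row-normalized
  adjacency matrix as transition kernel, and weights by
  $q_i = k_i / 2m$: $s_{ij} = q_i \pi_{ij}(t) + q_j \pi_{ji}(t)$.
* CPA uses external degrees $e_x = k_x - |\Gamma(i)\cap\Gamma(j)| -
  a_{ij}$ and $s = e_i e_j + e_i\,\mathrm{CAR} + e_j\,\mathrm{CAR} +
  \mathrm{CAR}^2$.
* CAA uses $\log_2$; any fixed base only rescales scores and leaves
  rankings unchanged.
* Ratio indices (Salton, Sørensen, LHN, CJC) return 0 when their
  denominator is 0 (isolated endpoints).

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `k` | CD family | `"diameter"` | distance cutoff defining coordinates; integers 2–6 give the localized CD-k / CD-LD-k / CD\*LD-k variants; values above the diameter are clamped (equivalent by construction) |
| `eps` | LP3/LP4 | 0.01 | damping of longer paths |
| `lrw_steps` | LRW | 3 | random-walk length (hops) |
| `fraction` | evaluation | 0.1 | probe proportion of edges |
| `iterations` | evaluation | 100 | number of random splits averaged |
| `include_self` | LD | `FALSE` | whether the degenerate $p = q$ terms enter the LD sum (see below) |

## Design choices that were genuinely open

* **LD pair convention.** The LD sum over $p, q \in \Gamma(i)\cap\Gamma(j)$
  is read as unordered *distinct* pairs, mirroring the idea of density
  *among* common neighbors. Including $p = q$ would add the base index's
  self-similarity once per common neighbor (for CD, exactly
  $|\Gamma(i)\cap\Gamma(j)|$, drifting LD toward plain CN); that variant
  remains available via `include_self = TRUE` but is not the default.
* **No adjacency restriction in LD.** Unlike the CAR family's LCL, the LD
  sum runs over all common-neighbor pairs whether or not they are linked;
  the base index already grades each pair.
* **Unreachable pairs.** CD is defined on connected networks, but probe
  removal can disconnect a training graph. Coordinates extend by
  continuity, $c_{ij} = 0$ as $l_{ij} \to \infty$; rows stay nonzero
  through the unit diagonal, so the cosine never divides by zero and no
  split is discarded.
* **Tie-breaking.** Uniformly random within tied scores, per-iteration
  seed; see the protocol above.
* **Probe size rounding.** Round-half-up of `fraction * m`, minimum 1.

## Numerical choices

* $\infty$ is represented by R's `Inf`, which orders above every finite
  distance and inverts to 0 exactly; it never overflows into arithmetic.
* Cosines are clipped to $[0, 1]$ to absorb floating-point excursions of
  order machine epsilon; equality assertions in the test suite use
  absolute tolerance $10^{-12}$ (scores) or $10^{-9}$–$10^{-10}$ (sums of
  scores against enumeration oracles).
* Score matrices are computed eagerly for all pairs via dense linear
  algebra ($C\,C$ for all cosines at once); the per-pair accessor
  `cd_score()` is value-identical and used for spot checks.
* The random streams for splitting, random scores, and tie-breaking are
  seeded at fixed offsets (`+250000`, `+500000`) from the per-iteration
  split seed, so an evaluation is bitwise reproducible from one base seed
  while the three draws stay decoupled.

## What the generators emulate — and what they do not

`make_ba()` grows a preferential-attachment graph from `m_attach`
initially edgeless seed nodes (the first arrival links to all of them), so
the edge count is exactly `m_attach * (n - m_attach)` and the graph is
connected — the degree-heterogeneous, mildly disassortative regime where
degree-driven indices do well. `make_er()` and `make_ws()` supply the
low-heterogeneity and high-clustering regimes, and `make_struct_equiv()`
plants an exact structural-equivalence twin for the CD tie property.
Deterministic toys (paths, cycles, stars, cliques) carry the
hand-computable cases.

Synthetic graphs at these sizes (up to a few hundred nodes; oracle suites
at $n \le 40$; the end-to-end comparison on a 200-node
preferential-attachment graph over 100 splits) validate *correctness* of
the formulas and *ordering* properties — an informative index beats the
random predictor; thresholds behave monotonically. They do not reproduce
the precision levels of real benchmark networks, which have clustering,
community structure, and assortativity profiles no single generator
matches; published per-network precision values are therefore not
regression targets here.

## Limitations

* Unweighted, undirected, simple graphs only; weighted, directed,
  bipartite, and temporal networks are out of scope.
* The LD family costs $O(n^3)$ in the worst case; at the sizes this
  package targets (up to a few thousand nodes) that is acceptable, but
  the dense matrices make memory the binding constraint well before time.
* The local-blocking (LB) index is not in the baseline roster; its
  definition lives in a source this package does not follow.
* Only precision@L is offered as an accuracy metric, by design.
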