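---
title: "Methods: gravity-model association networks and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gravity-model association networks and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravnet)
```

This vignette is the package's own account of the methods it implements:
the model behind each stage, the conventions and tunable parameters, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## 1. The gravity construction

### Model

The association intensity from region $i$ to region $j$ is

$$y_{ij} = k_{ij}\,
  \frac{\sqrt[4]{G_i P_i T_i C_i}\;\sqrt[4]{G_j P_j T_j C_j}}{D_{ij}^2},
  \qquad k_{ij} = \frac{C_i}{C_i + C_j},$$

with $P$ population (persons), $G$ gross regional product (constant-price
currency), $T$ technology level (patent grants), $C$ pollutant
concentration (e.g. µg/m³ of PM2.5) and $D_{ij}$ inter-capital distance
(km). The mass term is the geometric-mean style fourth root of the IPAT
product — impact = population × affluence × technology — augmented by the
pollutant level itself; the share weight $k_{ij}$ makes the matrix
directed, with $k_{ij} + k_{ji} = 1$ exactly. Two consequences worth
knowing: $y$ is homogeneous of degree 2 in a common rescaling of all four
attributes (each endpoint's mass scales linearly), and halving all
distances quadruples every intensity.

All four attributes must be strictly positive: a zero concentration makes
$k$ undefined and a zero mass would silently disconnect a region, so both
are rejected as errors rather than patched.

### Binarization

Each row $i$ of the intensity matrix is cut at its own critical value, the
mean of its off-diagonal entries; $a_{ij} = 1$ iff $y_{ij}$ strictly
exceeds it. Choices made here, both configurable:

* **Diagonal excluded from the row mean.** The diagonal is a structural
  zero; including it would deflate every threshold by a factor
  $(n-1)/n$ and mechanically densify the network.
* **Strict inequality.** A row whose off-diagonal entries are all equal
  produces no arcs (nothing is *above* the critical value). The `>=`
  variant is available for sensitivity analysis.

Because the threshold is a per-row mean, the binarized network is
invariant to any per-row rescaling of the intensities — in particular to
the degree-2 attribute homogeneity above.

## 2. Whole-network indices

The four overall measures follow the Krackhardt tradition as
operationalized in standard SNA software; the package states its exact
definitions because the vocabulary varies across packages:

* **Density**: arcs / $n(n-1)$.
* **Connectedness** (association degree): the fraction of unordered node
  pairs joined by a path in the underlying undirected graph; 1 iff that
  graph is connected.
* **Hierarchy** (rank degree): among unordered pairs reachable in at
  least one direction of the digraph, the fraction *not* mutually
  reachable; 0 for strongly connected networks and for edgeless ones
  (no reachable pair — defined as 0 rather than 0/0).
* **Efficiency**: with $L$ undirected edges and components of sizes
  $n_c$, the redundancy is $L - \sum_c (n_c - 1)$ and its maximum is
  $\sum_c \binom{n_c}{2} - (n_c - 1)$; efficiency is 1 minus their ratio
  (1 when no redundancy is possible). High efficiency = sparse, fragile
  linkage.

Hierarchy has several variants in the literature; the one above (mutual
vs one-way reachability) matches the prose meaning of "how asymmetrically
accessible nodes are to each other" and is validated against a
brute-force reachability oracle, not against any external program.

## 3. Centrality conventions

Three node-level measures, all reported as percentages:

* **Degree.** The default `"neighbor"` convention counts *distinct*
  neighbours in the symmetrized graph over $n-1$: a reciprocated dyad
  counts once. The textbook alternative
  $100\,(\mathrm{In}_i + \mathrm{Out}_i)/(2(n-1))$ is exposed as
  `"eq2"`. The two coincide exactly when no dyad is reciprocated. The
  packaged reference table follows the neighbour convention (its degree
  column equals unique-neighbour counts over 30, not the in/out
  average), which is why it is the default.
* **Betweenness.** Freeman shortest-path betweenness,
  $100 \cdot \sum_{j<k} g_{jk}(i)/g_{jk} \,/\, \binom{n-1}{2}$,
  disconnected pairs contributing zero; computed on the symmetrized
  graph by default since the $2/((n-1)(n-2))$ normalization is the
  undirected one. A directed option normalizes over ordered pairs.
* **Closeness.** Reciprocal farness, $100\,(n-1)/\sum_j d_{ij}$. The
  average-farness form (its reciprocal) appears in some write-ups; the
  reciprocal form is what reference values like 90.909 ( $=100 \cdot
  30/33$ ) correspond to, so it is what the package computes. On a
  disconnected graph each node is scored within its own component (with
  $n$ replaced by the component size) and the vector carries a
  `disconnected` attribute; `strict = TRUE` scores such nodes 0
  instead. Isolates score 0 in either mode.

The graph kernels (shortest paths, components, betweenness) are igraph's;
every convention layered on top is validated against exhaustive-path
brute-force oracles on all sampled digraphs with $n \le 6$.

## 4. CONCOR blockmodel

Each node's profile is the concatenation of its adjacency row and column
(ties sent and received; row-only and column-only profiles are options).
The node-by-node Pearson correlation matrix is correlated with itself
repeatedly until every off-diagonal entry is within `conv_tol` of $\pm 1$
or `max_iter` (default 25) is reached; nodes are then split by the sign
of their correlation with the first node, and the procedure recurses on
each group (profiles restricted to the group's members, over all $n$
columns) to the requested depth. Defaults `depth = 2`, `conv_tol = 0.2`
mirror the two knobs conventional blockmodeling software exposes
("segmentation depth" and "concentration criterion").

Degenerate cases are handled deterministically: groups of size ≤ 2 are
never split; a node with a constant profile (an isolate) gets correlation
0 with a warning — never an exception — and joins the group its mean
correlation favours; a split that fails to polarize leaves the group
whole, so `n_blocks` can be below $2^{\mathrm{depth}}$.

### Block accounting and roles

Arc flows are cross-tabulated by (source block, target block). For block
$k$ of size $n_k$: the *expected* internal ratio is
$100\,(n_k-1)/(n-1)$ — the share of a member's possible ties that stay
inside under uniform mixing — and the *actual* internal ratio is
$100\cdot\text{inside}/(\text{inside}+\text{outside sent})$. The
size-weighted average of the block density matrix equals the overall
density exactly (tested to machine precision), and the image matrix cuts
block densities at the overall density (`>=` by default; the strict
variant is available, and the two differ only when a block density equals
the threshold exactly).

The four spillover roles are defined qualitatively in the blockmodeling
literature (net receivers; net senders; heavy internal exchangers; pass-
through mediators). The package operationalizes them through the
receive/send ratio $\rho_k$ = total received / total sent with cut-points
2, 1 and 0.25: $\rho \ge 2$ net benefit, $1 \le \rho < 2$ two-way
spillover, $0.25 \le \rho < 1$ broker, $\rho < 0.25$ net spillover.
These cut-points are a calibrated, configurable operationalization — they
reproduce the four role assignments of the packaged reference study from
its printed flow counts — not a canonical definition. A block that sends
nothing has undefined $\rho$ and is flagged unclassifiable.

The packaged reference tables are internally consistent in every
derivable respect but two, documented here so users are not surprised by
the verification harness: the off-diagonal cells of the reference block
density matrix imply two fewer external arcs than the flow table prints
(a rounding/transcription artifact of the source; the diagonal cells and
all row/column sums otherwise agree exactly), and the reference's
expected-internal-ratio column mixes $(n_k-1)/(n-1)$ with $n_k/(n-1)$
across rows — the package computes the former uniformly.

## 5. QAP and MRQAP

Dyadic observations violate the independence assumptions of classical
tests: permuting individual cells would destroy the row/column dependence
that defines a network. The quadratic assignment procedure therefore
permutes *node labels* — one random relabelling applied to rows and
columns simultaneously — so every permuted matrix preserves the dyadic
dependence structure.

* **QAP correlation**: Pearson $r$ of the two off-diagonal
  vectorizations; the permutation distribution relabels the second
  matrix. Reported: $r$, both tail probabilities $p_{\ge}$ and
  $p_{\le}$, their minimum as `sig`, and the permutation distribution's
  mean/sd/min/max.
* **MRQAP**: OLS with intercept of the response's off-diagonal vector on
  the covariates', with Y-permutation — the classic approach of
  relabelling the response and refitting everything each draw. The
  double-semi-partialling refinement is a known alternative and is
  deliberately out of scope. Standardized coefficients are
  $b_k\,\mathrm{sd}(x_k)/\mathrm{sd}(y)$; adjusted $R^2$ uses the dyad
  count $m = n(n-1)$. Per-coefficient `sig` is the tail on the observed
  sign's side.

Numerical choices: permuted off-diagonals are gathered by linear
indexing and all permutation refits reuse one QR decomposition of the
design (the design never changes under Y-permutation), which keeps
10,000-permutation runs fast and avoids forming the ill-conditioned
normal equations; rank deficiency in the design is reported as an error
naming the offending covariates. Ties between a permuted statistic and
the observed one count in *both* tails, a deliberately conservative
choice.

One statistical subtlety is documented rather than hidden: `sig`, the
smaller of the two tails, is the conventional report format but is a
two-sided quantity — under a true null, `sig` $\le \alpha$ occurs with
probability close to $2\alpha$. The calibration checks in the test suite
and acceptance script therefore target the well-defined one-sided tail
($p_{\ge} \le 0.05$ rejecting at ~5%), which the suite verifies to lie
within binomial 3σ of nominal over 500 null replicates of 2000
permutations at $n = 20$. Power against a planted dyadic effect
($\beta = 2$, noise sd 0.5, $n = 25$) exceeds 90% over 100 replicates at
the same settings. These problem sizes were chosen to estimate the rates
to ~1 percentage point while keeping a full validation run around a
minute.

## 6. The synthetic-data generator

`generate_panel()` emulates the *statistical shape* of a province-level
panel — 31 regions × 12 years by default, matching the scale of the
packaged reference study. Attributes are log-normal (positive,
right-skewed, like regional GDP, population and patent counts), with a
region-level common factor inducing both cross-attribute correlation
(default ρ = 0.5 — rich regions are populous, patent-heavy and more
polluted) and persistence across years, plus a mild common yearly drift
(2% on the log scale). Location/scale defaults give magnitudes a
practitioner would recognise: populations of order 10⁷, concentrations of
a few tens of µg/m³. Coordinates are uniform on a 2000 km square, so
Euclidean distances span the few-hundred-to-~2800 km range of real
inter-capital distances without encoding any actual geography.

What it deliberately does **not** emulate: spatial autocorrelation of
attributes (neighbouring regions are not more similar), the true temporal
dynamics of pollution (policy shocks, trends reversing), real covariate
definitions, or any actual map. Passing tests on synthetic data therefore
validate the *mechanics* of every stage — not any empirical claim about
real pollution networks. The planted-structure generators are the
exception where recovery *is* the claim: `generate_block_network()`
plants a partition that CONCOR must recover (≥ 95% over 100 replicates at
$p_{in} = 0.8$, $p_{out} = 0.1$, blocks of 8), and
`generate_dyadic_design()` plants regression coefficients MRQAP must
detect.

QAP covariates can be aggregated as period means (the pipeline default)
or taken per year; the choice matters for interpretation but not for the
mechanics, and both shapes are supported.

## 7. Known limitations

* CONCOR's sign-split is a heuristic; it carries no optimality guarantee
  and can differ from structural-equivalence optimization on ambiguous
  networks. Alternative blockmodel criteria are out of scope.
* The role cut-points (2, 1, 0.25) are calibrated, not derived; users
  with different flow regimes should set their own.
* MRQAP uses Y-permutation only; with strongly collinear covariates,
  double-semi-partialling would give better-calibrated per-coefficient
  tests.
* The pipeline builds one network per year from that year's attributes
  and lets the final year drive the blockmodel and QAP stages; pooling
  years into a single network is possible by pre-aggregating the panel
  but is not a built-in mode.
* No geographic rendering, and no logit-type QAP for binary responses —
  the OLS linear-probability form is what the permutation test is built
  around.
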