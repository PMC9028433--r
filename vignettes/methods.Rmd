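---
title: "Prioritizing minimal drug combinations from disease networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing minimal drug combinations from disease networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugcombinet)
```

## The problem

Single-agent therapies for complex diseases are limited by toxicity and
resistance; combination therapy looks for *small* sets of drugs whose joint
action covers the disease mechanism from complementary angles.
`drugcombinet` implements an integrated network-pharmacology pipeline that,
starting from paired disease/control expression data, prior-knowledge
association layers and a drug library (targets, SMILES strings,
perturbational replicate profiles), ranks candidate drug combinations by
five simultaneous criteria: mutually dissimilar mechanisms of action,
dissimilar chemical structures, dispersed targets, high network coverage,
and minimal size.

This vignette documents the statistical models, the algorithmic choices and
their assumptions, the tunable parameters, and what the synthetic
validation study does and does not demonstrate.

## Candidate-gene scoring

Two nonparametric paired tests are run per gene on `log2(v + 1)` expression
(the pseudocount guards against zeros in FPKM-like inputs):

* a **paired Wilcoxon signed-rank test** on per-subject disease − control
  differences (exact null distribution up to 25 informative pairs without
  ties, normal approximation with continuity correction otherwise);
* a **variance F-test**, `F = s²_disease / s²_control`, with the two-sided
  p-value `2·min(P(F ≤ f), P(F ≥ f))`.

Neither p-value filters genes directly.  Each is combined with the log2
fold change into a **significance score**

$$SS^t_i = \left|\mathrm{logFC}_i \cdot (-\log_{10} p^t_i)\right|,$$

computed separately for each test *t*.  Both score lists are ranked
descending (ties broken lexicographically by gene id for bitwise
reproducibility) and the union of the two top-10% lists becomes the
candidate set, so between `⌊0.1·G⌋` and `2·⌊0.1·G⌋` genes survive.

Notes on this formula:

* The log base is not material for ranking (any base preserves order);
  log10 is used because it is conventional for p-values.
* The F-test branch multiplies by the *expression* fold change, not a
  variance-based effect size.  A gene whose variance changes while its mean
  does not therefore scores near zero.  This is a real property of the
  score as defined; the synthetic generator accounts for it (below).

## Consensus co-expression inference

A single inference algorithm on noisy expression data is fragile; the
pipeline therefore runs an ensemble over all combinations of three
inference algorithms — **CLR** (z-scores against row/column background),
**ARACNE** (data-processing-inequality pruning of the strictly weakest edge
in every triangle, tolerance `eps = 0`), and **MRNET**
(max-relevance-min-redundancy forward selection; predictors whose score
drops to zero stay unselected) — with three association estimators
(absolute Pearson, absolute Spearman, empirical mutual information) and,
for mutual information, two discretizers (equal-frequency and equal-width,
`⌊√n⌋` bins by default).  That yields 12 member networks, each min-max
rescaled to `[0, 1]`.

The **consensus** rank-normalizes each member's edge weights to `[0, 1]`
(average ranks over all unordered pairs) and takes the element-wise median,
keeping the strongest `2·N` edges (configurable; ties at the cutoff break
by gene-pair order).  The median of rank-normalized weights is robust to a
minority of discordant members; its flip side is that edges supported by
fewer than half the members are indistinguishable from noise — a property
to keep in mind when interpreting consensus networks of block-correlated
data, where ARACNE and MRNET intentionally thin out redundant
within-module edges.

**Hub ranking.** Nodes are ranked by six lists — weighted degree, mean
shortest-path distance to reachable nodes (ascending), betweenness,
closeness, eigenvector centrality, and the significance score — and
aggregated by mean-rank **Borda**: the consensus score of a node is the
mean of its per-list (average-tie) ranks; the final order is ascending by
that mean with lexicographic tie-breaks.  Path-based centralities use the
distance transform `d = 1 − w + 10⁻⁶`, so strong co-expression means short
distance; centralities are computed within connected components, and
isolated nodes get worst values.

## The multilayer prior

Prior-knowledge layers are tagged **Interaction**, **Regulation** or
**Functional**.  Gene–term (bipartite) layers are projected onto genes by
shared membership — two genes connect iff they share at least one term —
and gene–gene layers pass through symmetrized (a common-neighbor
projection is available as an option).  Layers within a category are
merged by edge-set **union**; the three category networks are then
**intersected**, so a prior edge needs support from all three evidence
classes.  The disease co-expression network keeps only edges present in
this prior; weights are untouched and isolated nodes are retained so the
node universe is stable for ranking.  A warning fires when under 1% of
co-expression edges find support, the typical symptom of an identifier
namespace mismatch.

## Drug feature tables

For every drug with more than five perturbational replicates, a
mechanism-of-action (MOA) network is inferred over the landmark gene panel
with the same consensus ensemble.  Four tables feed the optimizer:

* **HIM**: the Hamming–Ipsen–Mikhailov distance between MOA networks.  The
  Hamming term is the mean absolute adjacency difference over unordered
  pairs; the Ipsen–Mikhailov term is the L2 distance between Laplacian
  spectral densities $\rho(\omega) = K \sum_i
  \gamma/((\omega-\omega_i)^2+\gamma^2)$ with $\omega_i = \sqrt{\lambda_i}$
  (one zero mode dropped), $K$ normalizing unit mass on $[0,\infty)$, and
  $\gamma$ calibrated per node count so that IM(empty, complete) = 1.
  $\mathrm{HIM} = \sqrt{H^2 + IM^2}/\sqrt{2} \in [0,1]$.  Integration uses
  a fixed trapezoid grid (4,000 points, upper limit
  $\max\omega + 30\gamma$), which agrees with adaptive quadrature to about
  10⁻⁶ and keeps all-vs-all comparisons cheap because densities are
  evaluated once per network on a shared grid.
* **Levenshtein** edit distance between raw SMILES strings (no
  canonicalization, matching how the strings are retrieved; a
  canonicalization hook is intentionally out of scope).
* **Target dispersion**: mean unweighted shortest-path length between the
  two drugs' target sets on the filtered disease network.  Cross-component
  pairs contribute a penalty of `|V|` — finite, yet larger than any
  realizable path — so disconnected targets dominate without producing
  infinities.
* **Effect score**: `ES = N_t / M_R`, the number of network-mapped targets
  over their median Borda rank (even counts average the middle two).
  Many central targets give a large score.

## Five-objective optimization

A combination is a bit vector over the drug universe.  For `|x| = n ≥ 2`
(all objectives maximized):

$$\mathrm{MOA}_x = \tfrac1n \sum_{\{i,j\} \subset x} \mathrm{HIM}(d_i,d_j),
\quad \mathrm{SMILES}_x = \tfrac1n \sum \mathrm{L}(d_i,d_j),
\quad \mathrm{TARGETS}_x = \tfrac1n \sum \mathrm{SP}(d_i,d_j),$$
$$\mathrm{COVERAGE}_x = \tfrac1n \sum_{d \in x} ES_d, \qquad -\mathrm{SIZE}_x = -n.$$

Pairwise criteria are normalized by the combination *size*, not the pair
count; per-pair averaging is available through `ga_config(pair_norm =
"pairs")`.  Coverage aggregation uses the mean (a sum would reward
cardinality and duplicate the size axis; `coverage = "sum"` is available).
Combinations with fewer than two drugs receive a worst-case sentinel
vector that any valid combination dominates, letting selection purge them
without biasing the variation operators.

The genetic algorithm follows NSGA-II: a population of 100 chromosomes,
bits initialized Bernoulli(0.30); each generation creates 20 offspring,
each by one-point crossover of two random parents (probability 0.70,
first child kept) or by bit-swap mutation of one random parent
(probability 0.30; each position fires with probability 0.10 and swaps
with a uniformly chosen other position, conserving the popcount).  Parents
are drawn uniformly (the source procedure says "randomly selected"; no
tournament).  The 120-member union is reduced to 100 by fast
non-dominated sorting with crowding-distance truncation of the split
front; all tie-breaks are index-based, so a run is a pure function of its
seed.

**Hall of Fame.** An internal Pareto archive is updated incrementally every
iteration with the evaluated offspring; the HoF is its 10-member view
truncated by descending crowding distance.  The archive is deliberately
unbounded: truncating the archive itself could discard a non-dominated
solution that later dominates an entrant, which would violate the
guarantee that no evaluated individual dominates a HoF member.  Archive
updates compare only newcomers against members, so cost stays linear in
archive size per generation.

The default budget is 2,000 generations.  On study-scale inputs the
exploratory phase of the traces flattens by roughly the first half of the
run, after which generations refine trade-offs along the front.

**Stability.** `stability_analysis()` repeats the optimization (10 runs by
default) with distinct seeds, aggregates all HoF solutions into a
combination-frequency network (edge weight = number of HoF solutions
containing both drugs) and reports pairwise Jaccard agreement of the runs'
drug-pair sets.

## The synthetic study

Real inputs of this kind — tumor/normal cohorts, perturbational profile
compendia, curated drug–target links — cannot ship with a package, so the
generator builds inputs with the statistical structure the pipeline
assumes, plus planted ground truth:

* **Expression** (`simulate_disease_expression()`): 300 genes × 20 matched
  pairs by default, log-normal with per-subject random effects (the
  pairing), 10 equally sized modules with within-module correlation 0.6.
  Differential-mean genes (10%) receive a ±1.5 log2 shift; 1.5 is a strong
  but unexceptional fold change (≈2.8×) for disease cohorts.
  Differential-variance genes (10%) get their disease residual variance
  inflated ×4 *plus a half-size mean shift* — necessary because the
  significance score multiplies by logFC, so a pure variance change is
  invisible to it by construction.
* **Prior layers** (`simulate_prior_layers()`): 3 layers per category (9
  sources total); every truth edge (within-module pair) is planted in at
  least one layer per category, so the triple intersection recovers the
  truth exactly at zero noise, while spurious edges must be drawn
  independently in all three categories (≈ noise³) to survive.
* **Drug library** (`simulate_drug_library()`): 20 drugs over a 100-gene
  landmark panel in 10 modules; every drug perturbs five modules in its
  replicate profiles (8 replicates, all passing the >5 filter).  The two
  *planted* drugs perturb complementary halves of the panel, carry SMILES
  from disjoint token alphabets with very different lengths, and target
  the most central genes (up to 8) of the two largest network components;
  the redundant drugs target 3 genes from the worst-ranked half of a
  single component.  The planted pair is therefore the unique maximizer of
  mean effect score among all combinations, attains the maximal SMILES
  distance and the maximal (cross-component) target dispersion, and has a
  clearly positive MOA distance.  Being a boundary point of the coverage
  objective, it holds an infinite crowding distance and can never be
  truncated out of the Hall of Fame once found.

One honest caveat: the planted pair's HIM is high but not provably the
global maximum.  On block-correlated profiles, ARACNE's DPI and MRNET's
redundancy penalty legitimately thin redundant within-module edges, so the
median consensus retains only partially overlapping edge sets and spectral
fluctuations rival the Hamming margin between "disjoint modules" and
"one shared module".  Recovery of the planted pair rests on the coverage
guarantee above, which is exact, rather than on HIM dominance.

What passing the synthetic suite shows: the statistics, graph algorithms
and optimizer do what their definitions say, at study scale, end to end.
What it does not show: performance on real cohorts — real expression has
batch effects, unequal library sizes, non-modular correlation and missing
annotations; real SMILES carry chemical grammar the generator does not
attempt; L1000-style profiles have moderated-signal structure the
log-normal factor model does not emulate.

## Numerical and implementation choices

* All rank ties break lexicographically by identifier, selection ties by
  index; identical inputs and seed give bitwise-identical outputs.  The
  pipeline seeds the RNG once up front — eigenvector centrality uses
  ARPACK, which consumes random numbers, so an unseeded run would not be
  exactly reproducible.
* p-values are kept strictly positive (`p = 1` for degenerate tests, the
  smallest positive double when exactly one group has zero variance) so
  log-scores stay finite; zero-variance genes in association matrices are
  zeroed with a warning.
* The Ipsen–Mikhailov width calibration solves IM(empty, complete) = 1 by
  root bracketing on `[0.01, 10]` to 10⁻¹⁰ and caches the result per node
  count.
* Problem sizes in the shipped validation study (300 genes, 20 pairs, 20
  drugs, 100 landmark genes, 500-generation stability runs) were chosen so
  the full suite re-runs in a few minutes on a laptop-class single core
  while keeping every statistical check well-powered.

## Known limitations

* Gene identifiers must share one namespace across expression, layers and
  drug targets; no mapping is attempted (only the <1% support warning).
* The MOA comparison is between consensus networks, not raw profiles; two
  drugs with identical targets but opposite signs of regulation can look
  similar, because absolute association discards sign.
* Levenshtein distance on SMILES is a crude structural proxy — it is the
  intended design here, not a recommendation against fingerprints.
* The F-branch significance score cannot rank pure variance changes, as
  discussed above.
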