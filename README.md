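# drugcombinet

Network-pharmacology prioritization of minimal drug combinations.

Most computational drug-repositioning methods match a drug's expression
signature against a disease signature and stop there, ignoring what the
drugs themselves are: molecules with a mechanism of action, a chemical
structure, and a particular footprint on the disease network.
`drugcombinet` implements an integrated pipeline that folds those intrinsic
drug properties into the search for *small* combinations of drugs acting on
complementary parts of a disease. It is aimed at computational biologists
with paired case/control expression data, a curated set of gene–gene
association sources, and a drug library annotated with targets, SMILES
strings and replicate perturbational profiles.

## The method in brief

1. **Candidate genes.** Per gene, a paired Wilcoxon signed-rank test on
   disease − control differences and a variance F-test, each combined with
   the fold change into a significance score
   `SS_i^t = |logFC_i · (−log₁₀ p_i^t)|`. The union of the top 10% of both
   score rankings is kept.
2. **Disease network.** A consensus co-expression network from an ensemble
   of CLR, ARACNE and MRNET over Pearson/Spearman/mutual-information
   association estimates (median of rank-normalized weights, top `2N`
   edges kept), filtered by a three-category prior (Interaction ∪-merge,
   Regulation ∪-merge, Functional ∪-merge, then ∩ across categories).
3. **Hub genes.** Borda (mean-rank) aggregation of degree, mean shortest
   path, betweenness, closeness, eigenvector centrality and SS.
4. **Drug features.** Pairwise Hamming–Ipsen–Mikhailov distances between
   mechanism-of-action networks inferred from replicate profiles;
   Levenshtein distances between SMILES; mean shortest-path dispersion of
   target sets; per-drug effect score `ES = N_t / M_R` (targets over their
   median hub rank).
5. **Optimization.** A five-objective genetic algorithm (NSGA-II
   selection; population 100, 20 offspring/generation, 70% one-point
   crossover / 30% bit-swap mutation, 30% bit initialization, Hall of Fame
   of 10) maximizing
   `(MOA_x, SMILES_x, TARGETS_x, COVERAGE_x, −SIZE_x)`,
   the pairwise terms averaged over the combination size. Repeated seeded
   runs yield a combination-frequency network and stability statistics.

Everything runs from a single seed and reproduces bitwise.

## Worked example

The package ships a synthetic-study generator that emulates the pipeline's
intended inputs (paired tumor/normal-like counts with planted
differential-mean and differential-variance genes, noisy prior layers from
a known truth network, and a drug library with a planted ideal pair):

```r
library(drugcombinet)

fx <- build_default_fixture(seed = 1)   # full disease side + drug features
head(fx$scores[order(fx$scores$rank_wilcoxon),
               c("gene_id", "logFC", "p_wilcoxon", "SS_wilcoxon", "selected")], 3)
#>  gene_id    logFC   p_wilcoxon SS_wilcoxon selected
#>     G025 2.361287 1.907349e-05   11.144257        1
#>     G030 1.727228 3.814697e-06    9.359053        1
#>     G001 1.972365 3.623962e-05    8.758912        1

length(fx$selected)                      # 54 candidate genes (union of top 10%)
nrow(adjacency_to_edges(fx$network))     # 107 prior-supported co-expression edges

st <- run_optimizer(fx$feats, ga_config(generations = 500), seed = 1)
st
#> optimizer_state: 500 generations, population 100, HoF 10 combination(s)
#>   [1] {drug02, drug10, drug13}
#>   [2] {drug08, drug11}
#>   [3] {drug01, drug02, drug11}
#>   [4] {drug01, drug02}
#>   ...
```

The Hall of Fame holds ten trade-offs along the Pareto front, from tight
pairs to broad-coverage sets. Member `{drug01, drug02}` is the planted
ideal pair — maximally dissimilar SMILES, targets in disjoint network
components, and the two highest effect scores; its objective vector
`(moa = 0.032, smiles = 20, targets = 27, coverage = 1.04, −size = −2)`
makes it the unique coverage maximizer, which is why repeated seeded runs
recover it consistently (`stability_analysis()` reports the
combination-frequency network and per-run Jaccard agreement).

A file-based workflow with the same stages is available through the
command-line interface:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/drugcombinet.R", package = "drugcombinet"))')
Rscript $CLI simulate --out bundle --seed 1
Rscript $CLI run --config bundle/config.yaml
```

Subcommands `score-genes`, `infer-network`, `build-prior`,
`filter-network`, `rank-hubs`, `drug-features`, `optimize` and `stability`
re-run individual stages from the previous stage's files.

See `vignettes/methods.Rmd` for the models, parameter rationale, numerical
choices and limitations.

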