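---
title: "Methods: multi-omics network weighting and pathway extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics network weighting and pathway extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathext)
```

Curated pathway databases lag behind the biology: genes that functionally
participate in a pathway in a given disease context are often missing from its
curated gene list, and single-omics enrichment analyses silently lose the
signal those genes carry. `pathext` addresses this by (1) re-weighting a
protein-interaction network per phenotype from joint DNA-methylation and
expression evidence, (2) extending each curated pathway with network
neighbours that demonstrably connect its members in the phenotype-specific
network, and (3) testing the extended gene lists for association with the
phenotype. This vignette documents the model, every default, and the
numerical choices, in the order the pipeline applies them.

## 1. Per-gene feature blocks

A gene is usually covered by several CpG probes whose beta values are highly
collinear. `reduce_cpg()` centres the probes-by-samples block and keeps the
smallest number $s$ of principal components whose cumulative explained
variance reaches the target (default `variance_target = 0.8`); 80% retains
the dominant methylation modes while discarding probe-level noise, and for
typical promoter blocks yields $s \in \{1, 2\}$. Component signs are fixed
(largest-magnitude loading positive) so results do not depend on LAPACK sign
conventions. `merge_features()` appends the expression vector, giving a
samples-by-$(s{+}1)$ block per gene. Probes with more than `max_missing`
(default 20%) missing betas are dropped; remaining missing betas are
mean-imputed within the analysed sample set. Genes without usable probes can
be kept as expression-only blocks (`include_expr_only = TRUE`, the default)
so that the network does not lose nodes merely because array coverage is
sparse.

## 2. Sparse CCA edge weights

For each interaction $(u, v)$ and each phenotype separately, `scca_pair()`
fits a rank-1 penalized matrix decomposition between the two genes' feature
blocks restricted to that phenotype's samples: maximise
$a^\top X^\top Y b$ subject to $\|a\|_2 \le 1$, $\|a\|_1 \le c_1\sqrt{p}$
(and likewise for $b$), by alternating soft-thresholded updates where the
L1 bound is met by bisection on the threshold. The edge weight is the
absolute Pearson correlation of the two canonical variates $Xa$ and $Yb$,
clamped to $[0, 1]$.

Numerical notes:

* Because any unit-L2 vector has $\|a\|_1 \ge 1$, the L1 bound is clamped at
  $\max(1, c\sqrt{p})$; otherwise the feasible set would be empty for small
  blocks (with $p = 1$ the bound $c < 1$ would exclude the only unit
  vector).
* The initial $b$ (leading right singular vector of $X^\top Y$) is projected
  onto the constraint set before the first update, which makes the recorded
  objective trace non-decreasing at every step — a property the test suite
  asserts on random problems.
* With $p = q = 1$ the weight provably equals $|r|$, the plain absolute
  Pearson correlation; this limit is also under test.

The defaults `c1 = c2 = 0.7` sit in the middle of the useful range: small
enough to suppress noise components of multi-probe methylation blocks, large
enough that two informative features (say one methylation PC plus
expression) both stay active. Edges with an endpoint lacking any data are
deleted and counted (`n_deleted`), mirroring how incomplete cohorts prune
real interactomes.

## 3. Limited random-walk relevance

`transition_matrix()` normalises each node's incident weights into
$P_{ij} = W_{ij} / \sum_j W_{ij}$; zero-weight nodes are dropped because a
walk cannot leave them. For each pathway, `limited_kwalks()` starts a walk
at every mapped member in turn, lets it move by $P$, absorbs it at first
arrival in any *other* member, truncates at `L = 50` steps, and averages
over start members. Forward probability-mass propagation computes the
expected passage counts exactly (no sampling); the test suite cross-checks
it against an independent Monte-Carlo walker. `L = 50` is deep enough that
on connected networks almost all mass is absorbed (the truncated remainder
is orders of magnitude below the selection thresholds) while bounding the
cost at $L$ dense matrix-vector products per seed.

## 4. Selecting extension genes

Raw passage counts concentrate on high-degree hubs: a hub circulates a great
deal of walk mass without ever connecting two pathway members, so ranking by
raw counts sweeps in the background around any pathway. The default score
therefore is **seed flow**: the expected amount of walk mass a non-member
hands *directly into* a pathway member, i.e. the gene's share of the
successful member-to-member connection flow (`extension_rule(score =
"seed_flow")`). Hubs that merely shuffle mass score near zero; genuine
bridges score on par with the strongest members.

The default truncation keeps genes scoring at least half the best non-member
score (`type = "relative"`, `threshold = 0.5`) — scale-free, so it adapts to
pathway size and network density — and every rule is capped at `cap_factor =
3` times the mapped pathway size so a pathway can never drown in its
extension. Alternative scores (`passage`) and rules (`share`,
`cumulative_mass`, `top_k`, `quantile`) are available for sensitivity
analyses. The final gene list is the union of the case and control
extensions with the mapped members, because a gene that links the pathway in
*either* phenotype is informative for the downstream contrast.

## 5. Enrichment over extended pathways

`run_ora()` tests the overlap of each (extended) pathway with the
differential-expression set by the hypergeometric upper tail, adjusts with
Benjamini–Hochberg across the collection, and reports dense ranks. The DE
set comes from `call_de()`: per-gene Welch t-tests with BH correction at
`de_alpha = 0.05`.

`gsea_significance()` implements phenotype-permutation GSEA: genes are
ranked by a signal-to-noise ratio whose class standard deviations are
floored at $\max(sd, 0.2|\mu|, 0.2)$ (stabilising near-constant genes), the
enrichment score is the signed extremum of the weighted Kolmogorov–Smirnov
running sum (`weight_exponent = 1`), and the whole ranking is recomputed
under `n_perm = 1000` random label permutations. Permuting phenotype labels
— not genes — preserves inter-gene correlation, which is essential here
because extended pathways are *constructed* from correlated genes; a
gene-permutation null would be wildly anticonservative. NES normalises by
the same-sign mean permutation ES, the nominal p is the same-sign
permutation tail, and FDR q compares the pooled permutation NES distribution
against the observed NES values. The enrichment-score kernel used inside the
permutation loop touches only hit positions ($O(|S|)$ after sorting once per
permutation) and is tested to agree with the full running-sum profile and
with an independent implementation; exact ties between the positive and
negative extremum resolve to the positive peak with a $10^{-12}$ tolerance
so floating-point summation order cannot flip the sign.

## 6. The synthetic study

Real multi-omics cohorts cannot ship with a package, and no public cohort
comes with ground truth about which genes *should* extend a pathway. The
generator therefore plants the exact structure the method claims to
recover:

* a preferential-attachment background interactome (realistic degree skew,
  including hubs — the failure mode the seed-flow score exists for);
* disjoint, connected pathway gene sets carved out of it;
* **bridge genes** outside every curated list, wired to 2–3 members of one
  pathway, carrying the pathway's latent signal and a planted expression
  effect — these are the recoverable truth;
* a latent factor model in which pathway members share a per-pathway factor
  (cross-gene coupling `coupling = 0.8` on planted edges, zero on
  background edges) and every gene's promoter methylation follows its
  expression negatively on the logit scale, emulating the canonical
  promoter-methylation convention;
* planted differential expression (`de_effect = 1.5` on all bridges, 30% of
  pathway members, 2% of the background).

The default preset (200 genes, 5 pathways of 15, 3 bridges each, 35 samples
per class, 2–8 probes per gene) is the package's reference study: large
enough that hub confounding and multiple-testing effects are real, small
enough to run in seconds. `fixture_spec_mini()` is a reduced preset for
fast tests. What the generator deliberately does **not** emulate: batch
effects, cell-type composition, copy-number confounding, and probe
cross-hybridisation — pipeline inputs from real cohorts should be
pre-corrected for these.

```{r worked, message = FALSE}
spec <- fixture_spec_mini(seed = 7L)
st <- generate_network_and_pathways(spec)
co <- generate_cohort(spec, st)
nets <- lapply(c(case = "case", control = "control"), function(ph) {
  smp <- names(co$labels)[co$labels == ph]
  blocks <- build_feature_blocks(co$expression, co$methylation, co$probe_map, smp)
  build_weighted_network(blocks, st$edges, phenotype = ph)
})
ext <- extend_collection(st$pathways, nets$case, nets$control)
ext$report
added <- lapply(ext$details, function(d) setdiff(d$final_genes, d$mapped_genes))
extension_recovery(added, st$truth)
```

## 7. Limitations

* Edge weights are fitted per edge; the method does not model conditional
  independence across the whole network, so densely interconnected signal
  regions can share weight.
* The sparse CCA weight is correlational: it cannot distinguish methylation
  driving expression from shared upstream regulation.
* Extension quality degrades when a pathway maps fewer than ~3 genes into
  the network (such pathways are reported unextended, with a warning).
* FDR q-values from the pooled-NES procedure are conservative for small
  collections; with very few gene sets, nominal p-values are the more
  informative column.
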