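---
title: "Methods: building and analysing a functional interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing a functional interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finet)
```

This vignette is the package's own account of its models and procedures:
what is computed, under which assumptions, which parameters matter, and
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Functional interactions from pathway content

A *functional interaction* (FI) joins two proteins that take part in the
same biochemical reaction as an input, catalyst, activator or inhibitor, or
that are members of the same protein complex. Reaction outputs never
contribute: the product of a reaction is not, by that fact alone,
functionally coupled to the catalyst of the reaction. Complexes appearing
in reaction roles are recursively flattened to proteins first (cyclic
nesting is rejected as a structural error), splice-isoform suffixes are
stripped so identity is by base accession, and extraction has set
semantics: it is idempotent, order-independent and never pairs a protein
with itself. For `n` distinct non-output participants a reaction yields
exactly `C(n, 2)` FIs.

Direction is an *annotation* on an otherwise undirected edge, following the
visual semantics of pathway diagrams: catalyst/activator-to-input pairs are
tagged `activates` (oriented from the regulator), inhibitor-to-input pairs
`inhibits`, transcription-factor-to-target records `expression_regulates`;
input-input and complex pairs stay undirected. Two deterministic
conventions close the gaps left open by those semantics:

* when one protein holds several roles, the regulator reading wins for a
  regulator-input pair, and the inhibitor role wins over
  catalyst/activator;
* when duplicate reports of one pair disagree, a directed tag beats
  undirected, and among directed tags the precedence is inhibits >
  activates > expression_regulates.

All network analyses treat FIs as undirected adjacency; the tags are
carried through merges so that downstream interpretation (e.g. whether a
mutated gene sits upstream or downstream of a regulator) can take
directionality into account.

Pathway input uses a deliberately small line-oriented TSV
(`read_pathway_tsv()`): `PATHWAY`, `REACTION`, `COMPLEX` and `REGULATION`
records carrying exactly the fields the FI definition needs. Importers for
the exchange formats of live pathway databases (BioPAX, SBML, KGML) are out
of scope.

## 2. Nine evidence features and their screening

Candidate pairs carry nine boolean features (`FI_FEATURES`): human physical
PPIs; PPIs between the fly, worm and yeast orthologs of the two proteins
(interologs, obtained by projecting model-organism pairs through an
ortholog map, excluding self-pairs); domain-domain interaction; two
independent co-expression pair sets (consumed as precomputed significant
pairs; computing co-expression from raw arrays is out of scope); shared GO
biological-process annotation; and text-mined PPIs. Assignment is
closed-world: absence of an evidence record is `FALSE`.

Two features need conventions:

* **Record expansion** (`load_interactions()`): records with more than 4
  distinct participants are dropped (pull-down style records listing whole
  complexes correlate poorly with reaction-level interaction), and retained
  records are matrix-expanded to all pairs. The cap is a parameter.
* **GO BP sharing**: a shared term counts only if it is not explicitly
  excluded (e.g. the BP root) and annotates less than a configurable
  fraction (default 25%) of all annotated proteins. Broad terms say little
  about joint participation in a specific reaction; the breadth filter
  makes the feature reaction-scale. All evidence codes are accepted.

Each evidence source can be screened against a reference FI set with an
odds ratio (`odds_ratio()`): the 2x2 table crosses evidence-set membership
with reference-versus-control pairs, where each of (by default) 10
permutations draws a control set of random pairs from the reference protein
universe, the same size as the universe-restricted evidence set. Zero cells
receive the Haldane-Anscombe +0.5 correction. On the default synthetic
world the per-feature mean odds ratios span roughly 4-40 and rank by the
planted evidence contrast.

## 3. The classifier

The naive Bayes posterior for a feature vector `f` is

    P(FI | f) = pi * L1 / (pi * L1 + (1 - pi) * L0),
    Lc = prod_i theta[i, c]^f_i * (1 - theta[i, c])^(1 - f_i)

accumulated in log space. Three estimation choices matter:

* **Prior** (`compute_prior()`): the pair density of the filtered positive
  set, positives / C(n_proteins, 2) — *not* the class balance of the
  training sample. The negative:positive ratio rho (10 or 100) therefore
  only affects the precision of the negative-class conditionals, and models
  trained at both ratios give near-identical ROC curves (the acceptance
  suite checks their AUCs differ by well under 0.02).
* **Smoothing**: Laplace add-one, `(count + 1) / (n + 2)`, keeping every
  conditional strictly inside (0, 1).
* **Negatives** (`sample_negative_pairs()`): uniform random pairs over the
  proteins of the filtered positive set, excluding known positives. Random
  pairs are overwhelmingly non-interacting at FI densities of ~1%, and
  excluding the known positives removes the residual label noise at
  negligible cost.

Positives are filtered to pairs with at least one true feature, and
`predict_fis()` likewise never emits a pair with no evidence, whatever its
score: with a prior of order 10^-2 and the default threshold of 0.50, a
pair needs several concordant evidence types to clear the bar, which is the
high-specificity / modest-sensitivity operating point the threshold is
meant to buy. ROC evaluation (`evaluate_roc()`) computes TPR/FPR at every
distinct score, AUC by the trapezoid rule, and sensitivity/specificity at
the operating threshold; test positives come from held-out pathways and
test negatives are random pairs from the held-out pathway universe at the
training ratio (capped at the number of distinct pairs that universe
contains — a small-world accommodation a genome-scale run never hits).

## 4. The merged network and its validation

`merge_fi_network()` unions pathway-derived and predicted FIs; on
collision, pathway provenance wins and the direction tag is retained, and
source labels are unioned. The merge is commutative and idempotent up to
that precedence. `network_stats()` reports node/edge counts, mean and
maximum connection degree and component sizes; degree is reported both in
accession space and (after `map_to_gene_symbols()`, which drops unmapped
accessions with a logged count and re-deduplicates) in gene-symbol space,
since the two denominators differ.

As an independent quality check, `cc_sharing_rate()` measures the fraction
of edges whose endpoints share a GO cellular-component annotation, among
edges with both endpoints annotated (unannotated endpoints leave the
denominator; with no evaluable edge the rate is an error, not a number).
Subcellular co-localization was never a classifier feature, so an increase
of CC sharing in predicted FIs over the raw PPI input indicates genuine
enrichment for functional pairs; the acceptance script computes both rates
on the synthetic world and the predicted set shares substantially more.

## 5. Cancer cohort analysis

**Modules.** The altered genes of a cohort induce a subnetwork
(`induce_alteration_subnetwork()`; genes with no mutual FI are reported
separately and excluded from clustering). `girvan_newman_modules()` removes
the highest-edge-betweenness edge iteratively and returns the component
partition of maximal Newman-Girvan modularity over the removal sequence.
The algorithm itself fixes neither a stopping rule nor tie handling, so the
package chooses maximum modularity as the stopping criterion and breaks
betweenness ties by the lexicographically smallest edge, making runs
reproducible; the result is cross-checked in the test suite against an
independent reference implementation. Modules are indexed from 0 by
descending size.

**Co-hits.** `cohit_test()` measures the fraction of samples with altered
genes in both of two modules. The null preserves each sample's number of
in-universe altered genes and redraws them uniformly from the clustered
subnetwork's gene universe; since only per-module membership counts matter,
the redraw is realized as the exact equivalent multivariate hypergeometric
count draw. p = (permutations >= observed) / n_perm, reported as
"< 1/n_perm" when none reaches it. The test suite verifies both calibration
(uniform p-values on structureless cohorts) and power (two planted modules
hit with probability 0.85 each recover a co-hit fraction near
0.85^2 = 0.7225 — a check run without passenger noise, because passengers
landing in the modules by chance inflate the fraction above the pure
planted signal).

**Sample clustering.** Complete-linkage agglomeration on the asymmetric
binary distance between sample incidence rows (discordant / active
positions; two all-zero rows are at distance 0 by convention). Enrichment
of a sample cluster for a label uses the one-sided Fisher/hypergeometric
exact test (`contingency_test()`). The dendrogram cut (height or k) is a
parameter: no principled cutoff is implied by the method.

**Enrichment.** `enrich_annotations()` scores each term by the exact
binomial tail P(X >= k) with the universe's annotated fraction as the
background rate, and attaches a permutation FDR: over 1,000 random
same-size gene sets, the mean count of null p-values at or below the
observed p, divided by the observed rank, clipped to [0, 1] and made
monotone (step-up).

## 6. Core-network analysis

`recurrence_curve()` tabulates the fraction of altered genes occurring in
exactly / at least s samples against a null that reassigns genes to samples
uniformly (per-sample counts preserved), plus the average shortest path of
the >= s genes. `average_shortest_path()` means unweighted breadth-first
distances over all unordered pairs inside the largest connected component;
genes outside it are excluded and counted. Distances within the component
are computed once as a matrix and permutation nulls are subset means, which
is what keeps thousand-fold permutation tests cheap.

`asp_permutation_test()` draws null gene sets from the largest component,
either uniformly or degree-stratified: bins are generated dynamically from
the sorted candidate degrees, each bin closing only at a degree boundary
and only once its degree interval holds at least `min_bin_size` (default 5)
component nodes (a terminal bin that cannot supply its draw is merged
backwards); every null set then matches the candidate count bin by bin.
Degree stratification controls for hubs sitting close to everything, so on
hub-biased gene sets its null mean ASP falls at or below the uniform null
mean — the direction in which a degree-matched null is the more honest
comparison.

`cluster_genes_shortest_path()` clusters candidates by average linkage on
the shortest-path matrix and cuts the dendrogram at each distinct merge
height from the bottom up, returning the first (smallest) cluster
containing more than the coverage fraction (default 70%) of usable genes;
ties between simultaneously qualifying clusters resolve to the smallest,
then lexicographically. Height cuts, rather than individual merges, are
scanned because integer shortest-path matrices make tied merge heights
ubiquitous and a per-merge scan would return an arbitrary sub-cluster of
the tied level. If no cut below the root qualifies, the root is returned
with a warning.

`build_linker_subnetwork()` connects the candidates with a greedy
Steiner-style merge: clusters start as singletons and the two clusters at
the smallest shortest-path distance are repeatedly joined along one
shortest path (ties broken by the lexicographically smallest node
sequence), interior nodes becoming *linker genes*. The exact minimum
Steiner connector is NP-hard at scale; on all small random instances in
the acceptance suite the greedy count equals a brute-force minimum, and
the output is always connected and contains every in-component candidate.

## 7. The synthetic world

`world_spec()` / `gen_pathway_world()` / `gen_feature_sources()` /
`gen_cohort()` generate the fixtures every stage runs on. All generators
are pure functions of their specification and seed (byte-identical files on
re-run). The defaults define the package's study conditions:

* **500 proteins, 40 pathways**, pathway sizes 10-18 with 2-4 reactions and
  1-2 complexes, members rotated through roles so FIs spread thinly. This
  puts the planted FI density over the FI protein universe near 1% — the
  regime of real curated pathway data, and a precondition for drawing a
  100:1 negative sample of distinct pairs at all.
* **Evidence rates** `q_pos` (0.10-0.80) and `q_neg` (0.010-0.050) per
  feature: a planted FI carries feature i with probability `q_pos[i]`,
  every other pair with `q_neg[i]`. The implied per-feature odds ratios
  span roughly 4-40, mirroring the spread across real evidence sources.
* **Compartments**: each pathway is anchored to a home compartment from
  which 90% of its members are drawn, so pathway-derived (and hence
  predicted) FIs are compartment-coherent while background evidence pairs
  are not — the structure the CC-sharing validation needs.
* **Cohorts**: 91 samples; per planted module an independent hit with
  probability 0.85 contributing 1 + Pois(0.5) module genes; Pois(5)
  passengers per sample drawn uniformly from the network genes (the
  per-specimen alteration load of real resequencing cohorts, scaled to a
  network a few hundred genes in size). Empty alteration sets are topped up
  with one passenger.

Deliberate simplifications, and what they mean for the tests: each flagged
pair receives a *private* GO BP term and a *private* domain pair, so
realized feature rates equal (`q_pos`, `q_neg`) exactly, at the cost of not
reproducing the hub structure of real GO terms and Pfam domains (one broad
term covering 60% of proteins is planted so the breadth filter has work to
do); ortholog maps are complete and one-to-one, so interolog projection is
exercised structurally while many-to-many images are covered by unit
tests; synthetic evidence is emitted as two-column pair lists, with the
PSI-MI TAB subset parser exercised on dedicated fixtures. Passing tests on
this world therefore demonstrate the correctness and calibration of the
machinery — not the performance the classifier would achieve on real,
dependent, incomplete evidence, where features violate independence and
the closed world under-counts true interactions.

## 8. Numerical conventions and problem sizes

Scores are accumulated in log space; the score of an all-equal-conditionals
model equals the prior exactly. Betweenness and linker-path ties break
lexicographically. Permutation p-values are r / n_perm with the "< 1/n"
convention at r = 0. Every random procedure takes an explicit seed and
restores the caller's RNG state.

The shipped test and acceptance runs use the default 500-protein world,
91-sample cohorts, 120 replicates for calibration checks and 1,000
permutations per test (10,000 for the single co-hit test in the acceptance
script); the full suite runs in well under a minute of compute for the
analysis stages, with the classifier block dominating at a few seconds.
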