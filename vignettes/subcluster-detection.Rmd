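---
title: "Detecting biosynthetic sub-clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biosynthetic sub-clusters: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subclust)
```

Bacterial biosynthetic gene clusters (BGCs) are often modular: groups of
co-evolving genes — *sub-clusters* — are jointly responsible for one
chemical moiety of the encoded natural product. This vignette explains the
statistical models behind `subclust`, the parameters a user may want to
touch, and the design choices made where the methodology left room.

## Tokenisation and corpus filters

A gene is represented as the ordered string of its biosynthetic (sub)Pfam
domains, joined by `;`; a gene with no retained biosynthetic domain becomes
`-`. Working at the domain-combination level gives a scalable proxy for
(distant) homology: two proteins sharing the same domain string are treated
as the same gene type. The empty token is kept in place because it carries
positional information — it breaks gene adjacency without changing the
number of available gene slots.

Two corpus-level filters run once, in a fixed order: domains seen fewer
than `minDomainCount = 3` times corpus-wide are deleted from every token
(singleton domains cannot support co-occurrence statistics), and BGCs left
with fewer than `minNonemptyGenes = 2` non-empty genes are dropped (no pair
statistics are possible within them). Computing the counts on the input
corpus makes the operation idempotent, which the tests assert.

Domain calling itself is an external step: `parseDomtbl()` reads
`hmmscan --domtblout` tables and keeps hits with independent E-value at
most `maxIEvalue = 0.001`. That cut-off is our choice — upstream pipelines
differ and no single convention exists — so it is exposed as an argument.
Repeated hits of one domain within a gene collapse to a single occurrence
at the first alignment position; within-gene domain order follows alignment
start, with ties broken by alignment end and then accession text, so
tokenisation is fully deterministic. Gene order along the BGC follows the
CDS start coordinate irrespective of strand: all downstream statistics use
unordered adjacency, so orientation carries no information here.
Contig-edge regions are excluded by default; fragmented BGCs truncate
genuine sub-clusters and inflate the `-` content.

## Redundancy filtering

Public BGC collections are heavily redundant, and redundancy manufactures
spurious "sub-clusters" that span entire duplicated BGCs. Two BGCs are
connected in a similarity network when their **Adjacency Index** exceeds
0.95 or when one is contained in the other. We define the index as the
Jaccard similarity of the two sets of *unordered adjacent-domain bigrams*
built from each BGC's concatenated non-empty token sequence. Unordered
pairs make the index independent of strand and reading direction; using
bigrams rather than plain domain content makes a rearranged BGC distinct
from a colinear one. A BGC with fewer than two domains has an empty bigram
set; its index is defined as 0 and it is never "contained", so degenerate
BGCs do not link everything together.

From every maximal clique of the network only the member with the most
domains survives. Cliques are processed from largest to smallest (ties by
smallest member id), removed members stay removed, chosen representatives
cannot be removed later, and the reduction is iterated to a fixpoint —
overlapping cliques can leave two protected representatives connected
after one round, and the fixpoint guarantees the documented idempotence
property. On equal domain counts the lexicographically smallest id wins,
purely for determinism.

## The statistical layer

The null model asks: if gene B's occurrences were scattered at random over
all gene slots not occupied by gene A, how surprising is the observed
number of adjacencies? Available positions fall into three categories —
not adjacent to A (`N1` slots), adjacent on one side (`N2`), adjacent on
both sides (`N3`) — and a placement `(b1, b2, b3)` of B's `Btot`
occurrences has multivariate hypergeometric probability

$$P(b_1,b_2,b_3) = \frac{\binom{N_1}{b_1}\binom{N_2}{b_2}\binom{N_3}{b_3}}
                        {\binom{N_{tot}}{B_{tot}}},
\qquad I = b_2 + 2 b_3 .$$

The adjacency p-value is the exact upper tail $P(I \ge I_{obs})$. It is
enumerated over `(b2, b3)` only (`b1` is implied), with each term computed
via `lchoose` in log space and the terms summed from smallest to largest;
the unit tests hold the result to within $10^{-9}$ of a brute-force
enumeration of actual position subsets for every instance with at most 12
positions, and within Monte-Carlo error of a sampling oracle at larger
sizes.

Co-localisation uses the same logic with two categories (inside/outside
the BGCs containing A), i.e. an ordinary hypergeometric tail, delegated to
`phyper`. This two-state reduction is only valid when every token occurs
at most once per BGC, which is why duplicate genes are first blanked in
place and a single copy appended at the end behind a `-` separator. The
appended copy sits between separators and therefore participates in no
adjacency — the conservative reading of the simplification.

Each unordered pair gets two directional p-values (A fixed, B fixed); the
larger is kept. False-discovery control uses the Benjamini–Yekutieli
step-down adjustment (via `p.adjust`), which remains valid under the
arbitrary dependency among overlapping pairs. Pairs that never share a BGC
have p = 1 by construction; they are not materialised, but they still
enter the correction through its `nTests` argument, so the adjustment is
computed over all `choose(V, 2)` token pairs.

Clique detection runs on the graph with an edge where
`min(q_adj, q_coloc) < τ`. We apply the threshold to the *corrected*
q-values; the procedure is described in terms of p-values in places, but
correcting first and thresholding second is the only order in which the
0.1 threshold has an FDR interpretation, and the iteration over "all
values below the initial threshold" is unchanged in form. Iterating τ over
every distinct q-value below 0.1 peels nested structures apart: a clique
polluted by one marginal edge at τ = 0.1 reappears cleanly once τ drops
below that edge's q. Cliques with fewer than 3 genes or occurring
(token-set containment) in fewer than 2 BGCs are discarded. Occurrence is
containment, not adjacency: a sub-cluster's genes need not be contiguous
in a BGC that carries it.

Families and clans are K-means groupings (`kmeans`, 10 restarts, fixed
seed) of the binary sub-cluster × vocabulary matrix, with defaults
`kFam = ceiling(0.1 n)` and `kClan = ceiling(0.2 kFam)`, mirroring the
roughly 10:1 and further 5:1 reductions used at full scale. Duplicate
rows are clustered once and mapped back, so K-means never sees coincident
initial centres. Within a family, a member whose token set is a subset of
another's *with an identical occurrence set* is dropped: such a member is
pure nesting noise and adds no information. This concrete rule is our
realisation of the redundancy removal that accompanies the family
clustering, whose exact original form is not specified in the main
methodological description.

## The topic-model layer

The second detector treats a BGC as a bag of tokens and fits latent
Dirichlet allocation by online variational Bayes. A topic is a
*sub-cluster motif*: a probability vector over tokens that tend to occur
together across BGCs. Defaults follow the established practice for this
application: symmetric priors α = β = 1/N, mini-batches of
`max(2000, 0.05 · n)` documents, and a per-document variational iteration
cap of 500. For corpora below the minimum chunk size the update is
effectively full-batch, so the `passes` argument (default 50) controls the
actual number of EM updates; the per-pass plug-in log-likelihood of a
held-out 5% document split is stored in the model so convergence can be
inspected. All randomness (initialisation, held-out split) comes from a
private RNG stream seeded by `seed`; two runs with the same seed produce
bit-identical models within one R installation.

Motifs are truncated to the shortest descending-probability prefix
summing to at least 0.95, cutting away the long flat tail of near-zero
probabilities. Querying infers the BGC's topic mixture θ and assigns each
gene `g` (token `w`) a **gene-to-motif probability**
$\gamma_{g,k} \propto \theta_k \phi_{k,w}$, normalised over topics — the
posterior responsibility of topic `k` for that gene. This definition is
our interpretation (the quantity is named but not defined in the
methodological description); it is isolated in `inferBgcTopics()` so an
alternative, such as raw φ ranking, could be swapped in. A candidate match
keeps genes with γ ≥ 0.3 and is emitted when it has at least two genes,
Σγ > 1.1 and an overlap score — the sum of the motif's truncated feature
probabilities over tokens present in the match — of at least 0.15. The
gene-count rule is applied before the overlap rule; the final match set is
the same either way. Model selection at scale uses u_mass coherence
together with overlap against experimentally characterised reference
sub-clusters, where a reference counts as detected when at least 0.6 of
its genes appear in one detected sub-cluster; both evaluations are
implemented (`coherenceUmass`, `matchReferenceSubclusters`). In
`coherenceUmass`, a conditioning token absent from the evaluation corpus
would put a zero in the denominator; its document frequency is floored at
1 so the term stays finite — the +1 smoothing in the numerator already
handles absent co-occurrences.

Note one asymmetry between the layers: the statistical layer consumes the
duplicate-simplified corpus (its co-localisation model requires it), while
the topic model consumes the original corpus — bag-of-words multiplicity
is informative there, and nothing in LDA requires uniqueness.

## The metabologenomic layer

Linked features should co-occur across strains. For a (sub-cluster
feature, Mass2Motif) pair with 2×2 strain counts `n11, n01, n10, n00`, the
score is `10·n11 − 10·n01`: joint presence is rewarded, a strain producing
the substructure without the gene cluster is penalised, and a silent
(cryptic) gene cluster costs nothing. The exact weights of the original
co-occurrence score are configurable arguments, recorded with the output.
Significance is assessed by permuting the strain assignment of the
metabolomic vector (statistically equivalent to permuting the genomic one
for this score) with the pseudocount estimator
`(1 + #{null ≥ obs}) / (nPerm + 1)`, which can never return 0. Each pair
uses its own seed-derived permutation stream, so results are independent of
evaluation order. Following standard practice for this analysis, pairs with
p < 0.1 are flagged descriptively and no additional FDR layer is applied.

## What the synthetic fixtures emulate — and what they do not

`generateCorpus()` plants `nPlanted` sub-clusters with disjoint token
blocks; each BGC is the union of 1–3 of them plus Poisson-distributed
noise genes from a 5×-larger noise vocabulary, and each planted block is
contiguous with probability `pContig` (default conditions: 300 BGCs, 10
planted sub-clusters of 3–6 tokens, noise rate 2, contiguity 0.9). Ten
percent of BGCs are duplicated verbatim to exercise the redundancy filter.
`generatePairedDataset()` plants links as shared presence columns with
cryptic deletion at `flipRate` on the metabolomic side only (defaults: 50
strains, 30×30 features, 5 links, flip rate 0.2).

These fixtures deliberately idealise real data: planted token blocks are
perfectly disjoint, whereas real sub-clusters share promiscuous domains
(transporters, regulators) and overlap; noise is independent rather than
phylogenetically structured; every planted occurrence is complete, whereas
real sub-cluster instances vary in gene content; and strain presence
patterns carry no population structure, while real strain panels contain
clades of near-identical genomes that are the main source of co-correlation
noise. Passing the recovery tests therefore demonstrates correctness of
the machinery and sensible behaviour at realistic sizes — not expected
field performance on noisy, nested, phylogenetically biased data, where
the practical precision is known to be much lower.

## Numerical and scale choices

Exact tails are computed in log space with smallest-first summation;
enumeration is over `(b2, b3)` only. Ties are broken textually everywhere
a deterministic order is needed (domain order within genes, motif feature
order, clique processing, representative selection). The test suite and
the acceptance script run the full pipeline at the default fixture sizes
above — 300-BGC corpora, 20-topic models, 900 feature pairs at 999
permutations — which we consider the smallest scale at which all the
interacting behaviours (nesting, noise tokens surviving the frequency
filter, redundant near-duplicates) actually arise; everything completes in
about a minute on one CPU.

## Known limitations

* The Adjacency Index formula (bigram Jaccard over domains) is our
  concrete reading of "Adjacency Index of domains"; other readings (gene
  tokens instead of domains, ordered pairs) would shift the redundancy
  network slightly.
* PRESTO-style statistics test pairs independently; a clique of marginally
  significant pairs is not itself a calibrated hypothesis test, and the
  q < 0.1 clique threshold should be read as a ranking device.
* The LDA trainer is a straightforward online VB implementation; it is
  adequate for tens of thousands of documents but has no multicore path,
  and reproducibility is guaranteed per installation, not across BLAS
  builds.
* Query-time inference caps variational iterations at 50 for speed;
  extremely long BGCs may see slightly diffuse topic mixtures.
* The GenBank reader is intentionally minimal (CDS locations, locus tags,
  region qualifiers) and is not a general feature-table parser.
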