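---
title: "Pan-genome core gene analysis with pancore: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome core gene analysis with pancore}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pancore` implements a protein-level bacterial pan-genome pipeline: greedy
orthologous clustering of multi-strain protein sets, classification of
clusters into core, dispensable and strain-specific genes, functional
category weighting and enrichment, interpolated Markov-model genomic
signatures, core-gene phylogenetics, and recruitment profiling of metagenome
gene sets against species core genes.  A synthetic pan-genome generator with
known truth underpins validation of every stage.  This vignette documents
the models, their assumptions, the tunable parameters, and the design
choices that were genuinely open.

## Orthologous clustering

Genes are clustered on amino-acid sequences.  The pairwise engine is a
global alignment with free end gaps, scored match +1, mismatch 0, gap −1
(linear).  Two statistics gate cluster membership:

* **identity** — identical aligned residue pairs divided by, under the
  default `identity_denominator = "shorter"`, the length of the shorter
  sequence (the convention CD-HIT reports); `"alignment"` instead divides
  by the number of alignment columns (gap columns included) inside the
  aligned span;
* **coverage of the shorter sequence** — the aligned span on the shorter
  sequence divided by its length.

Clustering is greedy and incremental: genes are processed in order of
decreasing protein length (ties by gene id, C-locale), and each gene joins
the *first* existing cluster whose representative it matches at both
thresholds, else founds a new cluster.  Representatives are therefore
always at least as long as their members.  This is the clustering contract
of CD-HIT, but with exact alignments in place of its word-count
prefilters: at the scale this package targets (up to roughly 10^4 proteins
per run) exactness is affordable and makes the oracle tests meaningful.
The default thresholds are 70%/70% for within-species clustering and
40%/40% for genus-level core-gene pooling.

Determinism demanded two conventions worth recording.  First, among
co-optimal alignments the traceback prefers diagonal over up over left
moves, and the end cell is the best-scoring cell on the last row or column
with ties going to the smaller row, then column, index.  Second, a pair of
sequences is put into a canonical order (longer first; equal lengths
lexicographically) before alignment, which makes `pairwise_identity()`
symmetric by construction — co-optimal alignments could otherwise give
order-dependent match counts.

Classification follows the standard definitions: a cluster containing
genes from every strain of the roster is a **core** gene; a singleton
cluster is a **strain-specific** gene; anything in between is
**dispensable**.  A multi-member cluster confined to one strain (a
within-strain paralog family) does not fit the singleton definition; it is
labelled strain-specific with a `paralogous` flag, and the summary counts
keep the singleton definition by default (`specific_includes_paralogs`
flips this).  The shared-gene proportion between two strains divides the
co-occurring cluster count by the smaller of the two strains' cluster
counts by default; the mean and union (Jaccard) denominators are available
because the definition is genuinely underdetermined — published
shared-gene percentages do not pin the denominator down without the
underlying genomes, so the choice is configurable rather than asserted.

## Functional categories

COG assignment uses the rank-ordered five best hits per gene: a COG is
assigned when at least three hits (configurable via `min_agree`) name the
same COG id, otherwise the gene is *uncharacterized*.  The rule depends
only on the multiset of hit ids.  Each COG's functional class string is
split into equal partial weights — class "EH" contributes 0.5 to E and 0.5
to H — so every assigned gene carries total weight 1.  Mobilome (X)
weights are relabelled `X:t` or `X:p` when the COG product name matches a
transposase or phage keyword; the keyword lists are plain function
arguments, not hard-coded biology.

Enrichment between gene classes compares summed category weights as
proportions.  The default significance test is a two-sided Fisher exact
test on the 2×2 table of rounded summed weights versus the rounded
remainder per class; rounding fractional weights to integers is an
approximation, so a label-permutation alternative
(`method = "permutation"`) that needs no rounding is provided.
Benjamini–Hochberg adjusted p-values accompany the raw ones.

## Genomic signatures

Each gene's signature is the vector of 64 conditional probabilities
P(b | c1 c2) of a 2nd-order Markov chain, estimated with an add-one
pseudocount.  A context observed fewer than `fallback_min_count = 40`
times is too sparse for a stable 2nd-order estimate; the model then falls
back to the 1st-order estimate P(b | c2), and to the 0th-order base
composition if that is also sparse.  The fallback is a hard switch rather
than a weighted interpolation — the blend weights of gene-finder-style
IMMs add a free parameter this application does not need — and the
threshold, pseudocount and order are all arguments.  Features are computed
on the coding strand as given; reverse-complement symmetrization is
deliberately absent because coding-strand asymmetry is part of the signal
separating native from foreign genes.

PCA (column-centered, unscaled) projects the signatures; the sign of each
component is fixed by making its largest-magnitude loading positive.
Class separation on PC1 is summarized by the absolute mean difference,
pooled SD, and the mean silhouette width of the 1-D class partition.

The estimator-convergence test simulates 50 kb from a strongly structured
2nd-order chain in which each context prefers one base at probability
0.91 and the preferred base is the base two positions back.  That
preference makes the context dynamics measure-preserving, so all 16
contexts are visited about equally often and every one of the 64
conditional probabilities is estimated from a comparable number of
transitions; estimation error, not uneven context coverage, is then the
quantity under test (L∞ below 0.02 at this length).

## Phylogenetics

Core-gene trees are built from per-cluster protein alignments,
concatenated in deterministic cluster-id order.  Every column containing a
gap or missing character in any strain is removed (complete deletion), and
per-gene column ranges are remapped to post-deletion coordinates.
Distances are Poisson-corrected, d = −ln(1 − p) with p the proportion of
differing columns, under uniform rates among sites; saturated pairs are a
hard error naming the pair.  Gamma or empirical-matrix corrections are
out of scope — the Poisson model with uniform rates is the stated model
of this pipeline.

Neighbor-joining is the standard Saitou–Nei agglomeration with Q-matrix
minimization, written in the package rather than delegated, because the
pipeline promises specific behaviors a generic implementation leaves
unspecified: ties in Q resolve to the lexicographically smallest pair of
node labels (a node is labelled by the smallest taxon in its subtree),
and negative branch lengths are clamped to zero with the total deficit
recorded in an attribute.  On additive matrices the generating topology
and branch lengths are recovered exactly; the test suite cross-checks
against `ape::nj` on random additive trees.  Bootstrap support resamples
supermatrix columns with replacement, rebuilds the tree per replicate,
and maps support onto bipartitions (not node orders), making it
rooting-invariant.

Average-linkage clustering of the shared-gene matrix runs on distance
1 − proportion through `stats::hclust(method = "average")`, with taxa
sorted lexicographically first so ties resolve deterministically.

## Recruitment profiling

Metagenome genes shorter than or equal to 500 bp are discarded (the
filter is strict: 501 bp is kept, 500 bp is not).  The survivors'
proteins are pooled with every species' core-cluster representatives and
clustered greedily at the chosen thresholds — 70% to ask which core genes
are reconstructed at all, 90% for species-level resolution.  A species'
core cluster is **recruited** when its pooled cluster contains at least
one metagenome gene (multiple metagenome genes in one cluster count
once), and **exclusively recruited** when no other species' core gene
shares the cluster.  "Exclusive" is not formally standardized; the
implemented definition — recruited cluster containing core genes of
exactly one species — coincides, on these inputs, with the alternative
reading (cluster containing only that species' genes plus metagenome
genes).  The coverage threshold paired with 90% identity defaults to
0.7 and is configurable, as no single convention exists.  Metagenome
genes are compared as translated proteins in the frame provided by the
gene caller.

## The synthetic pan-genome generator

The generator defines the study conditions for every validation.  Core
and dispensable family members descend from a random ancestral CDS via
`mutate_sequence()`; strain-specific genes are drawn fresh from a
0th-order composition model at a shifted GC (higher-order alien models
are a non-goal).  Defaults: host GC 0.45 (close to *Bacillus*), alien GC
0.60, gene lengths 100–400 aa, per-site core divergence 0.02, dispensable
presence probability 0.5, and an enforced minimum gene length of 50 aa
below which identity estimates are too unstable to be useful.

`mutate_sequence()` substitutes the third codon position at the stated
divergence and the second position at a quarter of that rate (the first
position and the start/stop codons never change, and codons that would
become internal stops are redrawn), so protein divergence stays well
below nucleotide divergence, as in real orthologs under purifying
selection.  Empirically, protein divergence is about 0.5× the
third-position rate.  The realized substitution count is returned as an
attribute, giving tests an exact Hamming oracle.

Dispensable families draw their presence pattern from a Binomial
conditioned on having at least 2 and at most n − 1 members.  An
unconditioned Binomial would occasionally generate all-present families
(which are, by definition, core) or single-member families (which are,
by definition, strain-specific), making the generator's truth table
inconsistent with the classification it is meant to validate; the
conditioning keeps the three classes well-posed.  For the same reason
dispensable families require at least three strains.

`generate_genus()` adds a species level: the first *k* core families of
every species descend from common genus ancestors, each species lineage
diverging by a per-lineage third-position rate of 0.20 in the profiling
validation.  That places cross-species protein identity of shared
families near 0.78 — above the 70% clustering threshold (so shared
families recruit across species) and safely below 90% (so stringent
clustering resolves species) — which is precisely the regime that makes
genus-core genes a confounder at 70% and not at 90%.  The profiling
validation uses five species of 300 core families each (60 of them
genus-core), genes of 80–250 aa, three strains per species, two species
"present" in the metagenome at 0.99 core inclusion with 2% mutation, and
50 alien-composition decoys.

What the generator does *not* emulate: indels, recombination, gene
fusion, paralog expansion, operon structure, realistic codon usage, and
assembly or gene-calling artifacts.  Passing tests therefore demonstrate
that the algorithms are correct under their stated models, not that the
thresholds are optimal for any particular real genus.

## Numerical choices and problem sizes

All randomized procedures take explicit seeds and restore the caller's
RNG state.  Alignment and greedy clustering run in compiled code; all
statistics go through base R (`fisher.test`, `p.adjust`, `prcomp`,
`hclust`) or `cluster::silhouette`, with independent enumeration oracles
in the test suite.  The validation suite exercises: a 10-strain species
with 300 core, 150 dispensable and 200 strain-specific genes (clustered
exactly, truth recovered exactly); 100 random clustering instances of up
to 30 genes against a pure-R greedy replay; 100 random additive trees of
4–8 taxa recovered to 1e-9; the full set of 2×2 tables with row margins
up to 50 (reduced by the symmetry group under which the Fisher p-value
is invariant) against hypergeometric enumeration at 1e-10; and the
five-species recruitment scenario above.  These sizes were chosen as the
smallest at which each property is sharply testable.

## Known limitations

* Greedy first-match clustering is order-dependent by design; the
  canonical processing order makes it reproducible, not optimal.
* The Fisher test on rounded weights treats fractional category weights
  as counts; for heavily multi-category annotations prefer the
  permutation test.
* Trees are produced as Newick/`hclust` objects; visualization is left
  to `ape` and friends.
* Equivalence with any specific external clustering or tree program
  (word sizes, tie-breaking, negative-branch handling) is not claimed.
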