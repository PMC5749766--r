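---
title: "panmeta: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panmeta: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmeta)
```

## What the package computes

`panmeta` analyses a set of closely related bacterial strain proteomes and
their footprint in shotgun metagenomes.  The pipeline has five stages, each
usable on its own:

1. **Greedy protein clustering** groups genes into families at an
   identity-and-coverage threshold (the "70 over 70" style regimes).
2. **Pangenome partitioning** classifies each family as *core* (present in
   every strain), *dispensable* (present in a proper subset of at least
   two strains) or *strain-specific* (one strain only).
3. **Genome-content comparison** computes the Jaccard similarity of
   strains' dispensable-family repertoires and orders the matrix by
   average-linkage bi-clustering.
4. **Core-gene phylogeny** aligns each core family, concatenates the
   alignments into a supermatrix, computes Poisson-corrected distances
   with pairwise deletion, builds a neighbor-joining tree, and attaches
   bootstrap support.
5. **Metagenome profiling and functional screening** measure, per strain
   and sample, the fraction of the strain's genes that co-cluster with
   sample proteins; summarise contig best hits against reference genomes;
   and screen KEGG-ortholog (KO) catalogs for presence/absence.

A first-class **synthetic-data generator** plants all of this structure
with machine-readable truth, so every stage is validated against a known
answer rather than against another tool's output.

## Sequence comparison model

All alignment-based statistics use one fixed scoring scheme: global
Needleman–Wunsch with BLOSUM62 over the 20 standard amino acids and affine
gaps in the BLAST convention — a gap of length $L$ costs
$11 + 1 \cdot L$ (the first gap residue pays opening plus extension).  The
constants are exposed by `blosum62()` and `gap_penalties()`.  Two derived
quantities drive clustering:

* **identity** $= \#\{\text{identical aligned residue pairs}\} / m$, and
* **coverage** $= \#\{\text{residue–residue aligned positions}\} / m$,

where $m$ is the length of the *shorter* sequence.  Dividing by the
shorter sequence matches the "identity over the shorter sequence"
convention of short-word greedy clustering tools.

**Path independence.**  An optimal-score alignment is generally not
unique, and different optimal paths can disagree on the identity count.
The DP therefore maximises the triple *(score, identical pairs, aligned
pairs)* lexicographically, which makes identity and coverage well-defined
functions of the input pair — this is what allows the test suite to demand
*exact* agreement with an independently coded reference DP.

**k-mer prefilter.**  Before aligning, a candidate pair is screened by a
lossless word filter: if identity $\ge c$ over the shorter length $m$,
then with $t = \lceil c\,m \rceil$ identical alignment columns, the
identical columns form runs broken at most $n + m - 2t + 1$ times
($n$ the longer length), so at least $t - (k-1)(n + m - 2t + 1)$ intact
shared $k$-mers must exist.  A pair is rejected only when its shared
$k$-mer count is provably below this bound; when the bound is
non-positive (always at $c = 0.4$ with the default $k = 2$) everything
passes.  The filter can therefore never exclude a pair that would meet
the threshold.

**Greedy clustering.**  Records are sorted by decreasing length (ties by
id), the longest founds the first cluster, and each subsequent record
joins the *best-matching* representative among those meeting both
thresholds (ties to the lower cluster index), else founds a new cluster.
Best-match assignment (rather than first-fit) makes the partition
deterministic and invariant to input order, which the suite tests by
permutation.

## Pangenome partition and Jaccard comparison

Classification is pure presence/absence: paralogs (two genes of one
strain in one cluster) count once.  With a single input strain the core
and strain-specific rules coincide; the package resolves the degenerate
case as *core* and warns.  The Jaccard similarity between strains $s,t$
is computed on dispensable-cluster membership sets,
$J(s,t) = |D_s \cap D_t| / |D_s \cup D_t|$, with the conventions
$J(s,s) = 1$ (also for empty $D_s$, with a warning) and $0/0 = 0$ off the
diagonal.  Bi-clustering is agglomerative average linkage on Euclidean
distances between rows and, independently, columns; labels are pre-sorted
so tie-breaks are reproducible.

## Phylogeny

The internal aligner is a minimal progressive Needleman–Wunsch (3-mer
guide distances, UPGMA merge order, profile–profile DP with BLOSUM62
column means).  Parity with production multiple aligners is explicitly
*not* a goal: the synthetic generator introduces substitutions only, so
core-family alignments are unambiguous, and externally prealigned input
is accepted via `validate_alignment()`.

Distances use the Poisson correction $d = -\ln(1 - p)$ with uniform rates,
where $p$ is the mismatch fraction over columns in which *both* sequences
are ungapped (pairwise deletion).  $p = 1$ is flagged saturated and
refused by the tree builder with instructions to filter; a pair with zero
shared columns is an error naming the pair.  Neighbor joining is the
canonical Saitou–Nei algorithm with the Studier–Keppler criterion;
negative branch lengths are clamped to zero (the convention of widely
used GUI phylogeny software) with a message, and Q-ties break on the
lexicographically smallest pair of subtree label sets so taxon input
order is irrelevant.  Bootstrap resamples whole alignment columns with
replacement, rebuilds distance + NJ per replicate, and reports for each
internal bipartition of the original tree the percentage of replicates
containing it.

## Metagenome coverage profiling

For strain $s$ and sample $q$, after clustering the union of reference
and sample proteins, the coverage ratio is
$r_s(q) = 100 \cdot \#\{\text{genes of } s \text{ in clusters containing
a gene of } q\} / \#\{\text{genes of } s\}$.  The companion identity
statistic is not uniquely defined in the field ("average similarity" can
average over best pairs or over representatives), so both are reported:
`identity` averages, over each counted strain gene, the maximum pairwise
identity to a co-clustered sample gene; `identity_rep` averages the
sample members' recorded identity to their cluster representative.

Contig summaries drop contigs below a length floor and hits failing the
E-value/identity thresholds, keep one best hit per contig (E-value, then
bitscore, then identity, then subject id), and report per genome the hit
count, mean identity, and the percent of the genome covered by the merged
subject intervals — overlaps count once, reverse-strand coordinates are
normalised, and circular genomes are treated as linear.

## KO screening

`assign_ko()` implements the best-hit rule: filter (strain mode: E-value
strictly below the cutoff; metagenome mode: additionally identity
strictly above 90%), rank by E-value ascending, identity descending,
subject id ascending, and take the top hit's KO.  When the top subject
has no KO mapping the second-ranked hit is consulted *once*; the fallback
is deliberately not recursive.  Two catalogs are bundled as versioned
TSVs so no KEGG access happens at run time.  The phycobilisome catalog
encodes 6 allophycocyanin + 7 phycocyanin + 11 phycoerythrin + 2
phycoerythrobilin KOs (26 total).  Catalog counts in the literature are
not fully consistent — phycoerythrin-associated genes are variously
counted as 11 or 13 with cpeS/cpeT singled out as universal — and the
package encodes the 11-KO family without attempting to resolve the
discrepancy.  KO ids that appear in no printed source are filled from the
standard KEGG gene sets for the named symbols.

## The synthetic world

`generate_pangenome()` draws a uniformly random unrooted binary strain
tree with branch lengths uniform in $[0.02, 0.10]$, then evolves one
ancestral sequence per family along it.  The substitution process is the
uniform-replacement chain: along a branch of length $b$ each site
experiences an event with probability $1 - e^{-b\delta}$ (divergence
$\delta$), and an event redraws the residue uniformly from **all 20**
amino acids.  One twentieth of events are therefore silent — the
one-step analog of back-substitution — giving the closed form

$$ \mathbb{E}[p] = \tfrac{19}{20}\left(1 - e^{-\delta T}\right) $$

for leaves joined by path length $T$, which the tests check directly.
(The alternative convention, redrawing from the *other 19* residues, was
considered and rejected because it breaks this closed form; the chosen
model is what the package's own expected-value tests assume.)

Default parameters state one fixed world: protein length uniform in
$150 \pm 30$ residues (short enough for fast benchmarks, long enough that
random-sequence identity sits near its ~5% floor), and $\delta = 0.5$.
With the branch-length range above, the deepest typical leaf-to-leaf path
keeps expected within-family $p$ below 0.3, i.e. within-family identity
above 70%, while unrelated families stay near 5% — the separation the
clustering thresholds assume.  Unique genes and metagenome noise are
i.i.d. uniform sequences.  Samples take
$\lfloor f \cdot n \rfloor$ genes per mixed strain by a seeded shuffle
(deterministic rounding) plus a stated number of noise genes, and every
emitted gene id is resolvable in the truth table.

**What the generator does *not* emulate** — and hence what a green test
does not establish: insertions/deletions (alignments of planted families
are gap-free), paralogy and horizontal transfer, realistic amino-acid
composition or rate heterogeneity (WAG/LG matrices are a non-goal),
gene-length and abundance distributions of real proteomes, and the
fragmented, partial proteins produced by gene callers on short contigs.
Real-data behaviour of the thresholds (e.g. the 40%/70%/90%/95% ladder)
therefore still needs real genomes.

## Numerical and design choices

* Scoring constants are fixed (BLOSUM62, 11/1) because the upstream
  literature names only tools, not parameters; fixing them is what makes
  bit-exact testing possible.
* Identity/coverage tie-breaks, the greedy tie-to-lowest-cluster rule,
  and the NJ label-pair tie-break are arbitrary but documented and
  stable.
* `floor(f * n)` sample inclusion makes truth-predicted coverage ratios
  exact rather than distributional.
* Cluster files round-trip membership, representative flags and identity
  values; member coverage is not carried by the `.clstr` exchange format
  (use the TSV writer for the full table).
* The multilocus "sequence tags" phrasing sometimes attached to core-gene
  phylogenies is read as the concatenated supermatrix approach
  implemented here; no separate typing scheme exists in the package.

## Limitations

The aligner is a teaching-grade progressive NW, not a MUSCLE/MAFFT
replacement; the greedy clustering reproduces the *contract* of
short-word tools (thresholds, best-match mode, determinism), not their
banded heuristics; and desk-scale acceptance uses planted data — the
printed real-data cluster counts of any particular genome set are
reproducible only with those genomes in hand.
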