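---
title: "Methods: domain architectures and gene neighborhoods in a phylogenetic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain architectures and gene neighborhoods in a phylogenetic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotracks)
```

## What the package computes

`phylotracks` places two kinds of per-protein evidence next to a phylogeny:

* **Domain architectures** — the ordered, non-overlapping set of conserved
  domains (plus transmembrane and low-complexity segments) along each
  protein, resolved from raw search hits.
* **Gene neighborhoods** — the genes flanking each query gene on its
  replicon, clustered by shared domain content, with operons called from
  intergenic distances.

Both end in the same place: a tree whose leaves are query proteins, with one
evidence track per leaf, exported as deterministic JSON (for downstream
analysis) and SVG (for inspection).

## Domain architecture resolution

Raw hits (HMMER per-domain tabular output or a generic TSV) carry envelope
coordinates, a per-domain independent E-value and a bit score. Two rules
turn them into an architecture:

1. **E-value filter.** Domain hits with independent E-value above
   `evalue_max` are dropped. The default is 0.01, a conventional
   reporting threshold for profile searches; transmembrane and
   low-complexity segments come from tools that do not emit comparable
   E-values, so they bypass the filter.
2. **Greedy overlap resolution.** Hits are accepted in order of descending
   bit score (ties: smaller E-value, then smaller start). A hit is accepted
   only if its overlap with every previously accepted domain is at most
   `overlap_fraction_max` (default 0.2) of the shorter of the pair.
   Greedy-by-score is the standard practice for drawing architectures; on
   small conflict cliques it coincides with the maximum-score conflict-free
   subset, which the test suite verifies by exhaustive search.

The 20% tolerance admits the small envelope overlaps that adjacent true
domains routinely produce while rejecting alternative models of the same
region. Both thresholds are recorded in result metadata and in the JSON
`parameters` block, so a reader of an export can always see what was
applied, defaults included.

## Trees: built-in backend and adapters

The package's built-in tree path is intentionally simple and fully
deterministic: a k-mer set distance

\[ d(i,j) = 1 - \frac{|K_i \cap K_j|}{\min(|K_i|, |K_j|)} \]

with `k = 3` by default, followed by neighbor joining. Protein triplets are
the shortest words that are reasonably specific in a 20-letter alphabet;
the min-normalisation keeps the distance in [0, 1] when sequence lengths
differ. This backend is labeled `builtin_nj` in every output so its trees
are never mistaken for maximum-likelihood results. For publication-grade
trees the adapter contract accepts arbitrary command templates
(`mafft --quiet {input} > {output}`, `fasttree -quiet {input} > {output}`),
and their outputs are parsed with the package's own readers.

Neighbor joining is implemented in the package rather than delegated:
the implementation pins down three behaviors that matter for reproducible
output and that library implementations leave unspecified — a
deterministic tie-break (the lexicographically smallest label pair among
Q-minimisers), clamping of negative branch-length estimates to zero with
the deficit moved to the sibling branch (preserving path lengths), and a
stable child order. On additive matrices NJ is exact; the tests exploit
this by generating random trees, taking their patristic distances, and
requiring Robinson–Foulds distance zero both against the generating
topology and against an independent NJ implementation (`ape::nj`).

MSA rows are reordered to the depth-first leaf order of the tree so that
conserved columns in related clades sit together; optional enumeration
prefixes leaf *i* and row *i* with the same index. Partial mode uses a
user tree verbatim and skips every tree-related step; two-area mode builds
the tree from sequence fragments (for example, a conserved domain region)
while architectures are computed on the full-length sequences, joined by
identifier.

## Leaf identifiers

Leaf names carry a protein identifier prefix separated by underscore,
space, slash or vertical bar. Underscore is ambiguous: RefSeq accessions
contain one (`WP_011030745.1`). Resolution is therefore ordered — an
accession-shaped prefix (letters, underscore, digits, dotted version) is
taken whole; otherwise the name splits at the first space/`|`/`/`;
otherwise at the first underscore; otherwise the whole name is the id.
This makes `parse_leaf_id` total and idempotent, which the suite checks on
generated name corpora.

## Gene neighborhoods

The neighborhood of a query is up to `window` genes on each side (default
5 per side — "five genes upstream and downstream" is the usual genomic
context window in comparative genomics; the total track is at most
`2*window + 1` genes). On linear replicons the window truncates at the
ends and the truncation is flagged; on circular replicons it wraps across
the origin, genes keep their original coordinates, and the wrap is flagged
in metadata.

**Clustering by domain content.** Each gene's protein reduces to its *set*
of domain accessions (duplicates collapse; TM/low-complexity excluded).
Two genes are compatible when the symmetric difference of their sets has at
most `nonshared_max` elements (default 0, i.e. identical sets). Because
compatibility at k > 0 is not transitive, clusters are defined as connected
components of the compatibility graph (single linkage): deterministic,
order-independent in membership, and monotone — the partition at k+1 always
coarsens the partition at k, a property the tests assert directly. Genes
without any domain are never clustered: with no domains there is nothing
shared, and treating them as one family would invent structure. They render
in a reserved neutral gray.

**Operon calling.** Adjacent genes are linked when the intergenic gap
(bases strictly between them, negative if they overlap) is at most
`operon_gap_max`. The default threshold is **200 bp**, the classical
intergenic-distance cutoff for co-transcription in prokaryotes; the
comparison is inclusive, so a gap of exactly 200 bp links. Operons are
maximal linked runs of at least two genes — a single gene is not an
operon. By default members must also be co-oriented; transcription cannot
read through a strand switch, but the flag `require_same_strand = FALSE`
restores the distance-only rule for comparison.

Coordinates are half-open and 0-based internally — every format boundary
(GFF3 in/out, JSON export) converts exactly once, which makes the gap
formula `start(next) - end(prev)` literally "bases between" and removes
off-by-one ambiguity. Exports use 1-based inclusive coordinates.

## Rendering

Cluster identity is shown as gene fill color, operon identity as border
color, and query genes get a thick border. Color ranks are assigned by
first occurrence scanning leaves top-to-bottom and genes left-to-right,
from a fixed 20-color qualitative palette; after exhaustion colors cycle
with a hatch flag. This makes colors stable: appending new leaves at the
bottom never recolors existing rows. The SVG is static, with the gene
metadata that an interactive viewer would show on hover embedded as
`<title>` elements, and is byte-identical across runs — as is the JSON,
whose keys are sorted and whose `parameters` block records every applied
value including defaults.

Ladderizing (children ordered by subtree size, ties by smallest leaf name)
is available but off by default, since consumers may rely on the input
child order.

## The synthetic-data generator

All tests and the acceptance script run on generated data with known
ground truth, produced by `fixture_spec()` + `synth_genome()` /
`synth_tree_and_sequences()` from a single integer seed (no global RNG
state leaks; the seed is restored afterwards).

The genome generator emulates bacterial gene organisation at the level this
package analyses: ~1 gene per kb, gene lengths 300–1500 bp, operons planted
as co-oriented runs with 50 bp internal gaps, 500 bp between transcription
units, two replicons of 12 genes, four domain families with fixed accession
sets, about 15% of genes domain-less, and domain hits asserted through the
TSV channel with E-values (1e-40..1e-15) far below the filter. The gap
classes are deliberately separable (50 < 200 < 500) — that *is* the study
condition under which planted-operon recovery must be exact, and the spec
constructor refuses inseparable settings. The tree generator grows a random
topology by sequential leaf attachment with uniform branch lengths
(0.05–0.5) and evolves sequences by per-site Poisson substitution; its
patristic matrix is additive by construction (the four-point condition is
tested by brute force over quartets).

What the generator does **not** emulate: indels and alignment uncertainty,
codon structure, rate heterogeneity, horizontal transfer, overlapping
genes, pseudogenes and RNA genes, noisy or borderline domain hits, and
operon gaps near the threshold. Passing tests therefore demonstrate that
the machinery is correct under clean, separable conditions — not that a
200 bp cutoff or k-mer trees are accurate on hard real data.

## Problem sizes and numerical choices

The shipped checks use 50 seeded genomes (24 genes each) for operon and
cluster recovery, 100 random additive matrices of 4–12 leaves for NJ
equivalence, and 100 trees for Newick round-trips — sizes at which the
exhaustive oracles (subset search, quartet checks, brute-force grouping)
remain cheap while still exercising every code path. Branch lengths are
written with 6 decimal digits by default; distance-matrix symmetry is
checked to 1e-9; Q-criterion ties are resolved lexicographically so no
computation depends on floating-point comparison order.

## Known limitations

* The built-in k-mer distance is not a substitution model; for distant
  homologs use the external adapters.
* Redundancy reduction computes exact global alignments (Needleman–Wunsch
  via Biostrings) pairwise against representatives — quadratic, intended
  for the hundreds-of-sequences scale, not CD-HIT's millions.
* Operon calls use distance and strand only; no transcriptomic evidence.
* GenBank-format annotation is out of scope; annotations enter as GFF3.
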