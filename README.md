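# phylotracks

Protein families in their phylogenomic context, offline.

When studying a protein family — say, a set of chemoreceptor homologs
collected by BLASTP — two questions come up immediately: *what is the
domain architecture of each member*, and *what genes surround each member
on its genome*? Conserved gene neighborhoods and operon membership are
among the strongest functional clues available for prokaryotic proteins,
and both only become interpretable when laid out against the family's
phylogeny. `phylotracks` computes exactly that view for microbial
comparative genomicists: a tree whose leaves are the query proteins, with
a per-leaf evidence track, exported as deterministic JSON and SVG.

Two pipelines share one core model:

* **domains** — filter raw domain hits (HMMER per-domain table or generic
  TSV) by independent E-value (default ≤ 0.01), resolve overlaps greedily
  by bit score (≤ 20% overlap of the shorter hit tolerated), build or
  accept a tree, and sort the MSA rows into the tree's leaf order.
* **neighborhoods** — extract up to *w* genes on each side of every query
  gene (default *w* = 5), cluster genes whose proteins share domain
  content, and call operons.

The two quantitative rules at the core:

* Genes *i*, *j* belong to one cluster when their domain-accession sets
  A, B satisfy |A Δ B| ≤ k (symmetric difference; default k = 0, i.e.
  identical sets), extended by single linkage; domain-less genes never
  cluster.
* Adjacent genes are linked into an operon when the intergenic distance
  `start(next) − end(prev)` ≤ **200 bp** (inclusive; the classical
  co-transcription cutoff, user-adjustable) and, by default, both genes lie
  on the same strand; operons are maximal linked runs of ≥ 2 genes.

Trees come from a user Newick file, from an external aligner/tree-builder
via command templates (`mafft --quiet {input} > {output}`,
`fasttree -quiet {input} > {output}`), or from the built-in deterministic
backend: k-mer set distance `d = 1 − |K_i ∩ K_j| / min(|K_i|,|K_j|)`
followed by neighbor joining (Saitou–Nei, with deterministic tie-breaks
and non-negative branch lengths).

## Worked example

Four query proteins against a synthetic two-replicon genome with planted
operons and domain families:

```r
library(phylotracks)

fx   <- synth_genome(fixture_spec(seed = 7))
qpid <- fx$annotation$genes$protein_id[
  match(fx$truth$queries, fx$annotation$genes$gene_id)]

res <- run_neighborhoods_pipeline(paste(qpid, collapse = "\n"),
                                  fx$annotation, hits = fx$hits,
                                  sequences = fx$proteins)
res
#> <neighborhoods_result> 4 queries, 21 genes, 3 clusters, 3 operons

glance(res)
#> # A tibble: 1 × 7
#>   n_queries n_genes n_clusters n_operons window nonshared_max operon_gap_max
#>       <int>   <int>      <int>     <int>  <int>         <int>          <int>
#> 1         4      21          3         3      5             0            200
```

The 4 query neighborhoods cover 21 distinct genes; their proteins fall
into 3 domain-content clusters, and 3 operons lie inside the windows
(`operon_gap_max = 200` is the applied default, recorded in the output).
Per-gene detail, one row per gene per neighborhood:

```r
head(tidy(res)[, c("gene_id", "leaf_name", "offset", "strand",
                   "cluster_id", "operon_id")], 5)
#> # A tibble: 5 × 6
#>   gene_id   leaf_name      offset strand cluster_id operon_id
#>   <chr>     <chr>           <int> <chr>       <int>     <int>
#> 1 rep01_g01 WP_000001005.1     -4 -               1         1
#> 2 rep01_g02 WP_000001005.1     -3 -               2         1
#> 3 rep01_g03 WP_000001005.1     -2 -               2         1
#> 4 rep01_g04 WP_000001005.1     -1 -              NA         2
#> 5 rep01_g05 WP_000001005.1      0 -               1         2
```

`offset` positions each gene relative to the query (0 = the query itself);
`cluster_id = NA` marks a domain-less gene, which by design never joins a
cluster. Genes g1–g3 form one operon (co-oriented, 50 bp gaps), g4–g5 a
second.

Export and drawing (fill = cluster, border color = operon, thick border =
query; tooltips embedded as SVG `<title>`):

```r
export_json(res, "family.neighborhoods.json")
render_svg(assemble_render_model(res), "family.svg")
autoplot(res)   # ggplot2 version of the same tracks
```

The domains pipeline follows the same pattern:

```r
dres <- run_domains_pipeline(fx$proteins[1:6, ], hits = fx$hits)
glance(dres)
write_newick(dres$tree)
```

A thin CLI wraps the same functions
(`inst/exec/phylotracks fixtures|domains|neighborhoods ...`).

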