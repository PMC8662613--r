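# orthomapper

Orthology-aware functional annotation of proteins and assembled contigs,
as an R package. It is written for people who need a complete, inspectable
annotation workflow at teaching/benchmark scale: metagenomics students and
method developers who want every stage — gene calling, homology search,
orthology resolution, term transfer, domain calling — exposed as a tested
function with a ground-truth simulator behind it, rather than a black box
bound to a multi-gigabyte external database.

## What it computes

Given query proteins (or contigs, or nucleotide reads) and a reference
database of proteins organised into hierarchical orthologous groups (OGs)
over a taxonomy, for each query `q`:

1. **Seed ortholog** — the best local alignment hit under affine-gap
   Smith–Waterman (BLOSUM62, gap open 11 / extend 1), with
   Karlin–Altschul statistics: bit score
   `S' = (λS − ln K)/ln 2` (λ = 0.267, K = 0.041), reported at
   E ≤ 1e-3 and S' ≥ 60. Presets `fast` (k-mer seed k=5, ≥2 shared),
   `sensitive` (k=3, ≥1) and `iterative` (fast, then sensitive on the
   unmatched remainder). Nucleotide queries are handled by six-frame
   translation (blastx-like) or by a built-in prokaryotic ORF finder
   (table 11 starts ATG/GTG/TTG, normalised to M).
2. **Taxonomic scope** — the most specific OG of the seed spanning
   ≥ `min_species` species (automatic mode), or the most specific OG at
   or above a requested taxon (lineage-fixed mode).
3. **Ortholog set** — scope-OG members paired with the seed in the
   pairwise-orthology relation; unpaired co-members are in-paralogs and
   are excluded; pairs are typed one2one / one2many / many2one /
   many2many by co-ortholog counting.
4. **Annotation transfer** — per source (GO, KEGG, EC, BiGG, CAZy, name),
   the union of the orthologs' terms, or a majority rule
   (`policy = "majority"`, fraction `f`).
5. **Domains** — transferred from the seed through the alignment columns,
   optionally refined by PSSM rescoring against a gathering (GA)
   threshold, or called de novo with clan competition between
   overlapping same-clan hits.

The `simdata` module simulates the whole world — species tree, duplication–
loss gene families, sequence evolution, paralog-divergent functional terms,
planted domains — and emits a valid database plus a held-out query species
with an answer key, so precision/recall of every mode is measurable offline.

## Worked example

```r
library(orthomapper)

bm <- emit_benchmark(sim_params(n_species = 8, n_families = 12,
                                root_length = 120, seed = 42))
bm$db
#> ref_db: 89 proteins / 7 species, 82 OGs, 276 ortholog pairs,
#>         267 annotation rows, 6 domain models

res <- annotate(bm$queries, bm$db, domain_mode = "refine")
length(res$annotations)   #> 15   (all 15 held-out queries annotated)
res$annotations[[1]]
#> annotation f001_t11_g1: seed=f001_t14_g1 og=clade02 name=fam1
#>   GO: GO:0000101,...,GO:0000108
#>   KEGG_ko: ko:K00001
```

The first query's seed is its true ortholog in a sister species
(`f001_t14_g1`), the chosen scope is the `clade02`-level OG, and the
transferred GO set is exactly the family's ancestral term set — which the
answer key (`bm$key`) confirms. `write_annotations()` renders the fixed
17-column report; the first data row of this run is:

```
f001_t11_g1  f001_t14_g1  8.219e-66  243.0  OG0001@10@clade10,OG0001@5@clade05,OG0001@2@clade02,OG0001@1@clade01
             clade02  J  simulated family 1  fam1  GO:0000101,...  -  ko:K00001  -  -  -  -  PF0001
```

i.e. seed, E-value and bit score, the seed's OG memberships deepest-first,
the scope level, COG category, description, preferred name, per-source
term sets (`-` = empty) and the refined PFAM-style domain call.

A command-line wrapper (`inst/cli/orthomapper.R`) exposes `simulate`,
`annotate` (protein / CDS / contig input, GFF decoration included) and
`decorate` subcommands.

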