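# fraglib

Design tool for building large protein mutant libraries the fast way:
instead of one mutagenesis PCR per mutant, each mutant is created by
inserting a synthesized double-stranded DNA (dsDNA) fragment — carrying the
mutation(s), silent marker codons and short homology flanks — into a single
PCR-linearized plasmid via in vivo assembly (IVA) cloning. One
linearization PCR serves every mutant whose mutations fall in the same
stretch of the gene, so a library of dozens of mutants needs only a handful
of PCRs and one parallel transformation step.

`fraglib` is for molecular biologists and protein engineers planning such
libraries. From a plasmid (GenBank), the gene of interest (FASTA) and a
plain-text mutation list (point mutations `L123A`, combined mutations
`G45D+S210R`, deletions `del70-75`, insertions `ins12-GSGS`), it produces
order-ready outputs: per-mutant annotated GenBank files, a CSV order sheet
in 96-well layout, and a text map of the fragment regions.

## The method in brief

* **Clustering.** Mutations are mapped to bp positions on the CDS and
  grouped by K-medoids (PAM) on a constraint-modified distance matrix
  (distances within a combined mutation are multiplied by 0.01 to promote
  co-clustering, with a hard post-check). The cluster count *k* is swept
  upward, every clustering whose clusters all satisfy the synthesis limits
  is recorded, and an exact branch-and-bound refinement guarantees the
  selected partition is optimal for the chosen objective: `quantity`
  (fewest fragment regions = fewest PCRs) or `length` (fewest total bp =
  cheapest synthesis).
* **Size model.** For fragment limits [300, 1500] bp and ≥15 bp flanks, a
  cluster with wild-type span *s*, largest deletion *d* and largest
  insertion *i* (bp) needs a region of `max(s, 270 + d)` bp and is valid
  iff `region + i + 30 ≤ 1500` — the checks apply to the mutant fragment,
  the molecule actually ordered.
* **Fragments.** Substituted and inserted residues use the most frequent
  codon of the expression organism (computed from a CDS FASTA or a TSV
  table); two silent marker codons per fragment end make successful
  insertion detectable from a single junction read; flanks are exact
  plasmid subsequences, length-tuned to a 47–52 °C nearest-neighbor Tm.
* **Primers.** An outward-facing linearization pair flush with each region
  (lengths 18–30 nt, Tm 57–63 °C, pair ΔTm ≤ 3 °C) and plus-strand
  sequencing primers every 500 bp, with secondary-structure and off-target
  diagnostics.

See the methods vignette (`vignettes/fraglib-methods.Rmd`) for the full
model, parameter meanings and limitations.

## Worked example

A synthetic library on a 1500-codon gene: 24 mutations (18 point, 4 double,
2 deletions) concentrated in three hot-spot windows, the typical layout of
structure-guided mutagenesis on a large enzyme.

```r
library(fraglib)
paths <- write_case_study_inputs("example_inputs")   # plasmid.gb, gene.fasta, mutations.txt
b <- design_run(paths$plasmid, paths$gene, paths$mutations, out_dir = "example_out")
print(b)
#> design_bundle: 24 mutation(s) -> 3 fragment region(s), 24 fragment(s), total cost 375.25
print(b$fragments[[1]])
#> fragment 'toy552555_gene552555_r1_G100R': 301 bp (flanks 16/15), 4 silent marker(s), cost 15.05
print(b$linearization_pairs[[1]])
#> primer_pair (linearization): product 6630 bp
#> primer 'lin_r1_fwd' (+ strand @1743): TTCACTCAGCACCACCCCC  Tm 59.3 C, GC 0.63
#> primer 'lin_r1_rev' (- strand @1448): GGTGATGAGGTGATGGTATACGGAT  Tm 58.4 C, GC 0.48
```

The 24 mutations resolve into **3 fragment regions**, so the whole library
needs 3 linearization PCRs. Each mutant is one ~300 bp fragment (cost =
length × 0.05/bp here, so 15.05 per fragment); the order sheet assigns
wells A1, A2, … row-major:

```
            type                          name plate well length_bp  cost
1 dsDNA_fragment toy552555_gene552555_r1_G100R     1   A1       301 15.05
2 dsDNA_fragment toy552555_gene552555_r1_V103K     1   A2       301 15.05
3 dsDNA_fragment toy552555_gene552555_r1_W107E     1   A3       301 15.05
```

`example_out/` also contains one annotated GenBank per mutant (full mutant
plasmid with mutation, marker and primer features) and `region_map.txt`, an
ASCII map of regions and mutations along the gene.

The same pipeline is available from the shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fraglib", package = "fraglib"))')
$CLI design --plasmid p.gb --gene g.fasta --mutations m.txt --optimize quantity --out out/
$CLI validate --lengths 1:600:5 --replicates 10 --genes 3 --out sweep/
```

## How long can a variant be?

The simulation module answers the practical question of when a mutation set
stops fitting a single fragment. `run_sweep()` generates random 800-codon
genes carrying five random point mutations plus one controlled variant
(deletion/insertion of a given length, or a pair of point mutations a given
distance apart) and reports the fraction of panels with a complete design.
Under the default 300–1500 bp limits, deletions are never blocked by the
provider maximum, insertions fit up to 400 residues, and paired mutations
up to 489 residues apart (`designable_bound()` gives these closed forms).

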