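---
title: "Designing mutant libraries as synthesizable dsDNA fragments"
author: "fraglib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing mutant libraries as synthesizable dsDNA fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraglib)
```

## The problem

Generating many protein mutants one PCR at a time is slow: every mutant
needs its own primer pair, and mutations far apart in the gene need
sequential rounds of mutagenesis. A faster route is to order synthesized
double-stranded DNA (dsDNA) fragments, each carrying one or more mutations
plus short homology flanks, and insert them into a single PCR-linearized
plasmid by in vivo assembly (IVA) cloning: the linear fragment and the
opened vector recombine inside *E. coli* through their terminal homology,
with no ligase step. One linearization PCR can then serve an entire group
of mutants whose mutations fall in the same stretch of the gene.

`fraglib` automates the design side of this workflow. Given a plasmid
(GenBank), the gene of interest (FASTA) and a plain-text mutation list, it

1. clusters the mutations into *fragment regions* — codon-aligned intervals
   of the gene that each host a group of mutations;
2. designs one mutant fragment per mutation spec (codon-optimized
   substitutions, insertions or deletions, plus silent marker codons and
   Tm-constrained homology flanks);
3. designs the outward-facing linearization primer pair for each region and
   plus-strand sequencing primers covering it;
4. writes one annotated GenBank file per mutant, a CSV order sheet in
   96-well layout, and a plain-text region map.

## Mutation grammar

One mutation per line; `#` starts a comment. `XnY` is a point mutation
(wild-type amino acid `X` at residue `n` to `Y`); point specs joined by `+`
form a *combined* mutation whose members must end up in one fragment;
`del<i>-<j>` deletes residues `i..j` inclusive; `ins<i>-<PEPTIDE>` inserts
a peptide after residue `i`. Residues are 1-based. Duplicate labels are an
error rather than a silent dedup, since a duplicated line usually signals a
copy-paste mistake in a library sheet.

## Clustering model

Each mutation is mapped to a representative base-pair position on the
coding sequence (codon interval for points, affected interval midpoint for
indels) and to a bp *extent* it touches. The distance between two mutations
is the absolute bp distance between their positions; distances within a
combined mutation are multiplied by 0.01 so that partitioning around
medoids (PAM, via the `cluster` package) is steered towards co-clustering
them. The shrink factor only steers the search — a hard post-check rejects
any clustering that separates a combined group, so correctness never rests
on the heuristic.

A cluster is *valid* when a shared wild-type region can serve all its
members within the synthesis provider's limits. With fragment limits
`[300, 1500]` bp and minimum flanks of 15 bp, the interior floor is
`300 - 2*15 = 270` bp, and for a cluster with wild-type span `s`, largest
member deletion `d` bp and largest member insertion `i` bp:

* the region must be at least `max(s, 270 + d)` bp (covering all extents,
  keeping every mutant — including the most-deleting one — at the minimum
  fragment length), rounded up to a codon boundary;
* validity requires `region + i + 2*15 <= 1500`, i.e. the largest mutant
  fragment must fit the provider maximum.

The size checks apply to the *mutant* fragment, the molecule actually
synthesized, not to the wild-type span. A consequence worth knowing: long
deletions are never blocked by the provider maximum (the region grows while
the synthesized fragment stays at the minimum length), whereas insertions
hit the ceiling at `(1500 - 300)/3 = 400` residues and paired mutations at
a span of `3(L+1) + 30 <= 1500`, i.e. 489 residues apart. The
`designable_bound()` helper exposes these closed forms, and the test suite
asserts that the full pipeline agrees with them exactly at the boundaries.

The search over clusterings proceeds as in the underlying method: starting
from one cluster, PAM is run with an increasing number of clusters, every
all-valid clustering is recorded, and the sweep stops once every cluster's
span has fallen below the interior floor (further splitting cannot reduce
cost) or every mutation is a singleton. Because a medoid heuristic cannot
guarantee optimality — with combined pairs the optimal partition is
occasionally not contiguous in gene order — the sweep is complemented by an
exact branch-and-bound search (one run per objective) over assignments in
position order, with span-based pruning and a node budget of 2e5; the best
valid partitions it finds join the candidate list. For the panel sizes this
tool is used at (tens of mutations), the exact search completes well within
the budget, so the selected clustering is provably optimal for its
objective; if the budget were ever exhausted the PAM candidates still
guarantee a valid, near-optimal design.

Two selection objectives mirror the two things a lab optimizes:
`quantity` minimizes the number of fragment regions (fewest linearization
PCRs; ties broken by total region length), `length` minimizes the total
region length (cheapest synthesis; ties broken by fewer regions).

## Fragment construction

The region is the smallest codon-aligned interval covering the cluster,
expanded symmetrically to the required length; expansion that hits a CDS
boundary is shifted to the other side, and genes shorter than the region
spill into the plasmid backbone while keeping codon phase inside the CDS.

Within the region, point substitutions use the most frequent codon for the
target amino acid in the supplied codon-usage table; insertions are encoded
codon by codon the same way; deletions excise whole codons. Codon usage is
computed from a CDS FASTA of the expression organism (or read from a
three-column TSV); frequency ties break alphabetically so outputs are
reproducible. When no source is supplied, `design_run()` falls back to the
usage of the target gene itself — a crude stand-in that is deterministic
and always available, but a real design should use the expression host's
CDS collection, both for expression levels and because a small gene may
simply never use some amino acid, leaving no codon preference to consult.

Two silent marker codons (configurable) are placed at each end of the
mutant region: the codons nearest the end that sit inside the CDS, do not
belong to an intended mutation, and have a synonymous alternative (Met and
Trp codons, and stop codons, have none and are skipped). Markers let a
short sequencing read over either junction distinguish a true insertion
from re-circularized wild type without sequencing the whole insert. Markers
are kept inside the insert-only region — never in the flanks — so the
flanks stay perfectly homologous to the linearized vector ends.

Flanks are exact wild-type plasmid subsequences abutting the region
boundaries. Their length (15–60 bp) is chosen so the nearest-neighbor
melting temperature lands inside the 47–52 °C window, preferring the length
closest to the window midpoint; in pathological composition (e.g. long A/T
runs) the closest achievable Tm is used and a warning attached. When a
region sits near the provider maximum, flank lengths are capped so the
worst-case mutant fragment still fits.

## Melting temperature and primers

Tm uses the two-state nearest-neighbor model with the unified dinucleotide
parameter set, an entropic salt correction of `0.368 (N-1) ln[Na+]` at
50 mM monovalent salt, and an annealing concentration of `CT/4` with 500 nM
total oligonucleotide. These constants are stated here because flank and
primer lengths depend on them; tests pin the implementation against
independently computed reference values.

Linearization primers are flush with the region boundaries and face
outward, so the amplicon is the whole plasmid minus the region and its ends
are exactly homologous to the fragment flanks — the geometry IVA cloning
requires. Lengths 18–30 nt are scanned into a 57–63 °C window with a pair
Tm difference of at most 3 °C. Sequencing primers sit on the plus strand,
the first 100–200 bp upstream of the region, then one every 500 bp (an
800 bp read length leaves margin), each required to bind uniquely on the
plasmid and to meet the Tm and GC (0.40–0.60) windows, sliding by up to
±50 bp when a site fails.

Because linearization primers have no positional freedom, secondary
structure (inverted repeat with stem ≥ 4 bp and loop ≥ 3 nt; antiparallel
self-complementary run ≥ 8 bp) and off-target binding (3'-terminal 12-mer
occurring more than once on either strand) are treated as *diagnostics*:
candidates free of flags are always preferred, but when every candidate at
a pinned position carries a flag the best one is emitted with its flags
recorded and a warning raised, rather than aborting the whole library
design over a marginal 4 bp stem. Unique binding of the full primer and the
Tm windows remain hard requirements.

## The eligibility simulation

`run_sweep()` estimates, by simulation, how long an insertion or deletion
— or how distant a paired mutation — can be before a single-fragment design
stops being possible under given provider limits. Each test case is a
random gene (ATG, uniform non-stop codons, TAA; default 800 codons,
embedded mid-backbone in a random 2 kb circular plasmid) carrying five
random point mutations plus one controlled variant; the default grid is
3 genes × 10 replicates per condition, with per-case seeds derived
deterministically from the base seed so the sweep reproduces bit for bit.
A case counts as designable when clustering, region definition,
mutagenesis, flank design, marker placement and assembly all succeed for
the entire panel.

What the simulation does and does not emulate: random genes have uniform
codon composition and a uniform random backbone, so they exercise the
geometry and bookkeeping of the pipeline, not the pathologies of real
sequence (GC-rich repeats, homopolymers, synthesis-complexity screens —
explicitly out of scope). Success rates at the geometric boundaries are
therefore sharper than they would be on real genes, and a passing sweep
says the design logic is correct, not that every real-world order will
synthesize cleanly.

## Numerical and degenerate-input choices

* All internal bp coordinates are 0-based half-open on the gene's coding
  strand; user-facing residue numbers are 1-based; GenBank I/O converts to
  the format's 1-based closed convention at the boundary.
* Region lengths round *up* to codon boundaries; symmetric padding puts the
  odd codon on the 3' side.
* Codon-frequency ties, marker-codon choices and primer-length ties all
  break deterministically (alphabetical or closest-to-target), so a design
  run is a pure function of its inputs; GenBank output uses a fixed LOCUS
  date, making reruns byte-identical.
* Genes on the minus strand are designed entirely on the coding strand and
  mapped back at output time.
* A region that wraps the plasmid origin is substituted via rotation; the
  mutant GenBank then starts at the rotated origin (noted in the file).
* Empty mutation files, duplicate labels, wild-type mismatches,
  out-of-bounds residues, ambiguous or absent gene placements and oversized
  clusters all fail with errors naming the offending label.

## Problem sizes used in the test suite

The shipped tests run the sweep at the three headline variant lengths
(115/185/230 residues) with 3 genes × 10 replicates per condition, check
clustering optimality against exhaustive partition enumeration on 200
random panels of up to 8 mutations, and verify protein-level fidelity of
500 designed fragments on genes of 120–300 codons. These sizes keep the
default suite fast while leaving the estimators meaningful; the full-scale
sweep (lengths 1–600 step 5) is available through `validate_run()` or the
command-line `validate` subcommand.

## Known limitations

* One fragment per mutant: a mutation set too spread out for one region is
  reported as undesignable rather than split across several fragments
  (multi-fragment assembly is a possible extension). The practical
  workaround is to pre-introduce one distant mutation and rerun from the
  pre-mutated plasmid.
* GenBank only; SnapGene `.dna` is a proprietary binary format and is
  refused with a pointer to export as GenBank.
* The GenBank parser handles plain `a..b` and `complement(a..b)` feature
  locations — enough for plasmid maps from common editors, not arbitrary
  flat files.
* No vendor synthesis-complexity screening (homopolymer/GC windows) and no
  cross-dimer checks between primers of different pairs.
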