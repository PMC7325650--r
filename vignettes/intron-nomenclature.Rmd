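---
title: "Naming introns in fungal mitochondrial protein-coding genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naming introns in fungal mitochondrial protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonom)
```

## The problem

Fungal mitogenomes carry a standard set of 15 protein-coding genes (*atp6*,
*atp8*, *atp9*, *cob*, *cox1*, *cox2*, *cox3*, *nad1*–*nad6*, *nad4L*,
*rps3*), and these genes are frequently invaded by mobile group I and
group II introns. The literature has mostly numbered introns serially
within each gene of each genome (*cox1*-i1, *cox1*-i2, ...), which makes
names incomparable across species: the "first" *cox1* intron of one fungus
has nothing to do with the "first" of another. Because intron insertion
points are strongly conserved, a name anchored to a *position* transfers
across genomes.

mitonom implements such a position-anchored nomenclature. Every intron is
named on the coordinate axis of the corresponding intron-free gene of
*Tolypocladium inflatum* ARSEF 3280 (NC_036382), a mitogenome that carries
all 15 genes with no intron in any of them. A name has four mandatory and
three optional parts:

```
  Sce.cox1S169          Hau.cox3P640a         Hth.cobP429-1
  ^^^ ^^^^ ^ ^^^                   ^                     ^^
  |   |    | insertion site        twintron letter       variant number
  |   |    P = group I, S = group II, U = undetermined
  |   host gene
  species abbreviation
```

The type letter and insertion site may never be omitted; the species
abbreviation and gene name may be dropped when context disambiguates
(`cobP490`, `P717`). The canonical machine form uses an ASCII hyphen
before a variant number; the parser also accepts the typographic en-dash
seen in print.

## The coordinate axis

An insertion site is the number of reference CDS nucleotides 5′ of the
insertion point, 1-based, counted on the spliced reference gene. We count
the stop codon as part of the axis. Whether the stop codon belongs to the
axis is not fixed by published usage — every published site lies far from
a gene end, so the two conventions are indistinguishable in practice — and
including it keeps the axis equal to the annotated CDS length.

Site numbers expose intron phase directly: `compute_phase(site)` is
`site %% 3`, with phase 0 (between two codons) for sites divisible by
three, e.g. cobP393, and phases 1/2 for insertion after the first or
second codon position (cox1S205 → 1, cox1P386 → 2).

**The bundled reference is a synthetic stand-in.** The package ships
`inst/extdata/tinflatum_ref_synthetic.fasta`: 15 genes whose names and
lengths match a typical fungal mitogenome (every published insertion site
is a valid coordinate on its gene), but whose nucleotide sequences are
simulated (AT-rich, mold mitochondrial code, ATG…TAA). All coordinate
arithmetic, tests and examples are exact on this stand-in; for naming
introns in real data you must supply the genuine NC_036382 gene set:

```r
ref <- load_reference("tinflatum_genes.fasta")   # or a GenBank record
```

## Species abbreviations

The default abbreviation is the uppercase genus initial plus the first two
lowercase epithet letters (*Saccharomyces cerevisiae* → `Sce`). When two
species under study collide, all colliding species are re-abbreviated with
the smallest number of further epithet letters that separates them
(*Candida pseudojiufengensis* / *Candida psychrophila* → `Cpse` / `Cpsy`);
species that never collided keep their three-letter forms. This rule
reproduces all thirteen abbreviations in published usage of this
nomenclature. It is a reconstruction from those examples, not a rule
stated anywhere; manual overrides (`abbrev_registry(overrides = ...)`)
always win and are the escape hatch for pathological cases such as
congeneric genera sharing an initial and an epithet prefix.

## Locating the insertion point

For an annotated genome, `read_genbank_genes()` reconstructs exons and
introns from the CDS `join()` locations (minus-strand genes are handled in
transcription orientation; CDS spanning the circular origin are unwrapped;
fuzzy locations and `transl_except` are rejected, not guessed). Each
intron's host offset — its position on the host *spliced* CDS — is then
lifted onto the reference axis:

1. `align_to_reference()` aligns the host spliced CDS to the reference
   gene end-to-end (global, affine gaps). Defaults: match +2, mismatch −3,
   gap open 10, gap extension 1 per position (a gap of length L costs
   `10 + L`). Alignment identity below `min_identity` (default 0.30) sets
   a `low_confidence` flag — a warning, never an error, because even
   unrelated DNA pairs ~40–50% of columns under an optimal global
   alignment.
2. `map_insertion_site()` finds the alignment column holding host
   nucleotide N and counts reference nucleotides up to and including that
   column. If that column is a gap in the reference row (the insertion
   point falls inside host-only sequence), the 5′-nearest reference
   coordinate is reported and the result is flagged `gap_adjacent`. This
   mirrors common liftover practice; published usage is silent on the
   case.

Determinism matters because names are identifiers: for fixed inputs and
parameters the production aligner's traceback is deterministic, so
repeated runs give byte-identical names. We rely on the aligner's own
deterministic tie-breaking rather than enforcing a particular gap-pushing
direction; the mapping tests (identity, substitution-invariance, and
indel-consistency batteries) pin the behaviour that matters.

The production alignment score is cross-checked in the test suite against
an independent plain quadratic Gotoh implementation
(`alignment_score_dp()`, textbook recurrences in C++) on random pairs up
to 1 kb — two independent routes to the same optimum.

## De novo inference from raw regions

When annotations are missing or wrong, `infer_introns()` works from a raw
gene region (exons plus introns):

1. **Anchoring.** Exact 12-mers sampled every 3 nt of the reference are
   located in the region. No hits → `gene_not_found`. If fewer than 70% of
   the anchored reference positions fit one increasing chain, the region
   is not co-linear with the reference → `rearrangement_suspected`.
2. **Intron-tolerant alignment.** The region is aligned to the reference
   end-to-end *in the reference* (region ends are free), with the gap
   extension lowered to `intron_gap_extend` (default 0.2) so that an
   intron-length host-only run is cheaper than misaligning the downstream
   exon. Host-only runs of at least `min_intron` (default 30) nucleotides
   become candidate introns.
3. **Boundary refinement.** Each candidate interval may slide within
   ±12 nt. A placement is scored by how well the exon flanks it implies
   match the reference around the junction (12-nt windows each side),
   plus a half-point bonus when the intron carries a group I/II splice
   signature (group I introns end in G; group II introns end in AC/AT
   with a GTGYG-like 5′ terminus, one mismatch tolerated). Ties prefer
   the unshifted placement, then the smaller shift, and are flagged
   `ambiguous`.

Short exons are the known hard case: a 25-nt exon between two introns
survives because the chained alignment keeps it anchored and refinement
only moves boundaries locally.

One genuine limit is worth stating: when an intron's terminal nucleotides
repeat the adjacent exon sequence, two placements can yield the *identical*
spliced CDS with equally valid splice signatures. No sequence-based method
can separate them; the site is then reported from the preferred placement
and the ambiguity surfaces in the boundary confidence. Annotated inputs do
not suffer from this — the `join()` fixes the boundary.

## Intron types

Structural typing of group I/II introns is delegated to external tools;
`read_type_table()` consumes their verdicts (accession + gene + intron
serial number or host offset → type) and external evidence always wins.
The built-in `heuristic_type()` looks only at terminal signatures and is
deliberately conservative: its verdict is rendered as letter U unless
`trust_heuristic = TRUE`, because P and S assert a determined type.

## Twintrons and strain variants

Two or more introns of one genome at one site (a twintron) are lettered
`a`, `b`, … in 5′→3′ order of their genomic start in transcription
orientation; for nested members the outer intron precedes the inner. The
outer-first choice for nested pairs is a package decision — alphabetical
naming of internal/external members is established, which member is `a` is
not. In GenBank input, side-by-side or nested members inside one CDS gap
are recognized from `intron` features that tile or nest within the gap (a
`join()` alone cannot express them).

Dissimilar introns occupying one site in different strains of one species
get numeric suffixes: pairwise global-alignment identity (matches over
alignment columns), single-link clustering, clusters at or above
`variant_identity` (default 0.90) share a number, numbers assigned in
first-registration order. A single cluster — the common, conserved case —
yields no number at all.

## Cross-species comparison

`build_site_matrix()` arranges labels as species × gene cells;
`summarize_sites()` counts, per gene, introns (with multiplicity), species
carrying at least one intron, and distinct insertion points, where an
insertion point is the site *integer*: type letters and twintron letters
are ignored (a P and a U at one site are one point, two introns; twintron
members are multiple introns at one point). Re-tallying the bundled
16-genome survey table under these rules gives 149 introns; the per-gene
intron totals equal the survey's own summary row, and the distinct-point
counts are asserted against an independent recount of the table's rows.
Gene absence renders as `--` and missing data as `NA` in written matrices.

## The synthetic-fixture generator

`generate_fixture()` plants introns at known reference sites into mutated
copies of the reference genes, so every downstream claim can be checked
against exact truth without downloads. It emulates:

* neutral divergence — per-site substitutions (default 0.15, the
  mid-range of congeneric mitochondrial protein-gene divergence) and
  short indels (rate 0.01/site, lengths 1–10);
* a 20-nt mutation-free guard window around each planted site, so the
  planted truth stays exact (boundary-stress cases that violate the guard
  belong in separate, clearly named batteries);
* group I/II terminal signatures (5′ T … G 3′; 5′ GTGCG … AT 3′) around
  random cores GC-matched to the host gene (±5%), so intron and exon are
  not trivially separable by composition;
* annotated GenBank output (CDS `join()` plus `intron` features) or raw
  FASTA regions; for raw regions, plants whose terminal repeats would make
  the insertion point genuinely unrecoverable (see above) are redrawn.

It does not emulate intron secondary structure, intron-encoded ORFs,
homing-endonuclease footprints, compositional heterogeneity along genes,
sequencing error, or wrong annotations. Passing the recovery batteries
therefore shows the coordinate machinery is exact under realistic
divergence — not that boundary calls on real, structured introns are
infallible; for real data the external typing table and curated
annotations carry that weight.

`generate_strain_variants()` emits one species in several strains whose
same-site introns come from k unrelated cores (within-group divergence
~2%, between-group unrelated), encoding the expected variant numbering in
contiguous registration blocks.

## Problem sizes and tolerances used by the test suite

All stochastic batteries run under fixed documented seeds. The suite
checks, among others: a 10,000-name grammar round-trip; phase for every
label in the bundled survey; exhaustive self-alignment mapping identity on
the shortest gene and ≥1,000 sampled offsets across the rest; 100
substitution-only liftover fixtures at divergence up to 0.30 and 20
indel-bearing fixtures with indels ≥20 nt from the site (100% site
recovery required in both); 200 annotated fixtures at divergence 0.15
(100% recovery of site, letter and twintron suffix); strain batteries for
variant numbering; and score equality with the DP oracle on 100 random
pairs ≤1 kb. These sizes are the package's own validation choices and run
in about a minute on a laptop-class CPU.

## Known limitations

* The bundled reference is a labelled synthetic stand-in; sites computed
  against it are internally consistent but only match published site
  numbers when the genuine NC_036382 gene set is supplied.
* Nucleotide-level alignment only; a translated (protein-level) mode would
  help at extreme divergence.
* No rRNA (rnl/rns) coordinates — rRNA introns have their own established
  nomenclature — and no plant-specific genes (*nad7*, *ccmC*, *rps10*,
  *rpl2*), which would need an additional reference.
* Trans-spliced CDS and fuzzy annotations are rejected rather than
  interpreted.
* Uniqueness of names is per-dataset; there is no global registration
  authority.
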