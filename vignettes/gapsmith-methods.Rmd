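---
title: "Curating a reference assembly against donor assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a reference assembly against donor assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapsmith)
```

# The problem and the model

A chromosome-level reference assembly marks unresolved regions with runs of
`N`. Some runs have *arbitrary* placeholder lengths (25 or 200 bp), others
encode a size *estimate*. These gaps concentrate in extended repetitive
regions, sometimes inside gene bodies; distal telomeres may be missing; and
some scaffolds remain unplaced. gapsmith repairs these defects from donor
assemblies of the same genome, under one central assumption:

> gene content, order and orientation are locally conserved between the
> reference and its donors, so a gap's flanking genes identify the
> homologous, intact region of a donor.

Donors come in two classes with different trust levels. A *re-assembly* is
built from the reference's own reads: any sequence recovered from it is
(up to assembly error) the reference individual's own haplotype, which is
why a validated re-assembly candidate always outranks an alternative-strain
candidate. An *alternative* assembly derives from a related strain and may
carry real sequence divergence; competing alternatives are arbitrated by
read-depth support.

## Coordinates

All coordinates are 1-based closed intervals — the native convention of
GFF3, of the depth-tool output consumed here, and of the Bioconductor
ranges stack this package is built on. Because every boundary (file
formats, IRanges, Biostrings) already speaks this convention, there is no
conversion point anywhere in the code, which is the cheapest way to avoid
off-by-one drift.

# Stages, parameters and rationale

## Gap census

`find_gaps()` reports maximal N-runs of length at least `min_run`
(default **10 bp**). The default ignores isolated ambiguous bases while
safely catching the shortest placeholder gaps (25 bp) seen in practice;
it is configurable. Classification is a pure function of run length:
`arbitrary` iff the length is exactly in `arbitrary_lengths`
(default {25, 200}), else `estimated`. Flank context uses gene bodies
only; ties on identical coordinates break by lexicographic gene id. A gap
with no gene on one side cannot be anchored by this method and is reported
`closable = FALSE`. By default only `chromosome`-role records are scanned;
N-runs inside unplaced scaffolds are not part of the census (configurable
via `role = NULL`).

## Anchoring aligner

The built-in aligner (`builtin_anchor_align()`) is deliberately simple and
fully deterministic: exact k-mer seeds (default **k = 21**) on both
strands, banded dynamic-programming chaining that maximizes the number of
collinear seeds, identity estimated as matched-seed span over chained
target span, and query coverage as the fraction of non-N query bases under
chained seeds. Three guards matter:

* `max_occ` (default **64**) drops seeds from k-mers occurring more often
  than this in the target, so tandem repeat arrays cannot flood the chain.
* `max_join` (default **5000 bp**) caps the query- and target-side distance
  bridged by one chain step. Without it, the two copies of a duplicated
  gene would merge into one long fake chain; with it they surface as two
  separate chains and the marker is flagged `duplicated` and excluded —
  duplicated genes are a known cause of telomere mis-anchoring.
* the chained span is extended to the full query extent (an ungapped
  estimate), so anchor boundaries stay exact when terminal seeds are killed
  by point mismatches.

Acceptance thresholds `min_identity = min_coverage = 0.9` tolerate
subspecies-level point divergence (at 1% divergence the k-mer identity
estimate stays near 0.98) while rejecting paralogs. These thresholds are
this package's choices, documented rather than inherited from any specific
external mapping tool; the aligner is a *contract* — any function with the
same signature can be passed via the `aligner` argument, e.g. an adapter
around an external long-read mapper.

## Extraction and flank validation

For intergenic gaps the replaced interval runs from the end of the upstream
gene to the start of the downstream gene; for within-gene gaps the whole
containing gene is replaced by the donor's complete gene. Within-gene gaps
are anchored by the N-free gene fragments on either side of the run, so the
N-run itself never degrades the anchor.

Flank validation re-derives locality independently of the anchors: the
**100 bp** of donor sequence immediately outside each GCS end must place
onto a bounded reference window adjacent to the replaced interval at
**≥ 0.95** identity, with the placement within `adjacency_tol = 20 bp` of
the interval end. Flank identity is computed by an exact sliding *ungapped
Hamming* scan rather than by the k-mer chain statistic: on 100 bp fragments
the chain estimate is granular (one mismatch shadows a 21-mer
neighbourhood) whereas the Hamming count is exact — five substitutions in
100 bp give identity 0.95 precisely. The 20 bp adjacency tolerance absorbs
small indel jitter between donor and reference. The same machinery, at
**200 bp**, re-verifies every junction after splicing (and checks a 50 bp
N-free window for gap closures); events that fail are rolled back and their
gaps reported open.

The Hamming scan is exact but ungapped; a donor with an indel inside a
validation flank loses identity linearly in the displaced suffix. This is
conservative in the right direction (flanks are rejected, the gap stays
open with a reason) but means indel-rich donors under-close; see
*Limitations*.

## Ranking

Selection is a total, deterministic order: validated re-assembly candidates
first; then higher mean depth over the donor-side GCS span; ties by lower
CV, then shorter GCS, then donor id. "Best depth" is defined as
mean-then-CV as a documented policy — depth uniformity (CV) is the natural
second criterion once means tie, but other summaries (breadth at a
threshold) would be defensible. Depth tracks are supplied per *donor*
(reference reads mapped to each donor assembly), because the quantity being
compared is read support over the candidate span in its donor context.
Without depth tracks the depth keys drop out of the order and the
structural tie-breaks decide.

## Splicing, liftover, annotation

Events are applied right-to-left within each sequence so recorded pre-edit
intervals never need rewriting; the induced liftover chain is monotone and
invertible outside edits. Genes wholly outside edits shift; a gene whose
body *is* a replaced interval (within-gene closure) is re-anchored to the
inserted span, exactly — re-anchoring, not proportional interpolation,
because the donor gene's length generally differs from the gapped
reference gene's. Edited chromosomes are renamed with a `cor_` prefix;
genes are never silently dropped (irreconcilable overlaps are flagged
`review`).

## Telomeres

The insect telomeric repeat TTAGG (reverse complement CCTAA) is scanned in
non-overlapping windows of **1 kb**; a distal telomere is called present
when any window in the terminal **10 kb** reaches **0.4** combined motif
coverage. These three values are this package's defaults, exposed in the
configuration: telomeric arrays are near-pure tandem repeat (density ≈ 1)
while the genomic background density is below 0.01, so the call is
insensitive to the exact threshold over a wide range. Recovery replaces
the span from the terminal anchor gene's outer boundary to the chromosome
end with the donor's matching span, making the corrected anchor-to-end
distance equal the donor's by construction. A duplicated terminal anchor
gene is a hard error rather than a guess.

## Placement and redundancy

A scaffold is placed when at least `min_support = 3` donors agree on the
reference chromosome, an overlapping target interval, and orientation —
"more than two assemblies" read literally; with only a handful of donors
available the parameter is configurable. The donor locus is translated
back to reference coordinates through the reference genes whose donor
positions bracket the scaffold's genes. A consensus interval overlapping a
gap records the scaffold as `close_gap`.

Redundancy is decided *after* splicing: a scaffold aligning at ≥ 0.9
coverage and ≥ 0.98 identity whose footprint intersects an inserted span is
deleted — its content is now represented in the corrected chromosomes. A
scaffold that aligns equally well but entirely *outside* inserted spans is
retained with a note: it duplicated the reference before curation and
removing it is not this workflow's decision. Bookkeeping counts the full
length of removed scaffolds as "scaffold bp resolved", matching how such
curation efforts are usually totalled (a scaffold that closed a gap and was
then deleted is counted once, by its length).

# The synthetic truth set

`generate_truth_set()` builds the study the tests run against; all outputs
are pure functions of `(config, seed)`. The default configuration *is* the
package's reference study condition:

* 3 chromosomes × 500 kb, 50 genes each (gene bodies 1.5–4 kb, intergenic
  2–8 kb), CCTAA/TTAGG arrays of 2 kb at the ends;
* 12 planted gaps across the four-site-per-chromosome plan: intergenic and
  within-gene, arbitrary (25/200 bp) and estimated classes, tandem-repeat
  arrays planted around intergenic gap sites so flank validation faces
  realistic decoys;
* 10 of 12 gaps closable: two loci carry an N-run in *every* donor
  (all assemblies failing in the same repetitive region), and one further
  locus is gapped only in the re-assembly donor, forcing depth-arbitrated
  selection among alternatives;
* 2 truncated right telomeres;
* 5 scaffolds: one gene-bearing region excised onto an unlocalized
  scaffold (it both closes its gap by consensus and ends up redundant), two
  planted redundant copies of replaced spans, one novel sequence and one
  copy of an untouched region (both retained);
* donors: one re-assembly at divergence 0; two alternatives at 1% point
  substitutions, one with a local inversion spanning a gap region; depth is
  Poisson(mean 35) per base with a planted dropout (mean 2) in one
  alternative over the alternative-only gap.

Unit tests use the same plan scaled to 3 × 160 kb with 20 genes per
chromosome so the suite stays fast; the acceptance checks run the full
default scale.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: read-level error profiles (depth is sampled,
not simulated from read placement), structural variation beyond local
inversions, segmental duplications larger than single genes, haplotype
divergence within the reference individual, and assembly chimeras. Passing
the truth-set checks shows the machinery is correct under the stated model,
not that any particular real assembly pair satisfies the model.

# Numerical and degenerate-input choices

* Gap ids are positional (`chr_gapN` left to right) and stable under
  re-runs; all stages are RNG-free, so identical inputs give identical
  outputs bit for bit.
* Ambiguity codes other than N are coerced to N on ingest (counted and
  messaged): the census is defined on N-runs, and a rare IUPAC code inside
  an anchor would otherwise silently break exact seeding.
* Zero-width replaced intervals (pure insertions) are legal events;
  zero-length replacement strings are legal deletions.
* A candidate whose validation flank falls off the donor sequence end is
  *unassessable*, not validated: it keeps `candidate` status with a
  warning and can never be selected.
* Two gaps inside one gene share one replaced interval; the splice engine
  deduplicates the event and both gaps are reported closed by it.
* `coverage_stats` defines CV = 0 when the mean is 0 (an all-dropout
  interval carries no uniformity information).
* Telomere-graft events whose replaced interval would overlap a gap-close
  event are dropped with a note (the gap closure, which carries more
  validation, wins).

# Problem sizes used by the checks

The packaged checks run the default 3 × 500 kb study for the end-to-end
recovery criteria, twenty further seeded studies through the selection
stage for the no-false-splice property, 10⁴ random positions for liftover
invertibility, and randomized sequences against a regex oracle for the gap
finder. The whole suite completes in a few minutes on one core.

# Limitations

* The anchoring aligner is a desk-scale chainer, not a general-purpose
  mapper: it assumes mostly-collinear, low-divergence homology and is not
  suitable for cross-species liftover. For diverged donors, plug an
  external mapper into the `aligner` contract.
* Ungapped flank validation is conservative under indels (real candidates
  may be rejected); the adjacency tolerance absorbs only ±20 bp.
* Exon-level reconciliation of donor and reference gene structures inside
  replaced regions is out of scope: replaced genes are re-anchored as whole
  intervals and flagged for review where structures disagree.
* Scaffold placement requires annotated genes on the scaffold; gene-free
  scaffolds are reported `unresolved(no_markers)`.
* The redundancy rule never deletes scaffolds that were duplicated before
  curation; deciding those requires evidence outside this workflow.
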