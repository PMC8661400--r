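# gapsmith

Assembly-to-assembly gap closing and reference curation for chromosome-level
genomes.

Chromosome-level reference assemblies routinely carry residual defects:
polyN gap runs in hard-to-assemble repetitive regions (some placed inside
gene bodies), missing distal telomeres, and scaffolds that could not be
placed on a chromosome. When *independent long-read assemblies of the same
genome* exist — re-assemblies built from the reference's own reads, or
assemblies of closely related strains — those defects can be repaired
without any new sequencing: each gap's flanking genes act as synteny
anchors that locate the corresponding intact region in a donor assembly,
and the donor sequence between the anchors is excised and spliced into the
reference. gapsmith automates this assembly-to-assembly curation workflow
for genome maintainers and comparative genomicists.

## The method

For a reference *R* with annotation *G* and donor assemblies
*D₁ … Dₙ* (each labelled *re-assembly* or *alternative*):

1. **Gap census.** Maximal N-runs of length ≥ `min_run` are detected per
   chromosome, classified *arbitrary* (placeholder lengths, by default
   exactly 25 or 200 bp) or *estimated*, and annotated with their upstream,
   downstream and containing genes.
2. **Anchoring.** Each gap's marker intervals — the flanking gene bodies,
   or for within-gene gaps the N-free gene fragments on either side of the
   run — are located in every donor with a k-mer seed-and-chain aligner
   (exact 21-mers, banded collinear chaining, identity = matched-seed span /
   chained span). Markers that are duplicated in a donor are excluded.
3. **GCS extraction.** The gap-closing sequence (GCS) is the donor span
   between the anchors (or the donor's complete gene, for within-gene gaps),
   reverse-complemented when the donor region is inverted relative to the
   reference. Donors carrying their own N-run in that span are rejected
   (`donor_gapped`).
4. **Validation.** The 100 bp of donor sequence immediately outside each GCS
   end must place back (exact ungapped scan) onto the reference adjacent to
   the replaced interval with ≥ 0.95 identity — this rejects candidates
   extracted from paralogous repeat arrays.
5. **Ranking.** Any validated re-assembly candidate beats all alternative
   ones; within a class the best mean read depth over the donor span wins
   (CV, length, donor name break ties).
6. **Splicing and liftover.** Selected GCSs replace the span from the end of
   the upstream flank gene to the start of the downstream one (or the whole
   containing gene). Edits are applied right-to-left; an old→new liftover
   chain shifts untouched annotations and re-anchors replaced genes. Every
   junction is re-verified post hoc with 200 bp flanks; failing events are
   rolled back.
7. **Telomeres.** Chromosome ends are scanned for TTAGG/CCTAA density
   (1 kb windows); ends without a telomeric window within the terminal
   10 kb are repaired by grafting the donor span beyond the terminal anchor
   gene, so the corrected anchor-to-end distance equals the donor's.
8. **Scaffold placement and redundancy.** Unlocalized scaffolds are placed
   where the gene location, order and orientation agree in at least three
   donors; after splicing, scaffolds whose sequence aligns (≥ 0.9 coverage
   at ≥ 0.98 identity) into replaced regions are removed as redundant.

The result is a corrected assembly (`cor_`-prefixed chromosomes), a lifted
annotation, an AGP-like edit ledger with a JSON log, and a curation report
whose totals satisfy
`grand_total = closed gap bp + telomere bp + removed scaffold bp`.

## Worked example

The package ships a seeded generator that builds a complete synthetic study:
a truth genome, a degraded reference (12 planted gaps, two truncated
telomeres, five scaffolds), three donors and per-donor depth tracks.

```r
library(gapsmith)

cfg <- truth_config(chromosome_length = 160000L, genes_per_chromosome = 20L,
                    intergenic = c(800L, 2500L))
ts  <- generate_truth_set(cfg, seed = 7)
cur <- curate_assembly(ts$reference, ts$genes, ts$donors, depth = ts$depth)

glance(cur)
#> # A tibble: 1 × 8
#>   n_gaps_before n_gaps_closed closed_bp n_telomeres_recovered telomere_bp
#>           <int>         <int>     <int>                 <int>       <int>
#> 1            12            10     46809                     2       90898
#> # ℹ 3 more variables: n_scaffolds_removed <int>, scaffold_bp <int>,
#> #   grand_total_bp <int>

tidy(cur)
#> # A tibble: 10 × 5
#>   gap_id    gap_bp replaced_bp gcs_source gcs_bp
#>   <chr>      <int>       <int> <chr>       <int>
#> 1 chr1_gap1  10543       13343 reFlye      13343
#> 2 chr1_gap2     25        2118 reFlye       4404
#> 3 chr1_gap3    200        3000 reFlye       8488
#> 4 chr1_gap4   1427        3683 reFlye       3683
#> # ℹ 6 more rows

cur$report$open_gaps[, c("gap_id", "length", "reason")]
#> # A tibble: 2 × 3
#>   gap_id    length reason
#>   <chr>      <int> <chr>
#> 1 chr3_gap1  10297 donor_gapped
#> 2 chr3_gap2     25 donor_gapped
```

Ten of the twelve gaps close (`gap_bp` is the N-run length, `replaced_bp`
the flank-to-flank span actually replaced, `gcs_bp` the donor sequence
pasted in); the two gaps left open sit at loci where *every* donor carries
its own N-run — the situation where all assemblies fail in the same
repetitive region — and are reported rather than forced. Both truncated
telomeres are recovered and the three scaffolds whose content is now
represented inside replaced regions are removed. `autoplot(cur)` draws the
closed/open gap map and `write_curation(cur, "out/")` writes the corrected
FASTA, lifted GFF3, edit ledger and report.

A thin command-line wrapper with `census`, `run`, `simulate` and
`summarize` subcommands is installed at `inst/cli/gapsmith.R`.

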