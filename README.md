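# exonpatch

Draft genome assemblies carry blocks of unknown sequence — runs of `N`
("N-islands") that stand in for sequence the assembler could not resolve.
Annotation pipelines are forced to call intronic N-islands entirely
intronic, yet such a block can hide one or more real exons whose sequence
exists nowhere in the assembly. `exonpatch` finds those hidden exons, with
exact splice junctions and flanking intronic sequence, by cross-examining
three inputs that do not trust the assembly at the gap: de-novo-assembled
transcript sequences ("transcript objects"), the reference transcript
models, and short genomic DNA reads. It is aimed at people curating or
proofreading genome annotations, and it works just as well as a validator
of de-novo transcriptomes (it flags chimeric, "track-crossing" assemblies
as a by-product).

## The method in brief

1. **Bridge test.** Ungapped local alignment (seed + x-drop, +1/−2) of each
   transcript object to each annotated spliced transcript. A junction
   spanned by one continuous HSP is *covered*; two HSPs flanking the
   junction with extra object sequence strictly between them make it
   *bridged* — the insert is candidate hidden-exon sequence; one HSP within
   50 nt of an N-flagged junction with a >60% unaligned tail is a
   *half-bridge*.
2. **Conservation test.** Does inserting the bridge sequence between the
   flanks raise the best six-frame translated alignment score (BLOSUM62,
   gap 11/1) against a flank-preselected homologous peptide by more than
   10, while amino-acid-scrambled inserts never do?
3. **Island consensus.** Genomic reads aligned locally (min 20 nt) to an
   object pile their alignment starts/finishes up at genomic-segment
   boundaries (≈ read-length-fold). Seeded there, an iterative majority
   consensus grows one *island* per genomic segment: a core identical to
   the object plus ~80 nt intronic *tails* the object never contained.
4. **Splicing test.** Adjacent islands can be joined at exactly one
   position (k+1 positions under a k-nt direct repeat). At that join, donor
   and acceptor windows read from the island tails are scored in bits
   against a splice position-weight model trained on the annotation
   (score = Σ p·IC, the letter-height convention; invariant GT/AG alone
   give 8 bits, a strong consensus ~15). High confidence = literal GT…AG
   and ≥ 11 bits. Same-strand high-confidence splices chain islands into
   *connected islands*; more than one connected island per object flags a
   fusion artifact.
5. **Resolution.** Islands inside a bridge insert that sit in the same
   connected island as the flanking reference-matching islands become
   hidden-exon calls; covered N-islands are confirmed purely intronic;
   N-islands flanking a gene model can yield gene-model extension calls.

A full synthetic-data generator (`simulation_config()`,
`simulate_dataset()`) produces GC-rich genomes, N-masked assemblies with a
truth registry, transcript objects (with deliberate fusions) and read sets,
so every stage is testable against known ground truth.

## Worked example

```r
library(exonpatch)

cfg <- simulation_config(n_genes = 6, hidden_exon_genes = 2,
                         intronic_island_genes = 1,
                         genomic_depth = 30, fusion_rate = 0.2)
ds  <- simulate_dataset(cfg, seed = 7)
rep <- run_exonpatch(ds$truth$assembly, ds$truth$models,
                     ds$objects, ds$reads$genomic)
print(rep)
#> <exonpatch_report>
#>   junctions: 23 ( 3 N-flagged )
#>     covered n_flag=FALSE: 20
#>     bridged n_flag=TRUE: 2
#>     covered n_flag=TRUE: 1
#>   hidden exons called: 5 
#>   island verdicts: hidden_exons=2 purely_intronic=1 
#>   suspected fusions: 1 of 7 objects
#>   flanking extensions: 0 
```

Reading this: all 20 ordinary junctions are covered (the annotation's
splices are real); of the three junctions annotated to splice out an
N-island, two are bridged by transcript objects and resolve into five
hidden exons (`rep$hidden_exons` carries their sequences, splice windows
and bit scores — here they match the planted truth in
`ds$truth$hidden_exons` exactly), while the third is covered, i.e. that
island is genuinely intronic. The one deliberately fused object is the only
one split into multiple connected islands. `write_report(rep, "out/")`
emits `report.json`, `junctions.tsv`, `hidden_exons.gff3/.fa` and
`conservation.tsv`; `autoplot()` methods draw the pileup and island-span
diagnostics. A thin command-line front end lives in
`inst/scripts/exonpatch.R` (`simulate`, `pwm`, `run`).

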