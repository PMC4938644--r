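---
title: "Discovering exons hidden in assembly gaps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering exons hidden in assembly gaps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonpatch)
```

## The problem

Draft genome assemblies contain blocks of unknown sequence — runs of `N`
("N-islands") whose length only estimates the amount of missing sequence.
Many of these blocks sit inside introns of annotated gene models, where an
annotation pipeline has no choice but to call them intronic: it cannot posit
exons made of `N`. If an intronic N-island actually harbours one or more
exons, the annotated transcript is wrong, and the missing exonic sequence is
typically present nowhere in the assembly.

`exonpatch` recovers such hidden exons, their exact splice junctions and
their flanking intronic sequence from two data sources that do not trust the
assembly at the gap: de-novo-assembled transcript sequences ("transcript
objects", of initially unknown biological validity) and short genomic DNA
reads.

## The procedure

The pipeline chains five tests, each implemented and testable on its own.

**1. The separated-HSP (bridge) test.** Transcript objects are aligned to
the annotation's spliced transcripts with *ungapped* local alignment (exact
word seeding plus two-sided x-drop extension, BLASTN-like scores +1/−2,
word 11, x-drop 10, minimum HSP score 22). Forcing distinct HSPs instead of
gapped alignments is what makes the signature readable: a junction spanned
by one continuous HSP with aligned sequence on both sides is *covered* (the
annotated splice is supported); a junction flanked by two HSPs with extra
object sequence strictly between them is *bridged* — the insert is candidate
hidden-exon sequence; a single HSP ending within 50 nt of an N-flagged
junction with a long (>60% of the object) unaligned tail pointing at the
island is a *half-bridge*. Junctions with no nearby HSP carry
*no information*. Across multiple objects the junction status resolves by
the precedence `bridged > covered > half_bridged > no_information`
(information-richer calls win; disagreement is flagged).

Two numerical details matter at 65% GC. First, chance direct repeats of one
to a few nucleotides flank most junctions, so the two HSPs of a true bridge
usually overlap by a few nt on the subject. Rejecting overlapping pairs
outright silently converts most true bridges into spurious "covered" calls
(the downstream HSP starts 1–2 nt before the spliced position and satisfies
the one-nt-each-side containment test). The classifier therefore trims the
lower-scoring HSP of an overlapping pair back to non-overlap and re-tests
(`trim_overlap = TRUE`, repeat slack 10 nt); the guard against repeats
faking a bridge is retained as the requirement of a non-empty query insert
*after* trimming. Second, transcript objects are non-stranded, so both query
strands are searched and the best orientation per object–subject pair kept.

**2. The conservation (translated-improvement) test.** A bridge could be an
in-silico assembly artifact. If the insert encodes real protein, appending
it between the flanks should raise the best translated (six-frame,
BLOSUM62/11/1) local-alignment score against a homologous peptide that was
*pre-selected by the flanks alone* — and a random permutation of the
insert's amino acids (codons carried along, in the insert's best reading
frame; 20 replicates, seedable) should not. The verdict is `conserved` when
the intact insert improves the score by more than 10 bits while no
scramble does; the threshold follows the observation that scrambled
controls stay at or below a 10-point increase.

Two numerical choices make this test behave like the translated-search
tools it emulates, and both matter. First, scores are reported in
BLAST-style bits (Karlin–Altschul λ = 0.267, K = 0.041 for gapped
BLOSUM62 with gap 11/1): in raw matrix units a single coincidental
tryptophan pair is worth +11, so no aligner could keep hundreds of
scrambled controls below a *raw* increase of 10 — the 10-point ceiling is
only meaningful on the bit scale, where that pair is ~4 bits. Second, the
aligner follows HSP semantics rather than unconstrained Smith–Waterman:
every maximal ungapped diagonal segment (itself x-drop-bounded) anchors a
gapped extension that is pruned when its running score falls more than
`x_drop` raw units below the running best. Unconstrained local alignment
would bridge the flanks across the subject's unmatched middle and stitch
together composition-driven matches from any scrambled insert (gaining
50–85 raw units routinely), silently destroying the scrambled null; with
the extension drop-off at 11 — just below the 12-unit cost of any gap
move — default extensions are effectively ungapped, gap ladders through a
scrambled insert are impossible, and substitution crossings die within a
few residues, so the scrambled null is flat. (Raising `x_drop` above 12
admits short evolutionary indels at the price of a noisier null.) Very
rarely (~10⁻³) a permutation of a biased-composition insert is
positionally lucky enough to cross on the plain diagonal, so the extreme
value over very many controls can still exceed 10 bits even though the
null's upper percentiles sit at it. Stop codons
translate to `*`, which scores the matrix minimum against everything; a
flanks-only score below 40 bits means the object and peptide share no
common subject and the test abstains. Whether the original scramble
preserved codon usage is unknowable from the method description; permuting
whole codons preserves both the amino-acid multiset and the codon
multiset, which is the conservative choice.

**3. Island consensus from genomic reads.** Genomic reads (100 nt) are
aligned to each transcript object with ungapped local alignment (both
strands, minimum aligned length 20, mismatch fraction at most 5%). If a
stretch of the object derives from one contiguous genomic segment, reads
tile it continuously; where the object joins discontiguous segments,
alignment *starts* and *finishes* pile up at the exact join coordinate. The
expected pileup is `read_length − min_local_length + 1`-fold (≈81-fold for
100/20) over the mean interior count: every genomic start position within
80 nt upstream of a segment onset produces an alignment starting exactly at
the onset, while an interior position collects starts from a single genomic
position. (Summaries that quote "about read-length-fold" neglect the
minimum-length correction; chance direct repeats between the intron end and
the preceding segment also displace the pileup by a few nucleotides, so the
boundary count is read off a small window around the junction.) Positions
exceeding 10× the interior mean seed island growth; 10× (not the
asymptotic ~80–100×) keeps detection robust at moderate depth.

Growth is an iterative majority consensus: reads whose alignment boundary
sits at the seed are recruited and placed by their template alignment;
a per-position majority consensus is called (ties break to the template
base inside the core and to the alphabetically first base in tails, so the
result is deterministic); recruited reads disagreeing with the consensus at
more than 5% of their overlapping positions are discarded; unrecruited
template-aligned reads agreeing over at least 20 positions are recruited;
the loop stops when the recruited set is stable (cap 50 rounds). Reads that
touch the template only through a short internal repeat disagree with the
growing tails and are discarded — this is the mechanism that makes the
procedure robust to repeat-mediated misalignment. The result per genomic
segment is a *consensus island*: a core identical to the template over the
aligned interval plus *tails* of genomic (intronic) sequence the template
does not contain, typically ~80 nt (= 100 − 20) long. Islands grown from a
start seed and a finish seed of the same segment converge on the same
interval and are merged; merging requires at least 16 nt (or half the
smaller core) of core overlap, because *distinct* adjacent segments also
share a few nt of chance direct repeat at the junction.

**4. The splicing test.** Sequential islands share no sequence outside the
template frame, so the position where their genomic segments must be joined
to reconstitute the object is constrained to a single nucleotide — widened
to k+1 candidate offsets exactly when a k-nt direct repeat spans the
junction (the template-matching cores then overlap by k). At each candidate
offset, donor and acceptor windows are read out of the island consensus
sequences — crucially, mostly out of the *tails*, i.e. from sequence the
transcript object itself never contained, which makes a positive result
independent validation. Windows are 3 exonic + 6 intronic nt (donor) and
6 intronic + 3 exonic nt (acceptor); tails shorter than a window are
N-padded and N scores zero, so short tails degrade gracefully rather than
failing. Both strands are always scored (objects are non-stranded); on the
minus strand the donor window is the reverse complement of the downstream
island's acceptor-side window and vice versa. Under multiple offsets the
best splice score wins, ties to the smallest offset.

The splice model is a position-weight matrix trained on the annotation's
non-N-flagged junctions (self-training on the input annotation; a pre-built
model can be supplied instead). The score of a candidate is the sum over
positions of the observed base's frequency times the position's information
content (2 − entropy, bits) — the letter-height convention. This is the only
reading under which four invariant dinucleotide positions contribute exactly
8 bits and a strong consensus tops out near 15, which anchors the two-step
high-confidence test: literal `GT`…`AG` *and* a score of at least 11 bits.
The pseudocount defaults to 0 so invariant columns score exactly 2 bits; a
small pseudocount is available for noisy training sets.

A maximal run of islands whose consecutive junctions all carry same-strand
high-confidence splices is a *connected island*. One connected island
spanning the object certifies it as producible by splicing; several
connected islands indicate a track-crossing fusion (a strand flip between
runs pinpoints a fusion that inverted one part); a junction callable on both
strands is kept on both and flagged ambiguous.

**5. Resolution and reporting.** For a bridged N-flagged junction, islands
whose cores lie inside the bridge insert and that belong to the same
connected island as the flanking reference-matching islands become
hidden-exon calls, with exon boundaries at the splice-selected offsets, the
exon sequence from the island consensus, and the donor/acceptor windows and
scores attached; inserts with no island, or islands failing the splicing
test, are reported as unresolved rather than as exons. Covered N-flagged
junctions are reported as purely intronic. N-islands outside gene models
but starting within 100 nt of a model boundary are *flanking*; an object
half-bridging such an island whose hanging tail is part of the object's
connected island (and, when a proteome is given, passes the improvement
test) is reported as a gene-model extension. Intronic context wins over
flanking when both apply, and islands abutting an exon boundary exactly are
classified by the annotated intron interval, with multi-model ties counted
in `n_hosts`.

## The synthetic-data generator

`simulation_config()` fixes the reference study conditions: a single-contig
~200 kb genome at 65% GC with 20 multi-exon genes (4–8 exons of 90–240 nt,
introns 200–600 nt, intergenic gaps 4–8 kb, both strands), 100-nt genomic
and 50-nt RNA reads at 30× with 0.5% substitution error, six genes whose
island hides 1–3 exons, four with a purely intronic island, and two fusion
artifacts among the transcript objects. Masks swallow the hidden exons plus
their inner introns, leaving 20–60 nt of real intron next to the retained
exons, and the N-run length is the true hidden length times Uniform(0.5, 2)
— an estimate, as in real assemblies. The splice consensus places the
invariant `GT`/`AG` (8 bits) plus five informative positions at consensus
probability 0.93 with A/T consensus bases (donor +3 A, +4 A, +6 T; acceptor
−4 T, −3 T), echoing A/T-rich donors and polypyrimidine acceptors in
otherwise GC-rich sequence. Total specified information is ~15.6 bits, so
by a closed-form binomial argument the 11-bit two-step test passes ~99.7%
of consensus-drawn junctions while random 65%-GC windows containing
`GT`…`AG` pass at ~4% — the synthetic analogue of a ~99%/~1% split. A/T
consensus bases are what keep the false-positive rate down in a GC-rich
background; with G/C consensus bases the same information content would
admit ~20% of random windows.

What the generator deliberately does **not** emulate: repeat families and
low-complexity tracts (the dominant real-world cause of both assembly gaps
and alignment trouble), indel sequencing errors, quality scores, expression
variation, alternative splicing, and non-canonical (GC–AG, AT–AC) introns.
Passing tests on these fixtures therefore demonstrates the mechanics of the
method — boundary signatures, consensus growth, the join constraint, splice
scoring, fusion detection — not robustness to repeat-rich genomes.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| match/mismatch, word, x-drop, min HSP score | +1/−2, 11, 10, 22 | BLASTN-like ungapped defaults; the method only needs distinct HSPs |
| half-bridge gap / tail fraction | 50 nt / 0.6 | the stated half-bridge criteria |
| improvement threshold | 10 score units | empirical ceiling of scrambled controls |
| scramble replicates | 20 | enough to bound the null; seedable |
| min local read alignment | 20 nt | the local-alignment calling minimum; sets tail length ≈ 80 |
| max read mismatch fraction | 0.05 | tolerates 0.5% sequencing error with margin |
| seed enrichment threshold | 10× | detection at moderate depth; the asymptotic pileup is ~81× |
| consensus majority / poor fit | 0.75 / 5% disagreement | unstated in the method's description; exposed and logged |
| splice windows | 3+6 / 6+3 | 18 positions comfortably carry a ~15-bit consensus |
| score cutoff | 11 bits | the two-step test's second step |
| flank distance | 100 nt | the flanking-island definition |

## Numerical and degenerate-input policy

0-based half-open coordinates internally everywhere; GFF3 I/O converts to
1-based inclusive. N is a universal mismatch in nucleotide alignment, scores
0 in PWM windows, and translates to `X`. Empty alignment results are valid
empty tibbles, never errors. Zero-depth seeds return no island. All
tie-breaks (majority votes, offset choice, HSP-pair choice) are
deterministic and documented above; re-running any stage on identical
inputs and seed reproduces its output byte for byte.

Problem sizes used by the test-suite and the acceptance script — chosen as
comfortable desk-scale conditions for the properties under test: PWM
calibration on 1000–2000 training and 1000–4000 held-out windows; boundary
enrichment on a 1 kb two-segment template at 220×; tails on a 400-nt exon
at 60×; 50 synthetic bridges × 20 scrambles for the conservation null;
100 oracle-equivalence instances ≤ 200 nt; and one full pipeline run at the
reference study conditions above.

## Known limitations

* Ungapped read alignment means indel sequencing errors cost a read its
  alignment rather than being absorbed; fine at 0.5% substitution-only
  error, wrong for indel-prone chemistries.
* The island step can fragment at low depth (< ~10×); fragments are flagged
  `low_confidence`, not silently merged.
* Hidden exons shorter than the seed word, or islands whose flanking
  retained intron is shorter than a splice window, degrade to unresolved
  calls.
* One reading frame is assumed per insert when scrambling; chimeric inserts
  spanning frames are scrambled in their best single frame.
* Iteratively walking outward from island tails to recover whole introns is
  out of scope by design (track-crossing risk in repeat-rich introns).
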