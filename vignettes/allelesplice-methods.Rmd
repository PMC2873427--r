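---
title: "Separating allelic gene structure variation from alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating allelic gene structure variation from alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When expressed sequence tags (ESTs) from one locus are spliced-aligned to a
reference genome, they frequently disagree about the locus's exon/intron
structure. Such transcript structure variation (TSV) has two very different
causes. Alternative splicing (AS) produces several isoforms from one
pre-mRNA — the same allele, hence identical underlying genomic sequence.
Allelic gene structure variation instead reflects genomic differences
between alleles segregating in the sampled population: one allele splices
one way, the other another way. Distinguishing the two matters because
allelic structure variants change gene products far more drastically than
point mutations and are strong candidates for association studies, while
confirmed AS events are valuable training data for splicing models.

The key observation is linkage. Exonic SNPs sit on the same molecule as the
structural variant, and in organisms with low recombination the SNP pattern
carried by an EST tags the allele it was transcribed from. Isoforms produced
by AS therefore share a SNP pattern; isoforms from different alleles carry
different ones. `allelesplice` implements this inference end to end:
spliced-alignment ingestion and quality filtering, transcript clustering,
six-way structural classification of isoform differences, mismatch SNP
calling with a multi-EST filter, per-event SNP-pattern comparison, and
coding-impact annotation.

## Alignment ingestion and clustering

Alignments arrive as BED12 (optionally with coverage and identity as extra
percentage columns) or GFF3 (`match`/`match_part` or `exon` features with
`coverage`/`identity` attributes). Internally all coordinates are 0-based
half-open; GFF3's 1-based inclusive intervals are converted on input.

Three filters reproduce the standard screening for EST-to-genome work, and
their defaults are the pipeline's zero-configuration behaviour:

* coverage > 0.80 and identity > 0.95, both strict inequalities;
* uniexonic alignments are dropped — a single-block cDNA alignment is
  indistinguishable from genomic DNA or unspliced pre-mRNA contamination;
* when an EST aligns to several loci, only the placement maximizing
  `identity * coverage` is kept, with a deterministic tie-break by
  (chromosome, start, input order).

Alignments whose input lacks coverage/identity can be rejected (default) or
passed through; the upstream aligner normally computes both.

Transcript clusters are single-linkage components of the exonic-overlap
graph: two alignments are linked when any exon blocks share at least 1 bp
on the same chromosome and strand. Overlap is block-level rather than
span-level so that two genes sharing only an intron (for example a gene
nested in another's intron) are not chained into one cluster. Within a
cluster, members with identical intron chains — the ordered list of
junction coordinate pairs — collapse into one isoform; chain equality is
the definition of isoform identity, so a truncated EST whose chain is a
proper subchain forms its own isoform and simply produces no events against
its parent (their shared span is structurally identical).

For unstranded input the strand can be inferred from the canonical GT..AG /
CT..AC splice dinucleotides when a genome is supplied; alignments that
remain unstranded cluster separately.

## Event detection and the six categories

Every pair of distinct isoforms in a cluster is compared over the genomic
span both cover. Introns present in only one of the two chains are grouped
into connected components: two opposing introns belong to the same
localized difference when they overlap *or abut* (an abutting pair shares a
junction coordinate, and at base level the two changes form one contiguous
stretch of disagreement). Each component becomes one candidate event and is
classified in a fixed decision order:

1. **IntronR** — one isoform has an intron, the other is contiguously
   exonic across it with at least one anchored base beyond each end. The
   anchor requirement stops marginal overhangs from being read as
   retention.
2. **ExonS** — one isoform's single intron spans the other's two introns
   exactly (outer boundaries equal), with a covered internal exon between
   them.
3. **AltA / AltD** — two introns share one boundary. Labels follow the
   biological donor/acceptor: on the plus strand a shared genomic-left
   boundary means a shared donor, so the difference is an alternative
   acceptor (AltA); on the minus strand the same geometry is an
   alternative donor (AltD).
4. **AltS** — both boundaries differ and the introns genuinely overlap.
5. **Others** — everything else: components with three or more introns,
   abutting non-overlapping intron pairs, retention candidates without
   contiguous coverage, and any difference touching either isoform's
   terminal aligned base. Terminal differences are deliberately
   unclassifiable because a truncated EST cannot distinguish real
   variation (e.g. alternative transcript initialization) from incomplete
   coverage.

The variable region is the interval over which the two isoforms' exonic
structures differ (the retained intron; the exonic stretch between the two
acceptors or donors; the skipped exon; the component hull for AltS and
Others). The event's length difference is the absolute difference in exonic
base counts between the two isoforms across that region — exactly the
mRNA length change — and an event is in-frame when that difference is
divisible by 3. Identical events found in several isoform pairs (same
type, region and flanking junctions) are merged with their EST support
unioned; the same identity key drives the intersection of event sets from
two independent aligners, with a configurable coordinate slack
(default 0).

The classifier is validated against an independent brute-force reference
that paints per-base exon/intron states and enumerates intron relations
directly (`tests/testthat/helper-oracle.R`); the two agree on 100% of
randomly generated clusters with up to 4 isoforms and 6 introns.

## SNP calling and the mSNP filter

Mismatches between each EST (best alignment only) and the reference are
called per aligned base; both bases must be unambiguous A/C/G/T, and all
calls are reported on the genome forward strand. Two masks suppress
alignment artifacts: `end_mask` (default 3 bp) at the alignment's outer
ends and `gap_mask` (default 5 bp) around internal block boundaries, where
misplaced junctions concentrate spurious mismatches. Setting both to 0
restores unmasked behaviour. Indels are out of scope — ESTs here carry no
base qualities and the downstream decision rule compares base identities
only.

At an EST error rate of 0.0044 per bp, a 227-bp EST is expected to contain
one spurious mismatch (`est_length_for_one_false_positive(0.0044)`), so
single-EST calls are unreliable. Calls with identical (chromosome,
position, alternative base) are aggregated across ESTs, and only those
supported by more than one EST — mSNPs — feed the source classifier.
Multi-allelic positions stay as separate records keyed by the alternative
base.

## The source decision rule

For each event, the ESTs supporting the two isoforms form two groups. Each
EST's SNP pattern is its base at every mSNP position its alignment covers:
the alternative base when the EST is among that mSNP's supporters,
otherwise the reference base — so an EST matching the reference still has
a usable, fully informative pattern. Two consistency rules matter here:

* positions inside an EST's masking margins are treated as *uncovered* for
  that EST, not as reference matches. A mismatch there could never have
  been called, and recording "reference" would poison pattern comparisons
  near splice junctions (one corrupted position makes an entire pair
  mismatch, and for events with few informative pairs this flips the
  verdict);
* ESTs covering no mSNP position are removed from their group, mirroring
  the removal of deposited ESTs that were computationally derived from or
  corrected against the reference.

Every cross-group EST pair is then compared at the mSNP positions both
cover. A pair sharing at least one position is informative; it matches when
the bases agree at every shared position (partial overlap with agreement
counts as a match — the comparison is restricted to positions both ESTs
cover). The verdict is:

* `alternative_splicing` if any informative pair matches — one shared
  pattern suffices to show both structures on one allele;
* `allelic` if informative pairs exist and none matches;
* `undetermined` if no pair is informative.

`undetermined` is a first-class verdict: such events are reported but
excluded from allelic-fraction denominators, which reproduces the effect of
dropping mSNP-free ESTs while keeping the bookkeeping auditable. Matched
positions may lie anywhere on the shared EST span, not only inside the
variable region — linked SNPs flanking the event are exactly the tags the
method relies on. The rule is symmetric under group swap, and adding an
EST can only create matches, never remove them (allelic can become
alternative_splicing as evidence accumulates, not the reverse).

## Coding impact

Gene models are read from GFF3; when explicit UTR features are absent,
UTRs are reconstructed as exon-minus-CDS split by transcription direction.
Each event's variable region is assigned to CDS, 5'UTR or 3'UTR by maximal
overlap, against a partition of the transcript's genomic span at the CDS
boundaries (first to last CDS base, plus the two flanking spans labelled
by strand). The partition — rather than overlap with exonic intervals
only — is deliberate: the most common event type retains an *intron*,
which overlaps no exonic interval at all, yet a retention between coding
exons is plainly a coding-sequence variation. Ties break CDS > UTR5 >
UTR3, events overlapping several models go to the model with the largest
overlap (then lexicographic gene id), and events outside every model are
intergenic. For CDS events the distance from the region's 3'-most base to
the stop codon is reported in transcript coordinates; a "near the CDS end"
flag has no canonical threshold, so the raw distance is reported and any
cutoff is left to the caller.

Because UTR variations do not disturb the reading frame, their in-frame
fraction should sit at the random rate of 1/3 under uniform length
differences; the test suite verifies this with a binomial test at
significance 0.01 over 1,500 simulated events.

## The synthetic-data generator

`simulate_tsv_data()` builds loci with full truth tables so that every
stage is testable without external data. Per gene (one chromosome each, so
cluster truth is unambiguous): a multi-exon structure is drawn (defaults: 4
to 7 exons of 120 to 300 bp, introns 60 to 150 bp); one structural event of
a type drawn from the configured mix; and a source — allelic with
probability 0.28, otherwise AS. For an allelic gene each isoform is
transcribed from its own allele, each allele carrying independent SNPs
planted on exonic positions at density 0.01 per bp (intronic SNPs would be
invisible in ESTs); for an AS gene both isoforms share one SNP-bearing
allele. ESTs are windows of the isoform transcript (600 to 1200 bp),
constrained to span the event with 25 anchored bases on each side and to
cross at least one of their own splice junctions so they survive the
uniexonic filter, with uniform per-base substitution errors at 0.0044 and
no indels — the substitution-only model is what makes the reciprocal-rate
false-positive arithmetic exact. Truth alignments are exact placements
written as BED12 plus coverage/identity columns.

Defaults are the study conditions: SNP density 1/100 bp, EST error
0.0044/bp, allelic fraction 0.28, and a type mix proportional to the
genome-wide frequencies of the five classifiable types (41:10:14:11:6 for
IntronR:AltA:AltD:AltS:ExonS). The nominal UTR lengths (234 and 451 bp)
follow the reported median 5'UTR and 3'UTR lengths and are shrunk
proportionally on short transcripts, keeping the CDS a whole number of
codons.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: alignment error (truth placements are exact, so
the two-aligner intersection step is exercised only for its set logic);
indels and quality-dependent error; expression differences between
alleles; EST 5'/3' sampling bias; genes sharing loci or overlapping on
opposite strands; population structure beyond two alleles; and
modified/reference-derived database ESTs (their effect — mSNP-free
patterns — is modelled only through the undetermined verdict).

## Numerical and design choices

* Strict `>` at both quality thresholds; the boundary values 0.80/0.95 are
  rejected.
* Event identity for merging and intersection: (type, chromosome, strand,
  variable region, flanking junction coordinates) — coordinates are the
  only vocabulary two aligners share.
* AltS requires genuine intron overlap; abutting intron pairs are one
  `Others` event.
* The event-side convention: `ests_a` supports the isoform with fewer
  exonic bases in the variable region ("spliced" side), ties broken by
  chain string.
* All randomness in the generator flows from one integer seed; identical
  seeds give byte-identical output bundles.
* Validation problem sizes: 200 random clusters for oracle equivalence,
  200 genes per error condition for source-accuracy recovery, 500 genes
  for frequency recovery, 1,500 events for the UTR frame-rate check —
  sizes at which the binomial/multinomial confidence intervals are tight
  enough to be meaningful while the full suite stays fast.

## Limitations

The method is blind to allelic variants whose alleles carry no exonic SNP
in the shared span (undetermined), and rare alleles sampled by a single
EST never reach mSNP status, so the allelic fraction is a lower bound —
consistent with how the undetermined verdict is excluded from
denominators. Events in the `Others` category are heterogeneous by
construction and are not sub-classified. The pipeline consumes existing
spliced alignments; it does not run or wrap an aligner, and alignment
systematic error can only be mitigated through the two-aligner
intersection step.
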