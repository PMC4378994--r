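---
title: "Discovering miRNA-offset RNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA-offset RNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moRfinder)
```

## The biological object and the search model

A miRNA hairpin precursor is processed by Drosha and Dicer into up to two
mature miRNAs. Sequencing additionally recovers short RNAs whose loci lie
*immediately outside* the precursor: miRNA-offset RNAs, moR-5p upstream of
the hairpin's transcript 5' end and moR-3p downstream of its 3' end. Like
miRNAs they appear as clouds of overlapping length variants (isomoRs) with
one dominant sequence.

`moRfinder` models each precursor as an **extended hairpin**: the annotated
precursor interval widened by a 30 nt flank on each side, partitioned into
five base-level regions (moR-5p, miR-5p, loop, miR-3p, moR-3p). The moR
regions are defined by the *precursor boundary*, not the mature boundary —
the flank is the search space whether or not a mature is annotated flush
with the hairpin end. Internally every interval is 0-based half-open;
GFF3 input/output converts from and to 1-based inclusive coordinates, and
BED output stays 0-based half-open. On the minus strand the moR-5p region
sits at the higher genome coordinates; all region logic is written in
transcript orientation so the two strands are exact mirror images (a
property the test suite verifies by running the full pipeline on the
reverse-complemented genome).

Hairpins lacking a mature annotation on one arm keep that mir region
absent and the loop label absorbs the span. Flank truncation at chromosome
edges is silent but flagged on the extended-hairpin object, since edge
loci are a degenerate case the search model otherwise never meets.

## Pipeline stages and their assumptions

**Preprocessing.** Reads with mean Phred quality below 20 are removed,
then 3'-terminal bases below Q20 are trimmed. Trimming is 3'-only by
design: the 5' end of a small RNA is the biological molecule boundary, and
trimming it would corrupt every isoform-end statistic downstream. Adapter
removal takes the *leftmost* occurrence of an adapter prefix with minimum
overlap 5 nt and at most one mismatch per 7 matched adapter bases (both
exposed in the configuration, since adapter chemistry varies). The insert
is then classified: empty = adapter dimer; ≥ 90% one nucleotide =
homopolymer (strict 100% would miss one-error homopolymer artifacts);
shorter than 14 nt = too short; otherwise clean. Inserts longer than
36 nt are kept — size selection is a property of the gel, not of the
software.

**Alignment.** Reads are placed end-to-end (ungapped) on both strands
with at most 2 mismatches, the behaviour of a `-v`-mode short-read
aligner; indels are unsupported on purpose. A read with more than 10
placements is discarded as a multimapper. N bases count as mismatches
against everything, which makes the mismatch count deterministic and
conservative. The mismatch-tolerant scan is delegated to Biostrings'
`matchPattern`; an independent all-offsets Hamming oracle in the test
suite guarantees set-identical output at reference scales up to tens of
kilobases.

**Annotation cascade.** Reads are classified first-match-wins in the
order: miRNA hairpins (≤ 2 mismatches), then snRNA, snoRNA, rRNA,
mitochondrial tRNA, miscRNA, piRNA, tRNA and repeats, each requiring
exact containment in a class reference sequence. The order of the exact
classes is a genuine design choice (multi-class exact matches are rare
but possible); cascade order was chosen to mirror the conventional
reporting order of small RNA species and is user-controllable through the
order of the reference list. Matching is done in transcript (sense)
orientation, as class references are transcript sequences.

**Mature and moRNA counting.** A read counts for a mature miRNA when its
interval is contained in the mature locus ± 2 nt, same strand, and it
counts at *every* locus it satisfies — paralogous precursors sharing one
mature sequence receive identical counts rather than fractional ones.
The same convention drives flank collection: a read in the shared gap
between two clustered hairpins (< 60 nt apart) joins both candidate sets.
Boundary-spanning reads are assigned by *majority overlap*: a read is a
flank candidate only if it overlaps the flank by more nucleotides than
the hairpin. Any-overlap exclusion would be wrong — genuine moRNAs
overlap the mature miRNA by one or two nucleotides.

**Reference isomoR and quantification.** Per (hairpin, arm), the isomoR
with maximal read multiplicity becomes the reference. Ties are broken
deterministically: longer sequence, then 5'-most start in transcript
orientation, then lexicographic order. Quantification counts reads
contained in the reference locus ± 2 nt; the mismatch tolerance is a
mode switch (`quant_mismatches`): 0 for exact-match report tables, 2 for
differential-expression style counting. The tolerant mode is provably a
superset of the exact mode (property-tested). 5'-end consistency is the
multiplicity-weighted fraction of reads sharing the modal 5' position;
weighting by unique sequence instead would understate the dominance of
the main isoform, and the choice is flagged in the documentation because
either convention is defensible.

**RPM denominators.** Reported RPM defaults to reads mapped to the
genome at ≤ 2 mismatches; an exact-mappers-only denominator is available
because per-table conventions differ between exact-match reporting and
tolerant counting. Both are configuration switches rather than
hard-coded, since published tables mix the two conventions.

## Novel miRNA modules

**Minor-arm calls** require a precursor with exactly one annotated
mature. The candidate is the modal zero-mismatch read contained in the
opposite arm; acceptance needs ≥ 10 reads, and ≥ 14 paired bases between
the candidate's *first 20 nt* and the known mature over all ungapped
antiparallel registrations. The 20 nt window is candidate-anchored (the
plausible alternative — the duplex's first 20 positions — is nearly
always identical and the candidate anchor is simpler to reason about;
the choice is documented on the function). G:U wobble counts as a pair
by default because physiological RNA duplexes allow it; a strict
Watson–Crick mode is a flag.

**Novel hairpin post-filters** act on externally predicted candidates:
≥ 10 exactly-mapping reads on the dominant product, ≤ 10 genomic copies
(full-length placements at the mapping tolerance; an exact-copy mode
exists), and GC content within 15–90%. Hairpin prediction itself is out
of scope — the filters are deliberately predictor-agnostic.

**Conservation** is the mean per-base score over the locus from a
bedGraph track, with uncovered positions scoring 0 (their count is
reported); a locus is conserved when the mean *strictly* exceeds 0.5.
The strict inequality matters only at the exact boundary and is pinned
by a test.

## Seed-target analysis

The seed is positions 2–8 (1-based) of the small RNA; a target site is an
occurrence of its reverse complement in an annotated 3'UTR (U→T
normalization on input). Overlapping occurrences all count — the per-set
tables only distinguish zero from nonzero per gene, so overlap handling
only affects per-gene counts, and counting all windows is the convention
that needs no extra rule. Genes without an annotated 3'UTR are excluded
from every seed count rather than treated as zero-match genes.
`best_duplex_site` scans all ungapped antiparallel registrations of the
small RNA against the UTR and reports the maximal paired-base count
(ties to the 5'-most position). It is a complementarity maximizer and is
labelled as such in its output: it does not estimate folding free energy,
and its site calls should be read as screening hints, not thermodynamic
predictions.

## The synthetic-data generator

The generator emulates the study conditions the pipeline targets:

| parameter | default | rationale |
|---|---|---|
| hairpins | 20, 70–90 nt, both strands | desk-scale reference |
| planted moRNAs | 12 | one per selected hairpin |
| arm bias (5') | 0.58 | observed pluripotent-cell arm usage |
| 5'-end consistency | 0.97 | observed isomoR 5' homogeneity |
| moR-5p lengths | 16–26 nt, peak 19 | observed length profile |
| moR-3p lengths | 16–29 nt, feature-modal | broader observed profile |
| isomiR 5' consistency | 0.80 | observed mature-miRNA value |
| error rate | 0.001/base | high-quality sequencing |
| library size | 50,000 reads | keeps the suite at desk runtime |
| artifacts | 2% dimers, 1% homopolymers, 2% short, 4% low-quality | exercise every rejection path |
| background | 25%, 8 ncRNA classes | exercises the cascade |

Background reads are drawn from a finite pool of clonal fragments per
decoy ncRNA (as real tRNA/rRNA fragments are), which also keeps the
unique-sequence universe small. Quality strings use a two-state model
(Q38 good / Q8 bad): enough to exercise every Q20 rule without modelling
real error profiles. Reference and reads use separate RNG streams salted
from one master seed, so changing the library size cannot perturb the
reference; identical configurations are byte-identical.

Each planted feature records an analytic *in-window fraction*: the
probability, under the isoform model, that a read falls inside the
reference locus ± 2 nt. Recovery evaluation compares pipeline counts
against planted count × in-window fraction — the generator's own
expectation of what the ± 2 nt rule can see, computed by enumeration,
never by running the pipeline.

What passing tests do **not** show: the simulator has no PCR duplication,
no realistic per-cycle error profiles, no RNA-structure-dependent ligation
bias, and its decoy sequences are random rather than real ncRNA families.
Recovery rates on simulated data are therefore upper bounds on real-data
behaviour; the pipeline's value on real data rests on the fidelity of the
rules themselves, which is what the definitional fixtures pin down.

## Numerical conventions and degenerate inputs

* All tie-breaks (modal isoform, modal 5' end, duplex site position) are
  deterministic and documented; reruns are bit-reproducible.
* A read fully erased by quality trimming survives as a length-0 read so
  the dimer/length classifier accounts for it — preprocessing counts
  always conserve the raw total.
* An empty candidate set yields no isomoR group; an empty interval is an
  error for conservation; correlation with fewer than three surviving
  pairs is reported as absent (NA), not as a coefficient.
* Multiple placements of one sequence within a single flank are collapsed
  to the transcript-5'-most placement so multiplicities are never double
  counted; placements at *different* hairpins are intentionally kept.

## Problem sizes used by the validation suite

The test suite and the acceptance script run entirely on generated data:
the standard experiment uses 20 hairpins, 12 planted moRNAs and one
50,000-read library; the descriptive-statistics run deepens the moRNA
layer to roughly 20,000 moRNA reads; aligner-oracle comparisons use a
10 kb genome and 200 reads. These sizes were chosen so the whole suite
exercises every code path in about two minutes on one core while keeping
per-feature coverage (≈ 100–1,700 reads) high enough that recovery
tolerances (±10% abundance, ±0.03 consistency, ±0.05 arm fraction) are
dominated by sampling noise, not by pipeline bias.

## Known limitations

* Ungapped alignment only; an indel-bearing read is lost, as it would be
  with a `-v`-mode aligner.
* The in-memory scan engine is appropriate up to megabase references;
  full mammalian genomes need an external index-based aligner upstream
  (the pipeline accepts any alignment table with the documented columns).
* Differential expression is out of scope by design: the package exports
  filtered count matrices (≥ 1 RPM in at least one library) for DESeq2
  or edgeR rather than fitting its own model.
* Secondary-structure prediction is not performed; the duplex scorer is
  a complementarity count.
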