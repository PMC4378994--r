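# moRfinder

Discovery and quantification of microRNA-offset RNAs (moRNAs) from small
RNA-seq data, with a fully specified synthetic-data generator for
end-to-end validation.

## The problem

miRNA hairpin precursors do not only release the two mature miRNAs (miR-5p
and miR-3p). Deep small RNA sequencing also reveals short RNAs mapping
*immediately adjacent* to the precursor — 5' of the hairpin (moR-5p) or 3'
of it (moR-3p). These miRNA-offset RNAs are expressed as populations of
overlapping, variable-length reads (isomoRs), are strongly enriched in
pluripotent cells, and may act as miRNA-like regulators through a 7-mer
seed. Detecting them requires a dedicated analysis: they live in the 30 nt
flanks *outside* the annotated hairpin, so conventional miRNA quantifiers
never see them.

`moRfinder` is aimed at small RNA-seq analysts who want a transparent,
desk-scale reimplementation of that analysis: every stage from raw FASTQ
to moRNA call tables is an ordinary R function operating on plain data
structures, and a simulator with planted ground truth makes every stage
testable offline.

## The method

For each annotated hairpin *H* (with mature loci from a miRBase-style
GFF3), the pipeline:

1. **Preprocesses** reads: drop reads with mean Phred quality < 20, trim
   low-quality 3' ends, remove the 3' adapter (prefix match, minimum
   overlap 5 nt, ≤ 1 mismatch per 7 matched bases), and discard adapter
   dimers, homopolymers, and inserts < 14 nt.
2. **Aligns** the unique clean sequences to the genome: every ungapped
   end-to-end placement on either strand with ≤ 2 mismatches; reads with
   more than 10 placements are discarded as multimappers.
3. **Counts mature miRNAs**: a read counts for a mature locus *m* when its
   interval is contained in *m* widened by ±2 nt, same strand.
4. **Collects offset reads**: a read is a moRNA candidate for (*H*, 5p)
   when it lies inside *H* ± 30 nt, is not contained in *H*, overlaps the
   5' flank by more nucleotides than it overlaps *H*, and is
   strand-concordant (symmetrically for 3p).
5. **Groups isomoRs and quantifies**: per (hairpin, arm), the most
   abundant isomoR sequence becomes the reference; the moRNA's count in a
   library is the multiplicity of reads contained in the reference locus
   ± 2 nt (0 mismatches for report tables, ≤ 2 for DE-style counting).
   RPM = count / mapped-library-size × 10⁶.
6. **Summarizes**: 5'-arm usage fraction, per-arm length distributions
   (calls with ≥ 5 reads and ≥ 0.5 RPM), multiplicity-weighted 5'-end
   consistency, and the Spearman correlation of miR vs moR RPM over pairs
   with both RPM > 0.5.

Separate modules implement novel **minor-arm miRNA** calling (≥ 10
zero-mismatch reads on the unannotated arm, ≥ 14 paired bases within the
candidate's first 20 nt against the known mature), **novel hairpin
post-filters** (≥ 10 exact reads on the main product, ≤ 10 genomic
copies, GC within 15–90%, conservation call at mean score > 0.5), and the
**seed-target cross-tabulation** (occurrences of the reverse complement of
small RNA positions 2–8 in annotated 3'UTRs, tallied over gene sets).

## Worked example

A complete simulated experiment — reference, one 20,000-read library,
full pipeline — in a few lines:

```r
library(moRfinder)

sc  <- sim_config(rng_seed = 7, library_size = 20000L)
ref <- simulate_reference(sc)
lib <- simulate_library(ref, sc)

res <- run_morna_pipeline(list(hESC = lib$reads), ref$genome, ref$hairpins,
                          sc$adapter, pipeline_config(quant_mismatches = 2))
summary(res)
```

```
moRNA discovery summary

 library   raw cleaned genome_mapped hairpin_mapped mor5p mor3p arm_fraction_5p
    hESC 20000   18121         18121          12767   291   209           0.582

Pooled 5'-arm read fraction: 0.582 
moR-5p length mode: 19 nt
moR-3p length mode: 28 nt

Top calls by total raw count:
           name arm                      ref_seq rpm.hESC
 sim-moR-020-5p  5p          AGGTTCTCCCAACCCGCGC 3642.183
 sim-moR-006-5p  5p          CAACCGTAGTTCGAATTCT 2869.599
 ...
```

Reading the output: of 20,000 raw reads, 18,121 survived preprocessing
and mapped to the genome; 12,767 map to hairpin loci; 291 and 209 reads
fall in 5' and 3' flanks respectively, giving a 58.2% 5'-arm fraction
(the generator planted 58%). Each call row is one moRNA with its
reference isomoR sequence and RPM. Recovery against the planted truth:

```r
ev <- evaluate_recovery(res, lib)
ev$recall      # 1 — all 12 planted moRNAs found at the 5-read threshold
ev$precision   # 1 — no calls at moRNA-free hairpins
ev$abundance   # per-feature expected vs observed counts (max rel. err ~4%)
```

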