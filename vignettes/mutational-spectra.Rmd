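---
title: "Mutational spectra from haploid isolate resequencing: methods and design"
author: "MutSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutSpectra)
```

# The analysis problem

Weak mutagens induce few mutations, so discerning a reliable mutational
pattern from conventional reporter systems is hard. ssDNA mutagenesis
reporter strains (e.g. yeast *cdc13-1*) expose long subtelomeric
single-stranded DNA that is hypersensitive to mutagens and shielded from
double-strand-templated repair, concentrating informative mutations near
chromosome ends. Whole-genome sequencing of mutagenized isolates against
an unmutated progenitor reference then yields per-isolate variant calls,
and the analysis task is to turn those calls into comparable mutational
patterns.

MutSpectra implements that pipeline: quality filtering, merging to unique
variants, 96-channel SBS classification, 83-channel indel classification,
rainfall and end-proximity summaries, cross-species trinucleotide
correction, and cosine-similarity comparison.

# Procedure and assumptions

## Filtering and merging

Calls with QUAL < 30 or INFO/DP < 10 are removed *per sample*, before
merging — mirroring the usual per-sample bcftools filter step — with both
boundaries inclusive on the retained side (QUAL = 30, DP = 10 survive).
Calls missing QUAL or DP receive sentinel 0 and are removed by the default
filter rather than silently kept.

Merging identifies a variant by the 4-tuple (chrom, pos, ref, alt);
identical variants in multiple samples become one unique variant carrying
the union of samples. The merged record's qual/depth are per-sample
maxima and are for reporting only. Spectra count unique variants once:
recurrence at a single locus can reflect selection (reporter inactivation
is selected for) rather than intrinsic mutability, whereas a genuinely
susceptible motif will be hit at many different loci. A per-occurrence
weighting mode exists (`perOccurrence = TRUE`) strictly for sensitivity
analysis.

Calls are assumed haploid: presence of a record in a sample's VCF defines
carriage, genotype fields are ignored. Multi-allelic records are split per
alternate allele. MNVs and complex records fit neither spectrum and are
excluded with a diagnostics tally.

## SBS-96 classification

The classification uses the pyrimidine-strand convention: a substitution
at an A/G reference base is reverse-complemented together with its
trinucleotide context. Channel order is the canonical COSMIC order (types
C>A, C>G, C>T, T>A, T>C, T>G; contexts by 5' then 3' base, A/C/G/T), so
channel 1 is `A[C>A]A` and channel 96 is `T[T>G]T`. All serialized
spectra carry channel labels so ordering bugs are detectable on sight.

Degenerate inputs: a substitution at the first or last base of a
chromosome, or with an N in its window, has no defined context; it is
excluded from the spectrum and tallied in the spectrum's metadata. A
mismatch between the VCF ref allele and the genome base is a *hard error*,
not a skip — silent skips would hide a wrong-reference pairing.

## Indel classification

Indels are first normalized: the shared VCF anchor base is stripped and
the event is shifted 5' while the reference permits, so every equivalent
VCF representation of one event classifies identically (this is asserted
by test). Classification then follows a fixed priority:

1. 1 bp events, by pyrimidine base (A/G strand-collapsed to T/C) and
   homopolymer run length (deletions: run includes the deleted base, bins
   1–5, 6+; insertions: adjacent matching bases only, bins 0–4, 5+);
2. events of length ≥ 2 with ≥ 2 tandem copies of the unit adjacent 3' in
   the reference (the deleted copy counts as one), as repeat-context
   deletions/insertions by length bin 2/3/4/5+;
3. deletions of length ≥ 2 with exactly one copy and breakpoint
   microhomology ≥ 1, as microhomology deletions;
4. the remainder as length-binned deletions (repeat bin 1) or insertions
   (repeat bin 0).

Microhomology is computed two-sided — the longest prefix of the deleted
sequence matching the reference immediately 3', and the longest suffix
matching immediately 5' — taking the maximum, capped at deletion length
− 1 (a full-length match is by definition a tandem repeat and is caught by
rule 2 first; the two classes are mutually exclusive by construction).
Breakpoint homology can arise on either side of a deletion, so restricting
to one side would undercount.

The channel layout is the 83-channel ID83 convention (12 + 12 one-bp
channels, 24 + 24 repeat channels, 11 microhomology channels), with a
uniform six repeat bins per deletion-length row and the terminal repeat
bin at 6+ for deletions / 5+ for insertions. It collapses exactly onto the
16-category view (1 bp del C / del T / ins C / ins T; del and ins 2/3/4/5+;
MH-del 2/3/4/5+) and onto a repeat-unit view.

## Rainfall and end proximity

Rainfall series are per-chromosome distances between consecutive unique
variant positions; the first variant per chromosome carries NA. Distances
are never computed across chromosome boundaries and no genome
concatenation is performed. `endProximity()` quantifies subtelomeric
clustering as the fraction of unique variants within `window` bases of
either chromosome end. The literature describes this clustering
qualitatively, so `window` is a required explicit argument — there is no
defensible paper-derived default, and the pipeline's default of 5 kb is
a display choice recorded in its manifest.

## Cross-species correction

For channel c with motif m(c), the corrected frequency is
f′\_c = f\_c · p\_target(m(c)) / p\_source(m(c)). Trinucleotide
proportions are computed over all width-3 windows of a genome (both
flanks present, N windows skipped, purine-centered windows collapsed onto
their reverse complements; 32 motifs). The corrected vector is
renormalized to sum 1: downstream cosine comparisons are invariant to
that positive scalar, and renormalized output remains interpretable as
frequencies. The per-channel multipliers and the unnormalized scaled
vector are kept in the result's metadata for inspection.

Edge cases: a motif with zero source proportion under nonzero spectrum
mass is an error (undefined ratio); a motif with zero target proportion
zeroes its channels with a warning (it cannot mutate in the target
genome). Whether the mitochondrial contig or engineered cassette regions
should enter the proportions is a study-level choice;
`countTrinucleotides()` exposes an exclusion list and by default counts
every chromosome in the FASTA.

## Comparison and clustering

Cosine similarity is scale-invariant in each argument and equals 1 exactly
for proportional patterns. Similarity matrices force an exact unit
diagonal. Heatmap ordering uses agglomerative clustering on distance
1 − similarity with *average linkage*; the linkage is a display choice
that affects leaf order only, never a similarity value, and ties in
`bestMatches()` are broken by catalog order (stable sort). Catalog files
are accepted in either common dialect (single `A[C>A]A` label column, or
Type + trinucleotide columns), reordered to canonical channel order, and
column-renormalized; the catalog release used is the caller's input and
should be recorded alongside results (the pipeline manifest does so).

# The simulator: what it emulates, and what it does not

`simConfig()` defaults define the study-like conditions; they were chosen
once, on biological grounds:

| parameter | default | rationale |
|---|---|---|
| genome | 16 × 50 kb | yeast-like karyotype at 1/15 scale, large enough that every motif occurs thousands of times |
| gcContent | 0.38 | yeast-like GC |
| subtelomereWindow | 5 kb | scaled-down analogue of the subtelomeric ssDNA regions |
| subtelomereEnrichment | 10 | strong end-clustering, qualitatively matching rainfall plots of ssDNA mutagenesis |
| nSamples | 20 | a typical treatment arm |
| substitutionsPerSample / indelsPerSample | 100 / 10 | substitutions ≫ indels, as observed in mutagenized isolates |
| signature | flat background + C>A elevated, strongest at 5'-TC | qualitative shape of small-aldehyde mutagenesis in ssDNA |
| indelDistribution | 1 bp T/A events dominant | homopolymer slippage dominates spontaneous indel spectra |
| recurrenceRate | 0.1 | some hotspot recurrence across isolates |
| failFraction | 0.05 | a small tail of low-QUAL/low-DP calls for the filter to remove |

Substitutions are generated *channel-first*: a channel is drawn from the
signature, then a genomic site matching its motif is drawn (weighted by
the subtelomere enrichment, without replacement per motif). This
guarantees the realized spectrum converges to the configured signature
regardless of genome composition, making parameter recovery a sharp test;
a site-first scheme would convolve the signature with the genome's motif
abundances. Indel events are placed by rejection sampling into contexts
that guarantee their intended category (e.g. microhomology deletions
require the deleted sequence's first base to recur immediately 3', with
no full tandem copy and a stable left alignment), and events are kept
non-overlapping. A truth table records every emitted call, so tests never
re-derive ground truth from the pipeline under test.

What the simulator does **not** emulate: read-level error (no FASTQ, no
aligner or caller artifacts — the contract starts at variant calls),
correlated QUAL/DP structure, mutation clustering beyond the two-level
end-enrichment model, MNVs/complex variants, and any selection process.
Passing closed-loop tests therefore demonstrates correctness of the
classification and bookkeeping machinery under the stated statistical
model — not robustness to caller-specific artifacts in real data.

# Numerical choices

- Proportions are validated to sum to 1 within 1e-12 (computed) or 1e-6
  (read from files, then renormalized); signature catalogs within 1e-6.
- `similarityMatrix()` sets the diagonal to exactly 1 rather than
  computing cos(v, v), avoiding spurious 1 − 1e-16 artifacts in
  clustering heights.
- Variant sets are sorted by (chromosome order, position, ref, alt) with a
  stable radix sort; chromosome order follows the genome (or first
  appearance when no genome is supplied).
- Left alignment iterates single-base shifts; equivalence to an exhaustive
  minimal-position search over all representations is asserted by test.
- All simulation randomness derives from the single config seed
  (`set.seed(seed)` for the genome, `seed + 1` for mutation spiking), so
  identical configs give byte-identical VCFs.
- Zero-total spectra: `typeFractions()` and `asFrequencies()` refuse them;
  `endProximity()` refuses empty variant sets (undefined fraction);
  thresholds must be non-negative; degenerate GC (0 or 1) is rejected as
  it yields no motif diversity.

# Test problem sizes

The shipped test suite checks oracle equivalence on randomized instances
(roughly 12,000 trinucleotide windows, 2,000 substitution classifications,
1,200 indel classifications, 1,000 filter/merge records, 1,156 similarity
entries), recovers a generating signature from 50,000 simulated
substitutions at cosine ≥ 0.99 across five seeds, and recovers a 16-category
indel distribution from 5,000 simulated indels within three binomial
standard errors per category. These sizes were chosen so each statistical
check has sharp power while the whole suite stays lightweight.

# Known limitations

- The merge step treats any shared (chrom, pos, ref, alt) as one event;
  independent recurrent mutation and selection-driven recurrence are
  indistinguishable here, which is exactly why unique counting is used.
- Indel classification assumes simple anchored insertions/deletions;
  complex replacements are excluded (with a tally) rather than decomposed.
- The cross-species correction is trinucleotide-level and
  strand-symmetric; pentanucleotide effects and transcriptional strand
  asymmetries are out of scope.
- No NMF extraction or signature refitting: patterns are compared, not
  decomposed into exposures.
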