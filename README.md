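# MutSpectra

Mutational-spectrum analysis for haploid mutagenesis experiments: from
per-isolate variant calls (VCF) and a reference genome (FASTA) to filtered,
merged unique variants, 96-channel single-base-substitution (SBS) spectra,
microhomology-aware indel spectra, rainfall (inter-mutation distance)
summaries, cross-species trinucleotide-frequency-corrected patterns, and
cosine-similarity comparisons against signature catalogs.

The package targets data from ssDNA mutagenesis reporter systems — e.g.
yeast *cdc13-1* strains that expose long subtelomeric single-stranded DNA,
hypersensitizing the genome to weak mutagens such as formaldehyde and
acetaldehyde — but every operation applies to any haploid isolate
resequencing design.

## The model

**Unique variants.** Per-sample calls are filtered (QUAL ≥ 30, DP ≥ 10 by
default) and merged: identical variants (chrom, pos, ref, alt) found in
multiple isolates are combined into one unique variant. Spectra count each
unique variant once — a hotspot recurrently mutated across isolates may
reflect selection rather than intrinsic mutability, so mutated *motifs* are
counted, not occurrences.

**SBS-96.** Every substitution is reported from its pyrimidine strand: if
the reference base is A or G, the substitution and its trinucleotide
context are reverse-complemented. With 6 substitution types (C>A, C>G,
C>T, T>A, T>C, T>G) and 16 flanking contexts each, a spectrum is a vector
over 96 channels `5'[ref>alt]3'` in the canonical COSMIC order.

**Indels.** After anchor stripping and left alignment, indels are
classified into 83 channels: 1 bp deletions/insertions at C or T by
homopolymer run length; longer deletions/insertions by length bin
(2, 3, 4, 5+) and tandem repeat units; and deletions with breakpoint
microhomology — sequence shared between the deleted segment and its
immediate flank — by microhomology length. Repeat context (≥ 2 tandem
copies) takes priority over microhomology. The 83 channels collapse to a
16-category view and a repeat-unit view.

**Cross-species correction.** To infer how a pattern observed in genome A
would appear in genome B, each channel frequency is multiplied by the
ratio of the corresponding pyrimidine-centered trinucleotide proportions,
f′\_c = f\_c · p\_B(m(c)) / p\_A(m(c)), then renormalized. A motif half as
abundant in the target genome scales its channels by exactly 0.5.

**Comparison.** Patterns are compared by cosine similarity,
cos(a, b) = a·b / (‖a‖‖b‖), and similarity matrices are ordered by
average-linkage hierarchical clustering on 1 − similarity.

A seeded simulator (`simConfig()`, `generateGenome()`, `spikeMutations()`)
generates synthetic genomes and VCFs with signature-driven substitutions,
category-driven indels, subtelomeric enrichment, recurrence and QUAL/DP
annotations, plus a truth table, so the whole pipeline is testable without
any sequencing data.

## Worked example

```r
library(MutSpectra)

cfg <- simConfig(seed = 101, nSamples = 8, substitutionsPerSample = 400,
                 indelsPerSample = 30)
genome <- generateGenome(cfg)
sim <- spikeMutations(genome, cfg)

calls <- lapply(setNames(nm = names(sim$vcf)), function(s)
  filterVariants(readVariantVcf(sim$vcf[[s]], s)))
vs <- mergeUnique(calls, chromOrder = names(genome))
vs
#> VariantSet: 3263 unique variants from 3593 calls across 8 samples

parts <- partitionByClass(vs)
spec <- buildSbsSpectrum(parts$substitutions, genome, label = "simulated")
round(typeFractions(spec), 3)
#>   C>A   C>G   C>T   T>A   T>C   T>G
#> 0.473 0.106 0.110 0.099 0.104 0.109

cosineSimilarity(spec, cfg$signature)
#> 0.9911

ind <- buildIndelSpectrum(parts$indels, genome)
head(sort(collapse16(ind), decreasing = TRUE), 4)
#> del1T ins1T del1C  del2
#>    76    51    20    13

endProximity(vs, genome, window = 5000)$fraction
#> 0.676
```

Reading the numbers: of 3593 filtered calls, 330 were recurrent across
isolates and merged away. The simulated mutagen elevates C>A (47% of
substitutions, vs 1/6 under uniformity), the extracted spectrum recovers
the generating signature at cosine 0.99, indels are dominated by 1 bp
events at T/A pairs, and two-thirds of variants fall within 5 kb of a
chromosome end (the simulated ssDNA regions, default enrichment 10× over a
5 kb window).

`runPipeline(config, outDir)` performs all of the above — plus optional
cross-species correction and catalog matching — over grouped sample tables
(e.g. control / formaldehyde / acetaldehyde) and writes per-group TSVs and
a manifest.

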