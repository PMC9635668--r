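Package: MutSpectra
Title: Mutational Spectrum Analysis for ssDNA Mutagenesis Reporter Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds mutational spectra from per-isolate variant calls against
    a haploid reference genome. Variants are quality- and depth-filtered,
    merged across samples into unique variants, and classified into the
    96-channel single-base-substitution scheme (pyrimidine-strand
    trinucleotide convention) and an 83-channel indel scheme with
    microhomology and repeat-unit awareness. Spectra can be re-weighted
    between species by the ratio of genome-wide trinucleotide proportions,
    compared against signature catalogs by cosine similarity, ordered by
    hierarchical clustering, and examined with rainfall (inter-mutation
    distance) summaries. A seeded simulator generates synthetic genomes and
    VCFs with subtelomeric mutation enrichment for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
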