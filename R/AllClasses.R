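#' Genome-wide pyrimidine-centered trinucleotide proportions
#'
#' Holds the proportion of each of the 32 pyrimidine-centered trinucleotide
#' motifs in a genome, after collapsing purine-centered windows onto their
#' reverse complements, plus the number of windows counted.
#'
#' @slot proportions Named numeric vector of length 32 in canonical motif
#'   order ([trinucMotifs()]); non-negative, sums to 1 when any window was
#'   counted.
#' @slot counts Named numeric vector of raw collapsed window counts.
#' @slot totalCount Total number of counted trinucleotide windows.
#' @export
setClass("TrinucFrequencies",
  representation(proportions = "numeric", counts = "numeric",
                 totalCount = "numeric"))

setValidity("TrinucFrequencies", function(object) {
  p <- object@proportions
  if (length(p) != 32L || !identical(names(p), trinucMotifs()))
    return("proportions must be named by the 32 canonical motifs, in order")
  if (any(p < 0)) return("proportions must be non-negative")
  if (object@totalCount > 0 && abs(sum(p) - 1) > 1e-12)
    return("proportions must sum to 1")
  TRUE
})

#' 96-channel single-base-substitution spectrum
#'
#' Counts (or frequencies) over the 96 trinucleotide substitution channels in
#' canonical COSMIC order, pyrimidine-strand convention.
#'
#' @slot counts Named numeric vector of length 96, canonical channel order,
#'   all entries non-negative.
#' @slot label Free-text provenance label.
#' @slot metadata List of provenance/diagnostic values (e.g. unclassifiable
#'   counts, correction multipliers).
#' @export
setClass("SbsSpectrum",
  representation(counts = "numeric", label = "character", metadata = "list"),
  prototype(label = "", metadata = list()))

setValidity("SbsSpectrum", function(object) {
  x <- object@counts
  if (length(x) != 96L || !identical(names(x), sbsChannels()))
    return("counts must be named by the 96 canonical channels, in order")
  if (any(is.na(x)) || any(x < 0)) return("counts must be non-negative")
  TRUE
})

#' 83-channel indel spectrum
#'
#' Counts over the 83 indel channels: 1 bp deletions/insertions at C or T by
#' homopolymer run length, longer deletions/insertions by length bin and
#' tandem repeat units, and deletions with breakpoint microhomology by length
#' bin and microhomology length.
#'
#' @slot counts Named numeric vector of length 83 in canonical order
#'   ([indelChannels()]).
#' @slot label Free-text provenance label.
#' @slot diagnostics List: total calls, unique indels, unclassifiable count.
#' @export
setClass("IndelSpectrum",
  representation(counts = "numeric", label = "character",
                 diagnostics = "list"),
  prototype(label = "", diagnostics = list()))

setValidity("IndelSpectrum", function(object) {
  x <- object@counts
  if (length(x) != 83L || !identical(names(x), indelChannels()))
    return("counts must be named by the 83 canonical indel channels")
  if (any(is.na(x)) || any(x < 0)) return("counts must be non-negative")
  TRUE
})

#' Set of unique variants merged across samples
#'
#' One row per unique (chrom, pos, ref, alt); the `samples` column records
#' which samples carry the variant. Totals before deduplication are kept so
#' both "total calls" and "unique variants" can be reported.
#'
#' @slot records data.frame with columns chrom, pos, ref, alt, qual, depth,
#'   nCarriers, samples (list column), sorted by (chrom order, pos, ref, alt).
#' @slot nSamples Number of contributing samples.
#' @slot nTotalCalls Sum of per-sample call counts before deduplication.
#' @slot diagnostics List (e.g. count of complex variants excluded by class
#'   partitioning).
#' @export
setClass("VariantSet",
  representation(records = "data.frame", nSamples = "integer",
                 nTotalCalls = "integer", diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("VariantSet", function(object) {
  r <- object@records
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth", "nCarriers",
            "samples")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0) {
    key <- paste(r$chrom, r$pos, r$ref, r$alt)
    if (anyDuplicated(key)) return("records must be unique on (chrom, pos, ref, alt)")
    if (any(r$pos < 1)) return("positions must be >= 1")
  }
  if (object@nTotalCalls < nrow(r))
    return("nTotalCalls cannot be smaller than the number of unique records")
  TRUE
})

#' Catalog of reference mutational signatures
#'
#' A matrix of 96-channel frequency vectors (one column per signature, e.g.
#' COSMIC SBS signatures), rows aligned to the canonical channel order.
#'
#' @slot signatures Numeric matrix, 96 rows (canonical channel order), one
#'   named column per signature; columns non-negative, each summing to 1
#'   within 1e-6.
#' @export
setClass("SignatureCatalog", representation(signatures = "matrix"))

setValidity("SignatureCatalog", function(object) {
  m <- object@signatures
  if (nrow(m) != 96L || !identical(rownames(m), sbsChannels()))
    return("rows must be the 96 canonical channels, in order")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("signatures must have unique column names")
  if (any(m < 0)) return("signature vectors must be non-negative")
  if (any(abs(colSums(m) - 1) > 1e-6))
    return("each signature must sum to 1 (within 1e-6)")
  TRUE
})

setMethod("show", "TrinucFrequencies", function(object) {
  cat("TrinucFrequencies over", length(object@proportions), "motifs;",
      object@totalCount, "windows counted\n")
  top <- sort(object@proportions, decreasing = TRUE)[1:5]
  cat("  most abundant:",
      paste(sprintf("%s=%.4f", names(top), top), collapse = " "), "\n")
})

setMethod("show", "SbsSpectrum", function(object) {
  tot <- sum(object@counts)
  cat("SbsSpectrum", if (nzchar(object@label)) sQuote(object@label) else "",
      "- total", format(tot), "\n")
  if (tot > 0) {
    f <- typeFractions(object)
    cat("  type fractions:",
        paste(sprintf("%s=%.3f", names(f), f), collapse = " "), "\n")
  }
})

setMethod("show", "IndelSpectrum", function(object) {
  cat("IndelSpectrum", if (nzchar(object@label)) sQuote(object@label) else "",
      "- total", format(sum(object@counts)), "\n")
  f <- collapse16(object)
  nz <- f[f > 0]
  if (length(nz))
    cat("  categories:", paste(sprintf("%s=%g", names(nz), nz), collapse = " "),
        "\n")
})

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet:", nrow(object@records), "unique variants from",
      object@nTotalCalls, "calls across", object@nSamples, "samples\n")
})

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog with", ncol(object@signatures), "signatures:",
      paste(utils::head(colnames(object@signatures), 8), collapse = ", "),
      if (ncol(object@signatures) > 8) "..." else "", "\n")
})

#' @describeIn TrinucFrequencies-class Motif proportions (named, length 32).
#' @param x A `TrinucFrequencies` object.
#' @export
motifProportions <- function(x) {
  stopifnot(is(x, "TrinucFrequencies"))
  x@proportions
}

#' @describeIn TrinucFrequencies-class Number of windows counted.
#' @export
totalCount <- function(x) {
  stopifnot(is(x, "TrinucFrequencies"))
  x@totalCount
}

#' Channel counts of a spectrum
#'
#' @param x An `SbsSpectrum` or `IndelSpectrum`.
#' @return Named numeric vector of per-channel counts.
#' @export
channelCounts <- function(x) {
  stopifnot(is(x, "SbsSpectrum") || is(x, "IndelSpectrum"))
  x@counts
}

#' Spectrum as a frequency vector
#'
#' @param x An `SbsSpectrum` or `IndelSpectrum`.
#' @return Named numeric vector summing to 1.
#' @export
asFrequencies <- function(x) {
  cts <- channelCounts(x)
  tot <- sum(cts)
  if (tot <= 0) stop("cannot normalize a zero-total spectrum")
  cts / tot
}

#' Unique variant records of a VariantSet
#'
#' @param x A `VariantSet`.
#' @return data.frame with one row per unique variant.
#' @export
variantRecords <- function(x) {
  stopifnot(is(x, "VariantSet"))
  x@records
}

#' @describeIn VariantSet-class Number of contributing samples.
#' @param x A `VariantSet`.
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "VariantSet"))
  x@nSamples
}

#' @describeIn VariantSet-class Total call count before deduplication.
#' @export
nTotalCalls <- function(x) {
  stopifnot(is(x, "VariantSet"))
  x@nTotalCalls
}

#' Signature matrix of a catalog
#'
#' @param x A `SignatureCatalog`.
#' @return 96-row numeric matrix, one column per signature.
#' @export
signatureMatrix <- function(x) {
  stopifnot(is(x, "SignatureCatalog"))
  x@signatures
}

#' Signature names in a catalog
#'
#' @param x A `SignatureCatalog`.
#' @export
signatureNames <- function(x) {
  stopifnot(is(x, "SignatureCatalog"))
  colnames(x@signatures)
}
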