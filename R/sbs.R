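#' Classify substitutions into the 96-channel scheme
#'
#' Assigns each single-base substitution to one of the 6 pyrimidine-strand
#' substitution types and 96 trinucleotide channels. When the reference base
#' is a purine, the substitution and its context are reverse-complemented
#' first, so every event is reported from its pyrimidine strand. Variants
#' whose context is unavailable (chromosome end, or N in the window) get NA
#' and are tallied. A mismatch between a record's ref allele and the genome
#' base is a hard error: it indicates the wrong reference was supplied.
#'
#' @param vs A `VariantSet` of substitutions (see [partitionByClass()]), or
#'   a data.frame with chrom/pos/ref/alt columns.
#' @param genome A `DNAStringSet` from [readGenome()].
#' @return data.frame with columns chrom, pos, ref, alt, typeIndex (1..6),
#'   channelIndex (1..96), channel (label); NA rows where context is
#'   undefined.
#' @export
classifySubstitutions <- function(vs, genome) {
  .checkGenome(genome)
  r <- if (is(vs, "VariantSet")) vs@records else vs
  if (nrow(r) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      typeIndex = integer(), channelIndex = integer(),
                      channel = character(), stringsAsFactors = FALSE))
  stopifnot(all(nchar(r$ref) == 1L), all(nchar(r$alt) == 1L))
  unknown <- setdiff(unique(r$chrom), names(genome))
  if (length(unknown))
    stop("variant chromosome(s) not in genome: ",
         paste(unknown, collapse = ", "))

  ctx <- character(nrow(r))
  for (ch in unique(r$chrom)) {
    i <- which(r$chrom == ch)
    seq <- as.character(genome[[ch]])
    len <- nchar(seq)
    p <- r$pos[i]
    if (any(p < 1 | p > len))
      stop("position out of range on ", ch)
    refBase <- substring(seq, p, p)
    bad <- refBase != r$ref[i]
    if (any(bad)) {
      j <- i[which(bad)[1]]
      stop("reference mismatch at ", r$chrom[j], ":", r$pos[j],
           " (VCF ref ", r$ref[j], ", genome ", refBase[which(bad)[1]], ")")
    }
    w <- substring(seq, p - 1L, p + 1L)
    w[p == 1L | p == len] <- NA_character_
    ctx[i] <- w
  }
  ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA_character_

  motif <- rep(NA_character_, nrow(r))
  alt <- r$alt
  usable <- !is.na(ctx)
  motif[usable] <- .trinucLookup$motif[ctx[usable]]
  flip <- usable & .trinucLookup$flip[ifelse(usable, ctx, "AAA")]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  chIdx <- rep(NA_integer_, nrow(r))
  chIdx[usable] <- .channelIndex[paste0(motif[usable], ">", alt[usable])]
  data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
             typeIndex = ((chIdx - 1L) %/% 16L) + 1L,
             channelIndex = chIdx,
             channel = ifelse(is.na(chIdx), NA_character_,
                              sbsChannels()[pmax(chIdx, 1L)]),
             stringsAsFactors = FALSE)
}

#' Build a 96-channel spectrum from unique substitutions
#'
#' Each unique variant contributes once to its channel, no matter how many
#' samples carry it — recurrence at a hotspot may reflect selection rather
#' than intrinsic mutability, so mutated motifs are counted, not
#' occurrences. Set `perOccurrence = TRUE` to weight each variant by its
#' carrier count instead (sensitivity analysis only).
#'
#' @param vs A `VariantSet` of substitutions.
#' @param genome A `DNAStringSet`.
#' @param label Provenance label stored on the spectrum.
#' @param perOccurrence Weight variants by carrier count (default FALSE).
#' @return An [SbsSpectrum-class]; `metadata(x)$unclassified` counts
#'   variants without a defined context.
#' @export
buildSbsSpectrum <- function(vs, genome, label = "", perOccurrence = FALSE) {
  cls <- classifySubstitutions(vs, genome)
  w <- if (perOccurrence && is(vs, "VariantSet")) vs@records$nCarriers
       else rep(1, nrow(cls))
  ok <- !is.na(cls$channelIndex)
  counts <- stats::setNames(numeric(96), sbsChannels())
  if (any(ok)) {
    tab <- tapply(w[ok], factor(cls$channelIndex[ok], levels = 1:96), sum)
    counts[] <- ifelse(is.na(tab), 0, tab)
  }
  new("SbsSpectrum", counts = counts, label = label,
      metadata = list(unclassified = sum(!ok)))
}

.TYPE6_LABELS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Collapse a 96-channel spectrum to the 6 substitution types
#'
#' @param s An `SbsSpectrum` with positive total.
#' @return Named numeric vector of 6 fractions summing to 1, in the order
#'   C>A, C>G, C>T, T>A, T>C, T>G (strand-collapsed, so C>A covers C/G>A/T).
#' @export
typeFractions <- function(s) {
  cts <- channelCounts(s)
  tot <- sum(cts)
  if (tot <= 0) stop("type fractions are undefined for a zero-total spectrum")
  byType <- vapply(0:5, function(k) sum(cts[(k * 16 + 1):(k * 16 + 16)]),
                   numeric(1))
  stats::setNames(byType / tot, .TYPE6_LABELS)
}

#' Inter-mutation distances (rainfall series)
#'
#' For each chromosome, unique variants are sorted by position and each is
#' assigned the distance to the previous variant on the same chromosome;
#' the first variant per chromosome has distance NA. Distances are never
#' computed across chromosomes. Substitutions and indels can both be
#' included by passing the merged set.
#'
#' @param vs A `VariantSet`.
#' @param genome Optional `DNAStringSet` giving chromosome ordering.
#' @return data.frame with columns chrom, pos, distance.
#' @export
rainfall <- function(vs, genome = NULL) {
  r <- variantRecords(vs)
  chromLevels <- if (!is.null(genome)) names(genome) else unique(r$chrom)
  ord <- order(match(r$chrom, chromLevels), r$pos, method = "radix")
  r <- r[ord, , drop = FALSE]
  pos <- unique(r[, c("chrom", "pos")])
  dist <- unlist(lapply(split(pos$pos, factor(pos$chrom,
                                              levels = unique(pos$chrom))),
                        function(p) c(NA, diff(p))), use.names = FALSE)
  data.frame(chrom = pos$chrom, pos = pos$pos, distance = dist,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of variants near chromosome ends
#'
#' In the cdc13-1 ssDNA reporter system, long subtelomeric single-stranded
#' regions form at chromosome ends, so induced mutations cluster there. This
#' summarizes that clustering: the fraction of unique variants lying within
#' `window` bases of either end of their chromosome.
#'
#' @param vs A non-empty `VariantSet`.
#' @param genome A `DNAStringSet` (for chromosome lengths).
#' @param window Size in bases of the end windows; required, positive.
#' @return List: `fraction` (overall), `perChromosome` (data.frame with
#'   chrom, n, nNear, fraction).
#' @export
endProximity <- function(vs, genome, window) {
  .checkGenome(genome)
  if (window <= 0) stop("window must be positive")
  r <- variantRecords(vs)
  if (nrow(r) == 0L) stop("end proximity is undefined for an empty set")
  unknown <- setdiff(unique(r$chrom), names(genome))
  if (length(unknown))
    stop("variant chromosome(s) not in genome: ",
         paste(unknown, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  near <- r$pos <= window | r$pos > lens[r$chrom] - window
  per <- do.call(rbind, lapply(split(near, r$chrom), function(x)
    data.frame(n = length(x), nNear = sum(x), fraction = mean(x))))
  per <- data.frame(chrom = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(fraction = mean(near), perChromosome = per)
}

#' Write / read a 96-channel spectrum as TSV
#'
#' 96 rows with columns `channel` (e.g. `"A[C>A]A"`), `count`, `frequency`.
#' The same dialect is accepted by the signature-catalog reader.
#'
#' @param s An `SbsSpectrum`.
#' @param path TSV path.
#' @export
writeSpectrumTsv <- function(s, path) {
  cts <- channelCounts(s)
  tot <- sum(cts)
  df <- data.frame(channel = names(cts), count = cts,
                   frequency = if (tot > 0) cts / tot else cts * 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTsv
#' @param label Provenance label for the returned spectrum.
#' @export
readSpectrumTsv <- function(path, label = "") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "count") %in% names(df)))
    stop("spectrum TSV must have 'channel' and 'count' columns")
  if (!setequal(df$channel, sbsChannels()) || nrow(df) != 96L)
    stop("spectrum TSV must contain exactly the 96 canonical channels")
  cts <- stats::setNames(df$count, df$channel)[sbsChannels()]
  new("SbsSpectrum", counts = cts, label = label)
}
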