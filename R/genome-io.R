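#' Read a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA into a
#' [Biostrings::DNAStringSet], normalizing to uppercase and mapping U to T.
#' Chromosome order in the file is preserved. Characters outside
#' \{A, C, G, T, N, U\} are rejected: silently coercing ambiguity codes would
#' corrupt downstream motif counts.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per chromosome, uppercase.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' genome <- readGenome(fa)
#' width(genome)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  # names: first whitespace-delimited token, per common FASTA convention
  nms <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(nms))) stop("FASTA contains a record with an empty name")
  if (anyDuplicated(nms))
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop("non-{A,C,G,T,N,U} characters in FASTA (", paste(ch, collapse = ","),
         ") in record(s): ", paste(nms[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  out
}

.checkGenome <- function(genome) {
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet (see readGenome)")
  invisible(genome)
}

#' Trinucleotide context at a genomic position
#'
#' Returns the reference-strand 3-mer centered on `pos` (bases pos-1..pos+1),
#' or `NA` when no context exists: at the first or last base of a chromosome,
#' or when any base in the window is N.
#'
#' @param genome A `DNAStringSet` from [readGenome()].
#' @param chrom Chromosome name.
#' @param pos 1-based position within the chromosome.
#' @return A 3-character string, or `NA_character_`.
#' @export
trinucContext <- function(genome, chrom, pos) {
  .checkGenome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (pos < 1 || pos > len)
    stop("position ", pos, " out of range for ", chrom, " (length ", len, ")")
  if (pos == 1 || pos == len) return(NA_character_)
  ctx <- as.character(Biostrings::subseq(genome[[chrom]], pos - 1L, pos + 1L))
  if (grepl("N", ctx, fixed = TRUE)) return(NA_character_)
  ctx
}

#' Genome-wide trinucleotide proportions
#'
#' Slides a width-3 window over every chromosome (positions with both flanks
#' only), skips windows containing N, and collapses windows centered on A or
#' G onto their reverse-complement motif, yielding proportions of the 32
#' pyrimidine-centered motifs.
#'
#' @param genome A `DNAStringSet` from [readGenome()].
#' @param exclude Character vector of chromosome names to leave out (e.g. a
#'   mitochondrial contig or an engineered cassette).
#' @return A [TrinucFrequencies-class] object.
#' @export
countTrinucleotides <- function(genome, exclude = character()) {
  .checkGenome(genome)
  if (length(exclude)) {
    missing <- setdiff(exclude, names(genome))
    if (length(missing))
      stop("exclude names not in genome: ", paste(missing, collapse = ", "))
    genome <- genome[!names(genome) %in% exclude]
  }
  if (length(genome) == 0L) stop("no chromosomes left to count")
  # trinucleotideFrequency counts only ACGT words, so N windows drop out
  counts64 <- colSums(Biostrings::trinucleotideFrequency(genome, step = 1))
  canon <- .trinucLookup$motif[names(counts64)]
  counts32 <- vapply(trinucMotifs(),
                     function(m) sum(counts64[canon == m]), numeric(1))
  total <- sum(counts32)
  if (total == 0) stop("genome has no countable trinucleotide windows")
  new("TrinucFrequencies", proportions = counts32 / total,
      counts = counts32, totalCount = total)
}

#' Write / read trinucleotide frequency tables
#'
#' Plain TSV with columns `motif` and `proportion` (32 rows, canonical motif
#' order), so precomputed proportions for another species can be supplied in
#' place of a FASTA.
#'
#' @param x A `TrinucFrequencies` object.
#' @param path Output (or input) TSV path.
#' @return `readTrinucFrequencies` returns a `TrinucFrequencies` object;
#'   `totalCount` is 0 when the file does not carry window counts.
#' @export
writeTrinucFrequencies <- function(x, path) {
  stopifnot(is(x, "TrinucFrequencies"))
  df <- data.frame(motif = names(x@proportions), proportion = x@proportions,
                   count = x@counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrinucFrequencies
#' @export
readTrinucFrequencies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif", "proportion") %in% names(df)))
    stop("frequency table must have 'motif' and 'proportion' columns")
  if (!setequal(df$motif, trinucMotifs()) || nrow(df) != 32L)
    stop("frequency table must contain exactly the 32 canonical motifs")
  p <- stats::setNames(df$proportion, df$motif)[trinucMotifs()]
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop("proportions must sum to 1 (found ", s, ")")
  cts <- if ("count" %in% names(df))
    stats::setNames(df$count, df$motif)[trinucMotifs()] else p * 0
  new("TrinucFrequencies", proportions = p / s, counts = cts,
      totalCount = sum(cts))
}
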