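#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
NULL

.BASES <- c("A", "C", "G", "T")
.SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical 96-channel labels
#'
#' Channel order is fixed: the six pyrimidine-strand substitution types in the
#' order C>A, C>G, C>T, T>A, T>C, T>G, and within each type the 16 flanking
#' contexts ordered by 5' base then 3' base (each A, C, G, T). Channel 1 is
#' `A[C>A]A`; channel 96 is `T[T>G]T`.
#'
#' @return Character vector of 96 labels such as `"A[C>A]A"`.
#' @export
sbsChannels <- function() {
  unlist(lapply(.SBS_TYPES, function(ty) {
    unlist(lapply(.BASES, function(f) paste0(f, "[", ty, "]", .BASES)))
  }))
}

#' Canonical 32 pyrimidine-centered trinucleotide motifs
#'
#' Motifs with a C center come first, then a T center; within each center
#' block the 16 motifs are ordered by 5' base then 3' base.
#'
#' @return Character vector of 32 motifs such as `"ACA"`.
#' @export
trinucMotifs <- function() {
  unlist(lapply(c("C", "T"), function(ctr) {
    unlist(lapply(.BASES, function(f) paste0(f, ctr, .BASES)))
  }))
}

#' Trinucleotide motif underlying each of the 96 channels
#'
#' @return Character vector of 32 motif labels, one per channel, aligned to
#'   [sbsChannels()].
#' @export
channelMotifs <- function() {
  ch <- sbsChannels()
  paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
}

# lookup tables over all 64 trinucleotides: canonical pyrimidine-strand motif
# and whether the canonical representation required a strand flip
.trinucLookup <- local({
  all64 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  ctr <- substr(all64, 2, 2)
  canon <- ifelse(ctr %in% c("C", "T"), all64, .revcomp(all64))
  flip <- !(ctr %in% c("C", "T"))
  list(motif = stats::setNames(canon, all64), flip = stats::setNames(flip, all64))
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# channel index for (pyrimidine-strand motif, pyrimidine-strand alt)
.channelIndex <- local({
  ch <- sbsChannels()
  key <- paste0(channelMotifs(), ">", substr(ch, 5, 5))
  stats::setNames(seq_len(96L), key)
})
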