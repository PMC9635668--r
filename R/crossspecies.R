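#' Re-weight a spectrum between genomes with different trinucleotide content
#'
#' To infer how a mutational pattern observed in one species (e.g. yeast)
#' would appear in another (e.g. mouse), the frequency of each of the 96
#' channels is multiplied by the ratio of the corresponding trinucleotide
#' proportions in the target vs. the source genome: a motif half as abundant
#' in the target scales its channels by 0.5. The corrected vector is then
#' renormalized to sum 1; cosine comparisons are unaffected by that
#' scale factor.
#'
#' Channels whose motif has zero target proportion are set to 0 with a
#' warning (the motif cannot mutate in the target genome). A zero source
#' proportion under a channel carrying mass is an error: the ratio is
#' undefined.
#'
#' @param s An `SbsSpectrum` (counts or frequencies; used as frequencies).
#' @param source `TrinucFrequencies` of the genome the spectrum was
#'   observed on.
#' @param target `TrinucFrequencies` of the genome to project onto.
#' @return An `SbsSpectrum` of corrected frequencies;
#'   `metadata(x)$multipliers` holds the 96 per-channel ratios applied
#'   before renormalization, `metadata(x)$scaled` the unnormalized scaled
#'   vector.
#' @export
correctSpectrum <- function(s, source, target) {
  stopifnot(is(s, "SbsSpectrum"), is(source, "TrinucFrequencies"),
            is(target, "TrinucFrequencies"))
  f <- asFrequencies(s)
  motifs <- channelMotifs()
  ps <- motifProportions(source)[motifs]
  pt <- motifProportions(target)[motifs]
  bad <- ps == 0 & f > 0
  if (any(bad))
    stop("source proportion is zero for motif(s) carrying spectrum mass: ",
         paste(unique(motifs[bad]), collapse = ", "))
  mult <- ifelse(ps > 0, pt / ps, 0)
  if (any(pt == 0 & f > 0))
    warning("motif(s) absent from target genome; their channels set to 0: ",
            paste(unique(motifs[pt == 0 & f > 0]), collapse = ", "))
  scaled <- f * mult
  tot <- sum(scaled)
  if (tot <= 0) stop("all spectrum mass fell on motifs absent from target")
  new("SbsSpectrum", counts = stats::setNames(scaled / tot, sbsChannels()),
      label = paste0(s@label, if (nzchar(s@label)) " " else "",
                     "(trinucleotide-corrected)"),
      metadata = list(multipliers = stats::setNames(mult, sbsChannels()),
                      scaled = stats::setNames(scaled, sbsChannels())))
}
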