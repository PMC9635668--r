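#' Default 96-channel signature used by the simulator
#'
#' An aldehyde-like pattern: a flat background over all channels (as in the
#' clock-like SBS5/SBS40 family) with elevated C>A mass, strongest at
#' 5'-TC motifs — the qualitative shape of small-aldehyde mutagenesis in
#' ssDNA, where C/G>A/T transversions at TC/GA motifs are enriched.
#'
#' @return Named numeric vector of 96 frequencies summing to 1.
#' @export
defaultSignature <- function() {
  ch <- sbsChannels()
  w <- rep(1, 96)
  isCA <- grepl("[C>A]", ch, fixed = TRUE)
  w[isCA] <- 3
  w[isCA & substr(ch, 1, 1) == "T"] <- 8
  stats::setNames(w / sum(w), ch)
}

#' Default 16-category indel distribution used by the simulator
#'
#' Dominated by 1 bp events at T/A base pairs (homopolymer slippage), with
#' modest mass on longer deletions/insertions and on microhomology
#' deletions.
#'
#' @return Named numeric vector of 16 frequencies summing to 1.
#' @export
defaultIndelDistribution <- function() {
  p <- c(del1C = 0.10, del1T = 0.34, ins1C = 0.06, ins1T = 0.22,
         del2 = 0.05, del3 = 0.03, del4 = 0.02, "del5+" = 0.04,
         ins2 = 0.03, ins3 = 0.02, ins4 = 0.01, "ins5+" = 0.01,
         mhdel2 = 0.03, mhdel3 = 0.02, mhdel4 = 0.01, "mhdel5+" = 0.01)
  p / sum(p)
}

#' Simulation configuration
#'
#' Defines a synthetic mutagenized-genome experiment: a small
#' multi-chromosome haploid genome, point mutations drawn from a 96-channel
#' signature, indels drawn from a 16-category distribution, enrichment of
#' events near chromosome ends (where the ssDNA reporter system exposes
#' single-stranded DNA), recurrence of variants across samples, and
#' per-call QUAL/DP annotations of which a stated fraction fails the
#' standard quality filter.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param nChromosomes,chromosomeLength Genome shape (default 16 x 50 kb, a
#'   scaled-down yeast-like karyotype).
#' @param gcContent GC fraction of the random genome (default 0.38,
#'   yeast-like).
#' @param subtelomereWindow Bases at each chromosome end treated as
#'   ssDNA-exposed (default 5000).
#' @param subtelomereEnrichment Relative mutation rate inside end windows
#'   (>= 1; default 10).
#' @param nSamples Number of simulated isolates (default 20).
#' @param substitutionsPerSample,indelsPerSample Events per isolate
#'   (defaults 100 and 10).
#' @param signature 96-channel sampling distribution for substitutions.
#' @param indelDistribution 16-category sampling distribution for indels.
#' @param recurrenceRate Probability an event is copied into one additional
#'   sample (default 0.1).
#' @param failFraction Fraction of calls annotated with QUAL/DP failing the
#'   QUAL >= 30, DP >= 10 filter (default 0.05).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 16L,
                      chromosomeLength = 50000L,
                      gcContent = 0.38,
                      subtelomereWindow = 5000L,
                      subtelomereEnrichment = 10,
                      nSamples = 20L,
                      substitutionsPerSample = 100L,
                      indelsPerSample = 10L,
                      signature = defaultSignature(),
                      indelDistribution = defaultIndelDistribution(),
                      recurrenceRate = 0.1,
                      failFraction = 0.05) {
  if (gcContent <= 0 || gcContent >= 1)
    stop("gcContent must be strictly between 0 and 1")
  if (subtelomereEnrichment < 1) stop("subtelomereEnrichment must be >= 1")
  if (length(signature) != 96L || any(signature < 0) || sum(signature) <= 0)
    stop("signature must be a non-negative 96-vector with positive sum")
  if (length(indelDistribution) != 16L || any(indelDistribution < 0) ||
      sum(indelDistribution) <= 0)
    stop("indelDistribution must be a non-negative 16-vector with positive sum")
  if (recurrenceRate < 0 || recurrenceRate > 1 ||
      failFraction < 0 || failFraction > 1)
    stop("recurrenceRate and failFraction must be in [0, 1]")
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromosomeLength = as.integer(chromosomeLength),
              gcContent = gcContent,
              subtelomereWindow = as.integer(subtelomereWindow),
              subtelomereEnrichment = subtelomereEnrichment,
              nSamples = as.integer(nSamples),
              substitutionsPerSample = as.integer(substitutionsPerSample),
              indelsPerSample = as.integer(indelsPerSample),
              signature = signature / sum(signature),
              indelDistribution = indelDistribution / sum(indelDistribution),
              recurrenceRate = recurrenceRate, failFraction = failFraction)
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a random haploid genome
#'
#' i.i.d. bases at the configured GC fraction, one chromosome per entry,
#' reproducible from the config seed.
#'
#' @param cfg A [simConfig()].
#' @return A `DNAStringSet` with chromosomes named `chr1`, `chr2`, ...
#' @export
generateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  p <- c((1 - cfg$gcContent) / 2, cfg$gcContent / 2, cfg$gcContent / 2,
         (1 - cfg$gcContent) / 2)
  seqs <- vapply(seq_len(cfg$nChromosomes), function(i)
    paste(sample(.BASES, cfg$chromosomeLength, replace = TRUE, prob = p),
          collapse = ""), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(cfg$nChromosomes))
  out
}

# position-weight helper: enrichment inside end windows, 1 elsewhere
.posWeight <- function(pos, len, window, enrichment) {
  ifelse(pos <= window | pos > len - window, enrichment, 1)
}

.qualDepth <- function(n, failFraction) {
  fail <- stats::runif(n) < failFraction
  qual <- round(stats::runif(n, 30, 60), 1)
  depth <- sample(10:60, n, replace = TRUE)
  if (any(fail)) {
    lowQual <- fail & stats::runif(n) < 0.5
    lowDp <- fail & !lowQual
    qual[lowQual] <- round(stats::runif(sum(lowQual), 2, 29.5), 1)
    depth[lowDp] <- sample(1:9, sum(lowDp), replace = TRUE)
  }
  list(qual = qual, depth = depth, fail = fail)
}

#' Spike signature-driven mutations into a genome and emit VCFs
#'
#' Substitution channels are drawn first from the configured signature and a
#' matching genomic site is then chosen (weighted toward chromosome ends by
#' the subtelomere enrichment), so the realized spectrum converges to the
#' signature regardless of genome composition. Sites are drawn without
#' replacement per motif. Indels are built by rejection sampling so that
#' each event's constructed context guarantees its intended 16-category
#' class (e.g. microhomology deletions are placed where the deleted
#' sequence's first base recurs immediately 3' of the deletion, with no
#' full tandem copy). Each event lands in one sample; with probability
#' `recurrenceRate` it is copied into one additional sample. Every call is
#' annotated with QUAL and INFO/DP such that about `failFraction` of calls
#' fail the QUAL >= 30 / DP >= 10 filter.
#'
#' A truth table records every emitted call with its generating channel or
#' category, so tests never re-derive ground truth from the pipeline under
#' test.
#'
#' @param genome A `DNAStringSet` (typically from [generateGenome()]).
#' @param cfg The same [simConfig()].
#' @param dir Output directory for VCFs and the truth table (created).
#' @return List: `vcf` (named vector of per-sample VCF paths), `truth`
#'   (data.frame: sample, chrom, pos, ref, alt, class, channel, category,
#'   qual, depth, passesFilter), `truthPath`, `dir`.
#' @export
spikeMutations <- function(genome, cfg, dir = tempfile("simvcf")) {
  stopifnot(inherits(cfg, "SimConfig"))
  .checkGenome(genome)
  set.seed(cfg$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- names(genome)
  lens <- stats::setNames(Biostrings::width(genome), chroms)
  chars <- lapply(chroms, function(ch) strsplit(as.character(genome[[ch]]),
                                                "")[[1]])
  names(chars) <- chroms

  ## ---- site index: canonical motif of every interior position ----
  siteTab <- do.call(rbind, lapply(chroms, function(ch) {
    s <- as.character(genome[[ch]])
    n <- nchar(s)
    win <- substring(s, 1:(n - 2L), 3:n)
    data.frame(chrom = ch, pos = 2:(n - 1L),
               motif = unname(.trinucLookup$motif[win]),
               flip = unname(.trinucLookup$flip[win]),
               stringsAsFactors = FALSE)
  }))
  siteTab$w <- .posWeight(siteTab$pos, lens[siteTab$chrom],
                          cfg$subtelomereWindow, cfg$subtelomereEnrichment)
  rowsByMotif <- split(seq_len(nrow(siteTab)), siteTab$motif)

  ## ---- substitutions: channel first, then a matching site ----
  nSub <- cfg$nSamples * cfg$substitutionsPerSample
  chIdx <- sample.int(96L, nSub, replace = TRUE, prob = cfg$signature)
  motifs <- channelMotifs()[chIdx]
  siteRow <- integer(nSub)
  for (m in unique(motifs)) {
    ev <- which(motifs == m)
    cand <- rowsByMotif[[m]]
    if (is.null(cand) || length(cand) < length(ev))
      stop("not enough genomic sites for motif ", m, ": need ",
           length(ev), ", found ", length(cand))
    siteRow[ev] <- cand[sample.int(length(cand), length(ev),
                                   prob = siteTab$w[cand])]
  }
  subChrom <- siteTab$chrom[siteRow]
  subPos <- siteTab$pos[siteRow]
  flip <- siteTab$flip[siteRow]
  pyrAlt <- substr(sbsChannels()[chIdx], 5, 5)
  subAlt <- ifelse(flip, .COMPLEMENT[pyrAlt], pyrAlt)
  subRef <- mapply(function(ch, p) chars[[ch]][p], subChrom, subPos,
                   USE.NAMES = FALSE)
  subs <- data.frame(chrom = subChrom, pos = subPos, ref = subRef,
                     alt = unname(subAlt),
                     class = rep("substitution", nSub),
                     channel = sbsChannels()[chIdx],
                     category = rep(NA_character_, nSub),
                     stringsAsFactors = FALSE)

  ## ---- indels by rejection sampling with category-guaranteeing contexts ----
  nInd <- cfg$nSamples * cfg$indelsPerSample
  occupied <- lapply(lens, function(L) logical(L))
  catIdx <- if (nInd > 0)
    sample.int(16L, nInd, replace = TRUE, prob = cfg$indelDistribution)
  else integer(0)
  indList <- vector("list", nInd)
  chromProb <- lens / sum(lens)
  for (e in seq_len(nInd)) {
    cat16 <- .INDEL16[catIdx[e]]
    placed <- FALSE
    for (try in 1:2000) {
      ch <- sample(chroms, 1L, prob = chromProb)
      cc <- chars[[ch]]
      L <- lens[[ch]]
      ev <- .makeIndelEvent(cat16, cc, L)
      if (is.null(ev)) next
      lo <- max(1L, ev$p - 8L)
      hi <- min(L, ev$p + ev$len + 8L)
      if (any(occupied[[ch]][lo:hi])) next
      occupied[[ch]][lo:hi] <- TRUE
      indList[[e]] <- data.frame(chrom = ch, pos = ev$vcfPos, ref = ev$ref,
                                 alt = ev$alt, class = "indel",
                                 channel = NA_character_, category = cat16,
                                 stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a ", cat16, " indel after 2000 attempts; ",
           "genome too small or too occupied")
  }
  events <- rbind(subs, do.call(rbind, indList))

  ## ---- assign samples + recurrence ----
  owner <- sample.int(cfg$nSamples, nrow(events), replace = TRUE)
  recur <- cfg$nSamples > 1L &
    stats::runif(nrow(events)) < cfg$recurrenceRate
  second <- rep(NA_integer_, nrow(events))
  if (any(recur)) {
    off <- sample.int(cfg$nSamples - 1L, sum(recur), replace = TRUE)
    second[recur] <- ((owner[recur] - 1L + off) %% cfg$nSamples) + 1L
  }
  calls <- rbind(data.frame(sampleIdx = owner, events,
                            stringsAsFactors = FALSE),
                 data.frame(sampleIdx = second[recur], events[recur, ],
                            stringsAsFactors = FALSE))
  qd <- .qualDepth(nrow(calls), cfg$failFraction)
  calls$qual <- qd$qual
  calls$depth <- qd$depth
  calls$passesFilter <- calls$qual >= 30 & calls$depth >= 10
  sampleNames <- sprintf("sample%02d", seq_len(cfg$nSamples))
  calls$sample <- sampleNames[calls$sampleIdx]
  calls <- calls[order(match(calls$sample, sampleNames),
                       match(calls$chrom, chroms), calls$pos, calls$ref,
                       calls$alt, method = "radix"), ]
  rownames(calls) <- NULL

  ## ---- write VCFs + truth ----
  header <- c("##fileformat=VCFv4.2",
              "##source=MutSpectra simulator",
              sprintf("##contig=<ID=%s,length=%d>", chroms, lens),
              paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
                     "Description=\"Raw read depth\">"),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  vcfPaths <- stats::setNames(file.path(dir, paste0(sampleNames, ".vcf")),
                              sampleNames)
  for (s in sampleNames) {
    d <- calls[calls$sample == s, , drop = FALSE]
    body <- if (nrow(d)) sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d",
                                 d$chrom, d$pos, d$ref, d$alt,
                                 formatC(d$qual, format = "fg"), d$depth)
            else character(0)
    writeLines(c(header, body), vcfPaths[[s]])
  }
  truth <- calls[, c("sample", "chrom", "pos", "ref", "alt", "class",
                     "channel", "category", "qual", "depth", "passesFilter")]
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcfPaths, truth = truth, truthPath = truthPath, dir = dir)
}

# Construct one indel event of the requested 16-category class at a random
# position of chromosome char vector `cc` (length L); NULL if the sampled
# position cannot host the class. VCF anchor-base representation returned.
.makeIndelEvent <- function(cat16, cc, L) {
  margin <- 20L
  p <- sample.int(L - 2L * margin, 1L) + margin
  pasteRange <- function(a, b) paste(cc[a:b], collapse = "")
  if (cat16 %in% c("del1C", "del1T")) {
    want <- if (cat16 == "del1C") c("C", "G") else c("A", "T")
    if (!cc[p] %in% want) return(NULL)
    list(p = p, len = 1L, vcfPos = p - 1L,
         ref = paste0(cc[p - 1L], cc[p]), alt = cc[p - 1L])
  } else if (cat16 %in% c("ins1C", "ins1T")) {
    b <- sample(if (cat16 == "ins1C") c("C", "G") else c("A", "T"), 1L)
    list(p = p, len = 1L, vcfPos = p, ref = cc[p], alt = paste0(cc[p], b))
  } else if (grepl("^del", cat16) && !grepl("^del1", cat16)) {
    len <- sub("^del", "", cat16)
    k <- if (len == "5+") sample(5:8, 1L) else as.integer(len)
    D <- cc[p:(p + k - 1L)]
    # no 5' suffix homology (also keeps the event left-aligned), no 3'
    # prefix homology, hence no microhomology and no tandem copy
    if (D[k] == cc[p - 1L] || D[1L] == cc[p + k]) return(NULL)
    list(p = p, len = k, vcfPos = p - 1L,
         ref = paste0(cc[p - 1L], pasteRange(p, p + k - 1L)),
         alt = cc[p - 1L])
  } else if (grepl("^ins", cat16)) {
    len <- sub("^ins", "", cat16)
    k <- if (len == "5+") sample(5:8, 1L) else as.integer(len)
    U <- sample(.BASES, k, replace = TRUE)
    # no left shift, and no adjacent 3' tandem copy (repeat units 0)
    if (U[k] == cc[p]) return(NULL)
    if (identical(U, cc[(p + 1L):(p + k)])) return(NULL)
    list(p = p, len = 0L, vcfPos = p, ref = cc[p],
         alt = paste0(cc[p], paste(U, collapse = "")))
  } else {  # mhdel*
    len <- sub("^mhdel", "", cat16)
    k <- if (len == "5+") sample(5:8, 1L) else as.integer(len)
    D <- cc[p:(p + k - 1L)]
    # stable left alignment / no 5' homology; 3' prefix homology >= 1;
    # but not a full tandem copy
    if (D[k] == cc[p - 1L]) return(NULL)
    if (D[1L] != cc[p + k]) return(NULL)
    if (identical(D, cc[(p + k):(p + 2L * k - 1L)])) return(NULL)
    list(p = p, len = k, vcfPos = p - 1L,
         ref = paste0(cc[p - 1L], pasteRange(p, p + k - 1L)),
         alt = cc[p - 1L])
  }
}
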