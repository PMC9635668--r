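#' Canonical 83-channel indel labels
#'
#' Layout (in order):
#' \itemize{
#'   \item channels 1-12: 1 bp deletions at C then T, by homopolymer run
#'     length 1,2,3,4,5,6+ (label `del:C:1` ... `del:T:6+`);
#'   \item channels 13-24: 1 bp insertions at C then T, by adjacent
#'     homopolymer length 0,1,2,3,4,5+ (`ins:C:0` ...);
#'   \item channels 25-48: deletions of length 2, 3, 4, 5+ in tandem-repeat
#'     context, by repeat units 1..5,6+ where the deleted copy counts as one
#'     (`del:2:1` ... `del:5+:6+`);
#'   \item channels 49-72: insertions of length 2, 3, 4, 5+ by adjacent
#'     tandem copies 0..4,5+ (`ins:2:0` ... `ins:5+:5+`);
#'   \item channels 73-83: deletions of length 2, 3, 4, 5+ with breakpoint
#'     microhomology, by microhomology length (`mhdel:2:1`, `mhdel:3:1..2`,
#'     `mhdel:4:1..3`, `mhdel:5+:1..4,5+`).
#' }
#'
#' @return Character vector of 83 labels.
#' @export
indelChannels <- function() {
  c(paste0("del:C:", c(1:5, "6+")), paste0("del:T:", c(1:5, "6+")),
    paste0("ins:C:", c(0:4, "5+")), paste0("ins:T:", c(0:4, "5+")),
    unlist(lapply(c("2", "3", "4", "5+"),
                  function(L) paste0("del:", L, ":", c(1:5, "6+")))),
    unlist(lapply(c("2", "3", "4", "5+"),
                  function(L) paste0("ins:", L, ":", c(0:4, "5+")))),
    "mhdel:2:1", paste0("mhdel:3:", 1:2), paste0("mhdel:4:", 1:3),
    paste0("mhdel:5+:", c(1:4, "5+")))
}

.INDEL16 <- c("del1C", "del1T", "ins1C", "ins1T",
              "del2", "del3", "del4", "del5+",
              "ins2", "ins3", "ins4", "ins5+",
              "mhdel2", "mhdel3", "mhdel4", "mhdel5+")

#' Normalize an indel to its left-aligned representation
#'
#' Strips the shared VCF anchor base and shifts the event 5' while the
#' reference sequence permits (standard left alignment over repeated
#' sequence), so that equivalent VCF representations of one event classify
#' identically.
#'
#' @param chrom,pos,ref,alt One VCF-style indel record (anchor-base
#'   convention: ref and alt share their first base, one of them length 1).
#' @param genome A `DNAStringSet`.
#' @return List with chrom, pos (anchor base position after alignment; the
#'   event occupies/starts at pos+1), kind ("deletion"/"insertion"),
#'   sequence (deleted or inserted bases).
#' @export
normalizeIndel <- function(chrom, pos, ref, alt, genome) {
  .checkGenome(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  seq <- as.character(genome[[chrom]])
  if (substring(seq, pos, pos + nchar(ref) - 1L) != ref)
    stop("reference mismatch at ", chrom, ":", pos,
         " (VCF ref ", ref, ")")
  if (substr(ref, 1, 1) != substr(alt, 1, 1) ||
      (nchar(ref) > 1L) == (nchar(alt) > 1L))
    stop("not an anchored simple indel: ", ref, ">", alt)
  if (nchar(ref) > 1L) {
    kind <- "deletion"
    s <- substring(ref, 2L)
  } else {
    kind <- "insertion"
    s <- substring(alt, 2L)
  }
  anchor <- pos
  L <- nchar(s)
  repeat {
    if (anchor < 1L) break
    prev <- substring(seq, anchor, anchor)
    if (prev != substring(s, L, L)) break
    # shifting left: the event's last base equals the base 5' of it
    s <- paste0(prev, substring(s, 1L, L - 1L))
    anchor <- anchor - 1L
  }
  list(chrom = chrom, pos = anchor, kind = kind, sequence = s)
}

#' Repeat units at an indel site
#'
#' For 1 bp events, the length of the reference homopolymer run of the
#' event's base at the site (for deletions the deleted base itself is part
#' of the run; insertions count adjacent matching reference bases, so an
#' insertion with no neighbour of the same base scores 0). For events of
#' length >= 2, the number of tandem copies of the event's unit sequence
#' immediately 3' of the event site in the reference; for deletions the
#' deleted copy counts as one, so the minimum is 1.
#'
#' @param call Normalized indel from [normalizeIndel()].
#' @param genome A `DNAStringSet`.
#' @return Non-negative integer.
#' @export
repeatUnits <- function(call, genome) {
  seq <- as.character(genome[[call$chrom]])
  len <- nchar(seq)
  s <- call$sequence
  L <- nchar(s)
  start <- call$pos + 1L  # first base of the event site in the reference
  if (L == 1L) {
    if (call$kind == "deletion") {
      # run of the deleted base starting at the (left-aligned) site
      n <- 0L
      i <- start
      while (i <= len && substring(seq, i, i) == s) { n <- n + 1L; i <- i + 1L }
      n
    } else {
      n <- 0L
      i <- start
      while (i <= len && substring(seq, i, i) == s) { n <- n + 1L; i <- i + 1L }
      n
    }
  } else {
    n <- 0L
    i <- start
    while (i + L - 1L <= len && substring(seq, i, i + L - 1L) == s) {
      n <- n + 1L
      i <- i + L
    }
    if (call$kind == "deletion") max(n, 1L) else n
  }
}

#' Microhomology length at a deletion breakpoint
#'
#' For a deletion of length >= 2 outside repeat context (repeat units 1),
#' returns the longer of: the longest prefix of the deleted sequence
#' matching the reference immediately 3' of the deletion, and the longest
#' suffix matching immediately 5'. Capped at deletion length - 1 (a full
#' match would be a tandem repeat, not microhomology).
#'
#' @param call Normalized deletion from [normalizeIndel()].
#' @param genome A `DNAStringSet`.
#' @return Non-negative integer.
#' @export
microhomologyLength <- function(call, genome) {
  if (call$kind != "deletion")
    stop("microhomology is defined for deletions only")
  s <- call$sequence
  L <- nchar(s)
  if (L < 2L) stop("microhomology is defined for deletions of length >= 2")
  if (repeatUnits(call, genome) != 1L)
    stop("microhomology is undefined in tandem-repeat context")
  seq <- as.character(genome[[call$chrom]])
  len <- nchar(seq)
  start <- call$pos + 1L
  # 3' flank: prefix of deleted sequence vs reference after the deletion
  pre <- 0L
  i <- start + L
  while (pre < L - 1L && i <= len &&
         substring(seq, i, i) == substring(s, pre + 1L, pre + 1L)) {
    pre <- pre + 1L
    i <- i + 1L
  }
  # 5' flank: suffix of deleted sequence vs reference before the deletion
  suf <- 0L
  i <- call$pos
  while (suf < L - 1L && i >= 1L &&
         substring(seq, i, i) == substring(s, L - suf, L - suf)) {
    suf <- suf + 1L
    i <- i - 1L
  }
  max(pre, suf)
}

.lenBin <- function(L) if (L >= 5L) "5+" else as.character(L)

#' Classify one indel into the 83-channel scheme
#'
#' Priority order: (1) 1 bp events, classified by pyrimidine base (A/G
#' events are strand-collapsed to T/C) and homopolymer run length; (2)
#' events of length >= 2 with >= 2 tandem repeat units, as repeat-context
#' deletions/insertions of their length bin; (3) deletions of length >= 2
#' with repeat units 1 and microhomology >= 1, as microhomology deletions;
#' (4) everything else, as length-binned deletions at repeat bin 1 or
#' insertions at repeat bin 0. Repeat context therefore takes precedence
#' over microhomology, and the two are mutually exclusive by construction.
#'
#' @param call Normalized indel from [normalizeIndel()].
#' @param genome A `DNAStringSet`.
#' @return List: `index` (1..83), `channel` (label), `category` (one of the
#'   16 collapsed categories).
#' @export
classifyIndel <- function(call, genome) {
  s <- call$sequence
  L <- nchar(s)
  labels <- indelChannels()
  if (L == 1L) {
    base <- if (s %in% c("A", "G")) .COMPLEMENT[[s]] else s
    run <- repeatUnits(call, genome)
    if (call$kind == "deletion") {
      bin <- if (run >= 6L) "6+" else as.character(max(run, 1L))
      lab <- paste0("del:", base, ":", bin)
      cat16 <- paste0("del1", base)
    } else {
      bin <- if (run >= 5L) "5+" else as.character(run)
      lab <- paste0("ins:", base, ":", bin)
      cat16 <- paste0("ins1", base)
    }
  } else {
    units <- repeatUnits(call, genome)
    lb <- .lenBin(L)
    if (units >= 2L) {
      if (call$kind == "deletion") {
        bin <- if (units >= 6L) "6+" else as.character(units)
        lab <- paste0("del:", lb, ":", bin)
        cat16 <- paste0("del", lb)
      } else {
        bin <- if (units >= 5L) "5+" else as.character(units)
        lab <- paste0("ins:", lb, ":", bin)
        cat16 <- paste0("ins", lb)
      }
    } else if (call$kind == "deletion" &&
               (mh <- microhomologyLength(call, genome)) >= 1L) {
      mhMax <- switch(lb, "2" = 1L, "3" = 2L, "4" = 3L, "5+" = 5L)
      mhBin <- if (lb == "5+" && mh >= 5L) "5+"
               else as.character(min(mh, mhMax))
      lab <- paste0("mhdel:", lb, ":", mhBin)
      cat16 <- paste0("mhdel", lb)
    } else if (call$kind == "deletion") {
      lab <- paste0("del:", lb, ":1")
      cat16 <- paste0("del", lb)
    } else {
      lab <- paste0("ins:", lb, ":0")
      cat16 <- paste0("ins", lb)
    }
  }
  list(index = match(lab, labels), channel = lab, category = cat16)
}

#' Build an 83-channel indel spectrum from unique indels
#'
#' Each unique indel counts once regardless of recurrence across samples.
#'
#' @param vs A `VariantSet` of indels (see [partitionByClass()]).
#' @param genome A `DNAStringSet`.
#' @param label Provenance label.
#' @return An [IndelSpectrum-class]; diagnostics carry total calls, unique
#'   indels and unclassifiable count.
#' @export
buildIndelSpectrum <- function(vs, genome, label = "") {
  stopifnot(is(vs, "VariantSet"))
  r <- vs@records
  counts <- stats::setNames(numeric(83), indelChannels())
  unclass <- 0L
  for (i in seq_len(nrow(r))) {
    cl <- tryCatch({
      call <- normalizeIndel(r$chrom[i], r$pos[i], r$ref[i], r$alt[i], genome)
      classifyIndel(call, genome)
    }, error = function(e) {
      if (grepl("reference mismatch", conditionMessage(e))) stop(e)
      NULL
    })
    if (is.null(cl)) unclass <- unclass + 1L
    else counts[cl$index] <- counts[cl$index] + 1
  }
  new("IndelSpectrum", counts = counts, label = label,
      diagnostics = list(totalCalls = vs@nTotalCalls,
                         uniqueIndels = nrow(r),
                         unclassifiable = unclass))
}

#' Collapse an indel spectrum to the 16-category view
#'
#' Categories: 1 bp del/ins at C and at T; deletions and insertions of
#' length 2, 3, 4, 5+; and microhomology deletions of length 2, 3, 4, 5+.
#' Totals are preserved.
#'
#' @param x An `IndelSpectrum`.
#' @return Named numeric vector of 16 counts.
#' @export
collapse16 <- function(x) {
  cts <- channelCounts(x)
  lab <- names(cts)
  grp <- character(length(lab))
  parts <- strsplit(lab, ":", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    grp[i] <- if (p[2] %in% c("C", "T")) paste0(p[1], "1", p[2])
              else paste0(p[1], p[2])
  }
  out <- stats::setNames(numeric(16), .INDEL16)
  agg <- tapply(cts, grp, sum)
  out[names(agg)] <- agg
  out
}

#' Repeat-unit view of an indel spectrum
#'
#' Reshapes the non-microhomology channels by their repeat-unit bin: for
#' 1 bp events the homopolymer run length, for longer events the number of
#' adjacent tandem copies of the indel unit. Microhomology deletions are
#' reported under their own group with the microhomology-length bin.
#'
#' @param x An `IndelSpectrum`.
#' @return data.frame with columns group (e.g. `"del:C"`, `"ins:3"`,
#'   `"mhdel:5+"`), bin, count.
#' @export
repeatUnitView <- function(x) {
  cts <- channelCounts(x)
  parts <- strsplit(names(cts), ":", fixed = TRUE)
  data.frame(group = vapply(parts, function(p) paste(p[1], p[2], sep = ":"),
                            character(1)),
             bin = vapply(parts, `[`, character(1), 3),
             count = unname(cts), stringsAsFactors = FALSE)
}

#' Write an indel spectrum as TSV (83 channels + 16-category view)
#'
#' @param x An `IndelSpectrum`.
#' @param path Output TSV path for the 83-channel table.
#' @param path16 Optional output path for the collapsed 16-category table.
#' @export
writeIndelSpectrumTsv <- function(x, path, path16 = NULL) {
  cts <- channelCounts(x)
  utils::write.table(data.frame(channel = names(cts), count = cts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path16)) {
    c16 <- collapse16(x)
    utils::write.table(data.frame(category = names(c16), count = c16),
                       path16, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
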