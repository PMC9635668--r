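#' Read per-sample variant calls from a VCF
#'
#' Parses a VCF 4.x file (plain or bgzip-compressed) into a per-sample call
#' table. Multi-allelic records are split into one row per alternate allele,
#' sharing the record's QUAL and depth. Depth is taken from INFO/DP; records
#' missing QUAL or DP get sentinel 0, which the default quality filter
#' removes. Symbolic, spanning-deletion (`*`) and non-ACGT alleles are
#' dropped with a warning: they have no place in either spectrum.
#'
#' @param path Path to a VCF file.
#' @param sampleId Identifier recorded in the `sample` column; defaults to
#'   the file name without extension.
#' @return data.frame with columns chrom, pos, ref, alt, qual, depth, sample.
#' @export
readVariantVcf <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), depth = integer(),
                      sample = character(), stringsAsFactors = FALSE))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("malformed VCF: non-numeric POS at data line(s) ",
         paste(which(is.na(pos)), collapse = ", "))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  dp <- suppressWarnings(as.integer(
    sub("^.*?\\bDP=([0-9]+)\\b.*$", "\\1", paste0(";", fix$INFO, ";"))))
  dp[is.na(dp)] <- 0L

  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n)
  out <- data.frame(chrom = fix$CHROM[idx], pos = pos[idx],
                    ref = toupper(fix$REF[idx]),
                    alt = toupper(unlist(alts)),
                    qual = qual[idx], depth = dp[idx],
                    sample = sampleId, stringsAsFactors = FALSE)
  ok <- grepl("^[ACGT]+$", out$ref) & grepl("^[ACGT]+$", out$alt) &
    out$ref != out$alt
  if (any(!ok))
    warning(sum(!ok), " record(s) with symbolic/non-ACGT/identical alleles ",
            "dropped from ", basename(path))
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variant calls on quality and depth
#'
#' Retains exactly the calls with `qual >= minQual` and `depth >= minDepth`,
#' preserving input order. Defaults reproduce the standard pre-merge filter
#' for haploid isolate sequencing: drop calls with quality score below 30
#' or coverage below 10.
#'
#' @param records data.frame of calls as from [readVariantVcf()].
#' @param minQual Minimum Phred-scaled quality retained (default 30).
#' @param minDepth Minimum read depth retained (default 10).
#' @return The retained subset of `records`.
#' @export
filterVariants <- function(records, minQual = 30, minDepth = 10) {
  if (minQual < 0 || minDepth < 0) stop("thresholds must be non-negative")
  keep <- !is.na(records$qual) & !is.na(records$depth) &
    records$qual >= minQual & records$depth >= minDepth
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.sortRecords <- function(r, chromLevels) {
  ord <- order(match(r$chrom, chromLevels), r$pos, r$ref, r$alt,
               method = "radix")
  r <- r[ord, , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Merge per-sample calls into a set of unique variants
#'
#' Identical variants — same (chrom, pos, ref, alt) — found in multiple
#' samples are combined into one unique variant whose `samples` field is the
#' union of carriers, so a recurrent call counts once in downstream spectra.
#' Total pre-merge call counts are preserved for reporting. The merged
#' record's qual/depth are the per-sample maxima (reporting only; filtering
#' happens per sample before merging).
#'
#' @param perSample Named list of per-sample call data.frames (as returned
#'   by [readVariantVcf()], usually after [filterVariants()]), or a single
#'   data.frame with a `sample` column.
#' @param chromOrder Optional chromosome ordering for the sorted output;
#'   defaults to order of first appearance.
#' @return A [VariantSet-class].
#' @export
mergeUnique <- function(perSample, chromOrder = NULL) {
  if (is.data.frame(perSample)) {
    if (!"sample" %in% names(perSample))
      stop("a single data.frame input must carry a 'sample' column")
    perSample <- split(perSample, perSample$sample)
  }
  if (is.null(names(perSample)) || any(!nzchar(names(perSample)))) {
    nm <- vapply(perSample, function(d)
      if (nrow(d)) d$sample[1] else NA_character_, character(1))
    names(perSample) <- ifelse(is.na(nm), paste0("sample", seq_along(nm)), nm)
  }
  all <- do.call(rbind, lapply(names(perSample), function(s) {
    d <- perSample[[s]]
    if (nrow(d) == 0L) return(NULL)
    d$sample <- s
    d
  }))
  nTotal <- if (is.null(all)) 0L else nrow(all)
  if (!is.null(all)) all$pos <- as.integer(all$pos)
  if (is.null(all)) {
    rec <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), depth = integer(),
                      nCarriers = integer(), stringsAsFactors = FALSE)
    rec$samples <- list()
    return(new("VariantSet", records = rec,
               nSamples = length(perSample), nTotalCalls = 0L))
  }
  if (is.null(chromOrder)) chromOrder <- unique(all$chrom)
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = "\r")
  grp <- split(seq_len(nrow(all)), factor(key, levels = unique(key)))
  rec <- data.frame(
    chrom = vapply(grp, function(i) all$chrom[i[1]], character(1)),
    pos = vapply(grp, function(i) all$pos[i[1]], integer(1)),
    ref = vapply(grp, function(i) all$ref[i[1]], character(1)),
    alt = vapply(grp, function(i) all$alt[i[1]], character(1)),
    qual = vapply(grp, function(i) max(all$qual[i]), numeric(1)),
    depth = vapply(grp, function(i) max(all$depth[i]), numeric(1)),
    nCarriers = vapply(grp, function(i) length(unique(all$sample[i])),
                       integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  rec$samples <- lapply(grp, function(i) sort(unique(all$sample[i])))
  rec <- .sortRecords(rec, chromOrder)
  new("VariantSet", records = rec, nSamples = length(perSample),
      nTotalCalls = nTotal)
}

.subsetVariantSet <- function(vs, keep, diagnostics = list()) {
  rec <- vs@records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  new("VariantSet", records = rec, nSamples = vs@nSamples,
      nTotalCalls = as.integer(max(sum(rec$nCarriers), nrow(rec))),
      diagnostics = diagnostics)
}

#' Partition unique variants into substitutions and indels
#'
#' Records with single-base ref and alt are substitutions. Records where
#' exactly one allele has length 1 and is a prefix of the other (the VCF
#' anchor-base convention) are indels. Anything else (MNVs, complex events)
#' is excluded and tallied in the result's diagnostics.
#'
#' @param vs A [VariantSet-class] from [mergeUnique()].
#' @return List with elements `substitutions` and `indels` (both
#'   `VariantSet`) and `excluded` (data.frame of complex records).
#'   `substitutions@diagnostics$complexCount` carries the excluded tally.
#' @export
partitionByClass <- function(vs) {
  stopifnot(is(vs, "VariantSet"))
  r <- vs@records
  nr <- nchar(r$ref); na <- nchar(r$alt)
  isSub <- nr == 1L & na == 1L
  isIndel <- ((nr == 1L & na > 1L) | (na == 1L & nr > 1L)) &
    substr(r$ref, 1L, 1L) == substr(r$alt, 1L, 1L)
  isComplex <- !isSub & !isIndel
  diag <- list(complexCount = sum(isComplex))
  list(substitutions = .subsetVariantSet(vs, isSub, diag),
       indels = .subsetVariantSet(vs, isIndel, diag),
       excluded = {
         ex <- r[isComplex, , drop = FALSE]; rownames(ex) <- NULL; ex
       })
}

#' Write a unique-variant set as TSV
#'
#' Columns: chrom, pos, ref, alt, n_samples, samples (comma-separated).
#'
#' @param vs A `VariantSet`.
#' @param path Output path.
#' @export
writeVariantTsv <- function(vs, path) {
  r <- variantRecords(vs)
  df <- data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                   n_samples = r$nCarriers,
                   samples = vapply(r$samples, paste, character(1),
                                    collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
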