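#' Run the full mutational-pattern analysis
#'
#' Orchestrates every stage over grouped per-sample VCFs: read and filter
#' calls, merge each group into unique variants, partition into
#' substitutions and indels, build 96-channel SBS spectra with 6-type
#' fractions, 83-channel indel spectra with the 16-category view, rainfall
#' tables and end-proximity summaries; optionally project spectra onto
#' another genome's trinucleotide frequencies and rank matches against a
#' signature catalog. All outputs are plain TSV/JSON in `outDir`, plus a
#' manifest recording inputs and parameters so every number is reproducible
#' by calling the underlying function directly.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{genome}{path to the reference FASTA (required);}
#'     \item{samples}{data.frame (or list of lists) with columns `sample`,
#'       `vcf`, `group` (required);}
#'     \item{catalog}{optional path to a COSMIC-style signature TSV;}
#'     \item{targetTrinuc}{optional path to a 32-motif frequency TSV for
#'       cross-species correction;}
#'     \item{minQual, minDepth}{filter thresholds (defaults 30, 10);}
#'     \item{endWindow}{window in bases for the end-proximity summary
#'       (default 5000).}
#'   }
#' @param outDir Output directory (created).
#' @return Invisibly, a list of in-memory results (per-group spectra,
#'   variant sets, similarity matrix, matches) plus `manifest`.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("genome", "samples")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing required field(s): ", paste(miss, collapse = ", "))
  samples <- config$samples
  if (!is.data.frame(samples))
    samples <- do.call(rbind, lapply(samples, function(s)
      data.frame(sample = s$sample, vcf = s$vcf, group = s$group,
                 stringsAsFactors = FALSE)))
  if (!all(c("sample", "vcf", "group") %in% names(samples)))
    stop("samples must have columns sample, vcf, group")
  absent <- samples$vcf[!file.exists(samples$vcf)]
  if (length(absent))
    stop("missing VCF file(s): ", paste(absent, collapse = ", "))
  minQual <- if (is.null(config$minQual)) 30 else config$minQual
  minDepth <- if (is.null(config$minDepth)) 10 else config$minDepth
  endWindow <- if (is.null(config$endWindow)) 5000 else config$endWindow

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  genome <- readGenome(config$genome)
  sourceFreq <- countTrinucleotides(genome)
  writeTrinucFrequencies(sourceFreq, file.path(outDir,
                                               "trinuc_frequencies.tsv"))
  targetFreq <- NULL
  if (!is.null(config$targetTrinuc))
    targetFreq <- readTrinucFrequencies(config$targetTrinuc)
  catalog <- NULL
  if (!is.null(config$catalog))
    catalog <- readSignatureCatalog(config$catalog)
  else
    message("no signature catalog supplied; catalog comparison skipped")

  groups <- split(samples, samples$group)
  results <- list()
  spectraForSim <- list()
  for (g in names(groups)) {
    tab <- groups[[g]]
    perSample <- lapply(seq_len(nrow(tab)), function(i)
      filterVariants(readVariantVcf(tab$vcf[i], tab$sample[i]),
                     minQual = minQual, minDepth = minDepth))
    names(perSample) <- tab$sample
    vs <- mergeUnique(perSample, chromOrder = names(genome))
    parts <- partitionByClass(vs)
    if (nrow(variantRecords(parts$substitutions)) == 0L &&
        nrow(variantRecords(parts$indels)) == 0L)
      stop("group ", sQuote(g), " has zero classifiable variants")

    pfx <- function(x) file.path(outDir, paste0(g, "_", x))
    writeVariantTsv(vs, pfx("unique_variants.tsv"))
    sbs <- buildSbsSpectrum(parts$substitutions, genome, label = g)
    writeSpectrumTsv(sbs, pfx("sbs96.tsv"))
    tf <- if (sum(channelCounts(sbs)) > 0) typeFractions(sbs) else NULL
    if (!is.null(tf))
      utils::write.table(data.frame(type = names(tf), fraction = tf),
                         pfx("sbs6_type_fractions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    ind <- buildIndelSpectrum(parts$indels, genome, label = g)
    writeIndelSpectrumTsv(ind, pfx("indel83.tsv"), pfx("indel16.tsv"))
    rf <- rainfall(vs, genome)
    utils::write.table(rf, pfx("rainfall.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    prox <- endProximity(vs, genome, endWindow)

    corrected <- NULL
    if (!is.null(targetFreq) && sum(channelCounts(sbs)) > 0) {
      corrected <- correctSpectrum(sbs, sourceFreq, targetFreq)
      writeSpectrumTsv(corrected, pfx("sbs96_corrected.tsv"))
    }
    results[[g]] <- list(variants = vs, substitutions = parts$substitutions,
                         indels = parts$indels, sbs = sbs, indelSpectrum = ind,
                         typeFractions = tf, rainfall = rf,
                         endProximity = prox, corrected = corrected)
    if (sum(channelCounts(sbs)) > 0)
      spectraForSim[[g]] <- if (is.null(corrected)) sbs else corrected
  }

  simMat <- NULL
  matches <- list()
  if (length(spectraForSim) >= 2L) {
    simMat <- similarityMatrix(spectraForSim)
    writeSimilarityMatrixTsv(simMat, file.path(outDir,
                                               "similarity_matrix.tsv"))
    ord <- clusterOrder(simMat)
    writeLines(ord$newick, file.path(outDir, "similarity_dendrogram.nwk"))
  }
  if (!is.null(catalog)) {
    for (g in names(spectraForSim)) {
      bm <- bestMatches(spectraForSim[[g]], catalog)
      utils::write.table(bm, file.path(outDir,
                                       paste0(g, "_catalog_matches.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      matches[[g]] <- bm
    }
  }

  manifest <- list(
    package = "MutSpectra",
    version = as.character(utils::packageVersion("MutSpectra")),
    genome = normalizePath(config$genome),
    samples = samples,
    parameters = list(minQual = minQual, minDepth = minDepth,
                      endWindow = endWindow,
                      catalog = config$catalog,
                      targetTrinuc = config$targetTrinuc))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(similarity = simMat, matches = matches,
                            manifest = manifest)))
}
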