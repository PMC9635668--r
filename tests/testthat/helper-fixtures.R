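# fixtures are built in code at test time; no binary data on disk

randomGenome <- function(nChrom = 2, len = 500, seed = NULL,
                         bases = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(nChrom), function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""), character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(nChrom))
  g
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fa"), width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- as.character(seqs[[nm]])
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  path
}

writeMiniVcf <- function(df, path = tempfile(fileext = ".vcf"),
                         contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(df)) {
    info <- if ("depth" %in% names(df)) paste0("DP=", df$depth)
            else rep(".", nrow(df))
    qual <- if ("qual" %in% names(df)) as.character(df$qual)
            else rep(".", nrow(df))
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
            df$chrom, df$pos, df$ref, df$alt, qual, info)
  } else character(0)
  writeLines(c(hdr, body), path)
  path
}

# draw random single-base substitutions consistent with a genome
randomSubstitutions <- function(genome, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  ci <- sample(seq_along(chroms), n, replace = TRUE)
  pos <- vapply(ci, function(i) sample.int(lens[i], 1L), integer(1))
  ref <- mapply(function(i, p) substr(as.character(genome[[i]]), p, p),
                ci, pos, USE.NAMES = FALSE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(chrom = chroms[ci], pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

asVariantSet <- function(df) {
  df$qual <- if (is.null(df$qual)) 60 else df$qual
  df$depth <- if (is.null(df$depth)) 50 else df$depth
  df$sample <- if (is.null(df$sample)) "s1" else df$sample
  mergeUnique(split(df, df$sample))
}
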