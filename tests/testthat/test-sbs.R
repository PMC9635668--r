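test_that("canonical channel order starts A[C>A]A and ends T[T>G]T", {
  ch <- sbsChannels()
  expect_length(ch, 96L)
  expect_identical(ch[1], "A[C>A]A")
  expect_identical(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)
})

test_that("pyrimidine-strand classification reads direct and flipped sites", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG", chr2 = "ATGAG"))
  # TCA context, C>A read directly
  d <- classifySubstitutions(data.frame(chrom = "chr1", pos = 3L,
                                        ref = "C", alt = "A"), g)
  expect_equal(d$channel, "T[C>A]A")
  # TGA context, G>T: reverse complement of G is C on the TCA motif
  d2 <- classifySubstitutions(data.frame(chrom = "chr2", pos = 3L,
                                         ref = "G", alt = "T"), g)
  expect_equal(d2$channel, "T[C>A]A")
  expect_equal(d2$typeIndex, 1L)
})

test_that("context-less and N-context substitutions classify as NA", {
  g <- Biostrings::DNAStringSet(c(chr1 = "CTNGA"))
  d <- classifySubstitutions(
    data.frame(chrom = "chr1", pos = c(1L, 5L, 2L),
               ref = c("C", "A", "T"), alt = c("A", "C", "G")), g)
  expect_true(all(is.na(d$channelIndex)))
})

test_that("reference mismatch is a hard error naming the site", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG"))
  expect_error(
    classifySubstitutions(data.frame(chrom = "chr1", pos = 3L,
                                     ref = "G", alt = "A"), g),
    "reference mismatch at chr1:3")
})

test_that("channel assignment matches the dual-strand oracle", {
  g <- randomGenome(nChrom = 2, len = 2000, seed = 5)
  subs <- randomSubstitutions(g, 500, seed = 6)
  d <- classifySubstitutions(subs, g)
  want <- vapply(seq_len(nrow(subs)), function(i)
    oracleSbsChannel(g, subs$chrom[i], subs$pos[i], subs$ref[i],
                     subs$alt[i]), character(1))
  expect_equal(d$channel, want)
})

test_that("strand involution: the reverse-complement genome gives the same channel", {
  g <- randomGenome(nChrom = 1, len = 500, seed = 9)
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  L <- Biostrings::width(g)[1]
  subs <- randomSubstitutions(g, 200, seed = 10)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mirrored <- data.frame(chrom = subs$chrom, pos = L - subs$pos + 1L,
                         ref = comp[subs$ref], alt = comp[subs$alt],
                         stringsAsFactors = FALSE)
  expect_equal(classifySubstitutions(subs, g)$channel,
               classifySubstitutions(mirrored, rc)$channel)
})

test_that("spectra count unique variants once regardless of recurrence", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG"))
  per <- lapply(paste0("s", 1:5), function(s)
    data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "A",
               qual = 40, depth = 20, sample = s))
  names(per) <- paste0("s", 1:5)
  vs <- mergeUnique(per)
  s <- buildSbsSpectrum(vs, g)
  expect_equal(sum(channelCounts(s)), 1)
  expect_equal(unname(channelCounts(s)["T[C>A]A"]), 1)
  # per-occurrence mode exists for sensitivity analysis
  s5 <- buildSbsSpectrum(vs, g, perOccurrence = TRUE)
  expect_equal(sum(channelCounts(s5)), 5)
})

test_that("empty variant sets give a zero spectrum", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG"))
  vs <- mergeUnique(list(s1 = data.frame(chrom = character(),
                                         pos = integer(), ref = character(),
                                         alt = character(), qual = numeric(),
                                         depth = integer(),
                                         sample = character())))
  s <- buildSbsSpectrum(vs, g)
  expect_equal(sum(channelCounts(s)), 0)
  expect_error(typeFractions(s), "zero-total")
})

test_that("spectrum total equals classifiable unique substitutions", {
  g <- randomGenome(nChrom = 2, len = 1000, seed = 12)
  subs <- randomSubstitutions(g, 300, seed = 13)
  vs <- asVariantSet(subs)
  s <- buildSbsSpectrum(vs, g)
  cls <- classifySubstitutions(vs, g)
  expect_equal(sum(channelCounts(s)), sum(!is.na(cls$channelIndex)))
  expect_equal(s@metadata$unclassified, sum(is.na(cls$channelIndex)))
})

test_that("type fractions collapse and normalization commute", {
  set.seed(14)
  cts <- setNames(rpois(96, 5) + 0.0, sbsChannels())
  s <- new("SbsSpectrum", counts = cts)
  tf <- typeFractions(s)
  expect_equal(sum(tf), 1)
  # collapse-then-normalize equals normalize-then-collapse
  f <- asFrequencies(s)
  byType <- vapply(0:5, function(k) sum(f[(k * 16 + 1):(k * 16 + 16)]),
                   numeric(1))
  expect_equal(unname(tf), byType)
  # uniform spectrum puts 1/6 on each type
  u <- new("SbsSpectrum", counts = setNames(rep(1, 96), sbsChannels()))
  expect_equal(unname(typeFractions(u)), rep(1 / 6, 6))
})

test_that("rainfall distances are within-chromosome sorted differences", {
  df <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(350L, 100L, 7L),
                   ref = "C", alt = "A")
  vs <- asVariantSet(df)
  rf <- rainfall(vs)
  expect_equal(rf$pos, c(100L, 350L, 7L))
  expect_equal(rf$distance, c(NA, 250L, NA))
  # oracle: per chromosome, diff of sorted positions
  set.seed(15)
  df2 <- data.frame(chrom = sample(c("c1", "c2", "c3"), 200, replace = TRUE),
                    pos = sample(1:100000, 200), ref = "C", alt = "A")
  rf2 <- rainfall(asVariantSet(df2))
  for (ch in unique(df2$chrom)) {
    p <- sort(unique(df2$pos[df2$chrom == ch]))
    expect_equal(rf2$distance[rf2$chrom == ch], c(NA, diff(p)))
    expect_true(all(diff(rf2$pos[rf2$chrom == ch]) > 0))
  }
})

test_that("end proximity is exact for degenerate input and ~2w/L under uniformity", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 25000),
                                               collapse = "")))  # 100 kb
  near <- asVariantSet(data.frame(chrom = "chr1", pos = c(5L, 50L),
                                  ref = "C", alt = "A"))
  expect_equal(endProximity(near, g, 100)$fraction, 1)
  set.seed(16)
  n <- 4000
  unif <- asVariantSet(data.frame(chrom = "chr1",
                                  pos = sample.int(100000, n), ref = "A",
                                  alt = "C"))
  w <- 10000
  res <- endProximity(unif, g, w)
  expected <- 2 * w / 100000
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(res$fraction - expected), 3 * se + 0.01)
  empty <- mergeUnique(list(s1 = data.frame(chrom = character(),
                                            pos = integer(),
                                            ref = character(),
                                            alt = character(),
                                            qual = numeric(),
                                            depth = integer(),
                                            sample = character())))
  expect_error(endProximity(empty, g, w), "empty")
  expect_error(endProximity(near, g, 0), "positive")
})

test_that("spectrum TSVs round-trip counts and frequencies", {
  set.seed(17)
  s <- new("SbsSpectrum", counts = setNames(rpois(96, 3) + 0.0,
                                            sbsChannels()))
  path <- tempfile(fileext = ".tsv")
  writeSpectrumTsv(s, path)
  s2 <- readSpectrumTsv(path)
  expect_equal(channelCounts(s2), channelCounts(s))
})
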