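test_that("indel channel layout has 83 channels collapsing to 16 categories", {
  ch <- indelChannels()
  expect_length(ch, 83L)
  expect_false(anyDuplicated(ch) > 0)
  set.seed(20)
  x <- new("IndelSpectrum", counts = setNames(rpois(83, 4) + 0.0, ch))
  c16 <- collapse16(x)
  expect_length(c16, 16L)
  expect_equal(sum(c16), sum(channelCounts(x)))
  rv <- repeatUnitView(x)
  expect_equal(sum(rv$count), sum(channelCounts(x)))
})

test_that("indel normalization strips the anchor and left-aligns", {
  #            123456789012
  g <- Biostrings::DNAStringSet(c(chr1 = "GGGCAAATGGGG"))
  # deleting the third A of the run must shift to the first
  call <- normalizeIndel("chr1", 6, "AA", "A", g)
  expect_equal(call$kind, "deletion")
  expect_equal(call$sequence, "A")
  expect_equal(call$pos, 4L)  # anchor C; run starts at 5
  ins <- normalizeIndel("chr1", 3, "G", "GTG", g)
  expect_equal(ins$kind, "insertion")
  # TG insertion after G3: last base G matches ref, rotates/shifts left
  expect_equal(nchar(ins$sequence), 2L)
  expect_error(normalizeIndel("chr1", 6, "AT", "A", g),
               "reference mismatch")
})

test_that("normalization agrees with the exhaustive minimal-representation search", {
  reps <- 0
  for (seed in 1:40) {
    g <- randomGenome(nChrom = 1, len = 120, seed = 100 + seed,
                      bases = c("A", "C", "T"))  # repeat-rich alphabet
    s <- as.character(g[[1]])
    for (k in 1:6) {
      rec <- randomIndelRecord(s, seed = 1000 * seed + k)
      got <- normalizeIndel("chr1", rec$pos, rec$ref, rec$alt, g)
      want <- oracleLeftAlign(s, rec$pos, rec$ref, rec$alt)
      expect_equal(got$pos, want$pos)
      expect_equal(got$sequence, want$sequence)
      expect_equal(got$kind, want$kind)
      reps <- reps + 1
    }
  }
  expect_gte(reps, 200)
})

test_that("repeat units count homopolymer runs and tandem copies", {
  #                                 1234567890123456
  g <- Biostrings::DNAStringSet(c(chr1 = "GCAAAATCTGTGTGAC"))
  # deletion of one A from the AAAA run: 4 repeat units
  del <- normalizeIndel("chr1", 2, "CA", "C", g)
  expect_equal(repeatUnits(del, g), 4L)
  # deletion of TG from 3 tandem TGs (positions 9-14) -> 3
  delTG <- normalizeIndel("chr1", 8, "CTG", "C", g)
  expect_equal(repeatUnits(delTG, g), 3L)
  # insertion of A next to the run counts adjacent copies only
  insA <- normalizeIndel("chr1", 6, "A", "AA", g)
  expect_equal(repeatUnits(insA, g), 4L)
  # insertion of a unit with no adjacent copy -> 0
  insGG <- normalizeIndel("chr1", 7, "T", "TGG", g)
  expect_equal(repeatUnits(insGG, g), 0L)
})

test_that("microhomology takes the longer one-sided flank match, capped", {
  # deleted TAGC followed by TAG...: 3' prefix match of 3
  g <- Biostrings::DNAStringSet(c(chr1 = "GGGATAGCTAGGACG"))
  del <- normalizeIndel("chr1", 4, "ATAGC", "A", g)
  expect_equal(repeatUnits(del, g), 1L)
  expect_equal(microhomologyLength(del, g), 3L)
  # no shared sequence on either side -> 0
  g2 <- Biostrings::DNAStringSet(c(chr1 = "GGGATACGGGGG"))
  del2 <- normalizeIndel("chr1", 4, "ATAC", "A", g2)
  expect_equal(microhomologyLength(del2, g2), 0L)
  expect_error(microhomologyLength(list(kind = "insertion", sequence = "AT",
                                        chrom = "chr1", pos = 3), g),
               "deletions only")
})

test_that("microhomology matches the two-sided scan oracle on random contexts", {
  cases <- 0
  for (seed in 1:120) {
    set.seed(300 + seed)
    L <- sample(2:6, 1)
    flank5 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    core <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    s <- paste0(flank5, core, flank3)
    g <- Biostrings::DNAStringSet(c(chr1 = s))
    call <- normalizeIndel("chr1", 10, substr(s, 10, 10 + L), substr(s, 10, 10), g)
    if (repeatUnits(call, g) != 1L) next  # MH undefined in repeat context
    expect_equal(microhomologyLength(call, g),
                 as.integer(oracleMh(s, call)))
    cases <- cases + 1
  }
  expect_gte(cases, 60)
})

test_that("classification follows the 4-step priority rule", {
  # isolated C deleted: 1 bp del C, run 1
  g <- Biostrings::DNAStringSet(c(chr1 = "ATTTCAAAGGGGGGTTAT"))
  d <- normalizeIndel("chr1", 4, "TC", "T", g)
  expect_equal(classifyIndel(d, g)$channel, "del:C:1")
  # deleting one G from a run of 6: strand-collapsed to C, bin 6+
  d6 <- normalizeIndel("chr1", 8, "AG", "A", g)
  expect_equal(classifyIndel(d6, g)$channel, "del:C:6+")
  # 6 bp deletion with MH 2 lands in the 5+ MH bin
  g2 <- Biostrings::DNAStringSet(c(chr1 = "AAAACTGACGCTTTTT"))
  del6 <- normalizeIndel("chr1", 4, "ACTGACG", "A", g2)
  expect_equal(repeatUnits(del6, g2), 1L)
  expect_equal(microhomologyLength(del6, g2), 2L)
  expect_equal(classifyIndel(del6, g2)$channel, "mhdel:5+:2")
  expect_equal(classifyIndel(del6, g2)$category, "mhdel5+")
})

test_that("classification matches an independent straight-line reimplementation", {
  nOk <- 0
  for (seed in 1:100) {
    g <- randomGenome(nChrom = 1, len = 200, seed = 500 + seed,
                      bases = c("A", "C", "G", "T"))
    s <- as.character(g[[1]])
    for (k in 1:5) {
      rec <- randomIndelRecord(s, seed = 7000 * seed + k)
      call <- normalizeIndel("chr1", rec$pos, rec$ref, rec$alt, g)
      got <- classifyIndel(call, g)
      expect_equal(got$channel, oracleIndelChannel(s, call))
      expect_equal(got$index, match(got$channel, indelChannels()))
      nOk <- nOk + 1
    }
  }
  expect_gte(nOk, 500)
})

test_that("classification is invariant to the VCF shift of the same event", {
  # one A deleted from a homopolymer: every anchored representation of the
  # run must classify identically
  g <- Biostrings::DNAStringSet(c(chr1 = "GGCAAAAATGC"))
  chans <- vapply(3:7, function(p) {
    call <- normalizeIndel("chr1", p, substr("GGCAAAAATGC", p, p + 1),
                           substr("GGCAAAAATGC", p, p), g)
    classifyIndel(call, g)$channel
  }, character(1))
  expect_equal(unique(chans), "del:T:5")
})

test_that("indel spectra count unique events once with diagnostics", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATTTCAAAGGGTTTATACGT"))
  df <- data.frame(chrom = "chr1", pos = c(2L, 2L, 5L),
                   ref = c("TT", "TT", "CA"), alt = c("T", "T", "C"),
                   qual = 40, depth = 20,
                   sample = c("s1", "s2", "s1"), stringsAsFactors = FALSE)
  vs <- mergeUnique(split(df, df$sample))
  parts <- partitionByClass(vs)
  sp <- buildIndelSpectrum(parts$indels, g)
  expect_equal(sum(channelCounts(sp)), 2)
  expect_equal(sp@diagnostics$uniqueIndels, 2L)
  expect_equal(sp@diagnostics$totalCalls, 3L)
  c16 <- collapse16(sp)
  # both unique events are 1 bp deletions at T/A pairs (A collapses to T)
  expect_equal(unname(c16["del1T"]), 2)
  expect_equal(unname(c16["del1C"]), 0)
  expect_equal(sum(c16), 2)
})

test_that("known spectrum composition survives the collapse", {
  g <- randomGenome(nChrom = 1, len = 3000, seed = 33)
  s <- as.character(g[[1]])
  # place 3 isolated 1bp T-dels and 1 long deletion by construction
  found <- c()
  rows <- list()
  p <- 10
  while (length(found) < 3 && p < 2900) {
    if (substr(s, p, p) %in% c("A", "T") &&
        substr(s, p - 1, p - 1) != substr(s, p, p) &&
        substr(s, p + 1, p + 1) != substr(s, p, p)) {
      rows[[length(found) + 1]] <- data.frame(
        chrom = "chr1", pos = p - 1L, ref = substr(s, p - 1, p),
        alt = substr(s, p - 1, p - 1), qual = 40, depth = 20, sample = "s1")
      found <- c(found, p)
      p <- p + 20
    } else p <- p + 1
  }
  expect_length(found, 3L)
  vs <- mergeUnique(list(s1 = do.call(rbind, rows)))
  sp <- buildIndelSpectrum(vs, g)
  expect_equal(unname(collapse16(sp)["del1T"]), 3)
})
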