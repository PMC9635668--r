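# Independent brute-force reimplementations used as oracles. These stay
# deliberately naive (character loops, exhaustive searches) and share no
# code with the package internals they check.

.oc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevcomp <- function(s) {
  paste(rev(.oc[strsplit(s, "")[[1]]]), collapse = "")
}

# naive window enumerator with reverse-complement collapsing
oracleTrinucCounts <- function(genome) {
  counts <- setNames(numeric(32), trinucMotifs())
  for (nm in names(genome)) {
    s <- as.character(genome[[nm]])
    if (nchar(s) < 3) next
    for (i in 2:(nchar(s) - 1)) {
      w <- substr(s, i - 1, i + 1)
      if (grepl("N", w)) next
      ctr <- substr(w, 2, 2)
      m <- if (ctr %in% c("C", "T")) w else oracleRevcomp(w)
      counts[m] <- counts[m] + 1
    }
  }
  counts
}

# dual-strand channel assignment: builds the label from scratch
oracleSbsChannel <- function(genome, chrom, pos, ref, alt) {
  s <- as.character(genome[[chrom]])
  if (pos <= 1 || pos >= nchar(s)) return(NA_character_)
  w <- substr(s, pos - 1, pos + 1)
  if (grepl("N", w)) return(NA_character_)
  if (ref %in% c("A", "G")) {
    w <- oracleRevcomp(w)
    ref <- .oc[[ref]]
    alt <- .oc[[alt]]
  }
  paste0(substr(w, 1, 1), "[", ref, ">", alt, "]", substr(w, 3, 3))
}

oracleFilter <- function(records, minQual, minDepth) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records)))
    keep[i] <- records$qual[i] >= minQual && records$depth[i] >= minDepth
  records[keep, , drop = FALSE]
}

# dictionary-based grouping of calls into unique variants
oracleMerge <- function(calls) {
  d <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(calls))) {
    key <- paste(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i])
    cur <- if (exists(key, d)) get(key, d) else character(0)
    assign(key, union(cur, calls$sample[i]), d)
  }
  keys <- ls(d)
  data.frame(key = keys,
             nCarriers = vapply(keys, function(k) length(get(k, d)),
                                integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# exhaustive minimal-position representation of an indel: try every anchor
# position and keep the leftmost whose edit reproduces the same mutant
# chromosome
oracleLeftAlign <- function(seqStr, pos, ref, alt) {
  apply1 <- function(p, r, a)
    paste0(substr(seqStr, 1, p - 1), a,
           substring(seqStr, p + nchar(r)))
  target <- apply1(pos, ref, alt)
  isDel <- nchar(ref) > nchar(alt)
  L <- abs(nchar(ref) - nchar(alt))
  best <- NULL
  for (p in 0:(pos + 1)) {
    if (isDel) {
      if (p < 1 || p + L - 1 > nchar(seqStr)) next
      cand <- paste0(substr(seqStr, 1, p - 1),
                     substring(seqStr, p + L))
      if (cand == target) { best <- p; break }
    } else {
      # insertion of some L-mer after position p; recover it from target
      ins <- substr(target, p + 1, p + L)
      cand <- paste0(substr(seqStr, 1, p), ins, substring(seqStr, p + 1))
      if (cand == target) { best <- p; break }
    }
  }
  if (is.null(best)) stop("no equivalent representation found")
  if (isDel)
    list(pos = best - 1L,
         sequence = substr(seqStr, best, best + L - 1L), kind = "deletion")
  else
    list(pos = best,
         sequence = substr(target, best + 1, best + L), kind = "insertion")
}

oracleRepeatUnits <- function(seqStr, call) {
  s <- call$sequence
  L <- nchar(s)
  start <- call$pos + 1
  if (L == 1) {
    n <- 0
    i <- start
    while (i <= nchar(seqStr) && substr(seqStr, i, i) == s) {
      n <- n + 1
      i <- i + 1
    }
    n
  } else {
    n <- 0
    i <- start
    while (i + L - 1 <= nchar(seqStr) &&
           substr(seqStr, i, i + L - 1) == s) {
      n <- n + 1
      i <- i + L
    }
    if (call$kind == "deletion") max(n, 1) else n
  }
}

# two-sided microhomology scan, character by character
oracleMh <- function(seqStr, call) {
  s <- call$sequence
  L <- nchar(s)
  start <- call$pos + 1
  pre <- 0
  for (k in 1:(L - 1)) {
    if (start + L + k - 1 > nchar(seqStr)) break
    if (substr(s, k, k) == substr(seqStr, start + L + k - 1,
                                  start + L + k - 1)) pre <- k else break
  }
  suf <- 0
  for (k in 1:(L - 1)) {
    if (call$pos - k + 1 < 1) break
    if (substr(s, L - k + 1, L - k + 1) ==
        substr(seqStr, call$pos - k + 1, call$pos - k + 1)) suf <- k
    else break
  }
  max(pre, suf)
}

# straight-line reimplementation of the 4-step indel priority rule
oracleIndelChannel <- function(seqStr, call) {
  s <- call$sequence
  L <- nchar(s)
  if (L == 1) {
    b <- if (s %in% c("A", "G")) .oc[[s]] else s
    run <- oracleRepeatUnits(seqStr, call)
    if (call$kind == "deletion") {
      paste0("del:", b, ":", if (run >= 6) "6+" else max(run, 1))
    } else {
      paste0("ins:", b, ":", if (run >= 5) "5+" else run)
    }
  } else {
    lb <- if (L >= 5) "5+" else as.character(L)
    units <- oracleRepeatUnits(seqStr, call)
    if (units >= 2) {
      if (call$kind == "deletion")
        paste0("del:", lb, ":", if (units >= 6) "6+" else units)
      else
        paste0("ins:", lb, ":", if (units >= 5) "5+" else units)
    } else if (call$kind == "deletion") {
      mh <- oracleMh(seqStr, call)
      if (mh >= 1) {
        cap <- c("2" = 1, "3" = 2, "4" = 3, "5+" = 5)[[lb]]
        bin <- if (lb == "5+" && mh >= 5) "5+" else min(mh, cap)
        paste0("mhdel:", lb, ":", bin)
      } else paste0("del:", lb, ":1")
    } else paste0("ins:", lb, ":0")
  }
}

oracleCosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# random VCF-style representation of an indel event (possibly right-shifted)
randomIndelRecord <- function(seqStr, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(seqStr)
  L <- sample(1:6, 1)
  isDel <- runif(1) < 0.5
  p <- sample(seq(10, n - 15), 1)
  if (isDel) {
    list(pos = p, ref = substr(seqStr, p, p + L),
         alt = substr(seqStr, p, p))
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    list(pos = p, ref = substr(seqStr, p, p),
         alt = paste0(substr(seqStr, p, p), ins))
  }
}
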