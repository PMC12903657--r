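## Independent brute-force oracles. These deliberately avoid the code
## paths they check: binning by per-marker linear scan over explicit bin
## boundaries, shared regions by per-base integer coverage arrays.

## Per-marker linear scan: for each marker find the bin whose
## [start, end] span contains it, by enumerating all bin boundaries.
oracleBinCounts <- function(bp, chromLen, binSize) {
  nbin <- ceiling(chromLen / binSize)
  starts <- (seq_len(nbin) - 1) * binSize + 1
  ends <- pmin(seq_len(nbin) * binSize, chromLen)
  counts <- integer(nbin)
  for (p in bp) {
    hit <- which(p >= starts & p <= ends)
    stopifnot(length(hit) == 1)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

## Per-base coverage oracle on a small genome: boolean membership per
## individual (so one individual never counts twice on a base), integer
## sum, run-length extraction of maximal regions with coverage >= need.
oracleSharedRegions <- function(rec, threshold, genomeLen) {
  inds <- unique(rec$individual)
  n <- length(inds)
  need <- max(1L, as.integer(ceiling(threshold * n - 1e-9)))
  out <- NULL
  for (ch in unique(rec$chrom)) {
    cov <- integer(genomeLen)
    for (id in inds) {
      mem <- logical(genomeLen)
      sub <- rec[rec$individual == id & rec$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(sub)))
        mem[sub$start[r]:sub$end[r]] <- TRUE
      cov <- cov + mem
    }
    ok <- cov >= need
    if (!any(ok)) next
    rl <- rle(ok)
    stops <- cumsum(rl$lengths)
    starts <- stops - rl$lengths + 1
    keep <- which(rl$values)
    out <- rbind(out, data.frame(
      chrom = ch, start = starts[keep], end = stops[keep],
      count = vapply(keep, function(k)
        min(cov[starts[k]:stops[k]]), integer(1)),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Random interval table on a toy genome.
randomIntervalTable <- function(nInd, genomeLen, nChrom = 1,
                                maxSeg = 6, maxWidth = NULL) {
  if (is.null(maxWidth)) maxWidth <- max(2, genomeLen %/% 4)
  rec <- NULL
  for (i in seq_len(nInd)) {
    nSeg <- sample(maxSeg, 1)
    for (s in seq_len(nSeg)) {
      st <- sample(genomeLen, 1)
      en <- min(genomeLen, st + sample(maxWidth, 1) - 1)
      rec <- rbind(rec, data.frame(
        population = sprintf("P%d", 1 + (i - 1) %/% max(1, nInd %/% 2)),
        individual = sprintf("I%02d", i),
        chrom = as.character(sample(nChrom, 1)),
        start = st, end = en, stringsAsFactors = FALSE))
    }
  }
  IntervalTable(rec$population, rec$individual, rec$chrom, rec$start,
                rec$end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeTmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

## Output file sanity: correct magic bytes / header per format.
expectMagicBytes <- function(path, fmt) {
  expect_true(file.exists(path), info = path)
  expect_gt(file.size(path), 0)
  head <- readBin(path, "raw", 8)
  ok <- switch(fmt,
    png = identical(head[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47))),
    pdf = identical(rawToChar(head[1:4]), "%PDF"),
    svg = grepl("<svg", paste(readLines(path, n = 5, warn = FALSE),
                              collapse = "")),
    TRUE)
  expect_true(ok, info = sprintf("%s is not a valid %s", path, fmt))
}
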