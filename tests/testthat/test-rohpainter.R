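test_that("per-individual merging joins overlaps and book-ends only", {
  it <- IntervalTable(rep("P", 2), rep("A", 2), rep("1", 2),
                      c(100, 150), c(200, 300))
  m <- records(mergeIndividualIntervals(it))
  expect_equal(m[c("start", "end")], data.frame(start = 100, end = 300))

  bookEnd <- IntervalTable(rep("P", 2), rep("A", 2), rep("1", 2),
                           c(100, 201), c(200, 250))
  expect_equal(records(mergeIndividualIntervals(bookEnd))$end, 250)

  gap1 <- IntervalTable(rep("P", 2), rep("A", 2), rep("1", 2),
                        c(100, 202), c(200, 250))
  expect_equal(nrow(records(mergeIndividualIntervals(gap1))), 2)

  ## different individuals never merge with each other
  two <- IntervalTable(rep("P", 2), c("A", "B"), rep("1", 2),
                       c(100, 150), c(200, 300))
  expect_equal(nrow(records(mergeIndividualIntervals(two))), 2)
})

test_that("merging agrees with a per-base membership oracle", {
  set.seed(21)
  for (rep in 1:10) {
    it <- randomIntervalTable(nInd = 4, genomeLen = 10000, maxSeg = 50)
    m <- records(mergeIndividualIntervals(it))
    r <- records(it)
    for (id in unique(r$individual)) {
      mem <- logical(10000)
      sub <- r[r$individual == id, ]
      for (k in seq_len(nrow(sub))) mem[sub$start[k]:sub$end[k]] <- TRUE
      rl <- rle(mem)
      stops <- cumsum(rl$lengths)
      starts <- stops - rl$lengths + 1
      msub <- m[m$individual == id, ]
      expect_equal(msub$start, starts[rl$values])
      expect_equal(msub$end, stops[rl$values])
    }
  }
})

test_that("shared-interval calling follows the ceiling rule exactly", {
  one <- IntervalTable("P", "A", "1", 100, 200)
  sh <- computeSharedIntervals(one, 1.0)
  expect_equal(regions(sh),
               data.frame(chrom = "1", start = 100, end = 200, count = 1,
                          frequency = 1))

  ## 2 individuals, disjoint: required count ceil(0.7 * 2) = 2 -> empty
  disj <- IntervalTable(rep("P", 2), c("A", "B"), rep("1", 2),
                        c(100, 500), c(200, 600))
  expect_equal(nrow(regions(computeSharedIntervals(disj, 0.7))), 0)

  ## exact-fraction threshold must not float-round up: 3 of 5 at t = 0.6
  five <- IntervalTable(rep("P", 5), LETTERS[1:5], rep("1", 5),
                        c(10, 10, 10, 500, 600), c(90, 90, 90, 550, 650))
  expect_equal(nrow(regions(computeSharedIntervals(five, 0.6))), 1)

  expect_error(computeSharedIntervals(one, 0), "threshold")
  expect_error(computeSharedIntervals(one, 1.2), "threshold")
})

test_that("t = 1/N returns exactly the merged union of all individuals", {
  set.seed(31)
  for (rep in 1:10) {
    it <- randomIntervalTable(nInd = 5, genomeLen = 1000)
    sh <- regions(computeSharedIntervals(it, 1 / 5))
    ## oracle union: any coverage >= 1
    o <- oracleSharedRegions(records(it), 1 / 5, 1000)
    expect_equal(sh[c("chrom", "start", "end")],
                 o[c("chrom", "start", "end")])
  }
})

test_that("sweep line equals the per-base coverage oracle; t monotone", {
  set.seed(41)
  for (rep in 1:20) {
    nInd <- sample(2:10, 1)
    it <- randomIntervalTable(nInd = nInd, genomeLen = 1000)
    prevUnion <- NULL
    for (t in c(0.3, 0.5, 0.7, 1.0)) {
      got <- regions(computeSharedIntervals(it, t))
      want <- oracleSharedRegions(records(it), t, 1000)
      expect_equal(got[c("chrom", "start", "end", "count")], want,
                   ignore_attr = TRUE)
      ## emitted regions are disjoint and maximal per chromosome
      for (ch in unique(got$chrom)) {
        g <- got[got$chrom == ch, ]
        if (nrow(g) > 1)
          expect_true(all(g$start[-1] > g$end[-nrow(g)] + 1))
      }
      ## monotonicity: raising t shrinks the union (set inclusion)
      cover <- rep(FALSE, 1000)
      for (k in seq_len(nrow(got)))
        if (got$chrom[k] == "1")
          cover[got$start[k]:got$end[k]] <- TRUE
      if (!is.null(prevUnion)) expect_true(all(prevUnion | !cover))
      prevUnion <- cover
    }
  }
})

test_that("shared-intervals file round-trips, including empty", {
  it <- randomIntervalTable(nInd = 6, genomeLen = 500)
  sh <- computeSharedIntervals(it, 0.5)
  f <- tempfile()
  writeSharedIntervals(sh, f)
  expect_identical(readLines(f, n = 1),
                   "chrom\tstart\tend\tcount\tfrequency")
  back <- readSharedIntervals(f)
  expect_equal(regions(back), regions(sh), tolerance = 1e-9)

  empty <- computeSharedIntervals(
    IntervalTable(c("P", "P"), c("A", "B"), c("1", "1"), c(1, 500),
                  c(10, 510)), 1.0)
  f2 <- tempfile()
  writeSharedIntervals(empty, f2)
  expect_length(readLines(f2), 1)  # header only
  expect_equal(nrow(regions(readSharedIntervals(f2))), 0)
})

test_that("ROH plot lays out one lane per individual with markers", {
  idx <- GenomeIndex("1", 1000)
  it <- IntervalTable(c("P1", "P1", "P2"), c("A", "B", "C"),
                      rep("1", 3), c(100, 150, 400), c(300, 350, 600))
  sh <- computeSharedIntervals(it, 0.5)
  f <- renderRohPlot(it, idx, tempfile(fileext = ".png"), shared = sh)
  expect_equal(nrow(f$layout$lanes), 3)
  expect_equal(f$layout$xlim, c(1, 1000))
  expect_gt(length(f$layout$sharedMarkers), 0)
  ## population blocks contiguous in lane order
  expect_identical(f$layout$lanes$population, c("P1", "P1", "P2"))

  fNoLab <- renderRohPlot(it, idx, tempfile(fileext = ".png"),
                          showLabels = FALSE)
  expect_false(fNoLab$layout$showLabels)

  multi <- IntervalTable(c("P", "P"), c("A", "A"), c("1", "2"),
                         c(1, 1), c(10, 10))
  idx2 <- GenomeIndex(c("1", "2"), c(100, 100))
  expect_error(renderRohPlot(multi, idx2, tempfile(fileext = ".png")),
               "one at a time")
  ## but a chromosome selector resolves it
  fSel <- renderRohPlot(multi, idx2, tempfile(fileext = ".png"),
                        chrom = "2")
  expect_equal(fSel$layout$chrom, "2")
})
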