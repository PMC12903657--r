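test_that("bin boundaries follow the floor((p-1)/binSize) rule", {
  idx <- GenomeIndex("1", 10)
  mm <- MarkerMap(c("1", "1"), c("a", "b"), c(0, 0), c(1, 10))
  d <- computeBinCounts(mm, idx, binSize = 5)
  expect_equal(unname(binCounts(d))[[1]], c(1L, 1L))

  ## marker exactly at k * binSize belongs to the earlier bin
  mm2 <- MarkerMap(c("1", "1"), c("a", "b"), c(0, 0), c(5, 6))
  expect_equal(unname(binCounts(computeBinCounts(mm2, idx, 5)))[[1]],
               c(1L, 1L))
})

test_that("extent comes from the index: short last bin, zero chroms", {
  idx <- GenomeIndex(c("1", "2"), c(12, 7))
  mm <- MarkerMap("1", "a", 0, 3)
  d <- computeBinCounts(mm, idx, binSize = 5)
  cnt <- binCounts(d)
  expect_equal(unname(cnt[["1"]]), c(1L, 0L, 0L))  # ceil(12/5) = 3 bins
  expect_equal(unname(cnt[["2"]]), c(0L, 0L))      # no markers, 2 bins
})

test_that("preconditions are enforced as errors, not clamped", {
  idx <- GenomeIndex("1", 100)
  expect_error(computeBinCounts(MarkerMap("2", "a", 0, 5), idx, 10),
               "unindexed")
  expect_error(computeBinCounts(MarkerMap("1", "a", 0, 150), idx, 10),
               "beyond chromosome 1")
  expect_error(computeBinCounts(MarkerMap("1", "a", 0, 5), idx, 0),
               "binSize")
})

test_that("bin counts match the per-marker linear-scan oracle", {
  set.seed(11)
  for (rep in 1:25) {
    nChrom <- sample(3, 1)
    lens <- sample(50:500, nChrom)
    binSize <- sample(c(7, 10, 33, 64), 1)
    chrom <- as.character(sample(nChrom, 400, replace = TRUE))
    bp <- vapply(seq_along(chrom), function(i)
      sample(lens[as.integer(chrom[i])], 1), numeric(1))
    mm <- MarkerMap(chrom, sprintf("m%d", seq_along(chrom)), 0, bp)
    idx <- GenomeIndex(as.character(seq_len(nChrom)), lens)
    d <- computeBinCounts(mm, idx, binSize)
    cnt <- binCounts(d)
    for (c in seq_len(nChrom)) {
      expect_equal(unname(cnt[[as.character(c)]]),
                   oracleBinCounts(bp[chrom == as.character(c)],
                                   lens[c], binSize))
    }
    expect_equal(sum(unlist(cnt)), length(bp))  # conservation
  }
})

test_that("halving the bin size refines counts without changing totals", {
  set.seed(5)
  idx <- GenomeIndex("1", 640)
  bp <- sample(640, 200, replace = TRUE)
  mm <- MarkerMap(rep("1", 200), sprintf("m%d", 1:200), 0, bp)
  coarse <- unname(binCounts(computeBinCounts(mm, idx, 64))[[1]])
  fine <- unname(binCounts(computeBinCounts(mm, idx, 32))[[1]])
  expect_equal(sum(coarse), sum(fine))
  expect_equal(coarse, fine[c(TRUE, FALSE)] + fine[c(FALSE, TRUE)])
})

test_that("density heatmap renders tracks proportional to length", {
  idx <- GenomeIndex(c("1", "2"), c(1000, 500))
  mm <- MarkerMap(c("1", "2"), c("a", "b"), c(0, 0), c(10, 20))
  d <- computeBinCounts(mm, idx, 100)
  f <- renderDensityHeatmap(d, tempfile(fileext = ".png"))
  expect_true(file.exists(f$file))
  tr <- f$layout$tracks
  expect_equal(tr$widthBp[tr$chrom == "2"] / tr$widthBp[tr$chrom == "1"],
               0.5)
  ## index order top-down: first chromosome gets the highest lane
  expect_true(tr$y[1] > tr$y[2])

  ## all-zero counts render without error
  d0 <- computeBinCounts(MarkerMap(character(), character(), numeric(),
                                   numeric()),
                         idx, 100)
  f0 <- renderDensityHeatmap(d0, tempfile(fileext = ".pdf"))
  expect_true(file.exists(f0$file))

  expect_error(renderDensityHeatmap(d, tempfile(fileext = ".bmp")),
               "allowed formats")
})
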