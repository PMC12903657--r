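test_that("cumulative coordinates offset each chromosome by prior spans", {
  single <- AssocTable(rep("1", 3), c(10, 50, 90), c(1, 2, 3))
  lay <- cumulativeCoordinates(single)
  expect_equal(records(lay)$x, c(10, 50, 90))
  expect_equal(chromInfo(lay)$offset, 0)

  two <- AssocTable(c("1", "1", "2"), c(40, 100, 40), c(1, 2, 3))
  lay2 <- cumulativeCoordinates(two)
  ci <- chromInfo(lay2)
  expect_equal(ci$offset, c(0, 100))
  expect_equal(records(lay2)$x[records(lay2)$chrom == "2"], 140)
  expect_equal(ci$tick, c(50, 120))  # offset + span / 2
})

test_that("layout is invariant to input row order", {
  set.seed(23)
  tab <- data.frame(chrom = as.character(sample(4, 60, replace = TRUE)),
                    bp = sample(1e5, 60), value = stats::runif(60))
  a <- cumulativeCoordinates(AssocTable(tab$chrom, tab$bp, tab$value))
  sh <- tab[sample(nrow(tab)), ]
  b <- cumulativeCoordinates(AssocTable(sh$chrom, sh$bp, sh$value))
  expect_equal(records(a), records(b))
  expect_equal(chromInfo(a), chromInfo(b))
})

test_that("natural sort orders numerics, then X, Y, MT, then others", {
  expect_identical(naturalChromOrder(c("X", "2", "10", "MT", "1", "Y",
                                       "scaffold_3")),
                   c("1", "2", "10", "X", "Y", "MT", "scaffold_3"))
  tab <- AssocTable(c("X", "2", "1"), c(5, 5, 5), c(1, 1, 1))
  expect_identical(chromInfo(cumulativeCoordinates(tab))$chrom,
                   c("1", "2", "X"))
  ## explicit order wins; unknown chromosome in records is an error
  expect_identical(
    chromInfo(cumulativeCoordinates(tab, chromOrder = c("X", "1", "2")))$chrom,
    c("X", "1", "2"))
  expect_error(cumulativeCoordinates(tab, chromOrder = c("1", "2")),
               "not in chromOrder")
})

test_that("chromosome x ranges are disjoint and internally monotone", {
  set.seed(29)
  for (rep in 1:15) {
    nChrom <- sample(2:6, 1)
    n <- sample(50:200, 1)
    tab <- AssocTable(as.character(sample(nChrom, n, replace = TRUE)),
                      sample(1e6, n), stats::runif(n))
    lay <- cumulativeCoordinates(tab)
    ci <- chromInfo(lay)
    pts <- records(lay)
    for (i in seq_len(nrow(ci))) {
      xs <- pts$x[pts$chrom == ci$chrom[i]]
      expect_true(all(xs > ci$offset[i] & xs <= ci$offset[i] + ci$span[i]))
      expect_true(all(diff(xs) >= 0))
    }
    if (nrow(ci) > 1)
      expect_true(all(ci$offset[-1] >= (ci$offset + ci$span)[-nrow(ci)]))
  }
})

test_that("appending a new last chromosome preserves earlier coordinates", {
  tab <- AssocTable(c("1", "2"), c(100, 50), c(1, 2))
  lay <- cumulativeCoordinates(tab)
  ext <- AssocTable(c("1", "2", "3"), c(100, 50, 70), c(1, 2, 3))
  layE <- cumulativeCoordinates(ext)
  old <- records(lay)
  new <- records(layE)[seq_len(nrow(old)), ]
  expect_equal(new$x, old$x)
})

test_that("-log10 transform validates its domain and is exact", {
  tab <- AssocTable("1", 100, 0.001)
  expect_equal(records(transformValues(tab, logp = TRUE))$value, 3)
  expect_equal(records(transformValues(tab, logp = FALSE))$value, 0.001)

  set.seed(37)
  p <- stats::runif(200)
  t2 <- transformValues(AssocTable(rep("1", 200), seq_len(200), p), TRUE)
  expect_equal(records(t2)$value, -log10(p), tolerance = 1e-12)

  expect_error(transformValues(AssocTable("1", 1, 1.5), TRUE), "row 1")
  expect_error(transformValues(AssocTable("1", 1, 0), TRUE), "0, 1")
})

test_that("Manhattan rendering cycles colours and draws threshold lines", {
  set.seed(43)
  tab <- AssocTable(as.character(rep(1:4, each = 25)),
                    rep(seq(1000, 25000, by = 1000), 4),
                    stats::runif(100, 0, 8))
  lay <- cumulativeCoordinates(tab)
  f <- renderManhattan(lay, tempfile(fileext = ".png"), nColors = 2,
                       sug1 = 6)
  expect_equal(f$layout$colorCycle, c(0, 1, 0, 1))
  expect_equal(unname(f$layout$thresholds), 6)
  expect_length(f$layout$ticks, 4)

  f2 <- renderManhattan(lay, tempfile(fileext = ".png"), sug1 = 5,
                        sug2 = 7)
  expect_equal(unname(f2$layout$thresholds), c(5, 7))

  expect_error(renderManhattan(lay, tempfile(fileext = ".png"),
                               alpha = 1.2), "alpha")
})
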