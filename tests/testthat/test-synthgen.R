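test_that("generators are byte-identical under a fixed seed", {
  cfg <- synthConfig(seed = 101, nMarkers = 300, nIndividuals = 12)
  d1 <- tempfile(); d2 <- tempfile()
  genMapAndIndex(cfg, d1); genMapAndIndex(cfg, d2)
  expect_identical(readLines(file.path(d1, "markers.map")),
                   readLines(file.path(d2, "markers.map")))
  genIntervals(cfg, d1); genIntervals(cfg, d2)
  expect_identical(readLines(file.path(d1, "intervals.txt")),
                   readLines(file.path(d2, "intervals.txt")))
  genAssoc(cfg, d1); genAssoc(cfg, d2)
  expect_identical(readLines(file.path(d1, "assoc.txt")),
                   readLines(file.path(d2, "assoc.txt")))
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nMarkers = 0), "nMarkers")
  expect_error(synthConfig(K = 1), "K")
  expect_error(synthConfig(nSignal = 99, nAssocRecords = 10), "nSignal")
  expect_error(synthConfig(chromLengthRange = c(100, 10)),
               "chromLengthRange")
})

test_that("marker counts are conserved and positions stay in range", {
  cfg <- synthConfig(seed = 5, nChroms = 4, nMarkers = 777)
  g <- genMapAndIndex(cfg)
  expect_equal(sum(g$perChromCounts), 777)
  r <- records(g$markers)
  expect_equal(nrow(r), 777)
  lens <- chromLengths(g$index)
  expect_true(all(r$bp >= 1 & r$bp <= lens[r$chrom]))
})

test_that("every generated file passes validation against its index", {
  cfg <- synthConfig(seed = 8, nIndividuals = 16, nPopulations = 4)
  d <- tempfile()
  gm <- genMapAndIndex(cfg, d)
  expect_true(isOK(validateInput(gm$markers, index = gm$index)))
  gi <- genIntervals(cfg, d)
  expect_true(isOK(validateInput(gi$table, index = gi$index)))
  gr <- genRelationship(cfg, d, noiseSd = 0.01)
  expect_true(isOK(validateInput(gr$matrix)))
  ge <- genEigen(cfg, d)
  expect_true(isOK(validateInput(ge$eigen)))
  ga <- genAncestry(cfg, d)
  expect_true(isOK(validateInput(ga$table)))
  gs <- genAssoc(cfg, d)
  expect_true(isOK(validateInput(gs$table, index = gs$index)))
})

test_that("Dirichlet rows lie on the simplex", {
  ga <- genAncestry(synthConfig(seed = 3, nIndividuals = 50,
                                nPopulations = 5, K = 6))
  expect_true(all(abs(rowSums(proportions(ga$table)) - 1) < 1e-9))
})

test_that("planted interval region has exactly its carrier coverage", {
  cfg <- synthConfig(seed = 19, nIndividuals = 10)
  gi <- genIntervals(cfg, plantedFraction = 0.8)
  expect_length(gi$planted$carriers, 8)
  ## coverage at the planted region equals the carrier count: calling at
  ## t = 0.8 returns a region exactly bounding the plant
  sh <- regions(computeSharedIntervals(gi$table, 0.8))
  hit <- sh[sh$chrom == gi$planted$chrom &
              sh$start == gi$planted$start &
              sh$end == gi$planted$end, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$count, 8)

  ## f = 0 plants nothing
  gi0 <- genIntervals(cfg, plantedFraction = 0)
  expect_null(gi0$planted)
})

test_that("planted assoc signals sit below 1e-7 plus uniform background", {
  cfg <- synthConfig(seed = 4, nAssocRecords = 2000, nSignal = 7)
  gs <- genAssoc(cfg)
  v <- records(gs$table)$value
  expect_length(gs$signalRows, 7)
  expect_true(all(v[gs$signalRows] < 1e-7))
  ## background exceedances of -log10(p) > 6 are Binomial(n, 1e-6):
  ## with n = 1993 essentially none, so the planted count dominates
  expect_equal(sum(v < 1e-6), 7, tolerance = 1)
})

test_that("block relationship matrices recover their ground truth", {
  cfg <- synthConfig(seed = 6, nIndividuals = 20, nPopulations = 2)
  gr <- genRelationship(cfg, within = 0.5, between = 0.1, noiseSd = 0)
  av <- as.matrix(populationAverage(gr$matrix))
  expect_equal(unname(diag(av)), c(0.5, 0.5))
  expect_equal(unname(av[1, 2]), 0.1)
  expect_true(max(abs(as.matrix(gr$matrix) -
                        t(as.matrix(gr$matrix)))) < 1e-12)
})
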