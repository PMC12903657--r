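test_that("genome index parses in file order and rejects bad lengths", {
  gi <- readGenomeIndex(writeTmp(c("1 1000", "2 500")))
  expect_identical(chromNames(gi), c("1", "2"))
  expect_equal(unname(chromLengths(gi)), c(1000, 500))

  expect_error(readGenomeIndex(writeTmp("1 0")), "row 1")
  expect_error(readGenomeIndex(writeTmp(c("1 10", "1 20"))), "duplicate")
  expect_error(readGenomeIndex(writeTmp("# only comments")), "no entries")

  ## comments interleaved: rows cited against the original file
  expect_error(readGenomeIndex(writeTmp(c("# hd", "1 10", "2 -5"))),
               "row 3")
})

test_that("PLINK map parses, keeps order, errors on malformed rows", {
  mm <- readPlinkMap(writeTmp(c("1 rs1 0 5", "1 rs2 0 12")))
  expect_equal(nrow(records(mm)), 2)
  expect_identical(records(mm)$snp_id, c("rs1", "rs2"))

  expect_error(readPlinkMap(writeTmp(character())), "no marker records")
  expect_error(readPlinkMap(writeTmp("1 rs1 0")), "expected 4")
  expect_error(readPlinkMap(writeTmp(c("1 rs1 0 5", "1 rs2 0 abc"))),
               "row 2")
})

test_that("interval table auto-detects headers and checks start <= end", {
  it <- readIntervalTable(writeTmp("POP1 A 1 100 200"))
  expect_equal(records(it)$start, 100)

  withHdr <- readIntervalTable(writeTmp(c("pop id chr start end",
                                          "POP1 A 1 100 200")))
  expect_equal(nrow(records(withHdr)), 1)

  expect_error(readIntervalTable(writeTmp("POP1 A 1 300 200")),
               "start > end")
  expect_error(readIntervalTable(writeTmp("POP1 A 1 100")), "expected 5")
})

test_that("relationship mat and col dialects assemble the same matrix", {
  ids <- writeTmp(c("G1 A", "G1 B"))
  matRel <- readRelationship(writeTmp(c("1 0.2", "0.2 1")), "mat", ids)
  colRel <- readRelationship(writeTmp(c("A A 1", "B B 1", "B A 0.2")),
                             "col", ids)
  expect_equal(as.matrix(matRel), as.matrix(colRel),
               ignore_attr = TRUE)
  expect_identical(popLabels(matRel), c("G1", "G1"))
})

test_that("columnar assembly equals a fill-then-mirror oracle", {
  set.seed(42)
  for (n in 2:6) {
    ids <- sprintf("S%d", seq_len(n))
    m <- matrix(NA_real_, n, n)
    rows <- character()
    for (i in seq_len(n)) for (j in seq_len(i)) {
      v <- round(stats::runif(1), 6)
      m[i, j] <- m[j, i] <- v
      ## randomly emit (i,j) or (j,i)
      if (stats::runif(1) < 0.5)
        rows <- c(rows, sprintf("%s %s %g", ids[i], ids[j], v))
      else
        rows <- c(rows, sprintf("%s %s %g", ids[j], ids[i], v))
    }
    rel <- readRelationship(writeTmp(sample(rows)), "col",
                            writeTmp(sprintf("G %s", ids)))
    expect_equal(unname(as.matrix(rel)), m, tolerance = 1e-9)
  }
})

test_that("relationship reader flags dialect violations", {
  ids2 <- writeTmp(c("G A", "G B"))
  expect_error(
    readRelationship(writeTmp(c("1 0.2 0.3", "0.2 1 0.1")), "mat", ids2),
    "dimensional consistency")
  expect_error(
    readRelationship(writeTmp(c("A A 1", "B B 1", "C A 0.2")), "col", ids2),
    "sample-label matching")
  expect_error(
    readRelationship(writeTmp(c("A A 1", "B A 0.2")), "col", ids2),
    "diagonal")
  expect_error(
    readRelationship(writeTmp(c("A A 1", "B B 1", "B A 0.2", "A B 0.4")),
                     "col", ids2),
    "conflicting")
  ## pop override file
  rel <- readRelationship(writeTmp(c("1 0.2", "0.2 1")), "mat", ids2,
                          popPath = writeTmp(c("A P1", "B P2")))
  expect_identical(popLabels(rel), c("P1", "P2"))
})

test_that("eigen reader enforces eigenvalue count and rectangular rows", {
  ed <- readEigen(
    writeTmp(c("P1 a 0.1 0.2 0.3", "P1 b 0.0 0.1 0.2",
               "P2 c -0.1 0.0 0.1")),
    writeTmp(c("3", "2", "1")))
  expect_equal(dim(components(ed)), c(3, 3))
  expect_identical(popLabels(ed), c("P1", "P1", "P2"))

  expect_error(readEigen(writeTmp(c("P a 1 2 3", "P b 1 2")),
                         writeTmp(c("1", "1", "1"))), "ragged")
  expect_error(readEigen(writeTmp("P a 1 2 3"), writeTmp(c("1", "1"))),
               "3 PC columns")
})

test_that("ancestry reader enforces the simplex and constant K", {
  at <- readAncestry(writeTmp("P1 A 0.7 0.3"))
  expect_equal(ncol(proportions(at)), 2)

  expect_error(readAncestry(writeTmp("P1 B 0.7 0.7")), "sum to 1")
  expect_error(readAncestry(writeTmp(c("P1 A 0.5 0.3 0.2",
                                       "P1 B 0.5 0.5"))),
               "dimensional consistency")
  expect_error(readAncestry(writeTmp("P1 A 1.0")), "K >= 2")
})

test_that("assoc reader keeps chroms as strings and rejects non-finite", {
  at <- readAssocTable(writeTmp(c("1 100 0.5", "2 50 7.2")))
  expect_identical(records(at)$chrom, c("1", "2"))

  expect_error(readAssocTable(writeTmp(c("1 100 0.5", "1 200 NaN"))),
               "row 2")
  expect_error(readAssocTable(writeTmp("1 100 NA")), "row 1")
  ## header auto-detected, NaN in the first data line still errors
  expect_error(readAssocTable(writeTmp(c("chr bp p", "1 100 NaN"))),
               "row 2")
})

test_that("every writer/reader pair round-trips its domain type", {
  d <- tempfile(); dir.create(d)
  cfg <- synthConfig(seed = 7, nMarkers = 200, nIndividuals = 12,
                     nPopulations = 3, K = 4, nAssocRecords = 150)
  gm <- genMapAndIndex(cfg, d)
  expect_equal(records(readPlinkMap(gm$mapPath)), records(gm$markers),
               tolerance = 1e-9)
  expect_equal(as.data.frame(readGenomeIndex(gm$indexPath)),
               as.data.frame(gm$index))

  gi <- genIntervals(cfg, d)
  expect_equal(records(readIntervalTable(gi$path)), records(gi$table))

  gr <- genRelationship(cfg, d, noiseSd = 0.05)
  back <- readRelationship(gr$matPath, "mat", gr$idsPath)
  expect_equal(as.matrix(back), as.matrix(gr$matrix), tolerance = 1e-9,
               ignore_attr = TRUE)
  colPath <- file.path(d, "grm.col")
  writeRelationship(gr$matrix, colPath, "col", file.path(d, "grm2.ids"))
  backCol <- readRelationship(colPath, "col", file.path(d, "grm2.ids"))
  expect_equal(as.matrix(backCol), as.matrix(gr$matrix),
               tolerance = 1e-9, ignore_attr = TRUE)

  ge <- genEigen(cfg, d)
  backE <- readEigen(ge$evecPath, ge$evalPath)
  expect_equal(components(backE), components(ge$eigen), tolerance = 1e-9)
  expect_equal(eigenvalues(backE), eigenvalues(ge$eigen),
               tolerance = 1e-9)

  ga <- genAncestry(cfg, d)
  backA <- readAncestry(ga$path)
  expect_equal(proportions(backA), proportions(ga$table),
               tolerance = 1e-9)

  gs <- genAssoc(cfg, d)
  expect_equal(records(readAssocTable(gs$path)), records(gs$table),
               tolerance = 1e-9)
})

test_that("validateInput reports instead of throwing", {
  rel <- RelationshipMatrix(diag(2), c("a", "b"), c("P", "P"))
  rep1 <- validateInput(rel)
  expect_true(isOK(rep1))
  expect_equal(nrow(issues(rep1)), 0)

  ## asymmetric raw matrix perturbed by 1e-3
  m <- diag(3)
  m[1, 2] <- 0.2; m[2, 1] <- 0.2 + 1e-3
  repA <- validateInput(m)
  expect_false(isOK(repA))
  expect_true("symmetry" %in% issues(repA)$code)

  ## interval table naming a chromosome absent from the index
  it <- IntervalTable("P", "A", "99", 1, 10)
  idx <- GenomeIndex("1", 1000)
  repI <- validateInput(it, index = idx)
  expect_false(isOK(repI))
  expect_true(any(grepl("unknown chromosome",
                        issues(repI)$message)))
  expect_true("label-matching" %in% issues(repI)$code)

  ## interval beyond the chromosome end
  it2 <- IntervalTable("P", "A", "1", 900, 1200)
  expect_false(isOK(validateInput(it2, index = idx)))

  ## non-square matrix
  expect_true("dimensional-consistency" %in%
                issues(validateInput(matrix(0, 2, 3)))$code)
})
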