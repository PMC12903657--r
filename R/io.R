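## Readers and writers for every plain-text dialect the toolkit touches.
## All files are whitespace-delimited; lines beginning with '#' and blank
## lines are ignored; error messages cite 1-based rows of the original
## file. Parsing is deliberately hand-rolled: row-numbered diagnostics,
## header auto-detection and dialect checks are part of the validation
## contract.

## Tokenise a file, dropping comments/blanks but remembering original
## row numbers.
.readTokenLines <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^[ \t]*(#|$)", lines))
  list(tokens = strsplit(trimws(lines[keep]), "[ \t]+"), rows = keep)
}

.asNum <- function(x) suppressWarnings(as.numeric(x))

## Header auto-detection: the first retained line is a header when any of
## its numeric-expected columns fails numeric parsing. Missing-value
## literals ("NA", "NaN", "Inf") count as data — they must surface as
## missing-value errors, not vanish as a header.
.numericish <- function(tok) {
  !is.na(.asNum(tok)) | grepl("^[+-]?(na|nan|inf|infinity)$", tolower(tok))
}
.dropHeader <- function(tl, numericCols) {
  if (!length(tl$tokens)) return(tl)
  first <- tl$tokens[[1]]
  ## a first line too short to carry the numeric columns is malformed
  ## data, not a header: keep it so the column-count check names the row
  if (max(numericCols) > length(first) ||
      all(.numericish(first[numericCols])))
    return(tl)
  list(tokens = tl$tokens[-1], rows = tl$rows[-1])
}

.checkNCol <- function(tl, n, what, exact = TRUE) {
  len <- lengths(tl$tokens)
  bad <- if (exact) which(len != n) else which(len < n)
  if (length(bad))
    stop(sprintf("%s: expected %s%d fields but found %d (row %d)",
                 what, if (exact) "" else "at least ", n,
                 len[bad[1]], tl$rows[bad[1]]), call. = FALSE)
}

.col <- function(tl, i) vapply(tl$tokens, `[`, character(1), i)

#' Read a genome index file
#'
#' Two whitespace-delimited columns: chromosome identifier and physical
#' length in bp. Entry order defines the display order of all downstream
#' figures.
#'
#' @param path path to the genome index file.
#' @return A [GenomeIndex-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("1 1000", "2 500"), f)
#' readGenomeIndex(f)
#' @export
readGenomeIndex <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = 2L)
  if (!length(tl$tokens))
    stop("genome index: no entries in ", path, call. = FALSE)
  .checkNCol(tl, 2L, "genome index")
  chrom <- .col(tl, 1)
  len <- .asNum(.col(tl, 2))
  bad <- which(is.na(len) | len != round(len) | len <= 0)
  if (length(bad))
    stop(sprintf("genome index: non-positive or non-integer length, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  dup <- which(duplicated(chrom))
  if (length(dup))
    stop(sprintf("genome index: duplicate chromosome '%s', row %d",
                 chrom[dup[1]], tl$rows[dup[1]]), call. = FALSE)
  GenomeIndex(chrom, len)
}

#' @rdname readGenomeIndex
#' @param x a GenomeIndex.
#' @export
writeGenomeIndex <- function(x, path) {
  stopifnot(is(x, "GenomeIndex"))
  writeLines(sprintf("%s\t%.0f", x@chrom, x@length), path)
  invisible(path)
}

#' Read a PLINK marker map (.map)
#'
#' Four whitespace-delimited columns: chromosome, SNP identifier, genetic
#' position (cM) and 1-based physical position (bp). Rows keep file order.
#'
#' @param path path to the .map file.
#' @return A [MarkerMap-class].
#' @export
readPlinkMap <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = 4L)
  if (!length(tl$tokens))
    stop("marker map: no marker records in ", path, call. = FALSE)
  .checkNCol(tl, 4L, "marker map")
  bp <- .asNum(.col(tl, 4))
  gp <- .asNum(.col(tl, 3))
  bad <- which(is.na(bp) | bp != round(bp) | bp < 1)
  if (length(bad))
    stop(sprintf("marker map: non-numeric or invalid bp position, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  bad <- which(is.na(gp))
  if (length(bad))
    stop(sprintf("marker map: non-numeric genetic position, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  MarkerMap(.col(tl, 1), .col(tl, 2), gp, bp)
}

#' @rdname readPlinkMap
#' @param x a MarkerMap.
#' @export
writePlinkMap <- function(x, path) {
  stopifnot(is(x, "MarkerMap"))
  r <- x@records
  writeLines(sprintf("%s\t%s\t%.10g\t%.0f", r$chrom, r$snp_id,
                     r$genetic_pos, r$bp), path)
  invisible(path)
}

#' Read a five-column ROH/CNV interval table
#'
#' Columns: population label, individual ID, chromosome, start, end
#' (1-based, inclusive). An optional header line is auto-detected (first
#' line whose start/end columns are non-numeric).
#'
#' @param path path to the interval table.
#' @return An [IntervalTable-class].
#' @export
readIntervalTable <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = c(4L, 5L))
  if (!length(tl$tokens))
    stop("interval table: no records in ", path, call. = FALSE)
  .checkNCol(tl, 5L, "interval table")
  start <- .asNum(.col(tl, 4))
  end <- .asNum(.col(tl, 5))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("interval table: non-numeric start/end, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  bad <- which(start < 1 | start > end)
  if (length(bad))
    stop(sprintf("interval table: start > end or start < 1, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  IntervalTable(.col(tl, 1), .col(tl, 2), .col(tl, 3), start, end)
}

#' @rdname readIntervalTable
#' @param x an IntervalTable.
#' @export
writeIntervalTable <- function(x, path) {
  stopifnot(is(x, "IntervalTable"))
  r <- x@records
  writeLines(c("population\tindividual\tchrom\tstart\tend",
               sprintf("%s\t%s\t%s\t%.0f\t%.0f", r$population, r$individual,
                       r$chrom, r$start, r$end)), path)
  invisible(path)
}

#' Read a relationship matrix in "mat" or "col" dialect
#'
#' The "mat" dialect is an N x N whitespace-delimited numeric grid with a
#' companion ids file of N rows (group/family label, individual ID); the
#' group label doubles as the population label unless `popPath` is given.
#' The "col" dialect is long format (ID1, ID2, value) covering at least
#' the lower triangle including the diagonal; values given for only one
#' orientation are mirrored, and pairs given twice must agree within
#' 1e-9.
#'
#' @param path path to the matrix file.
#' @param dialect `"mat"` or `"col"`.
#' @param idsPath companion ids file (two columns: group label,
#'   individual ID).
#' @param popPath optional two-column file (individual ID, population)
#'   overriding the ids-file group labels.
#' @return A [RelationshipMatrix-class].
#' @export
readRelationship <- function(path, dialect = c("mat", "col"), idsPath,
                             popPath = NULL) {
  dialect <- match.arg(dialect)
  ids <- .readTokenLines(idsPath)
  .checkNCol(ids, 2L, "ids file", exact = FALSE)
  sampleIds <- .col(ids, 2)
  popLabels <- .col(ids, 1)
  if (anyDuplicated(sampleIds))
    stop("ids file: duplicate individual ID '",
         sampleIds[duplicated(sampleIds)][1], "'", call. = FALSE)
  if (!is.null(popPath)) {
    pp <- .readTokenLines(popPath)
    .checkNCol(pp, 2L, "pop file")
    m <- match(sampleIds, .col(pp, 1))
    if (anyNA(m))
      stop("pop file: no population for individual '",
           sampleIds[is.na(m)][1], "' (sample-label matching)",
           call. = FALSE)
    popLabels <- .col(pp, 2)[m]
  }
  n <- length(sampleIds)
  if (dialect == "mat") {
    tl <- .readTokenLines(path)
    vals <- lapply(tl$tokens, .asNum)
    widths <- lengths(vals)
    if (length(vals) != n || any(widths != n))
      stop(sprintf(paste0("relationship matrix: dimensional consistency ",
                          "error — grid is %d x %s but ids file has %d ",
                          "samples"), length(vals),
                   paste(unique(widths), collapse = "/"), n), call. = FALSE)
    bad <- which(vapply(vals, anyNA, logical(1)))
    if (length(bad))
      stop(sprintf("relationship matrix: missing or non-numeric value, row %d",
                   tl$rows[bad[1]]), call. = FALSE)
    m <- do.call(rbind, vals)
    if (max(abs(m - t(m))) > 1e-9)
      stop("relationship matrix: grid is not symmetric", call. = FALSE)
  } else {
    tl <- .dropHeader(.readTokenLines(path), numericCols = 3L)
    .checkNCol(tl, 3L, "columnar relationship file")
    id1 <- .col(tl, 1); id2 <- .col(tl, 2)
    v <- .asNum(.col(tl, 3))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("columnar relationship file: missing value, row %d",
                   tl$rows[bad[1]]), call. = FALSE)
    i <- match(id1, sampleIds); j <- match(id2, sampleIds)
    bad <- which(is.na(i) | is.na(j))
    if (length(bad))
      stop(sprintf(paste0("columnar relationship file: sample-label ",
                          "matching error — '%s' absent from ids file ",
                          "(row %d)"),
                   if (is.na(i[bad[1]])) id1[bad[1]] else id2[bad[1]],
                   tl$rows[bad[1]]), call. = FALSE)
    m <- matrix(NA_real_, n, n)
    for (k in seq_along(v)) {
      for (cell in list(c(i[k], j[k]), c(j[k], i[k]))) {
        old <- m[cell[1], cell[2]]
        if (!is.na(old) && abs(old - v[k]) > 1e-9)
          stop(sprintf(paste0("columnar relationship file: conflicting ",
                              "values for pair (%s, %s)"),
                       id1[k], id2[k]), call. = FALSE)
        m[cell[1], cell[2]] <- v[k]
      }
    }
    missDiag <- which(is.na(diag(m)))
    if (length(missDiag))
      stop("columnar relationship file: missing diagonal entry for '",
           sampleIds[missDiag[1]], "'", call. = FALSE)
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("columnar relationship file: no value for pair ",
                          "(%s, %s)"), sampleIds[idx[1]], sampleIds[idx[2]]),
           call. = FALSE)
    }
  }
  RelationshipMatrix(m, sampleIds, popLabels)
}

#' @rdname readRelationship
#' @param x a RelationshipMatrix.
#' @export
writeRelationship <- function(x, path, dialect = c("mat", "col"), idsPath) {
  stopifnot(is(x, "RelationshipMatrix"))
  dialect <- match.arg(dialect)
  writeLines(sprintf("%s\t%s", x@popLabels, x@sampleIds), idsPath)
  m <- x@values
  if (dialect == "mat") {
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.12g", r), collapse = "\t")), path)
  } else {
    n <- length(x@sampleIds)
    out <- character()
    for (i in seq_len(n))
      for (j in seq_len(i))
        out <- c(out, sprintf("%s\t%s\t%.12g", x@sampleIds[i],
                              x@sampleIds[j], m[i, j]))
    writeLines(out, path)
  }
  invisible(path)
}

#' Read PCA eigenvector/eigenvalue files
#'
#' The eigenvector file carries a group/family label and an individual ID
#' in its first two columns followed by numeric PC coordinates (PLINK
#' `--pca` layout); the eigenvalue file holds one non-negative number per
#' line, at least as many as there are PC columns.
#'
#' @param evecPath path to the eigenvector file.
#' @param evalPath path to the eigenvalue file.
#' @return An [EigenData-class]; population labels come from the first
#'   eigenvector column.
#' @export
readEigen <- function(evecPath, evalPath) {
  tl <- .readTokenLines(evecPath)
  if (!length(tl$tokens))
    stop("eigenvector file: no samples in ", evecPath, call. = FALSE)
  widths <- lengths(tl$tokens)
  if (length(unique(widths)) != 1)
    stop(sprintf("eigenvector file: ragged rows (%s columns)",
                 paste(unique(widths), collapse = "/")), call. = FALSE)
  if (widths[1] < 3)
    stop("eigenvector file: need label, ID and at least one PC column",
         call. = FALSE)
  k <- widths[1] - 2L
  comp <- matrix(NA_real_, length(tl$tokens), k)
  for (r in seq_along(tl$tokens)) {
    vals <- .asNum(tl$tokens[[r]][-(1:2)])
    if (anyNA(vals))
      stop(sprintf("eigenvector file: non-numeric PC value, row %d",
                   tl$rows[r]), call. = FALSE)
    comp[r, ] <- vals
  }
  ev <- .readTokenLines(evalPath)
  evals <- .asNum(vapply(ev$tokens, `[`, character(1), 1))
  if (anyNA(evals) || any(evals < 0))
    stop("eigenvalue file: values must be non-negative numbers",
         call. = FALSE)
  if (length(evals) < k)
    stop(sprintf("eigenvalue file: %d eigenvalues for %d PC columns",
                 length(evals), k), call. = FALSE)
  EigenData(comp, evals, .col(tl, 2), .col(tl, 1))
}

#' @rdname readEigen
#' @param x an EigenData.
#' @export
writeEigen <- function(x, evecPath, evalPath) {
  stopifnot(is(x, "EigenData"))
  rows <- vapply(seq_along(x@sampleIds), function(i)
    paste(c(x@popLabels[i], x@sampleIds[i],
            sprintf("%.12g", x@components[i, ])), collapse = "\t"),
    character(1))
  writeLines(rows, evecPath)
  writeLines(sprintf("%.12g", x@eigenvalues), evalPath)
  invisible(evecPath)
}

#' Read an admixture proportion table (Q table)
#'
#' Columns: population label, individual ID, then K >= 2 numeric ancestry
#' proportions. K is inferred from the first data row and enforced on all
#' rows; every row must sum to 1 within 0.01.
#'
#' @param path path to the table.
#' @return An [AncestryTable-class].
#' @export
readAncestry <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = 3L)
  if (!length(tl$tokens))
    stop("ancestry table: no records in ", path, call. = FALSE)
  widths <- lengths(tl$tokens)
  if (widths[1] < 4)
    stop("ancestry table: need population, individual and K >= 2 proportions",
         call. = FALSE)
  bad <- which(widths != widths[1])
  if (length(bad))
    stop(sprintf(paste0("ancestry table: dimensional consistency error — ",
                        "row %d has %d fields, expected %d"),
                 tl$rows[bad[1]], widths[bad[1]], widths[1]), call. = FALSE)
  k <- widths[1] - 2L
  props <- matrix(NA_real_, length(tl$tokens), k)
  for (r in seq_along(tl$tokens)) {
    vals <- .asNum(tl$tokens[[r]][-(1:2)])
    if (anyNA(vals))
      stop(sprintf("ancestry table: non-numeric proportion, row %d",
                   tl$rows[r]), call. = FALSE)
    if (abs(sum(vals) - 1) > 0.01)
      stop(sprintf(paste0("ancestry table: proportions do not sum to 1 ",
                          "(sum %.4g, row %d)"), sum(vals), tl$rows[r]),
           call. = FALSE)
    props[r, ] <- vals
  }
  AncestryTable(.col(tl, 1), .col(tl, 2), props)
}

#' @rdname readAncestry
#' @param x an AncestryTable.
#' @export
writeAncestry <- function(x, path) {
  stopifnot(is(x, "AncestryTable"))
  rows <- vapply(seq_along(x@individual), function(i)
    paste(c(x@population[i], x@individual[i],
            sprintf("%.12g", x@proportions[i, ])), collapse = "\t"),
    character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a three-column association table
#'
#' Columns: chromosome name (kept as a string), 1-based bp position and a
#' finite statistic value (p-value, Fst, nucleotide diversity, ...). An
#' optional header is auto-detected.
#'
#' @param path path to the table.
#' @return An [AssocTable-class].
#' @export
readAssocTable <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = c(2L, 3L))
  if (!length(tl$tokens))
    stop("association table: no records in ", path, call. = FALSE)
  .checkNCol(tl, 3L, "association table")
  bp <- .asNum(.col(tl, 2))
  val <- .asNum(.col(tl, 3))
  bad <- which(is.na(bp) | bp != round(bp) | bp < 1)
  if (length(bad))
    stop(sprintf("association table: invalid bp position, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad))
    stop(sprintf("association table: missing or non-finite value, row %d",
                 tl$rows[bad[1]]), call. = FALSE)
  AssocTable(.col(tl, 1), bp, val)
}

#' @rdname readAssocTable
#' @param x an AssocTable.
#' @export
writeAssocTable <- function(x, path) {
  stopifnot(is(x, "AssocTable"))
  r <- x@records
  writeLines(sprintf("%s\t%.0f\t%.12g", r$chrom, r$bp, r$value), path)
  invisible(path)
}
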