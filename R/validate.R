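## validateInput(): the non-throwing inspection layer. Readers throw on
## malformed files; validateInput() enumerates violations on loaded (or
## raw) objects, so pipelines can report everything at once.

.chromCheck <- function(chrom, index, what) {
  if (is.null(index)) return(NULL)
  unknown <- setdiff(unique(chrom), index@chrom)
  if (!length(unknown)) return(NULL)
  .issue("error", "label-matching",
         sprintf("%s names unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")))
}

#' @describeIn validateInput consistency of a genome index.
#' @export
setMethod("validateInput", "GenomeIndex", function(x, ...) .report())

#' @describeIn validateInput marker map, optionally cross-checked against
#'   a genome index (`index=`): unknown chromosomes and positions beyond
#'   the indexed length are errors.
#' @param index optional [GenomeIndex()] for chromosome cross-checks.
#' @export
setMethod("validateInput", "MarkerMap", function(x, index = NULL, ...) {
  iss <- .chromCheck(x@records$chrom, index, "marker map")
  if (!is.null(index)) {
    len <- chromLengths(index)[x@records$chrom]
    bad <- which(!is.na(len) & x@records$bp > len)
    if (length(bad))
      iss <- rbind(iss, .issue("error", "range",
        sprintf("marker '%s' at bp %.0f beyond length of chromosome %s",
                x@records$snp_id[bad[1]], x@records$bp[bad[1]],
                x@records$chrom[bad[1]]), bad[1]))
  }
  .report(iss)
})

#' @describeIn validateInput interval table; with `index=`, unknown
#'   chromosomes and intervals beyond the chromosome end are errors.
#' @export
setMethod("validateInput", "IntervalTable", function(x, index = NULL, ...) {
  iss <- .chromCheck(x@records$chrom, index, "interval table")
  if (!is.null(index)) {
    len <- chromLengths(index)[x@records$chrom]
    bad <- which(!is.na(len) & x@records$end > len)
    if (length(bad))
      iss <- rbind(iss, .issue("error", "range",
        sprintf("interval [%.0f, %.0f] beyond length of chromosome %s",
                x@records$start[bad[1]], x@records$end[bad[1]],
                x@records$chrom[bad[1]]), bad[1]))
  }
  ind <- unique(x@records[c("individual", "population")])
  dup <- ind$individual[duplicated(ind$individual)]
  if (length(dup))
    iss <- rbind(iss, .issue("warning", "label-matching",
      sprintf("individual(s) with conflicting population labels: %s",
              paste(unique(dup), collapse = ", "))))
  .report(iss)
})

#' @describeIn validateInput a classed relationship matrix (symmetry and
#'   completeness hold by construction; labels re-checked).
#' @export
setMethod("validateInput", "RelationshipMatrix", function(x, ...) {
  .report(.validateRelValues(x@values, length(x@sampleIds)))
})

#' @describeIn validateInput a raw numeric matrix (optionally with
#'   `sampleIds=`): squareness, symmetry within 1e-9, missing cells.
#' @param sampleIds optional sample identifiers to match against a raw
#'   matrix's dimensions.
#' @export
setMethod("validateInput", "matrix", function(x, sampleIds = NULL, ...) {
  iss <- .validateRelValues(x, if (is.null(sampleIds)) nrow(x)
                               else length(sampleIds))
  .report(iss)
})

.validateRelValues <- function(v, n) {
  iss <- NULL
  if (nrow(v) != ncol(v))
    iss <- rbind(iss, .issue("error", "dimensional-consistency",
      sprintf("matrix is %d x %d, not square", nrow(v), ncol(v))))
  if (nrow(v) == ncol(v) && nrow(v) != n)
    iss <- rbind(iss, .issue("error", "dimensional-consistency",
      sprintf("matrix is %d x %d but %d samples are labelled",
              nrow(v), ncol(v), n)))
  if (anyNA(v))
    iss <- rbind(iss, .issue("error", "missing-values",
                             "matrix contains missing cells"))
  else if (nrow(v) == ncol(v) && nrow(v) &&
           max(abs(v - t(v))) > 1e-9)
    iss <- rbind(iss, .issue("error", "symmetry",
      sprintf("matrix is asymmetric (max |v - t(v)| = %.3g)",
              max(abs(v - t(v))))))
  iss
}

#' @describeIn validateInput eigen data: PC/eigenvalue bookkeeping.
#' @export
setMethod("validateInput", "EigenData", function(x, ...) {
  iss <- NULL
  if (length(x@eigenvalues) < ncol(x@components))
    iss <- rbind(iss, .issue("error", "dimensional-consistency",
      "fewer eigenvalues than PC columns"))
  if (anyNA(x@components))
    iss <- rbind(iss, .issue("error", "missing-values",
                             "missing PC coordinates"))
  .report(iss)
})

#' @describeIn validateInput ancestry table: simplex rows within 0.01.
#' @export
setMethod("validateInput", "AncestryTable", function(x, ...) {
  iss <- NULL
  bad <- which(abs(rowSums(x@proportions) - 1) > 0.01)
  if (length(bad))
    iss <- rbind(iss, .issue("error", "file-structure",
      sprintf("proportions do not sum to 1 for %d row(s)", length(bad)),
      bad[1]))
  .report(iss)
})

#' @describeIn validateInput association table; with `index=`, unknown
#'   chromosomes are errors and indexed chromosomes with no records get a
#'   warning.
#' @export
setMethod("validateInput", "AssocTable", function(x, index = NULL, ...) {
  iss <- .chromCheck(x@records$chrom, index, "association table")
  if (anyNA(x@records$value) || any(!is.finite(x@records$value)))
    iss <- rbind(iss, .issue("error", "missing-values",
                             "non-finite statistic values"))
  if (!is.null(index)) {
    empty <- setdiff(index@chrom, unique(x@records$chrom))
    if (length(empty))
      iss <- rbind(iss, .issue("warning", "label-matching",
        sprintf("no records on indexed chromosome(s): %s",
                paste(empty, collapse = ", "))))
  }
  .report(iss)
})
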