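#' Accessors for popgenviz data classes
#'
#' Slot access goes through these accessors; slots are implementation
#' detail.
#'
#' @param x a popgenviz object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("chromNames", "GenomeIndex", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeIndex", function(x) {
  stats::setNames(x@length, x@chrom)
})
#' @rdname accessors
#' @export
setMethod("records", "MarkerMap", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("records", "IntervalTable", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("records", "AssocTable", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("sampleIds", "RelationshipMatrix", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "EigenData", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("popLabels", "RelationshipMatrix", function(x) x@popLabels)
#' @rdname accessors
#' @export
setMethod("popLabels", "EigenData", function(x) x@popLabels)
#' @rdname accessors
#' @export
setMethod("components", "EigenData", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("eigenvalues", "EigenData", function(x) x@eigenvalues)
#' @rdname accessors
#' @export
setMethod("proportions", "AncestryTable", function(x) x@proportions)
#' @rdname accessors
#' @export
setMethod("proportions", "AdmixLayout", function(x) x@proportions)
#' @rdname accessors
#' @export
setMethod("individuals", "AncestryTable", function(x) x@individual)
#' @rdname accessors
#' @export
setMethod("individuals", "AdmixLayout", function(x) x@individual)
#' @rdname accessors
#' @export
setMethod("populations", "AncestryTable", function(x) x@population)
#' @rdname accessors
#' @export
setMethod("populations", "AdmixLayout", function(x) x@population)
#' @rdname accessors
#' @export
setMethod("isOK", "ValidationReport", function(x) x@ok)
#' @rdname accessors
#' @export
setMethod("issues", "ValidationReport", function(x) x@issues)
#' @rdname accessors
#' @export
setMethod("regions", "SharedIntervals", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("popIds", "PopAverageMatrix", function(x) x@popIds)
#' @rdname accessors
#' @export
setMethod("groups", "AdmixLayout", function(x) x@groups)
#' @rdname accessors
#' @export
setMethod("chromInfo", "ManhattanLayout", function(x) x@chromInfo)
#' @rdname accessors
#' @export
setMethod("records", "ManhattanLayout", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("chromNames", "BinDensity", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("chromLengths", "BinDensity", function(x) {
  stats::setNames(x@length, x@chrom)
})
#' @rdname accessors
#' @export
setMethod("binCounts", "BinDensity", function(x) {
  stats::setNames(x@counts, x@chrom)
})
#' @rdname accessors
#' @export
setMethod("binSize", "BinDensity", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("length", "GenomeIndex", function(x) length(x@chrom))

## Matrix views -------------------------------------------------------------

#' @param ... unused.
#' @rdname accessors
#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("as.matrix", "PopAverageMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@popIds, x@popIds)
  v
})

#' @param row.names,optional passed on conventionally, unused.
#' @rdname accessors
#' @export
setMethod("as.data.frame", "GenomeIndex",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(chrom = x@chrom, length = x@length, stringsAsFactors = FALSE)
  })
#' @rdname accessors
#' @export
setMethod("as.data.frame", "SharedIntervals",
  function(x, row.names = NULL, optional = FALSE, ...) x@regions)

## show() -------------------------------------------------------------------

setMethod("show", "GenomeIndex", function(object) {
  cat(sprintf("GenomeIndex with %d chromosomes, total %.0f bp\n",
              length(object@chrom), sum(object@length)))
})
setMethod("show", "MarkerMap", function(object) {
  r <- object@records
  cat(sprintf("MarkerMap with %d markers on %d chromosomes\n",
              nrow(r), length(unique(r$chrom))))
})
setMethod("show", "IntervalTable", function(object) {
  r <- object@records
  cat(sprintf(
    "IntervalTable with %d segments, %d individuals, %d populations\n",
    nrow(r), length(unique(r$individual)), length(unique(r$population))))
})
setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix: %d samples, %d populations\n",
              length(object@sampleIds), length(unique(object@popLabels))))
})
setMethod("show", "EigenData", function(object) {
  cat(sprintf("EigenData: %d samples x %d PCs (%d eigenvalues)\n",
              length(object@sampleIds), ncol(object@components),
              length(object@eigenvalues)))
})
setMethod("show", "AncestryTable", function(object) {
  cat(sprintf("AncestryTable: %d individuals, %d populations, K = %d\n",
              length(object@individual), length(unique(object@population)),
              ncol(object@proportions)))
})
setMethod("show", "AssocTable", function(object) {
  r <- object@records
  cat(sprintf("AssocTable with %d records on %d chromosomes\n",
              nrow(r), length(unique(r$chrom))))
})
setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d issue%s)\n",
              if (object@ok) "OK" else "FAILED", nrow(object@issues),
              if (nrow(object@issues) == 1) "" else "s"))
  if (nrow(object@issues)) {
    iss <- object@issues
    for (i in seq_len(nrow(iss)))
      cat(sprintf("  [%s] %s: %s%s\n", iss$severity[i], iss$code[i],
                  iss$message[i],
                  if (is.na(iss$row[i])) "" else sprintf(" (row %d)", iss$row[i])))
  }
})
setMethod("show", "BinDensity", function(object) {
  cat(sprintf("BinDensity: %d chromosomes, bin size %.0f bp, %d markers\n",
              length(object@chrom), object@binSize,
              sum(unlist(object@counts))))
})
setMethod("show", "SharedIntervals", function(object) {
  cat(sprintf(
    "SharedIntervals: %d regions (threshold %.3g, %d individuals)\n",
    nrow(object@regions), object@threshold, object@nIndividuals))
})
setMethod("show", "PopAverageMatrix", function(object) {
  cat(sprintf("PopAverageMatrix over %d populations\n",
              length(object@popIds)))
})
setMethod("show", "AdmixLayout", function(object) {
  cat(sprintf("AdmixLayout: %d individuals in %d population blocks, K = %d\n",
              length(object@individual), nrow(object@groups),
              ncol(object@proportions)))
})
setMethod("show", "ManhattanLayout", function(object) {
  cat(sprintf("ManhattanLayout: %d points over %d chromosomes\n",
              nrow(object@points), nrow(object@chromInfo)))
})
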