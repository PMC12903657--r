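## User-facing constructors: light wrappers over new() that normalise
## argument types and let the class validity methods do the checking.

#' @param chrom,length chromosome identifiers and physical lengths (bp).
#' @rdname GenomeIndex-class
#' @export
GenomeIndex <- function(chrom = character(), length = numeric()) {
  new("GenomeIndex", chrom = as.character(chrom), length = as.numeric(length))
}

#' @param chrom,snp_id,genetic_pos,bp marker map columns.
#' @rdname MarkerMap-class
#' @export
MarkerMap <- function(chrom = character(), snp_id = character(),
                      genetic_pos = numeric(), bp = numeric()) {
  new("MarkerMap", records = data.frame(
    chrom = as.character(chrom), snp_id = as.character(snp_id),
    genetic_pos = as.numeric(genetic_pos), bp = as.numeric(bp),
    stringsAsFactors = FALSE))
}

#' @param population,individual,chrom,start,end interval table columns.
#' @rdname IntervalTable-class
#' @export
IntervalTable <- function(population = character(), individual = character(),
                          chrom = character(), start = numeric(),
                          end = numeric()) {
  new("IntervalTable", records = data.frame(
    population = as.character(population),
    individual = as.character(individual),
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), stringsAsFactors = FALSE))
}

#' @param values N x N symmetric matrix.
#' @param sampleIds,popLabels sample identifiers and population labels.
#' @rdname RelationshipMatrix-class
#' @export
RelationshipMatrix <- function(values, sampleIds, popLabels) {
  values <- as.matrix(values)
  dimnames(values) <- list(sampleIds, sampleIds)
  new("RelationshipMatrix", sampleIds = as.character(sampleIds),
      popLabels = as.character(popLabels), values = values)
}

#' @param components N x k PC coordinate matrix.
#' @param eigenvalues non-negative eigenvalues (k' >= k).
#' @param sampleIds,popLabels sample identifiers and population labels.
#' @rdname EigenData-class
#' @export
EigenData <- function(components, eigenvalues, sampleIds, popLabels) {
  new("EigenData", sampleIds = as.character(sampleIds),
      popLabels = as.character(popLabels),
      components = as.matrix(components),
      eigenvalues = as.numeric(eigenvalues))
}

#' @param population,individual label vectors.
#' @param proportions N x K matrix of ancestry proportions.
#' @rdname AncestryTable-class
#' @export
AncestryTable <- function(population, individual, proportions) {
  new("AncestryTable", population = as.character(population),
      individual = as.character(individual),
      proportions = as.matrix(proportions))
}

#' @param chrom,bp,value association table columns.
#' @rdname AssocTable-class
#' @export
AssocTable <- function(chrom = character(), bp = numeric(),
                       value = numeric()) {
  new("AssocTable", records = data.frame(
    chrom = as.character(chrom), bp = as.numeric(bp),
    value = as.numeric(value), stringsAsFactors = FALSE))
}

## Internal: assemble a ValidationReport from an issue data.frame.
.report <- function(issues = NULL) {
  if (is.null(issues) || !nrow(issues)) {
    issues <- data.frame(severity = character(), code = character(),
                         message = character(), row = integer(),
                         stringsAsFactors = FALSE)
  }
  new("ValidationReport", ok = !any(issues$severity == "error"),
      issues = issues)
}

.issue <- function(severity, code, message, row = NA_integer_) {
  data.frame(severity = severity, code = code, message = message,
             row = as.integer(row), stringsAsFactors = FALSE)
}
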