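## Central S4 data containers. All genomic coordinates are 1-based and
## intervals are inclusive on both ends (PLINK .hom convention). Positions
## and lengths are stored as doubles so coordinates beyond 2^31 survive;
## validity checks enforce integral values.

.isWholeNumber <- function(x, tol = 1e-6) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

#' GenomeIndex: ordered chromosome identifiers with physical lengths
#'
#' The authoritative genomic extent for all downstream layout. Entry order
#' is the display order in every figure.
#'
#' @slot chrom character vector of unique chromosome identifiers.
#' @slot length numeric vector of positive chromosome lengths in bp.
#' @exportClass GenomeIndex
setClass("GenomeIndex",
  representation(chrom = "character", length = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@chrom) != length(object@length))
      msg <- c(msg, "chrom and length differ in length")
    if (anyDuplicated(object@chrom))
      msg <- c(msg, "duplicate chromosome identifiers")
    if (length(object@length) && (any(!.isWholeNumber(object@length)) ||
        any(object@length <= 0)))
      msg <- c(msg, "chromosome lengths must be positive integers")
    if (length(msg)) msg else TRUE
  })

#' MarkerMap: PLINK-style marker map (.map)
#'
#' @slot records data.frame with columns chrom (character), snp_id
#'   (character), genetic_pos (numeric, cM), bp (numeric, 1-based).
#'   Rows retain file order.
#' @exportClass MarkerMap
setClass("MarkerMap",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("chrom", "snp_id", "genetic_pos", "bp")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(r)) {
      if (any(!.isWholeNumber(r$bp)) || any(r$bp < 1))
        msg <- c(msg, "bp must be integer >= 1")
      if (any(!nzchar(r$snp_id)))
        msg <- c(msg, "snp_id must be non-empty")
    }
    if (length(msg)) msg else TRUE
  })

#' IntervalTable: per-individual genomic segments (ROH or CNV)
#'
#' Rows may overlap within an individual; overlap is resolved downstream
#' by [mergeIndividualIntervals()], never rejected here.
#'
#' @slot records data.frame with columns population, individual, chrom
#'   (character), start, end (numeric bp, 1-based inclusive, start <= end).
#' @exportClass IntervalTable
setClass("IntervalTable",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("population", "individual", "chrom", "start", "end")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(r)) {
      if (any(!.isWholeNumber(r$start)) || any(!.isWholeNumber(r$end)))
        msg <- c(msg, "start/end must be integers")
      else if (any(r$start < 1) || any(r$start > r$end))
        msg <- c(msg, "intervals must satisfy 1 <= start <= end")
    }
    if (length(msg)) msg else TRUE
  })

#' RelationshipMatrix: square symmetric sample-by-sample relatedness
#'
#' @slot sampleIds ordered character vector of sample identifiers.
#' @slot popLabels character vector of population labels, aligned to
#'   sampleIds.
#' @slot values N x N symmetric numeric matrix (tolerance 1e-9), no NAs.
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(sampleIds = "character", popLabels = "character",
                 values = "matrix"),
  validity = function(object) {
    n <- length(object@sampleIds)
    v <- object@values
    msg <- character()
    if (length(object@popLabels) != n)
      msg <- c(msg, "popLabels must align with sampleIds")
    if (!is.numeric(v) || nrow(v) != n || ncol(v) != n)
      msg <- c(msg, "values must be an N x N numeric matrix")
    else {
      if (anyNA(v)) msg <- c(msg, "missing cells in relationship matrix")
      else if (n && max(abs(v - t(v))) > 1e-9)
        msg <- c(msg, "matrix is not symmetric (tolerance 1e-9)")
    }
    if (anyDuplicated(object@sampleIds))
      msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
  })

#' EigenData: PCA eigenvector coordinates with eigenvalues
#'
#' @slot sampleIds ordered character vector.
#' @slot popLabels aligned character vector of population labels.
#' @slot components N x k numeric matrix of PC coordinates.
#' @slot eigenvalues numeric vector of k' >= k non-negative eigenvalues.
#' @exportClass EigenData
setClass("EigenData",
  representation(sampleIds = "character", popLabels = "character",
                 components = "matrix", eigenvalues = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@sampleIds)
    if (length(object@popLabels) != n)
      msg <- c(msg, "popLabels must align with sampleIds")
    if (nrow(object@components) != n)
      msg <- c(msg, "components rows must match sampleIds")
    if (ncol(object@components) < 1)
      msg <- c(msg, "at least one PC required")
    if (length(object@eigenvalues) < ncol(object@components))
      msg <- c(msg, "fewer eigenvalues than PC columns")
    if (length(object@eigenvalues) && any(object@eigenvalues < 0))
      msg <- c(msg, "eigenvalues must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' AncestryTable: per-individual ancestry proportions (Q matrix)
#'
#' @slot population character vector of population labels.
#' @slot individual aligned character vector of individual IDs.
#' @slot proportions N x K numeric matrix; each row sums to 1 within 0.01.
#' @exportClass AncestryTable
setClass("AncestryTable",
  representation(population = "character", individual = "character",
                 proportions = "matrix"),
  validity = function(object) {
    n <- length(object@population)
    msg <- character()
    if (length(object@individual) != n)
      msg <- c(msg, "individual must align with population")
    if (nrow(object@proportions) != n)
      msg <- c(msg, "proportions rows must match individuals")
    if (ncol(object@proportions) < 2)
      msg <- c(msg, "K must be >= 2")
    p <- object@proportions
    if (n) {
      if (anyNA(p) || any(p < -1e-9) || any(p > 1 + 1e-9))
        msg <- c(msg, "proportions must lie in [0, 1]")
      else if (any(abs(rowSums(p) - 1) > 0.01))
        msg <- c(msg, "proportions do not sum to 1 (tolerance 0.01)")
    }
    if (length(msg)) msg else TRUE
  })

#' AssocTable: per-marker association/selection statistics
#'
#' @slot records data.frame with columns chrom (character), bp (numeric,
#'   1-based), value (finite numeric).
#' @exportClass AssocTable
setClass("AssocTable",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("chrom", "bp", "value")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(r)) {
      if (any(!.isWholeNumber(r$bp)) || any(r$bp < 1))
        msg <- c(msg, "bp must be integer >= 1")
      if (anyNA(r$value) || any(!is.finite(r$value)))
        msg <- c(msg, "statistic values must be finite and non-missing")
    }
    if (length(msg)) msg else TRUE
  })

#' ValidationReport: outcome of input validation
#'
#' Violations are reported, not thrown; ok is TRUE iff no error-severity
#' issue is present.
#'
#' @slot ok logical scalar.
#' @slot issues data.frame with columns severity ("error"/"warning"),
#'   code, message (character) and row (integer, NA when not row-bound).
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(ok = "logical", issues = "data.frame"),
  validity = function(object) {
    iss <- object@issues
    need <- c("severity", "code", "message", "row")
    if (!all(need %in% names(iss)))
      return(paste("issues must have columns", paste(need, collapse = ", ")))
    hasErr <- any(iss$severity == "error")
    if (!identical(object@ok, !hasErr))
      return("ok must be TRUE iff there is no error-severity issue")
    TRUE
  })

#' BinDensity: fixed-bin SNP counts per chromosome
#'
#' For every indexed chromosome, counts has ceiling(length / binSize)
#' entries even when no marker maps there; genomic extent always comes
#' from the genome index, never from the last SNP.
#'
#' @slot chrom character vector in genome-index order.
#' @slot length numeric chromosome lengths (bp).
#' @slot binSize single numeric bin width in bp.
#' @slot counts list of non-negative integer vectors, one per chromosome.
#' @exportClass BinDensity
setClass("BinDensity",
  representation(chrom = "character", length = "numeric",
                 binSize = "numeric", counts = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@binSize) != 1 || object@binSize < 1)
      msg <- c(msg, "binSize must be a single value >= 1")
    if (length(object@chrom) != length(object@counts) ||
        length(object@chrom) != length(object@length))
      msg <- c(msg, "chrom, length and counts must align")
    else {
      expect <- ceiling(object@length / object@binSize)
      got <- lengths(object@counts)
      if (any(got != expect))
        msg <- c(msg, "each chromosome needs ceiling(length/binSize) bins")
      if (any(unlist(object@counts) < 0))
        msg <- c(msg, "bin counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' SharedIntervals: genomic regions covered by many individuals
#'
#' Result of the sweep-line shared-region caller. count is the minimum
#' per-base coverage across the region; frequency = count / N.
#'
#' @slot regions data.frame with columns chrom, start, end, count,
#'   frequency.
#' @slot nIndividuals number of distinct individuals the frequency
#'   denominator refers to.
#' @slot threshold the minimum-frequency cutoff used.
#' @exportClass SharedIntervals
setClass("SharedIntervals",
  representation(regions = "data.frame", nIndividuals = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    r <- object@regions
    need <- c("chrom", "start", "end", "count", "frequency")
    if (!all(need %in% names(r)))
      return(paste("regions must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(r)) {
      if (any(r$start > r$end)) msg <- c(msg, "start must be <= end")
      if (any(r$frequency <= 0 | r$frequency > 1))
        msg <- c(msg, "frequency must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' PopAverageMatrix: population-level average pairwise relationships
#'
#' @slot popIds ordered character vector of population labels.
#' @slot values P x P symmetric numeric matrix of averaged relationships.
#' @exportClass PopAverageMatrix
setClass("PopAverageMatrix",
  representation(popIds = "character", values = "matrix"),
  validity = function(object) {
    p <- length(object@popIds)
    v <- object@values
    if (nrow(v) != p || ncol(v) != p)
      return("values must be P x P")
    if (p && max(abs(v - t(v))) > 1e-9)
      return("averaged matrix must be symmetric")
    TRUE
  })

#' AdmixLayout: plotting order for an admixture barplot
#'
#' Individuals are grouped by population (first-appearance order) and,
#' within each group, sorted ascending by the group's dominant ancestry
#' component.
#'
#' @slot population,individual character vectors in plotting order.
#' @slot proportions N x K matrix re-ordered to match.
#' @slot groups data.frame with population, first, last (1-based index
#'   span) and dominant (component index in 1..K).
#' @exportClass AdmixLayout
setClass("AdmixLayout",
  representation(population = "character", individual = "character",
                 proportions = "matrix", groups = "data.frame"),
  validity = function(object) {
    g <- object@groups
    need <- c("population", "first", "last", "dominant")
    if (!all(need %in% names(g)))
      return(paste("groups must have columns", paste(need, collapse = ", ")))
    msg <- character()
    for (i in seq_len(nrow(g))) {
      idx <- seq(g$first[i], g$last[i])
      if (any(object@population[idx] != g$population[i]))
        msg <- c(msg, "group members must be contiguous")
      vals <- object@proportions[idx, g$dominant[i]]
      if (is.unsorted(vals))
        msg <- c(msg, "within-group order must be ascending in the dominant component")
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' ManhattanLayout: cumulative genomic coordinates for a Manhattan plot
#'
#' @slot points data.frame with chrom, bp, x (cumulative coordinate),
#'   y (plotted statistic) and colorIndex (0-based, cycling).
#' @slot chromInfo data.frame with chrom, offset, span and tick
#'   (tick = offset + span / 2); chromosomes occupy disjoint x ranges.
#' @exportClass ManhattanLayout
setClass("ManhattanLayout",
  representation(points = "data.frame", chromInfo = "data.frame"),
  validity = function(object) {
    ci <- object@chromInfo
    need <- c("chrom", "offset", "span", "tick")
    if (!all(need %in% names(ci)))
      return(paste("chromInfo must have columns", paste(need, collapse = ", ")))
    if (nrow(ci) > 1 && any(diff(ci$offset) < ci$span[-nrow(ci)]))
      return("chromosome x ranges must be disjoint and ordered")
    TRUE
  })
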