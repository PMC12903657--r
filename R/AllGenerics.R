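#' @import methods
NULL

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("isOK", function(x) standardGeneric("isOK"))
#' @rdname accessors
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("popIds", function(x) standardGeneric("popIds"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("chromInfo", function(x) standardGeneric("chromInfo"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Validate a loaded dataset
#'
#' Runs the systematic input checks (structure, dimensional consistency,
#' missing values, label matching) against a loaded object and reports
#' every violation instead of throwing.
#'
#' @param x a loaded domain object.
#' @param ... method-specific arguments; most methods accept `index`, a
#'   [GenomeIndex()] to cross-check chromosome identifiers against.
#' @return A [ValidationReport-class] whose `ok` is TRUE iff no
#'   error-severity issue was found.
#' @export
setGeneric("validateInput", function(x, ...) standardGeneric("validateInput"))
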