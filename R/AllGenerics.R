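#' Accessor generics
#'
#' Small accessor family for the package's S4 result and data classes:
#' \code{pValue} returns a permutation or analytic p-value, \code{nullSample}
#' the stored permutation null draws, \code{locusName} the locus label,
#' \code{analyzedSites} the logical site mask, \code{alignedSequences} the
#' underlying \link[Biostrings]{DNAStringSet}, \code{populations} the
#' sequence-to-population map and \code{groups} the population-to-group map.
#'
#' @param x an object of one of the package's S4 classes.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases pValue nullSample locusName analyzedSites alignedSequences
#'   populations groups
NULL

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("nullSample", function(x) standardGeneric("nullSample"))

#' @rdname accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname accessors
#' @export
setGeneric("analyzedSites", function(x) standardGeneric("analyzedSites"))

#' @rdname accessors
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
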