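#' Accessors for package classes
#'
#' \code{gcContent} returns the per-unigene GC fraction, \code{sampleOf} the
#' sample labels, and \code{unigeneSequences} the underlying
#' \code{DNAStringSet}.
#'
#' @param x An object.
#' @param ... Further arguments for methods.
#' @return See the method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gcContent", function(x, ...) standardGeneric("gcContent"))

#' @rdname accessors
#' @export
setGeneric("sampleOf", function(x) standardGeneric("sampleOf"))

#' @rdname accessors
#' @export
setGeneric("unigeneSequences", function(x) standardGeneric("unigeneSequences"))

#' Percentage-of-total arithmetic on a taxon count table
#'
#' @param x A \linkS4class{TaxonCountTable}.
#' @param group Row label of the taxon group.
#' @param sample Sample label.
#' @param fraction \code{"rRNA"} or \code{"mRNA"}.
#' @param ... Further arguments for methods (\code{formatted}, `taxonomy`).
#' @export
setGeneric("percentOfTotal",
           function(x, group, sample, fraction, ...)
             standardGeneric("percentOfTotal"))
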