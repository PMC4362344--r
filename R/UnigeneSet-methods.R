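#' @describeIn UnigeneSet-class Number of unigenes.
#' @param x,object A \code{UnigeneSet}.
#' @export
setMethod("length", "UnigeneSet", function(x) length(x@sequences))

#' @describeIn UnigeneSet-class Unigene identifiers.
#' @export
setMethod("names", "UnigeneSet", function(x) names(x@sequences))

#' @describeIn UnigeneSet-class Sequence lengths in bp.
#' @export
setMethod("width", "UnigeneSet", function(x) Biostrings::width(x@sequences))

#' @describeIn UnigeneSet-class Underlying \code{DNAStringSet}.
#' @export
setMethod("unigeneSequences", "UnigeneSet", function(x) x@sequences)

#' @describeIn UnigeneSet-class Sample label per unigene.
#' @export
setMethod("sampleOf", "UnigeneSet", function(x) {
  stats::setNames(x@sample, names(x@sequences))
})

#' @describeIn UnigeneSet-class Subset by index, id or logical mask.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "UnigeneSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  methods::new("UnigeneSet", sequences = x@sequences[i],
               sample = x@sample[if (is.logical(i)) which(i) else i])
})

#' @describeIn UnigeneSet-class Per-unigene GC fraction: (G + C + S) over the
#'   full length; ambiguity codes other than S count only in the denominator.
#' @export
setMethod("gcContent", "UnigeneSet", function(x, ...) {
  freq <- Biostrings::letterFrequency(x@sequences, letters = c("G", "C", "S"))
  stats::setNames(rowSums(freq) / Biostrings::width(x@sequences),
                  names(x@sequences))
})

setMethod("show", "UnigeneSet", function(object) {
  n <- length(object)
  cat("UnigeneSet with", n, "unigene(s)\n")
  if (n) {
    tab <- table(object@sample, useNA = "ifany")
    cat("  samples:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  length: %d-%d bp, median %.0f\n",
                min(w), max(w), stats::median(w)))
  }
  invisible(object)
})

#' Combine unigene sets
#'
#' @param x,... \code{UnigeneSet} objects.
#' @return A single \code{UnigeneSet}.
#' @export
setMethod("c", "UnigeneSet", function(x, ...) {
  args <- c(list(x), list(...))
  methods::new("UnigeneSet",
               sequences = do.call(c, lapply(args, function(u) u@sequences)),
               sample = unlist(lapply(args, function(u) u@sample),
                               use.names = FALSE))
})
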