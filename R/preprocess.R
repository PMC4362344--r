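#' Length filter
#'
#' Removes unigenes shorter than \code{min_len}; a sequence of exactly
#' \code{min_len} bp is kept.
#'
#' @param unigenes A \linkS4class{UnigeneSet}.
#' @param min_len Minimum length in bp (default 200).
#' @return A list with elements \code{kept} and \code{removed}, both
#'   \code{UnigeneSet}s, partitioning the input.
#' @export
lengthFilter <- function(unigenes, min_len = 200L) {
  stopifnot(min_len >= 1)
  keep <- width(unigenes) >= min_len
  list(kept = unigenes[keep], removed = unigenes[!keep])
}

# Longest qualifying tail run: suffix of >= min_run bases that starts and
# ends with the run base and carries at most 1 other base per 10 positions.
.tailRun <- function(chars, base, min_run) {
  n <- length(chars)
  if (n < min_run) return(0L)
  isb <- rev(chars) == base          # from the end inward
  if (!isb[1]) return(0L)
  mism <- cumsum(!isb)
  L <- seq_len(n)
  ok <- isb & (mism <= L %/% 10) & L >= min_run
  if (!any(ok)) return(0L)
  max(L[ok])
}

.trimPolyAOne <- function(seq, min_run) {
  repeat {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    tail_len <- .tailRun(chars, "A", min_run)
    head_len <- .tailRun(rev(chars), "T", min_run)
    if (tail_len == 0L && head_len == 0L) return(seq)
    if (head_len + tail_len >= length(chars)) return("")
    seq <- substr(seq, head_len + 1L, length(chars) - tail_len)
  }
}

#' Trim poly-A tails and poly-T heads
#'
#' Removes a trailing adenine run of at least \code{min_run} nt, tolerating
#' one non-A base per 10 nt of run as long as the run begins and ends with A
#' (so a qualifying tail never consumes the transcript base that precedes
#' it). Leading thymine runs -- the reverse-strand appearance of a poly-A
#' tail under poly-T-primed cDNA synthesis -- are trimmed symmetrically. The
#' rule is applied to a fixed point, which makes it idempotent.
#'
#' @param x A \code{UnigeneSet} or character vector.
#' @param min_run Minimum run length to trigger trimming (default 10 nt).
#' @return Object of the same type with trimmed sequences. Unigenes trimmed
#'   to length zero are dropped from a \code{UnigeneSet}.
#' @examples
#' trimPolyA(paste0("ACGT", strrep("A", 15)))
#' @export
trimPolyA <- function(x, min_run = 10L) {
  if (methods::is(x, "UnigeneSet")) {
    seqs <- vapply(as.character(x@sequences), .trimPolyAOne, "",
                   min_run = min_run, USE.NAMES = FALSE)
    keep <- nzchar(seqs)
    return(methods::new("UnigeneSet",
      sequences = Biostrings::DNAStringSet(
        stats::setNames(seqs[keep], names(x@sequences)[keep])),
      sample = x@sample[keep]))
  }
  vapply(x, .trimPolyAOne, "", min_run = min_run)
}

#' Trim exact adapter matches
#'
#' Removes user-supplied adapter strings by exact prefix/suffix match only
#' (each adapter is also checked as its reverse complement); no fuzzy or
#' internal adapter search is attempted.
#'
#' @param x A \code{UnigeneSet} or character vector.
#' @param adapters Character vector of adapter sequences.
#' @return Object of the same type with adapters removed. Unigenes trimmed
#'   to length zero are dropped from a \code{UnigeneSet}.
#' @export
trimAdapters <- function(x, adapters) {
  adapters <- unique(c(adapters, vapply(adapters, .revComp, "")))
  one <- function(seq) {
    repeat {
      hit <- FALSE
      for (ad in adapters) {
        if (startsWith(seq, ad)) {
          seq <- substr(seq, nchar(ad) + 1L, nchar(seq)); hit <- TRUE
        }
        if (nzchar(seq) && endsWith(seq, ad)) {
          seq <- substr(seq, 1L, nchar(seq) - nchar(ad)); hit <- TRUE
        }
      }
      if (!hit || !nzchar(seq)) return(seq)
    }
  }
  if (methods::is(x, "UnigeneSet")) {
    seqs <- vapply(as.character(x@sequences), one, "", USE.NAMES = FALSE)
    keep <- nzchar(seqs)
    return(methods::new("UnigeneSet",
      sequences = Biostrings::DNAStringSet(
        stats::setNames(seqs[keep], names(x@sequences)[keep])),
      sample = x@sample[keep]))
  }
  vapply(x, one, "")
}

#' Per-sample summary statistics
#'
#' Computes, per sample, the unigene count, total bp, mean and median
#' length, and overall GC percentage (total G+C+S over total bp).
#'
#' @param unigenes A non-empty \code{UnigeneSet}.
#' @return A data.frame with one row per sample and columns \code{sample},
#'   \code{n}, \code{total_bp}, \code{mean_length}, \code{median_length},
#'   \code{gc_percent}.
#' @export
sampleStats <- function(unigenes) {
  if (!length(unigenes)) stop("empty unigene set")
  w <- width(unigenes)
  gc_counts <- rowSums(Biostrings::letterFrequency(
    unigenes@sequences, letters = c("G", "C", "S")))
  by_sample <- split(seq_along(w), unigenes@sample)
  rows <- lapply(names(by_sample), function(s) {
    i <- by_sample[[s]]
    data.frame(sample = s, n = length(i), total_bp = sum(w[i]),
               mean_length = mean(w[i]),
               median_length = stats::median(w[i]),
               gc_percent = 100 * sum(gc_counts[i]) / sum(w[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
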