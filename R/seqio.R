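#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importFrom Biostrings width DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet letterFrequency reverseComplement
#'   translate subseq
NULL

#' Read unigenes from a FASTA file
#'
#' Wraps \code{\link[Biostrings]{readDNAStringSet}} and enforces the
#' contracts the pipeline relies on: identifiers (first word of the
#' description line) are unique and no record is empty. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @param sample Sample label attached to every record.
#' @return A \linkS4class{UnigeneSet}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC", "GT"), f)
#' readFasta(f, sample = "S1")
#' @export
readFasta <- function(path, sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("record(s) with empty identifier in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  empty <- ids[Biostrings::width(seqs) == 0L]
  if (length(empty))
    stop("empty sequence record(s): ", paste(empty, collapse = ", "))
  names(seqs) <- ids
  UnigeneSet(seqs, sample = sample)
}

#' Write sequences to FASTA
#'
#' @param x A \code{UnigeneSet}, \code{XStringSet} or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (methods::is(x, "UnigeneSet")) x <- x@sequences
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                  "s_end", "evalue", "bitscore", "subject_description",
                  "subject_taxon")
.HIT_NUMERIC <- c("pct_identity", "aln_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end", "evalue",
                  "bitscore")

#' Read a similarity-hit table
#'
#' Reads the 13-column blast-tabular dialect used throughout the package
#' (the 12 standard columns plus a subject description), optionally with a
#' 14th subject-taxon column. Lines starting with \code{#} are skipped.
#' Coordinates are 1-based inclusive on the wire.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_length}, \code{mismatches},
#'   \code{gap_opens}, \code{q_start}, \code{q_end}, \code{s_start},
#'   \code{s_end}, \code{evalue}, \code{bitscore},
#'   \code{subject_description}, \code{subject_taxon}. An empty file yields
#'   a zero-row data.frame.
#' @export
readHits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(emptyHits())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf != 13L & nf != 14L
  if (any(bad))
    stop("expected 13 or 14 tab-separated columns at line ",
         lineno[which(bad)[1]], " (found ", nf[which(bad)[1]], ")")
  fields <- lapply(fields, function(f) c(f, rep(NA_character_, 14L - length(f))))
  m <- do.call(rbind, fields)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .HIT_COLUMNS
  for (col in .HIT_NUMERIC) out[[col]] <- as.numeric(out[[col]])
  out$subject_taxon[is.na(out$subject_taxon)] <- ""
  out
}

#' @rdname readHits
#' @return \code{emptyHits} returns the zero-row hit table template.
#' @export
emptyHits <- function() {
  cols <- c(rep(list(character(0)), 2), rep(list(numeric(0)), 10),
            rep(list(character(0)), 2))
  names(cols) <- .HIT_COLUMNS
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write a similarity-hit table
#'
#' Inverse of \code{\link{readHits}}; all 14 columns are written, so a
#' read/write round trip preserves every field.
#'
#' @param hits A hit data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxonomy parent map
#'
#' Expects a 2- or 3-column TSV (node, parent, optional rank); the root is
#' the node listed as its own parent.
#'
#' @param path Path to a TSV file.
#' @return A \linkS4class{TaxonomyMap}.
#' @export
readTaxonomyMap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(tab) < 2L) stop("taxonomy table needs node and parent columns")
  parent <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  rank <- if (ncol(tab) >= 3L)
    stats::setNames(as.character(tab[[3]]), as.character(tab[[1]]))
  else character(0)
  taxonomyMap(parent, rank)
}

#' GC fraction of a sequence
#'
#' Counts G, C and the ambiguity code S (G or C); every other position,
#' including other ambiguity codes, contributes to the denominator only.
#'
#' @param seq A character vector of nucleotide sequences.
#' @return Numeric vector of fractions in [0, 1].
#' @examples
#' gcFraction(c("GCGC", "ATAT", "ACGT"))
#' @export
gcFraction <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  s <- Biostrings::DNAStringSet(seq)
  counts <- Biostrings::letterFrequency(s, letters = c("G", "C", "S"))
  out <- rowSums(counts) / Biostrings::width(s)
  names(out) <- names(seq)
  out
}
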