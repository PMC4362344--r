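.RRNA_KEYWORDS <- c("5.8S", "16S", "18S", "23S", "26S", "28S", "ITS",
                    "rRNA", "rDNA", "ribosomal DNA", "ribosomal RNA",
                    "LSU", "SSU")
.CASE_SENSITIVE_TOKENS <- c("ITS", "LSU", "SSU")

#' Ribosomal-keyword partition rule
#'
#' The rule used to call a unigene ribosomal: its hit description must
#' contain at least one keyword of the 13-phrase ribosomal vocabulary, with
#' identity strictly above \code{min_identity} percent and alignment length
#' strictly above \code{min_aln_length} bp. \code{"ITS"}, \code{"LSU"} and
#' \code{"SSU"} match case-sensitively as whole tokens (delimited by
#' non-alphanumerics) so that words like "its" or "sites" never fire; all
#' other phrases match as case-insensitive substrings.
#'
#' @param keywords Character vector of phrases.
#' @param min_identity Identity threshold in percent (strict \code{>}).
#' @param min_aln_length Alignment-length threshold in bp (strict \code{>}).
#' @param strict Use strict inequalities (default) or \code{>=}.
#' @return A list with class \code{"PartitionRule"}.
#' @export
partitionRule <- function(keywords = .RRNA_KEYWORDS, min_identity = 80,
                          min_aln_length = 100, strict = TRUE) {
  stopifnot(length(keywords) > 0, min_identity > 0, min_aln_length > 0)
  structure(list(keywords = keywords, min_identity = min_identity,
                 min_aln_length = min_aln_length, strict = strict),
            class = "PartitionRule")
}

#' Match a description line against the ribosomal keyword list
#'
#' @param desc Character vector of description lines.
#' @param keywords Keyword phrases (see \code{\link{partitionRule}}).
#' @return Logical vector.
#' @export
matchesRrnaKeyword <- function(desc, keywords = .RRNA_KEYWORDS) {
  out <- rep(FALSE, length(desc))
  for (kw in keywords) {
    if (kw %in% .CASE_SENSITIVE_TOKENS) {
      pat <- paste0("(^|[^A-Za-z0-9])", kw, "([^A-Za-z0-9]|$)")
      out <- out | grepl(pat, desc)
    } else {
      # literal, case-insensitive substring match ("5.8S" must not behave
      # as a regular expression)
      out <- out | grepl(toupper(kw), toupper(desc), fixed = TRUE)
    }
  }
  out
}

#' Is a hit a ribosomal hit?
#'
#' @param hits A hit data.frame (see \code{\link{readHits}}).
#' @param rule A \code{\link{partitionRule}}.
#' @return Logical vector, one entry per hit row.
#' @export
isRrnaHit <- function(hits, rule = partitionRule()) {
  if (!nrow(hits)) return(logical(0))
  kw <- matchesRrnaKeyword(hits$subject_description, rule$keywords)
  if (rule$strict) {
    kw & hits$pct_identity > rule$min_identity &
      hits$aln_length > rule$min_aln_length
  } else {
    kw & hits$pct_identity >= rule$min_identity &
      hits$aln_length >= rule$min_aln_length
  }
}

#' Partition unigenes into rRNA and putative mRNA
#'
#' A unigene is labelled \code{rRNA} when at least one of its hits satisfies
#' the partition rule; all remaining unigenes -- including those with no
#' hits at all -- are labelled \code{mRNA} (putative messenger RNA). Hits
#' whose query is not in the unigene set are dropped with a warning.
#'
#' @param unigenes A \linkS4class{UnigeneSet}.
#' @param hits Hit data.frame.
#' @param rule A \code{\link{partitionRule}}.
#' @return A \linkS4class{PartitionResult}.
#' @export
partitionUnigenes <- function(unigenes, hits, rule = partitionRule()) {
  ids <- names(unigenes)
  unknown <- setdiff(unique(hits$query_id), ids)
  if (length(unknown)) {
    warning("ignoring hit(s) with unknown query id: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    hits <- hits[hits$query_id %in% ids, , drop = FALSE]
  }
  qualifying <- hits[isRrnaHit(hits, rule), , drop = FALSE]
  # deterministic triggering hit: best score then subject id
  if (nrow(qualifying)) {
    qualifying <- qualifying[order(qualifying$query_id,
                                   -qualifying$bitscore,
                                   qualifying$subject_id), , drop = FALSE]
    trigger <- qualifying[!duplicated(qualifying$query_id), , drop = FALSE]
    trig_map <- stats::setNames(trigger$subject_id, trigger$query_id)
  } else {
    trig_map <- character(0)
  }
  label <- ifelse(ids %in% names(trig_map), "rRNA", "mRNA")
  labels <- data.frame(
    id = ids, sample = unname(sampleOf(unigenes)), label = label,
    trigger_subject = ifelse(label == "rRNA", trig_map[ids], NA_character_),
    stringsAsFactors = FALSE)
  tab <- table(labels$sample, factor(labels$label, c("rRNA", "mRNA")))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  methods::new("PartitionResult", labels = labels, counts = counts)
}

#' @describeIn PartitionResult-class Extract one fraction as a
#'   \code{UnigeneSet}.
#' @param result A \code{PartitionResult}.
#' @param unigenes The unigene set the partition was computed from.
#' @param fraction \code{"rRNA"} or \code{"mRNA"}.
#' @export
partitionFraction <- function(result, unigenes, fraction = c("mRNA", "rRNA")) {
  fraction <- match.arg(fraction)
  ids <- result@labels$id[result@labels$label == fraction]
  unigenes[names(unigenes) %in% ids]
}

setMethod("show", "PartitionResult", function(object) {
  cat("PartitionResult:", sum(object@labels$label == "rRNA"), "rRNA /",
      sum(object@labels$label == "mRNA"), "mRNA unigene(s)\n")
  print(object@counts)
  invisible(object)
})
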