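#' Scoring scheme for pairwise alignment
#'
#' Bundles the substitution scores and affine gap penalties used by the
#' built-in local/global aligners. A gap of length L costs
#' \code{gap_open + L * gap_extend}.
#'
#' @slot mode \code{"nucleotide"} or \code{"protein"}.
#' @slot matrix Substitution matrix (alphabet x alphabet).
#' @slot alphabet Residue alphabet indexing the matrix.
#' @slot gapOpen,gapExtend Gap penalty magnitudes.
#' @aliases ScoringScheme
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(mode = "character", matrix = "matrix",
                 alphabet = "character", gapOpen = "numeric",
                 gapExtend = "numeric"))

setValidity("ScoringScheme", function(object) {
  if (!object@mode %in% c("nucleotide", "protein"))
    return("mode must be 'nucleotide' or 'protein'")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap penalties are magnitudes and must be >= 0")
  if (!isSymmetric(unname(object@matrix)))
    return("substitution matrix must be symmetric")
  TRUE
})

#' Create a scoring scheme
#'
#' Defaults follow common practice for short-read homology searches:
#' nucleotide match +2 / mismatch -3 with gap open 5 / extend 2, and
#' BLOSUM62 with gap open 10 / extend 1 for proteins.
#'
#' @param mode \code{"nucleotide"} or \code{"protein"}.
#' @param match,mismatch Nucleotide scores (nucleotide mode only).
#' @param matrix Protein substitution matrix name; only \code{"BLOSUM62"}
#'   is shipped.
#' @param gap_open,gap_extend Gap penalties (magnitudes); mode-specific
#'   defaults when \code{NULL}.
#' @return A \linkS4class{ScoringScheme}.
#' @export
scoringScheme <- function(mode = c("nucleotide", "protein"), match = 2,
                          mismatch = -3, matrix = "BLOSUM62",
                          gap_open = NULL, gap_extend = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    S <- .ntMatrix(match, mismatch)
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
  } else {
    if (!identical(matrix, "BLOSUM62"))
      stop("unknown substitution matrix: ", matrix)
    S <- .blosum62()
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 1
  }
  methods::new("ScoringScheme", mode = mode, matrix = S,
               alphabet = rownames(S), gapOpen = gap_open,
               gapExtend = gap_extend)
}

.alnStrings <- function(a_chars, b_chars, a_idx, b_idx) {
  qa <- ifelse(a_idx > 0, a_chars[pmax(a_idx, 1)], "-")
  sa <- ifelse(b_idx > 0, b_chars[pmax(b_idx, 1)], "-")
  c(query = paste(qa, collapse = ""), subject = paste(sa, collapse = ""))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param query,subject Sequences (single characters strings) over the
#'   alphabet of \code{scheme}.
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return A list with \code{score}, \code{alignment} (gapped query/subject
#'   strings; empty when no cell scores positively), \code{pct_identity}
#'   (100 x identical columns / alignment length), \code{aln_length},
#'   \code{nmatch} and the 1-based inclusive endpoints \code{q_start},
#'   \code{q_end}, \code{s_start}, \code{s_end} (0 for an empty alignment).
#' @examples
#' sw <- smithWaterman("ACGT", "ACGT",
#'                     scoringScheme("nucleotide", match = 1, mismatch = -1,
#'                                   gap_open = 0, gap_extend = 1))
#' sw$score
#' @export
smithWaterman <- function(query, subject, scheme = scoringScheme("protein")) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  a <- .encode(query, scheme@alphabet)
  b <- .encode(subject, scheme@alphabet)
  r <- .sw_align(a, b, scheme@matrix, scheme@gapOpen, scheme@gapExtend)
  aln <- .alnStrings(strsplit(toupper(query), "")[[1]],
                     strsplit(toupper(subject), "")[[1]],
                     r$a_idx, r$b_idx)
  if (r$aln_length == 0L) aln <- c(query = "", subject = "")
  list(score = r$score, alignment = aln,
       pct_identity = if (r$aln_length) 100 * r$nmatch / r$aln_length else 0,
       aln_length = r$aln_length, nmatch = r$nmatch,
       q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end)
}

#' Optimal global alignment with deterministic identity
#'
#' Needleman-Wunsch with affine gaps; among all score-optimal alignments the
#' one with the largest number of identical columns defines the reported
#' match count, so identity is a well-defined function of the inputs.
#'
#' @inheritParams smithWaterman
#' @return A list with \code{score}, \code{nmatch}, \code{aln_length} and
#'   \code{alignment} (gapped strings).
#' @export
globalAlign <- function(query, subject, scheme = scoringScheme("protein")) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  a <- .encode(query, scheme@alphabet)
  b <- .encode(subject, scheme@alphabet)
  r <- .nw_align(a, b, scheme@matrix, scheme@gapOpen, scheme@gapExtend)
  aln <- .alnStrings(strsplit(toupper(query), "")[[1]],
                     strsplit(toupper(subject), "")[[1]],
                     r$a_idx, r$b_idx)
  list(score = r$score, nmatch = r$nmatch, aln_length = r$aln_length,
       alignment = aln, a_idx = r$a_idx, b_idx = r$b_idx)
}

# global identity with the shorter sequence as denominator (CD-HIT
# convention); encoded inputs
.globalIdentity <- function(a, b, S, go, ge) {
  st <- .nw_stats(a, b, S, go, ge)
  st[["nmatch"]] / min(length(a), length(b))
}

# Batched six-frame translation: one Biostrings call per frame for a whole
# set. Returns a list of 6 named character vectors ("+1".."-3").
.sixFrameSet <- function(dss) {
  if (!methods::is(dss, "DNAStringSet")) dss <- Biostrings::DNAStringSet(dss)
  rc <- Biostrings::reverseComplement(dss)
  out <- list()
  for (k in 1:3) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") dss else rc
      w <- Biostrings::width(s)
      len <- pmax((w - (k - 1L)) %/% 3L * 3L, 0L)
      sub <- Biostrings::subseq(s, start = pmin(k, w + 1L), width = len)
      pep <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      out[[paste0(strand, k)]] <- stats::setNames(pep, names(dss))
    }
  }
  out[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1..+3 read the forward strand with offsets 0..2; frame -k reads
#' the reverse complement with offset k-1. Translation uses the standard
#' genetic code; stop codons are rendered \code{*} and ambiguous codons
#' \code{X}.
#'
#' @param seq A nucleotide sequence (character).
#' @return Named character vector of 6 peptides, names \code{"+1"},
#'   \code{"+2"}, \code{"+3"}, \code{"-1"}, \code{"-2"}, \code{"-3"}.
#' @examples
#' sixFrameTranslate("ATGGCC")[["+1"]]
#' @export
sixFrameTranslate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  vapply(.sixFrameSet(Biostrings::DNAStringSet(stats::setNames(seq, "q"))),
         `[[`, "", 1L)
}

#' Split a frame peptide into ORF segments
#'
#' Splits at stop codons (\code{*}) and keeps segments of at least
#' \code{min_len} residues, mimicking the segment behaviour of a translated
#' similarity search.
#'
#' @param peptide A peptide string possibly containing \code{*}.
#' @param min_len Minimum segment length in aa (default 20).
#' @return data.frame with columns \code{start} (1-based aa offset in the
#'   frame peptide), \code{end} and \code{seq}.
#' @export
orfSegments <- function(peptide, min_len = 20L) {
  if (!nzchar(peptide))
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  starts <- cumsum(c(1L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= min_len
  data.frame(start = starts[keep], end = starts[keep] + nchar(parts[keep]) - 1L,
             seq = parts[keep], stringsAsFactors = FALSE)
}

.refDescriptions <- function(refs) {
  full <- names(refs)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  list(ids = ids, desc = desc)
}

#' Similarity search against a reference set
#'
#' Desk-scale stand-in for an external similarity search. In nucleotide mode
#' each query is aligned locally against every reference on both strands; in
#' protein mode the six reading frames of each query are split into ORF
#' segments (>= \code{min_orf} aa, alignments never cross a stop) and
#' aligned against every reference peptide, recording the frame in the hit.
#' All hits scoring at least \code{min_score} are returned, the best hit per
#' (query, subject, frame); ties are broken by subject identifier.
#'
#' @param queries A \code{UnigeneSet} or named character vector of
#'   nucleotide sequences.
#' @param references Reference set: \code{DNAStringSet} (nucleotide mode) or
#'   \code{AAStringSet} (protein mode); name format \code{"id description"}.
#' @param scheme A \linkS4class{ScoringScheme}; its mode selects the search
#'   mode.
#' @param min_score Raw-score threshold; defaults to 40 (nucleotide) or 50
#'   (protein).
#' @param ref_taxa Optional named character vector mapping subject id to
#'   taxon label, filled into \code{subject_taxon}.
#' @param min_orf Minimum ORF segment length for protein mode.
#' @return Hit data.frame in the 14-column dialect of \code{\link{readHits}}
#'   plus a \code{frame} column (0 for plus-strand nucleotide hits, -1 for
#'   minus-strand). Protein-mode \code{q_start}/\code{q_end} are 1-based aa
#'   positions in the frame peptide.
#' @export
searchHomology <- function(queries, references,
                           scheme = scoringScheme("nucleotide"),
                           min_score = NULL, ref_taxa = NULL,
                           min_orf = 20L) {
  if (!length(references)) stop("empty reference set")
  if (methods::is(queries, "UnigeneSet"))
    queries <- stats::setNames(as.character(queries@sequences),
                               names(queries@sequences))
  if (is.null(min_score))
    min_score <- if (scheme@mode == "nucleotide") 40 else 50
  rd <- .refDescriptions(references)
  refs <- stats::setNames(as.character(references), rd$ids)
  refenc <- lapply(refs, .encode, alphabet = scheme@alphabet)
  frames_all <- if (scheme@mode == "protein")
    .sixFrameSet(Biostrings::DNAStringSet(queries)) else NULL
  rows <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qseq <- queries[[qi]]
    if (scheme@mode == "nucleotide") {
      cand <- list(`0` = qseq, `-1` = .revComp(qseq))
      for (str in names(cand)) {
        qenc <- .encode(cand[[str]], scheme@alphabet)
        for (ri in seq_along(refenc)) {
          if (.sw_score(qenc, refenc[[ri]], scheme@matrix, scheme@gapOpen,
                        scheme@gapExtend) < min_score) next
          r <- .sw_align(qenc, refenc[[ri]], scheme@matrix, scheme@gapOpen,
                         scheme@gapExtend)
          if (r$score >= min_score)
            rows[[length(rows) + 1L]] <- data.frame(
              query_id = qid, subject_id = rd$ids[ri], frame = as.integer(str),
              score = r$score, nmatch = r$nmatch, aln_length = r$aln_length,
              q_start = r$q_start, q_end = r$q_end, s_start = r$s_start,
              s_end = r$s_end, gaps = sum(r$a_idx == 0L) + sum(r$b_idx == 0L),
              gap_opens = sum(diff(c(FALSE, r$a_idx == 0L)) == 1L) +
                sum(diff(c(FALSE, r$b_idx == 0L)) == 1L),
              stringsAsFactors = FALSE)
        }
      }
    } else {
      if (nchar(qseq) < 3L) next
      for (fr in names(frames_all)) {
        segs <- orfSegments(frames_all[[fr]][[qi]], min_len = min_orf)
        if (!nrow(segs)) next
        for (si in seq_len(nrow(segs))) {
          qenc <- .encode(segs$seq[si], scheme@alphabet)
          for (ri in seq_along(refenc)) {
            if (.sw_score(qenc, refenc[[ri]], scheme@matrix, scheme@gapOpen,
                          scheme@gapExtend) < min_score) next
            r <- .sw_align(qenc, refenc[[ri]], scheme@matrix, scheme@gapOpen,
                           scheme@gapExtend)
            if (r$score >= min_score)
              rows[[length(rows) + 1L]] <- data.frame(
                query_id = qid, subject_id = rd$ids[ri],
                frame = as.integer(fr), score = r$score, nmatch = r$nmatch,
                aln_length = r$aln_length,
                q_start = segs$start[si] + r$q_start - 1L,
                q_end = segs$start[si] + r$q_end - 1L,
                s_start = r$s_start, s_end = r$s_end,
                gaps = sum(r$a_idx == 0L) + sum(r$b_idx == 0L),
                gap_opens = sum(diff(c(FALSE, r$a_idx == 0L)) == 1L) +
                  sum(diff(c(FALSE, r$b_idx == 0L)) == 1L),
                stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    out <- emptyHits()
    out$frame <- integer(0)
    return(out)
  }
  h <- do.call(rbind, rows)
  # best hit per (query, subject, frame)
  key <- paste(h$query_id, h$subject_id, h$frame)
  h <- h[order(key, -h$score), , drop = FALSE]
  h <- h[!duplicated(paste(h$query_id, h$subject_id, h$frame)), , drop = FALSE]
  desc <- stats::setNames(rd$desc, rd$ids)
  out <- data.frame(
    query_id = h$query_id, subject_id = h$subject_id,
    pct_identity = 100 * h$nmatch / pmax(h$aln_length, 1L),
    aln_length = h$aln_length,
    mismatches = h$aln_length - h$nmatch - h$gaps,
    gap_opens = h$gap_opens, q_start = h$q_start, q_end = h$q_end,
    s_start = h$s_start, s_end = h$s_end, evalue = NA_real_,
    bitscore = h$score,
    subject_description = unname(desc[h$subject_id]),
    subject_taxon = if (is.null(ref_taxa)) ""
                    else unname(ref_taxa[h$subject_id]),
    frame = h$frame, stringsAsFactors = FALSE)
  out$subject_taxon[is.na(out$subject_taxon)] <- ""
  out <- out[order(out$query_id, -out$bitscore, out$subject_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
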