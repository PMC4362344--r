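#' C-type lectin domain grammar constructor
#'
#' The operational CTLD definition used throughout the package: four
#' conserved cysteines whose consecutive spacings fall inside
#' \code{cys_gap_bounds}, a WIGL-like 4-mer (W, then I/L/V, then G, then
#' I/L/V/F) between the first and third cysteine, and a 3-residue
#' sugar-binding motif position between the second and fourth cysteine
#' (EPN = glucose/mannose binding, LND = galactose binding; anything else
#' is recorded as a variant).
#'
#' @param cys_gap_bounds 3 x 2 matrix (or length-6 vector) of min/max
#'   residues between consecutive conserved cysteines.
#' @param wigl_pattern List of 4 character vectors of allowed residues.
#' @return A \linkS4class{CTLDGrammar}.
#' @export
ctldGrammar <- function(cys_gap_bounds = rbind(c(5, 60), c(20, 90), c(5, 40)),
                        wigl_pattern = list("W", c("I", "L", "V"), "G",
                                            c("I", "L", "V", "F"))) {
  b <- matrix(as.numeric(cys_gap_bounds), nrow = 3)
  methods::new("CTLDGrammar", nCys = 4L, cysGapBounds = b,
               wiglPattern = wigl_pattern,
               sugarClasses = c(EPN = "glucose/mannose", LND = "galactose"))
}

setMethod("show", "CTLDGrammar", function(object) {
  b <- object@cysGapBounds
  cat("CTLDGrammar: 4 cysteines, gaps",
      paste(sprintf("[%g,%g]", b[, 1], b[, 2]), collapse = " "),
      "\n  WIGL-like:",
      paste(vapply(object@wiglPattern, paste, "", collapse = "/"),
            collapse = "-"), "\n")
  invisible(object)
})

#' Does a 4-mer satisfy the WIGL-like pattern?
#'
#' @param x Character vector of 4-mers.
#' @param grammar A \linkS4class{CTLDGrammar}.
#' @return Logical vector.
#' @export
matchesWiglPattern <- function(x, grammar = ctldGrammar()) {
  vapply(x, function(s) {
    if (nchar(s) != 4L) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    all(vapply(1:4, function(i) ch[i] %in% grammar@wiglPattern[[i]], TRUE))
  }, TRUE, USE.NAMES = FALSE)
}

# All WIGL-pattern match start positions strictly inside (from, to)
# 0-based positions in `chars`
.wiglMatches <- function(chars, grammar) {
  n <- length(chars)
  if (n < 4L) return(integer(0))
  ok <- rep(TRUE, n - 3L)
  for (i in 1:4)
    ok <- ok & chars[i:(n - 4L + i)] %in% grammar@wiglPattern[[i]]
  which(ok)
}

# Scan a single peptide for CTLD windows. Returns a data.frame of domains
# with 0-based half-open [start, end) coordinates and 0-based cysteine
# offsets, or a zero-row frame.
.scanPeptide <- function(peptide, grammar) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      cys1 = integer(0), cys2 = integer(0),
                      cys3 = integer(0), cys4 = integer(0),
                      wigl = character(0), stringsAsFactors = FALSE)
  n <- nchar(peptide)
  if (n < 4L) return(empty)
  chars <- strsplit(peptide, "")[[1]]
  cys <- which(chars == "C")             # 1-based
  stops <- which(chars == "*")
  wigl_at <- .wiglMatches(chars, grammar) # 1-based starts
  b <- grammar@cysGapBounds
  out <- list()
  from <- 1L
  repeat {
    found <- NULL
    cc <- cys[cys >= from]
    if (length(cc) < 4L) break
    # leftmost-compact enumeration of 4-subsets in lexicographic order
    for (i1 in seq_along(cc)) {
      c1 <- cc[i1]
      cand2 <- cc[cc - c1 >= b[1, 1] & cc - c1 <= b[1, 2]]
      for (c2 in cand2) {
        cand3 <- cc[cc - c2 >= b[2, 1] & cc - c2 <= b[2, 2]]
        for (c3 in cand3) {
          w_ok <- wigl_at[wigl_at > c1 & (wigl_at + 3L) < c3]
          if (!length(w_ok)) next
          cand4 <- cc[cc - c3 >= b[3, 1] & cc - c3 <= b[3, 2]]
          for (c4 in cand4) {
            if (any(stops >= c1 & stops <= c4)) next
            found <- c(c1, c2, c3, c4, w_ok[1])
            break
          }
          if (!is.null(found)) break
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    c1 <- found[1]; c4 <- found[4]; w <- found[5]
    out[[length(out) + 1L]] <- data.frame(
      start = c1 - 1L, end = c4, cys1 = found[1] - 1L, cys2 = found[2] - 1L,
      cys3 = found[3] - 1L, cys4 = found[4] - 1L,
      wigl = paste(chars[w:(w + 3L)], collapse = ""),
      stringsAsFactors = FALSE)
    from <- c4 + 1L
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

.DOMAIN_COLUMNS <- c("unigene", "sample", "frame", "start", "end",
                     "cys1", "cys2", "cys3", "cys4", "wigl", "sugar_motif",
                     "sugar_class", "domain_seq")

.emptyDomains <- function() {
  data.frame(unigene = character(0), sample = character(0),
             frame = character(0), start = integer(0), end = integer(0),
             cys1 = integer(0), cys2 = integer(0), cys3 = integer(0),
             cys4 = integer(0), wigl = character(0),
             sugar_motif = character(0), sugar_class = character(0),
             domain_seq = character(0), stringsAsFactors = FALSE)
}

#' Scan unigenes for c-type lectin domains
#'
#' Translates each unigene in six frames and returns all maximal
#' non-overlapping windows satisfying the CTLD grammar; a transcript whose
#' frame holds several qualifying windows yields several domains
#' (multi-domain splitting). When \code{seed_hits} is given (typically the
#' result of a translated similarity search against reference CTLDs) only
#' the (unigene, frame) pairs with a seed hit are scanned, mirroring the
#' pre-filter role of the similarity search; grammar-only mode (no seeds)
#' scans everything and finds a superset of the seeded domains.
#'
#' Domains are classified on the fly: the sugar-binding motif between the
#' second and fourth cysteine via \code{\link{classifySugar}}, the
#' WIGL-like 4-mer from the grammar match.
#'
#' @param unigenes A \linkS4class{UnigeneSet}.
#' @param grammar A \linkS4class{CTLDGrammar}.
#' @param seed_hits Optional hit data.frame with \code{query_id} and
#'   \code{frame} columns restricting the scan.
#' @param reference Optional reference CTLD peptide used to locate the
#'   sugar-motif column for variant domains (see \code{\link{classifySugar}});
#'   defaults to the first packaged reference domain.
#' @return data.frame with one row per domain: \code{unigene},
#'   \code{sample}, \code{frame}, 0-based half-open \code{start}/\code{end}
#'   in the frame peptide, cysteine offsets \code{cys1..cys4}, \code{wigl},
#'   \code{sugar_motif}, \code{sugar_class}, \code{domain_seq}.
#' @export
scanCtld <- function(unigenes, grammar = ctldGrammar(), seed_hits = NULL,
                     reference = NULL) {
  if (is.null(reference)) reference <- referenceCtldAnchor()
  smap <- sampleOf(unigenes)
  seqs <- as.character(unigenes@sequences)
  allowed <- NULL
  if (!is.null(seed_hits) && nrow(seed_hits)) {
    fr_lab <- ifelse(seed_hits$frame > 0, paste0("+", seed_hits$frame),
                     as.character(seed_hits$frame))
    allowed <- unique(paste(seed_hits$query_id, fr_lab))
  } else if (!is.null(seed_hits)) {
    return(.emptyDomains())
  }
  keep <- nchar(seqs) >= 3L
  frames_all <- if (any(keep))
    .sixFrameSet(Biostrings::DNAStringSet(seqs[keep])) else NULL
  out <- list()
  for (id in names(seqs)[keep]) {
    for (fr in names(frames_all)) {
      if (!is.null(allowed) && !(paste(id, fr) %in% allowed)) next
      pep <- frames_all[[fr]][[id]]
      d <- .scanPeptide(pep, grammar)
      if (!nrow(d)) next
      d$unigene <- id
      d$sample <- unname(smap[id])
      d$frame <- fr
      d$domain_seq <- substring(pep, d$start + 1L, d$end)
      sug <- lapply(seq_len(nrow(d)), function(k)
        classifySugar(d$domain_seq[k], d$cys2[k] - d$start[k],
                      d$cys4[k] - d$start[k], grammar, reference))
      d$sugar_motif <- vapply(sug, `[[`, "", "sugar_motif")
      d$sugar_class <- vapply(sug, `[[`, "", "sugar_class")
      out[[length(out) + 1L]] <- d[, .DOMAIN_COLUMNS]
    }
  }
  if (!length(out)) return(.emptyDomains())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sugar-binding motif classification
#'
#' Searches the region between the second and fourth conserved cysteine for
#' the glucose/mannose binding motif EPN, then the galactose binding motif
#' LND. When neither occurs, the 3-mer occupying the reference motif column
#' is recorded: the domain is globally aligned to a reference CTLD whose EPN
#' position is known, the reference motif columns are mapped through the
#' alignment, and the aligned residues are reported with class
#' \code{"variant"} (e.g. DSS or WSD at the EPN position, VND at the LND
#' position of natural variants).
#'
#' @param domain_seq Domain peptide (first conserved cysteine first).
#' @param cys2,cys4 0-based offsets of the second and fourth cysteine
#'   within \code{domain_seq}.
#' @param grammar A \linkS4class{CTLDGrammar}.
#' @param reference Reference CTLD peptide containing EPN.
#' @return A list with \code{sugar_motif} (3-mer or \code{""}) and
#'   \code{sugar_class} (\code{"glucose/mannose"}, \code{"galactose"} or
#'   \code{"variant"}).
#' @export
classifySugar <- function(domain_seq, cys2, cys4, grammar = ctldGrammar(),
                          reference = NULL) {
  region_start <- cys2 + 2L           # strictly between cys2 and cys4
  region_end <- cys4                  # 1-based substring bounds
  if (region_end - region_start + 1L < 3L)
    return(list(sugar_motif = "", sugar_class = "variant"))
  region <- substr(domain_seq, region_start, region_end)
  for (motif in names(grammar@sugarClasses)) {
    if (grepl(motif, region, fixed = TRUE))
      return(list(sugar_motif = motif,
                  sugar_class = unname(grammar@sugarClasses[motif])))
  }
  if (is.null(reference)) reference <- referenceCtldAnchor()
  ref_pos <- as.integer(regexpr("EPN", reference, fixed = TRUE))
  if (ref_pos < 1L)
    return(list(sugar_motif = "", sugar_class = "variant"))
  aln <- globalAlign(domain_seq, reference)
  motif_cols <- which(aln$b_idx %in% ref_pos:(ref_pos + 2L))
  res_idx <- aln$a_idx[motif_cols]
  res_idx <- res_idx[res_idx > 0L]
  motif <- paste(strsplit(domain_seq, "")[[1]][res_idx], collapse = "")
  list(sugar_motif = motif, sugar_class = "variant")
}

#' Remove redundant domains
#'
#' Greedy collapse of near-identical domains: domains are visited by
#' decreasing length (ties by unigene id), and a domain joins the first
#' retained representative with global-alignment identity at least
#' \code{identity_threshold} (identical columns over the shorter length);
#' otherwise it is retained. The retained domain of each group is its
#' longest member. Output rows are sorted by unigene id.
#'
#' @param domains Domain data.frame from \code{\link{scanCtld}}.
#' @param identity_threshold Collapse threshold (default 0.97).
#' @param scheme Scoring scheme for the global alignment.
#' @return The unique-domain subset of \code{domains}.
#' @export
dedupeDomains <- function(domains, identity_threshold = 0.97,
                          scheme = scoringScheme("protein")) {
  if (!nrow(domains)) return(domains)
  ord <- order(-nchar(domains$domain_seq), domains$unigene, domains$start)
  enc <- lapply(domains$domain_seq, .encode, alphabet = scheme@alphabet)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in kept) {
      idt <- .globalIdentity(enc[[i]], enc[[k]], scheme@matrix,
                             scheme@gapOpen, scheme@gapExtend)
      if (idt >= identity_threshold) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  out <- domains[sort(kept), , drop = FALSE]
  out <- out[order(out$unigene, out$frame, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample WIGL-like motif variants
#'
#' @param domains Domain data.frame with \code{sample} and \code{wigl}
#'   columns.
#' @return Named list sample -> sorted character vector of distinct
#'   WIGL-like 4-mers.
#' @export
wiglVariants <- function(domains) {
  if (!nrow(domains)) return(stats::setNames(list(), character(0)))
  lapply(split(domains$wigl, domains$sample), function(w) sort(unique(w)))
}

#' Packaged synthetic reference CTLD peptides
#'
#' A small set of synthetic c-type lectin domain peptides satisfying the
#' default grammar, used to seed translated similarity searches and to
#' anchor sugar-motif localization. These are constructed sequences, not
#' database entries.
#'
#' @return An \code{AAStringSet} with description lines.
#' @export
referenceCtlds <- function() {
  path <- system.file("extdata", "synthetic_ctld_refs.fasta",
                      package = "HolobiontEST")
  Biostrings::readAAStringSet(path)
}

#' @rdname referenceCtlds
#' @return \code{referenceCtldAnchor}: the anchor domain (first reference)
#'   as a plain string; its EPN motif defines the sugar-motif column.
#' @export
referenceCtldAnchor <- function() {
  as.character(referenceCtlds()[[1]])
}
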