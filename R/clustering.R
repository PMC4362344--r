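#' Greedy identity clustering (CD-HIT semantics)
#'
#' Sequences are sorted by decreasing length (ties by identifier) and
#' processed in order: each sequence joins the first existing cluster whose
#' representative aligns to it with identity at least \code{threshold},
#' otherwise it founds a new cluster. Identity is the number of identical
#' columns of the optimal global alignment divided by the length of the
#' shorter sequence; the match count is the deterministic lexicographic
#' optimum (see \code{\link{globalAlign}}).
#'
#' @param peptides Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1] (default 0.5).
#' @param sample Named character vector id -> sample label (optional).
#' @param scheme A \linkS4class{ScoringScheme} (protein default).
#' @param kmer_filter 0 to compare against every representative (exact,
#'   default); a positive k restricts comparisons to representatives
#'   sharing at least one k-mer with the candidate (speed heuristic for
#'   larger inputs).
#' @return A \linkS4class{ClusterSet}.
#' @export
greedyCluster <- function(peptides, threshold = 0.5, sample = NULL,
                          scheme = scoringScheme("protein"),
                          kmer_filter = 0L) {
  stopifnot(length(peptides) > 0, threshold > 0, threshold <= 1)
  ids <- names(peptides)
  if (is.null(ids) || anyDuplicated(ids))
    stop("peptides must carry unique names")
  ord <- order(-nchar(peptides), ids)
  enc <- lapply(peptides, .encode, alphabet = scheme@alphabet)
  reps <- integer(0)              # index (into peptides) of each rep
  members <- list()
  assign_of <- integer(length(peptides))
  kindex <- if (kmer_filter > 0L) new.env(parent = emptyenv()) else NULL
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < kmer_filter) return(s)
    unique(substring(s, 1:(n - kmer_filter + 1L),
                     kmer_filter:(n)))
  }
  for (i in ord) {
    cand <- seq_along(reps)
    if (!is.null(kindex)) {
      km <- kmersOf(peptides[[i]])
      hit <- unlist(lapply(km, function(k) kindex[[k]]), use.names = FALSE)
      cand <- sort(unique(hit))
    }
    placed <- 0L
    for (ci in cand) {
      idt <- .globalIdentity(enc[[i]], enc[[reps[ci]]], scheme@matrix,
                             scheme@gapOpen, scheme@gapExtend)
      if (idt >= threshold) { placed <- ci; break }
    }
    if (placed) {
      members[[placed]] <- c(members[[placed]], ids[i])
      assign_of[i] <- placed
    } else {
      reps <- c(reps, i)
      members[[length(reps)]] <- ids[i]
      assign_of[i] <- length(reps)
      if (!is.null(kindex))
        for (k in kmersOf(peptides[[i]]))
          kindex[[k]] <- c(kindex[[k]], length(reps))
    }
  }
  samp <- if (is.null(sample)) stats::setNames(rep(NA_character_,
                                                   length(ids)), ids)
          else sample[ids]
  methods::new("ClusterSet", members = members,
               representatives = ids[reps],
               sample = stats::setNames(unname(samp), ids),
               params = list(threshold = threshold,
                             kmer_filter = kmer_filter))
}

#' @describeIn ClusterSet-class Number of clusters.
#' @param x,object A \code{ClusterSet}.
#' @export
setMethod("length", "ClusterSet", function(x) length(x@members))

setMethod("show", "ClusterSet", function(object) {
  sz <- lengths(object@members)
  cat("ClusterSet with", length(sz), "cluster(s),",
      sum(sz), "member(s)\n")
  if (length(sz))
    cat("  sizes: max", max(sz), ", singletons", sum(sz == 1L), "\n")
  invisible(object)
})

#' Cluster unigenes through their six reading frames
#'
#' Translates every unigene in all six frames, clusters the frame peptides
#' greedily at \code{threshold} identity, then collapses frame-level
#' clusters to unigene level: clusters sharing any unigene are merged
#' (connected components), so each unigene belongs to exactly one
#' unigene-level cluster.
#'
#' @param unigenes A \linkS4class{UnigeneSet}.
#' @inheritParams greedyCluster
#' @param min_peptide Frames shorter than this many aa are skipped.
#' @return A unigene-level \linkS4class{ClusterSet}.
#' @export
clusterSixFrames <- function(unigenes, threshold = 0.5,
                             scheme = scoringScheme("protein"),
                             kmer_filter = 0L, min_peptide = 10L) {
  ids <- names(unigenes)
  seqs <- as.character(unigenes@sequences)
  keep <- nchar(seqs) >= 3L
  peps <- character(0)
  if (any(keep)) {
    frames_all <- .sixFrameSet(Biostrings::DNAStringSet(seqs[keep]))
    for (fr in names(frames_all)) {
      v <- frames_all[[fr]]
      v <- v[nchar(v) >= min_peptide]
      if (length(v))
        peps[paste0(names(v), "|", fr)] <- unname(v)
    }
  }
  if (!length(peps)) stop("no translatable unigenes")
  frame_sample <- stats::setNames(
    unname(sampleOf(unigenes)[sub("\\|[+-][123]$", "", names(peps))]),
    names(peps))
  cs <- greedyCluster(peps, threshold = threshold, sample = frame_sample,
                      scheme = scheme, kmer_filter = kmer_filter)
  # collapse to unigene level: union clusters sharing a unigene
  uni_of <- lapply(cs@members, function(m)
    unique(sub("\\|[+-][123]$", "", m)))
  parent <- seq_along(uni_of)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  seen <- new.env(parent = emptyenv())
  for (ci in seq_along(uni_of)) {
    for (u in uni_of[[ci]]) {
      prev <- seen[[u]]
      if (is.null(prev)) seen[[u]] <- ci
      else {
        ra <- find(prev); rb <- find(ci)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp <- vapply(seq_along(uni_of), find, 0L)
  groups <- split(seq_along(uni_of), comp)
  sample_map <- sampleOf(unigenes)
  members <- lapply(groups, function(g)
    sort(unique(unlist(uni_of[g], use.names = FALSE))))
  # representative: unigene of the longest member frame (first founding rep)
  rep_ids <- vapply(groups, function(g) {
    sub("\\|[+-][123]$", "", cs@representatives[min(g)])
  }, "")
  names(members) <- NULL
  methods::new("ClusterSet", members = members,
               representatives = unname(rep_ids),
               sample = stats::setNames(unname(sample_map), names(unigenes)),
               params = c(cs@params, list(level = "unigene")))
}

#' Venn-style overlap counts over a cluster set
#'
#' Each cluster contributes to exactly one sample subset: the set of sample
#' labels present among its members.
#'
#' @param cluster_set A \linkS4class{ClusterSet} whose members carry sample
#'   tags.
#' @return A list with \code{subset_counts} (named integer vector; names are
#'   sample subsets joined by \code{"+"}) and \code{private_fraction}
#'   (per-sample fraction of its clusters containing no other sample).
#' @export
vennCounts <- function(cluster_set) {
  smap <- cluster_set@sample
  subsets <- vapply(cluster_set@members, function(m) {
    s <- sort(unique(smap[m]))
    if (any(is.na(s))) stop("every member needs a sample tag")
    paste(s, collapse = "+")
  }, "")
  counts <- table(subsets)
  samples <- sort(unique(unname(smap)))
  priv <- vapply(samples, function(s) {
    with_s <- vapply(cluster_set@members, function(m)
      s %in% smap[m], TRUE)
    only_s <- subsets == s
    if (!any(with_s)) return(NA_real_)
    sum(only_s) / sum(with_s)
  }, 0)
  list(subset_counts = stats::setNames(as.integer(counts), names(counts)),
       private_fraction = priv)
}
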