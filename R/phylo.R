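#' Progressive multiple alignment of peptides
#'
#' Desk-scale progressive aligner: pairwise global-alignment identities
#' give a distance matrix, a UPGMA guide tree (average-linkage
#' \code{\link[stats]{hclust}}) fixes the merge order, and profiles are
#' merged by profile-profile dynamic programming under the scoring scheme.
#' Deterministic for a fixed input order.
#'
#' @param peptides Named character vector or \code{AAStringSet}
#'   (at least 2 sequences).
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return An aligned \code{AAStringSet} (equal widths; degapping row i
#'   recovers input i).
#' @export
progressiveAlign <- function(peptides, scheme = scoringScheme("protein")) {
  if (methods::is(peptides, "AAStringSet"))
    peptides <- stats::setNames(as.character(peptides), names(peptides))
  n <- length(peptides)
  if (n < 2L) stop("need at least 2 sequences to align")
  ids <- names(peptides)
  if (is.null(ids) || anyDuplicated(ids)) stop("unique names required")
  enc <- lapply(peptides, .encode, alphabet = scheme@alphabet)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idt <- .globalIdentity(enc[[i]], enc[[j]], scheme@matrix,
                           scheme@gapOpen, scheme@gapExtend)
    D[i, j] <- D[j, i] <- 1 - idt
  }
  K <- length(scheme@alphabet)
  gapRow <- K + 1L
  toFreq <- function(codes) {
    # alphabet x columns frequency matrix for a single sequence
    m <- matrix(0, K, length(codes))
    m[cbind(codes + 1L, seq_along(codes))] <- 1
    m
  }
  profiles <- lapply(enc, toFreq)
  rows <- lapply(seq_len(n), function(i)
    stats::setNames(list(strsplit(peptides[[i]], "")[[1]]), ids[i]))
  mergeTwo <- function(pa, pb, ra, rb) {
    al <- .profile_align(pa, pb, scheme@matrix, scheme@gapOpen,
                         scheme@gapExtend)
    ncols <- length(al$step_a)
    na <- nrow(pa); wa <- ncol(pa); wb <- ncol(pb)
    newp <- matrix(0, K, ncols)
    ia <- 0L; ib <- 0L
    colA <- integer(ncols); colB <- integer(ncols)
    for (k in seq_len(ncols)) {
      if (al$step_a[k] == 1L) { ia <- ia + 1L; colA[k] <- ia }
      if (al$step_b[k] == 1L) { ib <- ib + 1L; colB[k] <- ib }
    }
    wA <- length(ra); wB <- length(rb)
    for (k in seq_len(ncols)) {
      if (colA[k] > 0L) newp[, k] <- newp[, k] + pa[, colA[k]] * wA
      if (colB[k] > 0L) newp[, k] <- newp[, k] + pb[, colB[k]] * wB
    }
    newp <- newp / (wA + wB)
    expand <- function(rowlist, col) {
      lapply(rowlist, function(ch) {
        out <- rep("-", ncols)
        out[col > 0L] <- ch[col[col > 0L]]
        out
      })
    }
    list(profile = newp, rows = c(expand(ra, colA), expand(rb, colB)))
  }
  if (n == 2L) {
    m <- mergeTwo(profiles[[1]], profiles[[2]], rows[[1]], rows[[2]])
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    getNode <- function(k) {
      if (k < 0) list(profile = profiles[[-k]], rows = rows[[-k]])
      else nodes[[k]]
    }
    for (s in seq_len(nrow(hc$merge))) {
      a <- getNode(hc$merge[s, 1]); b <- getNode(hc$merge[s, 2])
      nodes[[s]] <- mergeTwo(a$profile, b$profile, a$rows, b$rows)
    }
    m <- nodes[[nrow(hc$merge)]]
  }
  aligned <- vapply(m$rows, paste, "", collapse = "")
  Biostrings::AAStringSet(aligned[ids])
}

#' Curate alignment blocks
#'
#' Conserved-block curation in the spirit of classic alignment-cleaning
#' tools, reduced to three parameters: a column is good when its gap
#' fraction is at most \code{max_gap_fraction} and its most frequent
#' non-gap residue covers at least \code{min_conservation} of the rows;
#' maximal runs of good columns shorter than \code{min_block_length} are
#' discarded.
#'
#' @param msa Aligned \code{AAStringSet}.
#' @param max_gap_fraction Maximum per-column gap fraction (default 0).
#' @param min_conservation Minimum modal-residue fraction (default 0.5).
#' @param min_block_length Minimum run length in columns (default 10).
#' @return A list with \code{msa} (curated alignment, possibly 0 columns,
#'   with a warning when nothing survives) and \code{kept} (ascending
#'   original column indices).
#' @export
curateBlocks <- function(msa, max_gap_fraction = 0, min_conservation = 0.5,
                         min_block_length = 10L) {
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  nc <- ncol(mat); nr <- nrow(mat)
  good <- vapply(seq_len(nc), function(j) {
    col <- mat[, j]
    gapf <- mean(col == "-")
    if (gapf > max_gap_fraction) return(FALSE)
    res <- col[col != "-"]
    if (!length(res)) return(FALSE)
    max(table(res)) / nr >= min_conservation
  }, TRUE)
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kept <- integer(0)
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= min_block_length)
      kept <- c(kept, starts[k]:ends[k])
  if (!length(kept)) {
    warning("no alignment columns survive curation")
    return(list(msa = Biostrings::AAStringSet(
      stats::setNames(rep("", nr), names(msa))), kept = integer(0)))
  }
  curated <- apply(mat[, kept, drop = FALSE], 1, paste, collapse = "")
  list(msa = Biostrings::AAStringSet(stats::setNames(curated, names(msa))),
       kept = kept)
}

#' Pairwise protein distance from an alignment
#'
#' p-distance over columns where neither row is gapped, optionally with the
#' Poisson correction \code{-log(1 - p)}.
#'
#' @param row_i,row_j Equal-length gapped peptide strings.
#' @param poisson Apply the Poisson correction.
#' @return A single distance.
#' @export
proteinDistance <- function(row_i, row_j, poisson = FALSE) {
  a <- strsplit(row_i, "")[[1]]
  b <- strsplit(row_j, "")[[1]]
  if (length(a) != length(b)) stop("rows must have equal gapped length")
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("no shared ungapped columns")
  p <- mean(a[shared] != b[shared])
  if (!poisson) return(p)
  if (p >= 1) stop("Poisson correction undefined for p >= 1")
  -log(1 - p)
}

#' Distance matrix over alignment rows
#'
#' @param msa Aligned \code{AAStringSet}.
#' @inheritParams proteinDistance
#' @return Symmetric matrix of distances with a zero diagonal.
#' @export
distanceMatrix <- function(msa, poisson = FALSE) {
  s <- as.character(msa)
  n <- length(s)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- proteinDistance(s[i], s[j], poisson)
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou-Nei Q criterion, via
#' \code{\link[ape]{nj}}) on a symmetric distance matrix; for an additive
#' matrix the generating topology is recovered exactly. Negative branch
#' lengths are clamped to zero and flagged in the attribute
#' \code{"clamped"}.
#'
#' @param D Symmetric distance matrix with zero diagonal, at least 3 taxa.
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("diagonal must be zero")
  tr <- ape::nj(D)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Does a leaf set form a clade of an unrooted tree?
#'
#' True when some edge of the tree separates exactly \code{tips} from the
#' remaining leaves (the unrooted meaning of a clade).
#'
#' @param tree A \code{phylo} object.
#' @param tips Character vector of leaf labels.
#' @return Logical.
#' @export
isCladeUnrooted <- function(tree, tips) {
  all_tips <- tree$tip.label
  tips <- intersect(tips, all_tips)
  if (!length(tips)) return(FALSE)
  if (length(tips) %in% c(1L, length(all_tips))) return(TRUE)
  outside <- setdiff(all_tips, tips)
  rooted <- ape::root(tree, outgroup = outside[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the reference tree the
#' percentage of replicates in which its leaf bipartition reappears.
#'
#' @param msa Curated aligned \code{AAStringSet}.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param poisson Passed to \code{\link{distanceMatrix}}.
#' @return A list with \code{tree} (reference NJ tree) and \code{support}
#'   (percent support per internal edge, in \code{ape::prop.clades} order).
#' @export
njBootstrap <- function(msa, n_replicates = 100L, seed = 1L,
                        poisson = FALSE) {
  ref <- njTree(distanceMatrix(msa, poisson))
  mat <- do.call(rbind, strsplit(as.character(msa), ""))
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boot <- Biostrings::AAStringSet(stats::setNames(
      apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
      names(msa)))
    njTree(distanceMatrix(boot, poisson))
  })
  support <- ape::prop.clades(ref, reps, rooted = FALSE)
  list(tree = ref, support = 100 * support / n_replicates)
}
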