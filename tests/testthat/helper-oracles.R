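# Independent plain-R oracles used to cross-check the compiled alignment
# kernels and the greedy/LCA logic. Deliberately naive implementations.

encSeq <- function(s, alphabet) {
  idx <- match(strsplit(toupper(s), "")[[1]], alphabet)
  idx[is.na(idx)] <- length(alphabet)
  idx - 1L
}

# local affine-gap DP, score only; same state machine as the package kernel
# (gap states open from the substitution state only)
swOracle <- function(aseq, bseq, scheme) {
  a <- encSeq(aseq, scheme@alphabet); b <- encSeq(bseq, scheme@alphabet)
  S <- scheme@matrix; go <- scheme@gapOpen; ge <- scheme@gapExtend
  n <- length(a); m <- length(b)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    d <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
    v <- d + S[a[i - 1] + 1, b[j - 1] + 1]
    M[i, j] <- if (v < 0) NEG else v
    best <- max(best, M[i, j])
  }
  best
}

# global affine-gap DP maximizing (score, matches) lexicographically
nwOracle <- function(aseq, bseq, scheme) {
  a <- encSeq(aseq, scheme@alphabet); b <- encSeq(bseq, scheme@alphabet)
  S <- scheme@matrix; go <- scheme@gapOpen; ge <- scheme@gapExtend
  n <- length(a); m <- length(b)
  NEG <- -1e30
  Ms <- matrix(NEG, n + 1, m + 1); Xs <- Ms; Ys <- Ms
  Mm <- matrix(0, n + 1, m + 1); Xm <- Mm; Ym <- Mm
  Ms[1, 1] <- 0
  for (i in 2:(n + 1)) Xs[i, 1] <- -go - ge * (i - 1)
  for (j in 2:(m + 1)) Ys[1, j] <- -go - ge * (j - 1)
  lexmax2 <- function(s1, m1, s2, m2) {
    if (s1 > s2 + 1e-9 || (abs(s1 - s2) <= 1e-9 && m1 >= m2)) c(s1, m1)
    else c(s2, m2)
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    v <- lexmax2(max(Ms[i - 1, j] - go - ge, NEG), Mm[i - 1, j],
                 max(Xs[i - 1, j] - ge, NEG), Xm[i - 1, j])
    Xs[i, j] <- v[1]; Xm[i, j] <- v[2]
    v <- lexmax2(max(Ms[i, j - 1] - go - ge, NEG), Mm[i, j - 1],
                 max(Ys[i, j - 1] - ge, NEG), Ym[i, j - 1])
    Ys[i, j] <- v[1]; Ym[i, j] <- v[2]
    v <- lexmax2(Ms[i - 1, j - 1], Mm[i - 1, j - 1],
                 Xs[i - 1, j - 1], Xm[i - 1, j - 1])
    v <- lexmax2(v[1], v[2], Ys[i - 1, j - 1], Ym[i - 1, j - 1])
    if (v[1] < NEG / 2) { Ms[i, j] <- NEG; Mm[i, j] <- 0 } else {
      Ms[i, j] <- v[1] + S[a[i - 1] + 1, b[j - 1] + 1]
      Mm[i, j] <- v[2] + as.numeric(a[i - 1] == b[j - 1])
    }
  }
  v <- lexmax2(Ms[n + 1, m + 1], Mm[n + 1, m + 1],
               Xs[n + 1, m + 1], Xm[n + 1, m + 1])
  v <- lexmax2(v[1], v[2], Ys[n + 1, m + 1], Ym[n + 1, m + 1])
  list(score = v[1], nmatch = v[2])
}

identityOracle <- function(aseq, bseq, scheme) {
  nwOracle(aseq, bseq, scheme)$nmatch / min(nchar(aseq), nchar(bseq))
}

# brute-force re-evaluation of the greedy clustering rule
greedyOracle <- function(peptides, threshold, scheme) {
  ids <- names(peptides)
  ord <- order(-nchar(peptides), ids)
  reps <- character(0); members <- list()
  for (i in ord) {
    placed <- 0L
    for (ci in seq_along(reps)) {
      if (identityOracle(peptides[[i]], peptides[[reps[ci]]], scheme) >=
          threshold) { placed <- ci; break }
    }
    if (placed) members[[placed]] <- c(members[[placed]], ids[i])
    else { reps <- c(reps, ids[i]); members[[length(reps)]] <- ids[i] }
  }
  lapply(members, sort)
}

# brute-force LCA over ancestor sets
ancestorsOf <- function(parent, x) {
  path <- x
  while (parent[[x]] != x) { x <- parent[[x]]; path <- c(path, x) }
  path
}

lcaBrute <- function(parent, taxa) {
  common <- Reduce(intersect, lapply(unique(taxa),
                                     function(t) ancestorsOf(parent, t)))
  depths <- vapply(common, function(c) length(ancestorsOf(parent, c)), 0)
  common[which.max(depths)]
}

randomTaxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("t", seq_len(n_nodes))
  parent <- stats::setNames(character(n_nodes), nodes)
  parent[1] <- nodes[1]
  for (k in 2:n_nodes) parent[k] <- nodes[sample.int(k - 1, 1)]
  parent
}

randPeptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

randNtSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# CTLD template with exact architecture (1-based: C at 1, 1+g1, 1+g1+g2,
# 1+g1+g2+g3), WIGL-like 4-mer at wigl_at, sugar 3-mer at sugar_at.
makeTemplate <- function(g1 = 25, g2 = 55, g3 = 20, wigl = "WIGL",
                         sugar = "EPN", wigl_at = 11, sugar_at = 61) {
  free_aa <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L",
                       "K", "M", "F", "P", "S", "T", "Y", "V"), NULL)
  len <- 1 + g1 + g2 + g3
  ch <- sample(free_aa, len, replace = TRUE)
  cys <- c(1, 1 + g1, 1 + g1 + g2, 1 + g1 + g2 + g3)
  ch[cys] <- "C"
  ch[wigl_at:(wigl_at + 3)] <- strsplit(wigl, "")[[1]]
  ch[sugar_at:(sugar_at + 2)] <- strsplit(sugar, "")[[1]]
  paste(ch, collapse = "")
}

# variant of the packaged anchor domain (stays alignable to the anchor, so
# the sugar-motif column can be located by anchored alignment)
anchorVariant <- function(sugar = "EPN", wigl = "WIGL", p = 0.3) {
  arch <- HolobiontEST:::.scaffoldArch()
  ch <- arch$chars
  hit <- arch$free[runif(length(arch$free)) < p]
  pool <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K",
                    "M", "F", "P", "S", "T", "Y", "V"), NULL)
  ch[hit] <- sample(pool, length(hit), replace = TRUE)
  ch[arch$wigl_start:(arch$wigl_start + 3)] <- strsplit(wigl, "")[[1]]
  ch[arch$sugar_start:(arch$sugar_start + 2)] <- strsplit(sugar, "")[[1]]
  paste(ch, collapse = "")
}

mklcahits <- function(taxa, scores) {
  n <- length(taxa)
  h <- emptyHits()
  for (i in seq_len(n))
    h[i, ] <- list("q1", paste0("s", i), 90, 100, 0, 0, 1, 100, 1, 100, NA,
                   scores[i], "", taxa[i])
  h
}
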