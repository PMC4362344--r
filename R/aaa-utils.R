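# Internal helpers shared across modules.

NT_ALPHABET <- c("A", "C", "G", "T", "N")

#' @importFrom utils data
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Encode a sequence as 0-based integer codes into `alphabet`; characters not
# in the alphabet map to the last symbol (N / X).
.encode <- function(seq, alphabet) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- length(alphabet)
  idx - 1L
}

# Nucleotide substitution matrix over ACGTN; N scores `mismatch` against
# everything (conservative: ambiguity never creates identity).
.ntMatrix <- function(match, mismatch) {
  k <- length(NT_ALPHABET)
  m <- matrix(mismatch, k, k, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# round-half-up formatting used for percentage reports (42 from 41.91,
# 13 from 12.66, 0.4 from 0.391)
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Deterministic per-stream seed below 2^31, keyed by (seed, label) so adding
# one sample never perturbs the reads of another.
.deriveSeed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1000000007
  as.integer((abs(seed) %% 65011 + 1) * 32003 + h %% 32000) %% 2147483647L
}

# iid nucleotides at a target GC fraction
.randNt <- function(n, gc) {
  if (n <= 0) return("")
  isGC <- stats::runif(n) < gc
  out <- character(n)
  out[isGC] <- sample(c("G", "C"), sum(isGC), replace = TRUE)
  out[!isGC] <- sample(c("A", "T"), sum(!isGC), replace = TRUE)
  paste(out, collapse = "")
}

.truncNorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

# Fixed most-frequent-codon reverse-translation table (deterministic).
.CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGC", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACA", W = "TGG",
  Y = "TAT", V = "GTT"
)

.revTranslate <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), names(.CODON_OF))
  if (length(bad))
    stop("cannot reverse-translate residue(s): ", paste(bad, collapse = ", "))
  paste(.CODON_OF[aa], collapse = "")
}

.revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
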