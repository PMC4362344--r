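test_that("local alignment handles self-alignment and hopeless pairs", {
  sch <- scoringScheme("nucleotide", match = 1, mismatch = -1,
                       gap_open = 0, gap_extend = 1)
  sw <- smithWaterman("ACGT", "ACGT", sch)
  expect_equal(sw$score, 4)
  expect_equal(sw$pct_identity, 100)
  expect_equal(sw$aln_length, 4L)

  sw0 <- smithWaterman("AAAA", "CCCC", sch)
  expect_equal(sw0$score, 0)
  expect_equal(unname(sw0$alignment), c("", ""))
  expect_equal(sw0$aln_length, 0L)
})

test_that("local alignment scores match an exhaustive DP oracle", {
  set.seed(31)
  nt <- scoringScheme("nucleotide")
  aa <- scoringScheme("protein")
  for (k in 1:25) {
    q <- randNtSeq(sample(5:30, 1)); s <- randNtSeq(sample(5:30, 1))
    expect_equal(smithWaterman(q, s, nt)$score, swOracle(q, s, nt))
  }
  for (k in 1:25) {
    q <- randPeptide(sample(5:30, 1)); s <- randPeptide(sample(5:30, 1))
    expect_equal(smithWaterman(q, s, aa)$score, swOracle(q, s, aa))
  }
})

test_that("local alignment is symmetric for symmetric schemes", {
  set.seed(13)
  aa <- scoringScheme("protein")
  for (k in 1:10) {
    q <- randPeptide(sample(8:25, 1)); s <- randPeptide(sample(8:25, 1))
    expect_equal(smithWaterman(q, s, aa)$score,
                 smithWaterman(s, q, aa)$score)
  }
})

test_that("global alignment agrees with the lexicographic oracle", {
  set.seed(37)
  aa <- scoringScheme("protein")
  for (k in 1:20) {
    q <- randPeptide(sample(4:25, 1)); s <- randPeptide(sample(4:25, 1))
    got <- globalAlign(q, s, aa)
    want <- nwOracle(q, s, aa)
    expect_equal(got$score, want$score)
    expect_equal(got$nmatch, want$nmatch)
  }
})

test_that("six-frame translation follows the standard code", {
  expect_equal(sixFrameTranslate("ATGGCC")[["+1"]], "MA")
  expect_equal(sixFrameTranslate("TAA")[["+1"]], "*")
  expect_error(sixFrameTranslate("AT"), "codon")
  revComp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(3)
  for (k in 1:10) {
    s <- randNtSeq(sample(9:60, 1))
    expect_equal(sixFrameTranslate(s)[["-1"]],
                 sixFrameTranslate(revComp(s))[["+1"]])
  }
  # ambiguous codon renders X
  expect_equal(sixFrameTranslate("ATGNNN")[["+1"]], "MX")
})

test_that("ORF segmentation splits frames at stops", {
  segs <- orfSegments(paste0(strrep("A", 25), "*", strrep("L", 30), "*",
                             strrep("K", 5)), min_len = 20)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start, c(1L, 27L))
  expect_equal(nchar(segs$seq), c(25L, 30L))
})

test_that("similarity search finds planted references and respects order", {
  set.seed(41)
  refs <- Biostrings::DNAStringSet(setNames(
    vapply(1:4, function(i) randNtSeq(500), ""),
    paste0("ref", 1:4, " synthetic reference ", 1:4)))
  q <- UnigeneSet(setNames(as.character(refs[[2]]), "q1"), sample = "S")
  hits <- searchHomology(q, refs, scoringScheme("nucleotide"))
  expect_equal(hits$subject_id[1], "ref2")
  expect_equal(hits$pct_identity[1], 100)
  expect_equal(hits$subject_description[1], "synthetic reference 2")

  none <- searchHomology(q, refs, scoringScheme("nucleotide"),
                         min_score = 1e6)
  expect_equal(nrow(none), 0L)

  perm <- searchHomology(q, refs[c(3, 1, 4, 2)],
                         scoringScheme("nucleotide"))
  expect_equal(perm, hits, ignore_attr = TRUE)
})

test_that("translated search records the reading frame", {
  set.seed(43)
  tpl <- makeTemplate()
  refs <- Biostrings::AAStringSet(setNames(tpl, "ctldref synthetic"))
  for (fr in c(2L, -1L)) {
    nt <- plantCtld(tpl, fr)
    q <- UnigeneSet(setNames(nt, "q1"), sample = "S")
    hits <- searchHomology(q, refs, scoringScheme("protein"),
                           min_score = 60)
    expect_true(nrow(hits) >= 1L)
    expect_true(fr %in% hits$frame)
    expect_equal(max(hits$pct_identity), 100)
  }
})
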