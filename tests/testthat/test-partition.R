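mkhit <- function(identity, aln, desc, query = "q1", subject = "s1",
                  score = 100) {
  h <- emptyHits()
  h[1, ] <- list(query, subject, identity, aln, 0, 0, 1, aln, 1, aln, NA,
                 score, desc, "")
  h
}

test_that("the keyword matcher respects token rules for ITS/LSU/SSU", {
  expect_true(matchesRrnaKeyword("Homo sapiens 18S ribosomal RNA"))
  expect_true(matchesRrnaKeyword("internal transcribed spacer (ITS)"))
  expect_true(matchesRrnaKeyword("LSU rRNA gene"))
  expect_true(matchesRrnaKeyword("partial 5.8S sequence"))
  expect_true(matchesRrnaKeyword("ribosomal dna, complete"))
  expect_false(matchesRrnaKeyword("its a binding site"))
  expect_false(matchesRrnaKeyword("restriction sites upstream"))
  expect_false(matchesRrnaKeyword("lsu-like protein"))
  expect_false(matchesRrnaKeyword("60S ribosomal protein L3"))
  # "5.8S" must not behave as a regular expression dot
  expect_false(matchesRrnaKeyword("5X8S domain"))
})

test_that("the ribosomal rule combines keyword, identity and length strictly", {
  rule <- partitionRule()
  expect_true(isRrnaHit(mkhit(85, 150, "Homo sapiens 18S ribosomal RNA"),
                        rule))
  expect_false(isRrnaHit(mkhit(80.0, 150, "18S rRNA"), rule))     # strict >
  expect_false(isRrnaHit(mkhit(85, 100, "18S rRNA"), rule))       # strict >
  expect_false(isRrnaHit(mkhit(95, 150, "60S ribosomal protein L3"), rule))
  lax <- partitionRule(strict = FALSE)
  expect_true(isRrnaHit(mkhit(80.0, 150, "18S rRNA"), lax))
})

test_that("partition uses any-hit semantics and defaults to mRNA", {
  set.seed(17)
  u <- UnigeneSet(setNames(vapply(rep(300, 3), randNtSeq, ""),
                           c("a", "b", "c")), sample = "S")
  hits <- rbind(mkhit(50, 150, "18S ribosomal RNA", query = "a"),
                mkhit(95, 150, "18S ribosomal RNA", query = "a"),
                mkhit(95, 50, "18S ribosomal RNA", query = "b"))
  p <- partitionUnigenes(u, hits)
  lab <- setNames(p@labels$label, p@labels$id)
  expect_equal(unname(lab[c("a", "b", "c")]), c("rRNA", "mRNA", "mRNA"))
  expect_false(is.na(p@labels$trigger_subject[p@labels$id == "a"]))
  expect_equal(sum(p@counts), length(u))

  p0 <- partitionUnigenes(u, emptyHits())
  expect_true(all(p0@labels$label == "mRNA"))

  expect_warning(partitionUnigenes(u, mkhit(95, 150, "18S", query = "zz")),
                 "unknown query")
})

test_that("loosening thresholds never shrinks the ribosomal set", {
  set.seed(19)
  u <- UnigeneSet(setNames(vapply(rep(300, 30), randNtSeq, ""),
                           paste0("u", 1:30)), sample = "S")
  hits <- do.call(rbind, lapply(1:30, function(i)
    mkhit(runif(1, 60, 100), sample(50:250, 1), "18S ribosomal RNA",
          query = paste0("u", i))))
  strictSet <- function(idn, aln) {
    p <- partitionUnigenes(u, hits, partitionRule(min_identity = idn,
                                                  min_aln_length = aln))
    p@labels$id[p@labels$label == "rRNA"]
  }
  base <- strictSet(80, 100)
  expect_true(all(base %in% strictSet(70, 100)))
  expect_true(all(base %in% strictSet(80, 60)))
  expect_true(all(strictSet(90, 150) %in% base))
})

test_that("partition recovers the simulated rRNA fraction exactly", {
  p <- sampleProfile("S1", n_reads = 40, rrna_fraction = 0.3)
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 23))
  reads <- lengthFilter(trimPolyA(sim@reads))$kept
  rrefs <- sim@references[matchesRrnaKeyword(names(sim@references))]
  hits <- searchHomology(reads, rrefs, scoringScheme("nucleotide"))
  part <- partitionUnigenes(reads, hits)
  truth <- setNames(sim@truthReads$fraction, sim@truthReads$id)
  lab <- setNames(part@labels$label, part@labels$id)
  expect_identical(unname(lab), unname(truth[names(lab)]))
})
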