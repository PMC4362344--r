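test_that("length filter keeps the 200 bp boundary and partitions input", {
  set.seed(2)
  u <- UnigeneSet(setNames(vapply(c(199, 200, 201), randNtSeq, ""),
                           c("a", "b", "c")), sample = "S")
  r <- lengthFilter(u, 200)
  expect_setequal(names(r$kept), c("b", "c"))
  expect_setequal(names(r$removed), "a")
  expect_equal(length(r$kept) + length(r$removed), length(u))

  r1 <- lengthFilter(u, 1)
  expect_equal(length(r1$kept), 3L)
  expect_equal(length(r1$removed), 0L)

  empty <- UnigeneSet(Biostrings::DNAStringSet(), sample = character(0))
  r0 <- lengthFilter(empty)
  expect_equal(length(r0$kept), 0L)

  again <- lengthFilter(r$kept, 200)
  expect_identical(names(again$kept), names(r$kept))  # idempotent
})

test_that("poly-A/poly-T trimming follows the anchored mismatch rule", {
  expect_equal(trimPolyA(paste0("ACGT", strrep("A", 15)))[[1]], "ACGT")
  expect_equal(trimPolyA("ACGTAAAA")[[1]], "ACGTAAAA")      # run below 10
  expect_equal(trimPolyA(paste0(strrep("T", 15), "ACGT"))[[1]], "ACGT")
  # one mismatch per 10 nt of run is tolerated inside the tail
  tail <- paste0(strrep("A", 6), "G", strrep("A", 8))
  expect_equal(trimPolyA(paste0("ACGG", tail))[[1]], "ACGG")
})

test_that("trimming is idempotent and strand-symmetric", {
  set.seed(7)
  revComp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in 1:25) {
    s <- paste0(randNtSeq(sample(30:80, 1)),
                strrep("A", sample(c(0, 5, 12, 25), 1)))
    if (runif(1) < 0.5) s <- revComp(s)
    t1 <- trimPolyA(s)[[1]]
    expect_identical(trimPolyA(t1)[[1]], t1)
    # trimming commutes with reverse complement
    expect_identical(trimPolyA(revComp(s))[[1]], revComp(trimPolyA(s)[[1]]))
  }
})

test_that("adapter trimming is exact prefix/suffix only", {
  ad <- "GTACGTA"
  expect_equal(trimAdapters(paste0(ad, "ACGTACGT"), ad)[[1]], "ACGTACGT")
  expect_equal(trimAdapters(paste0("ACGTACGT", ad), ad)[[1]], "ACGTACGT")
  # reverse complement of the adapter is also recognised
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ad)))
  expect_equal(trimAdapters(paste0(rc, "AACCGGTT"), ad)[[1]], "AACCGGTT")
  # internal occurrences are deliberately left alone
  inner <- paste0("ACGT", ad, "ACGT")
  expect_equal(trimAdapters(inner, ad)[[1]], inner)
})

test_that("sample statistics aggregate counts, lengths and GC", {
  u <- UnigeneSet(setNames(c(strrep("AT", 50), strrep("GC", 150)),
                           c("a", "b")), sample = "S1")
  st <- sampleStats(u)
  expect_equal(st$n, 2L)
  expect_equal(st$mean_length, 200)
  expect_equal(st$median_length, 200)
  expect_equal(st$total_bp, 400)
  expect_equal(st$gc_percent, 100 * 300 / 400)
  expect_error(sampleStats(UnigeneSet(Biostrings::DNAStringSet(),
                                      sample = character(0))), "empty")
})

test_that("total bp is exact integer arithmetic per sample", {
  set.seed(9)
  lens <- sample(200:900, 40, replace = TRUE)
  u <- UnigeneSet(setNames(vapply(lens, randNtSeq, ""),
                           paste0("u", seq_along(lens))),
                  sample = rep(c("S1", "S2"), each = 20))
  st <- sampleStats(u)
  expect_equal(sum(st$total_bp), sum(lens))
  expect_equal(st$total_bp[st$sample == "S1"], sum(lens[1:20]))
})
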