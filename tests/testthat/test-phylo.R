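test_that("progressive alignment handles identical and near pairs", {
  m <- progressiveAlign(c(a = "MKLVND", b = "MKLVND"))
  expect_equal(unique(Biostrings::width(m)), 6L)
  expect_false(any(grepl("-", as.character(m), fixed = TRUE)))

  m2 <- progressiveAlign(c(a = "ACDEF", b = "ACEF"))
  expect_equal(unique(Biostrings::width(m2)), 5L)
  expect_equal(sum(strsplit(as.character(m2[["b"]]), "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", as.character(m2[["b"]])), "ACEF")
})

test_that("degapping alignment rows recovers the inputs", {
  set.seed(151)
  for (k in 1:5) {
    n <- sample(3:6, 1)
    base <- randPeptide(40)
    peps <- setNames(vapply(seq_len(n), function(i) {
      ch <- strsplit(base, "")[[1]]
      pos <- sample(40, 6)
      ch[pos] <- sample(c("A", "G", "S", "L", "V", "T"), 6, replace = TRUE)
      if (runif(1) < 0.5) ch <- ch[-sample(40, 2)]
      paste(ch, collapse = "")
    }, ""), paste0("s", seq_len(n)))
    m <- progressiveAlign(peps)
    expect_equal(length(unique(Biostrings::width(m))), 1L)
    expect_identical(gsub("-", "", as.character(m)), peps)
  }
})

test_that("block curation keeps conserved runs and drops gapped columns", {
  cons <- Biostrings::AAStringSet(c(a = strrep("MKLVN", 4),
                                    b = strrep("MKLVN", 4)))
  cur <- curateBlocks(cons)
  expect_equal(cur$kept, 1:20)

  # gap block inside: columns 5-8 gapped in one row
  a <- paste0(strrep("K", 20))
  b <- paste0(strrep("K", 4), "----", strrep("K", 12))
  msa <- Biostrings::AAStringSet(c(a = a, b = b))
  cur2 <- curateBlocks(msa, max_gap_fraction = 0, min_conservation = 0.5,
                       min_block_length = 10)
  expect_equal(cur2$kept, 9:20)   # leading run of 4 is below block length

  id <- curateBlocks(msa, max_gap_fraction = 1, min_conservation = 0,
                     min_block_length = 1)
  expect_equal(id$kept, 1:20)
  expect_warning(curateBlocks(msa, min_block_length = 15), "survive")
})

test_that("protein distances follow the p-distance definition", {
  expect_equal(proteinDistance("MKLV", "MKLV"), 0)
  expect_equal(proteinDistance(paste0("A", strrep("K", 9)),
                               paste0("G", strrep("K", 9))), 0.1)
  expect_equal(proteinDistance(paste0("A", strrep("K", 9)),
                               paste0("G", strrep("K", 9)),
                               poisson = TRUE), -log(0.9))
  expect_error(proteinDistance("--A", "A--"), "shared")
})

test_that("neighbor joining recovers a hand-computed additive tree", {
  # tree ((A:1,B:2):1,(C:3,D:1)); path distances computed by hand
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- njTree(D)
  expect_s3_class(tr, "phylo")
  expect_true(isCladeUnrooted(tr, c("A", "B")))
  expect_true(isCladeUnrooted(tr, c("C", "D")))
  expect_false(isCladeUnrooted(tr, c("A", "C")))

  # 3 taxa: the unique unrooted star
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- njTree(D3)
  expect_equal(length(tr3$tip.label), 3L)
  expect_error(njTree(D3[1:2, 1:2]), "3 taxa")
  bad <- D; bad[1, 2] <- 99
  expect_error(njTree(bad), "symmetric")
})

test_that("topology is invariant under taxon-order permutation", {
  set.seed(157)
  tr0 <- ape::rtree(6)
  D <- ape::cophenetic.phylo(tr0)
  t1 <- njTree(D)
  perm <- sample(6)
  t2 <- njTree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("NJ recovers generating topologies from additive matrices", {
  set.seed(163)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr0)
    tr <- njTree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap support is reported per internal edge", {
  set.seed(167)
  base <- randPeptide(60)
  peps <- setNames(vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[sample(60, 4 * i)] <- sample(c("A", "G", "S", "V"), 4 * i, TRUE)
    paste(ch, collapse = "")
  }, ""), paste0("s", 1:5))
  msa <- progressiveAlign(peps)
  bs <- njBootstrap(msa, n_replicates = 20, seed = 3)
  expect_s3_class(bs$tree, "phylo")
  expect_true(all(bs$support >= 0 & bs$support <= 100, na.rm = TRUE))
})
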