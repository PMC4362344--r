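test_that("LCA assignment follows the definitional examples", {
  tax <- demoTaxonomy()
  expect_equal(lcaAssign(mklcahits(c("Gammaproteobacteria",
                                     "Alphaproteobacteria"), c(100, 100)),
                         tax), "Proteobacteria")
  expect_equal(lcaAssign(mklcahits("Acantharea", 80), tax), "Acantharea")
  expect_equal(lcaAssign(emptyHits(), tax), "No hits")
  expect_equal(lcaAssign(mklcahits("Acantharea", 10), tax), "Not assigned")
  # hits outside the top-percent window do not vote
  h <- mklcahits(c("Acantharea", "Fungi"), c(100, 85))
  expect_equal(lcaAssign(h, tax, top_percent = 10), "Acantharea")
  expect_equal(lcaAssign(h, tax, top_percent = 20), "Eukaryota")
  expect_error(lcaAssign(mklcahits("NotATaxon", 100), tax), "NotATaxon")
})

test_that("LCA assignment is invariant under hit order", {
  tax <- demoTaxonomy()
  h <- mklcahits(c("Metazoa", "Fungi", "Ciliophora"), c(100, 98, 95))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(lcaAssign(h[perm, ], tax), lcaAssign(h, tax))
})

test_that("LCA agrees with a brute-force oracle on random trees", {
  parent <- randomTaxonomy(30, seed = 71)
  tax <- taxonomyMap(parent)
  set.seed(72)
  for (k in 1:100) {
    n <- sample(1:6, 1)
    taxa <- sample(names(parent), n, replace = TRUE)
    scores <- round(runif(n, 40, 100), 1)
    got <- lcaAssign(mklcahits(taxa, scores), tax, top_percent = 10,
                     min_score = 50)
    qual <- scores >= 50
    if (!any(qual)) {
      expect_equal(got, "Not assigned")
    } else {
      voting <- taxa[qual & scores >= max(scores[qual]) * 0.9]
      expect_equal(got, lcaBrute(parent, voting))
    }
  }
})

test_that("count tables satisfy column-sum invariants", {
  set.seed(73)
  asn <- data.frame(
    id = paste0("u", 1:50),
    sample = sample(c("S1", "S2"), 50, replace = TRUE),
    fraction = sample(c("rRNA", "mRNA"), 50, replace = TRUE),
    taxon = sample(c("Acantharea", "Fungi", "No hits", "Not assigned"),
                   50, replace = TRUE))
  tab <- buildTaxonCountTable(asn)
  for (k in seq_along(tab@sample)) {
    col <- tab@counts[, k]
    expect_equal(col[["Total"]],
                 sum(col[setdiff(names(col), "Total")]))
    expect_equal(col[["Total"]],
                 sum(asn$sample == tab@sample[k] &
                     asn$fraction == tab@fraction[k]))
  }
})

test_that("percentage formatting uses integer/one-decimal rounding", {
  counts <- matrix(c(171, 408, 54, 13800), 2, 2,
                   dimnames = list(c("Total Rhizaria", "Total"), NULL))
  tab <- taxonCountTable(counts, c("A", "A"), c("rRNA", "mRNA"))
  expect_equal(percentOfTotal(tab, "Total Rhizaria", "A", "rRNA"), 42)
  expect_equal(percentOfTotal(tab, "Total Rhizaria", "A", "mRNA"), 0.4)
  expect_equal(percentOfTotal(tab, "Total Rhizaria", "A", "rRNA",
                              formatted = FALSE), 100 * 171 / 408)
  zero <- taxonCountTable(matrix(c(0, 0), 2, 1,
                                 dimnames = list(c("x", "Total"), NULL)),
                          "A", "rRNA")
  expect_error(percentOfTotal(zero, "x", "A", "rRNA"), "zero")
})

test_that("subtree roll-up counts members of a group", {
  tax <- demoTaxonomy()
  counts <- matrix(c(10, 5, 2, 40), 4, 1,
                   dimnames = list(c("Acantharea", "Polycystinea",
                                     "Cercozoa", "Total"), NULL))
  tab <- taxonCountTable(counts, "A", "rRNA")
  expect_equal(groupCount(tab, "Rhizaria", "A", "rRNA", taxonomy = tax), 17)
  expect_equal(groupCount(tab, "Radiolaria", "A", "rRNA", taxonomy = tax),
               15)
})
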