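test_that("keyword scan counts unigenes once per category", {
  ann <- data.frame(
    unigene = c("u1", "u2", "u3"),
    sample = c("S1", "S1", "S2"),
    description = c("c-type lectin 2 precursor", "ferritin heavy chain",
                    "triose phosphate isomerase"))
  tab <- keywordScan(ann)
  expect_equal(tab["lectin", "S1"], 1L)
  expect_equal(tab["ferritin", "S1"], 1L)
  expect_equal(tab["Total", "S1"], 2L)
  expect_equal(tab["Total", "S2"], 0L)

  # two phrases of one category still count once
  ann2 <- data.frame(unigene = "u1", sample = "S1",
                     description = "glutathione transferase / glutathione s-transferase")
  tab2 <- keywordScan(ann2)
  expect_equal(tab2["glutathione S-transferase", "S1"], 1L)

  empty <- keywordScan(ann[0, ])
  expect_true(all(empty == 0))
})

test_that("keyword totals equal the category sums", {
  set.seed(211)
  ann <- data.frame(
    unigene = paste0("u", 1:40),
    sample = sample(c("S1", "S2"), 40, TRUE),
    description = sample(c("lectin-like", "lipase 3", "ferritin",
                           "unknown protein"), 40, TRUE))
  tab <- keywordScan(ann)
  expect_equal(unname(tab["Total", ]),
               unname(colSums(tab[rownames(tab) != "Total", , drop = FALSE])))
})

test_that("KS statistics behave at the identity and disjoint extremes", {
  set.seed(223)
  g <- runif(300, 0.3, 0.6)
  same <- gcCompare(list(a = g, b = g))
  expect_equal(same$ks["a", "b"], 0)
  disj <- gcCompare(list(lo = runif(200, 0, 0.2),
                         hi = runif(200, 0.8, 1)))
  expect_equal(disj$ks["lo", "hi"], 1)
  expect_error(gcCompare(list(a = numeric(0))), "empty")
})

test_that("the KS statistic approaches the closed-form value for normals", {
  set.seed(227)
  a <- rnorm(2000, 0.44, 0.03)
  b <- rnorm(2000, 0.51, 0.03)
  got <- gcCompare(list(a = a, b = b))$ks["a", "b"]
  # numeric-integration oracle: sup |Phi_a - Phi_b| over a fine grid
  grid <- seq(0.3, 0.65, by = 1e-4)
  want <- max(abs(pnorm(grid, 0.44, 0.03) - pnorm(grid, 0.51, 0.03)))
  expect_lt(abs(got - want), 0.05)
})

test_that("the pipeline is deterministic and writes a complete bundle", {
  p1 <- sampleProfile("S1", n_reads = 20, rrna_fraction = 0.2)
  p2 <- sampleProfile("S2", n_reads = 20, rrna_fraction = 0.2,
                      n_planted_ctld = 3, n_redundant_copies = 0)
  cfg <- simulationConfig(list(p1, p2), seed = 229)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- runPipeline(cfg, out_dir = d1)
  r2 <- runPipeline(cfg, out_dir = d2)
  expect_gt(length(list.files(d1)), 8)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # report composition matches the truth table within binomial error
  truth <- r1$sim@truthReads
  lab <- r1$partition@labels
  expect_equal(sum(lab$label == "rRNA"),
               sum(truth$fraction[match(lab$id, truth$id)] == "rRNA"))
})

test_that("an rRNA-only simulation degrades gracefully", {
  p <- sampleProfile("S1", n_reads = 15, rrna_fraction = 1)
  r <- runPipeline(simulationConfig(list(p), seed = 233))
  expect_equal(sum(r$partition@labels$label == "mRNA"), 0L)
  expect_null(r$clusters)
  expect_equal(nrow(r$domains), 0L)
  expect_null(r$tree)
})
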