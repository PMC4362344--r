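test_that("profile and config invariants are enforced", {
  expect_error(sampleProfile("S", taxon_mix = c(host = 0.6, sym = 0.6),
                             gc_by_taxon = c(host = 0.4, sym = 0.5)),
               "sum to 1")
  expect_error(sampleProfile("S", n_planted_ctld = 1, n_multidomain = 2),
               "n_multidomain")
  expect_error(sampleProfile("S", n_redundant_copies = 3), "redundant")
  p <- sampleProfile("S")
  expect_error(simulationConfig(list(p), mutation_rate = 0.5),
               "mutation_rate")
  expect_error(simulationConfig(list(p), read_length_min = 400),
               "read_length_min")
})

test_that("a JSON config round-trips into an equivalent simulation", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "seed": 59, "mutation_rate": 0.01, "n_shared_genes": 1,
    "profiles": [
      {"sample_id": "S1", "n_reads": 12, "rrna_fraction": 0.25,
       "taxon_mix": {"host": 0.6, "symbiont": 0.4},
       "gc_by_taxon": {"host": 0.42, "symbiont": 0.55}}
    ]
  }', f)
  cfg <- readSimulationConfig(f)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(cfg@seed, 59L)
  expect_equal(cfg@profiles[[1]]@taxon_mix,
               c(host = 0.6, symbiont = 0.4))
  sim1 <- simulateHolobiont(cfg)
  sim2 <- simulateHolobiont(
    simulationConfig(list(sampleProfile("S1", n_reads = 12,
      rrna_fraction = 0.25, taxon_mix = c(host = 0.6, symbiont = 0.4),
      gc_by_taxon = c(host = 0.42, symbiont = 0.55))),
      seed = 59, mutation_rate = 0.01, n_shared_genes = 1))
  expect_identical(as.character(unigeneSequences(sim1@reads)),
                   as.character(unigeneSequences(sim2@reads)))
})

test_that("a degenerate single-taxon mixture labels every read host", {
  p <- sampleProfile("S1", n_reads = 100, rrna_fraction = 0,
                     taxon_mix = c(host = 1),
                     gc_by_taxon = c(host = 0.45))
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 171))
  expect_equal(nrow(sim@truthReads), 100L)
  expect_true(all(sim@truthReads$taxon == "host"))
  expect_true(all(sim@truthReads$fraction == "mRNA"))
})

test_that("the generator is byte-identical for a fixed seed", {
  p <- sampleProfile("S1", n_reads = 25, rrna_fraction = 0.2,
                     n_planted_ctld = 1, n_redundant_copies = 0)
  cfg <- simulationConfig(list(p), seed = 173)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateHolobiont(cfg, out_dir = d1)
  simulateHolobiont(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("adding a sample does not perturb existing samples", {
  p1 <- sampleProfile("S1", n_reads = 20, rrna_fraction = 0.2)
  p2 <- sampleProfile("S2", n_reads = 20, rrna_fraction = 0.2)
  one <- simulateHolobiont(simulationConfig(list(p1), seed = 179))
  two <- simulateHolobiont(simulationConfig(list(p1, p2), seed = 179))
  s1_only <- two@reads[two@reads@sample == "S1"]
  expect_identical(as.character(unigeneSequences(s1_only)),
                   as.character(unigeneSequences(one@reads)))
})

test_that("per-taxon GC targets are met in expectation", {
  p <- sampleProfile("S1", n_reads = 4000, rrna_fraction = 0,
                     taxon_mix = c(host = 0.5, symbiont = 0.5),
                     gc_by_taxon = c(host = 0.40, symbiont = 0.55))
  cfg <- simulationConfig(list(p), seed = 181, mutation_rate = 0)
  sim <- simulateHolobiont(cfg)
  clean <- trimPolyA(sim@reads)
  gc <- gcContent(clean)
  taxon <- setNames(sim@truthReads$taxon, sim@truthReads$id)[names(gc)]
  mean_gc <- tapply(gc, taxon, mean)
  expect_lt(abs(mean_gc[["host"]] - 0.40), 0.02)
  expect_lt(abs(mean_gc[["symbiont"]] - 0.55), 0.02)
  # mixture property: pooled variance at least the per-taxon maximum
  expect_gte(stats::var(gc), max(tapply(gc, taxon, stats::var)))
  # taxon proportions within 3 binomial SD
  n <- length(gc)
  expect_lt(abs(sum(taxon == "host") - 0.5 * n), 3 * sqrt(n * 0.25) + 1)
})

test_that("some reads fall below the cleaning threshold by design", {
  p <- sampleProfile("S1", n_reads = 400, rrna_fraction = 0)
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 191))
  expect_gt(sum(sim@truthReads$length < 200), 0)
})

test_that("planted templates round-trip through every frame", {
  set.seed(193)
  tpl <- makeTemplate()
  for (fr in c(-3:-1, 1:3)) {
    nt <- plantCtld(tpl, fr)
    lab <- if (fr > 0) paste0("+", fr) else as.character(fr)
    expect_true(grepl(tpl, sixFrameTranslate(nt)[[lab]], fixed = TRUE))
  }
  expect_error(plantCtld("MKLVND", 1), "grammar")
  expect_error(plantCtld(tpl, 4), "frame")
})

test_that("random planted templates are recovered by the scanner", {
  set.seed(197)
  for (k in 1:10) {
    g1 <- sample(15:35, 1)
    tpl <- makeTemplate(g1 = g1, g2 = sample(40:70, 1),
                        g3 = sample(10:30, 1),
                        wigl = sample(c("WIGL", "WLGL", "WVGL"), 1),
                        sugar_at = g1 + 4)   # inside (cys2, cys3)
    fr <- sample(c(-3:-1, 1:3), 1)
    u <- UnigeneSet(setNames(plantCtld(tpl, fr), "u1"), sample = "S")
    lab <- if (fr > 0) paste0("+", fr) else as.character(fr)
    d <- scanCtld(u)
    d <- d[d$frame == lab, ]
    expect_equal(nrow(d), 1L)
    expect_equal(d$domain_seq, tpl)
    pos <- regexpr(tpl, sixFrameTranslate(plantCtld(tpl, fr))[[lab]],
                   fixed = TRUE)
    expect_equal(d$start, as.integer(pos) - 1L)
  }
})

test_that("planted domain truth coordinates match the scanner exactly", {
  p <- sampleProfile("S1", n_reads = 5, rrna_fraction = 0,
                     n_planted_ctld = 3, n_multidomain = 1,
                     n_redundant_copies = 2)
  sim <- simulateHolobiont(simulationConfig(list(p), seed = 199))
  reads <- trimPolyA(sim@reads)
  ctld_ids <- sim@truthReads$id[sim@truthReads$ctld]
  d <- scanCtld(reads[ctld_ids])
  expect_equal(nrow(d), nrow(sim@truthDomains))
  got <- d[order(d$unigene, d$frame, d$start),
           c("unigene", "frame", "start", "end", "wigl")]
  want <- sim@truthDomains[order(sim@truthDomains$read,
                                 sim@truthDomains$frame,
                                 sim@truthDomains$start),
                           c("read", "frame", "start", "end", "wigl")]
  expect_equal(unname(as.list(got)), unname(as.list(want)),
               ignore_attr = TRUE)
})
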